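# Fragment-based intergenomic similarity: ANI x aligned fraction.

#' Split a genome into consecutive fragments
#'
#' Non-overlapping windows of `fragment_len` nt; a terminal remainder shorter
#' than `fragment_len / 2` is dropped, otherwise kept as a short fragment.
#'
#' @param seq A nucleotide string.
#' @param fragment_len Window size in nt (>= 100).
#' @return A tibble with 1-based `start`, `end` and `seq` per fragment.
#' @export
#' @examples
#' nrow(fragment_genome(strrep("A", 10000), 3000)) # 3
fragment_genome <- function(seq, fragment_len = 3000L) {
  stopifnot(fragment_len >= 100)
  L <- nchar(seq)
  if (L < fragment_len / 2) {
    abort(paste0(
      "genome too short to fragment: ", L, " nt < fragment_len/2 = ",
      fragment_len / 2
    ))
  }
  n_full <- L %/% fragment_len
  starts <- fragment_len * (seq_len(n_full) - 1L) + 1L
  ends <- starts + fragment_len - 1L
  rem <- L - n_full * fragment_len
  if (rem >= fragment_len / 2) {
    starts <- c(starts, n_full * fragment_len + 1L)
    ends <- c(ends, L)
  }
  tibble::tibble(
    start = starts, end = ends,
    seq = substring(seq, starts, ends)
  )
}

# Encode every k-mer of a sequence as a base-4 integer code (NA where the
# window contains a non-ACGT base). Returned vector is parallel to start
# positions 1..(L-k+1).
kmer_codes <- function(seq, k = 13L) {
  b <- utf8ToInt(seq)
  map <- rep(NA_real_, 128)
  map[utf8ToInt("A")] <- 0
  map[utf8ToInt("C")] <- 1
  map[utf8ToInt("G")] <- 2
  map[utf8ToInt("T")] <- 3
  v <- map[b]
  n <- length(v) - k + 1L
  if (n < 1) {
    return(numeric(0))
  }
  code <- numeric(n)
  pow <- 4^((k - 1):0)
  for (j in seq_len(k)) {
    code <- code + v[j:(n + j - 1L)] * pow[j]
  }
  code
}

# Prebuilt seed index for a reference genome: sorted k-mer codes with their
# start positions, for binary-search lookup.
ani_reference_index <- function(seq, k = 13L) {
  codes <- kmer_codes(seq, k)
  keep <- which(!is.na(codes))
  ord <- keep[order(codes[keep])]
  list(
    seq = seq, k = k,
    codes = codes[ord], pos = ord,
    bytes = utf8ToInt(seq)
  )
}

# fast reverse complement for plain ACGTN strings
revcomp_fast <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

# Per-fragment encodings reusable across all references: bytes and sampled
# seed codes for both strands.
ani_query_cache <- function(frag_seqs, k = 13L, stride = 6L) {
  lapply(frag_seqs, function(fs) {
    enc <- function(s) {
      codes <- kmer_codes(s, k)
      if (length(codes) == 0) {
        return(list(codes = numeric(0), pos = integer(0), bytes = utf8ToInt(s)))
      }
      take <- seq(1L, length(codes), by = stride)
      fc <- codes[take]
      ok <- !is.na(fc)
      list(codes = fc[ok], pos = take[ok], bytes = utf8ToInt(s))
    }
    list(fwd = enc(fs), rev = enc(revcomp_fast(fs)), len = nchar(fs))
  })
}

# Core matcher on cached encodings; returns c(identity, matched 0/1).
# Each candidate diagonal is scored only over its seed-supported span (plus
# a one-stride margin), and near-disjoint spans on different diagonals are
# chained into one gapped local match -- so an insertion inside a fragment
# leaves the flanking homology matchable, as a gapped local aligner would.
# A fragment is matched iff the best (chained) span covers at least half of
# it at `min_identity`.
match_fragment_cached <- function(fc, ref, min_identity, n_diagonals = 3L,
                                  stride = 6L, k = 13L) {
  best_id <- 0
  best_ov <- 0
  half <- fc$len / 2
  for (side in c("fwd", "rev")) {
    e <- fc[[side]]
    if (length(e$codes) == 0) next
    hit <- findInterval(e$codes, ref$codes)
    valid <- hit >= 1L
    valid[valid] <- ref$codes[hit[valid]] == e$codes[valid]
    if (!any(valid)) next
    fpos <- e$pos[valid]
    offsets <- ref$pos[hit[valid]] - fpos
    tab <- sort(table(offsets), decreasing = TRUE)
    cand <- as.integer(names(tab))[seq_len(min(n_diagonals, length(tab)))]
    segs <- list()
    for (off in cand) {
      sup <- fpos[offsets == off]
      i1 <- max(1L, min(sup) - stride, 1L - off)
      i2 <- min(length(e$bytes), max(sup) + k - 1L + stride,
                length(ref$bytes) - off)
      if (i2 < i1) next
      len <- i2 - i1 + 1L
      nmatch <- sum(e$bytes[i1:i2] == ref$bytes[(i1 + off):(i2 + off)])
      segs[[length(segs) + 1L]] <- c(i1 = i1, i2 = i2, len = len, nm = nmatch)
    }
    if (length(segs) == 0) next
    # single best diagonal
    for (s in segs) {
      sc <- score_span(s["len"], s["nm"], half)
      if (!is.null(sc) && sc[1] > best_id) {
        best_id <- sc[1]
        best_ov <- sc[2]
      }
    }
    # chains of near-disjoint diagonals (gapped match across an indel)
    if (length(segs) > 1) {
      ord <- order(vapply(segs, `[`, numeric(1), "i1"))
      segs <- segs[ord]
      cur <- segs[[1]]
      for (j in 2:length(segs)) {
        nxt <- segs[[j]]
        ovl <- cur["i2"] - nxt["i1"] + 1
        if (ovl <= 0.25 * min(cur["len"], nxt["len"])) {
          add <- max(0, nxt["len"] - max(0, ovl))
          cur <- c(
            i1 = unname(cur["i1"]), i2 = unname(max(cur["i2"], nxt["i2"])),
            len = unname(cur["len"] + add),
            nm = unname(cur["nm"] + nxt["nm"] * add / nxt["len"])
          )
        }
      }
      sc <- score_span(cur["len"], cur["nm"], half)
      if (!is.null(sc) && sc[1] > best_id) {
        best_id <- sc[1]
        best_ov <- sc[2]
      }
    }
  }
  c(
    identity = best_id,
    matched = as.numeric(best_ov >= half && best_id >= min_identity)
  )
}

score_span <- function(len, nm, half) {
  if (len < half) {
    return(NULL)
  }
  c(min(100, 100 * nm / len), len)
}

# Directed similarity from cached query fragments against a reference index.
directed_similarity <- function(qcache, ref_idx, min_identity) {
  hits <- vapply(qcache, match_fragment_cached,
    numeric(2),
    ref = ref_idx, min_identity = min_identity
  )
  n_tot <- length(qcache)
  matched <- hits["matched", ] > 0
  n_match <- sum(matched)
  ani <- if (n_match > 0) mean(hits["identity", matched]) else 0
  af <- n_match / n_tot
  c(ani = ani, af = af, s = ani * af, n_total = n_tot, n_matched = n_match)
}

#' Best orthologous match of a fragment against a reference genome
#'
#' Seeds with exact shared k-mers, votes on the implied diagonal offsets and
#' scores the best diagonals by column identity over the overlapping span
#' (both strands are searched). A match is reported iff the best identity
#' reaches `min_identity` over at least half the fragment length.
#'
#' @param fragment A fragment sequence (nt string).
#' @param ref A reference genome string, or an index prebuilt internally.
#' @param min_identity Percent identity required to call a match.
#' @param k Seed word length.
#' @param stride Sampling stride for fragment seed words.
#' @param n_diagonals Number of top-voted diagonals to score.
#' @return One-row tibble: `identity`, `matched` (logical), `strand`.
#' @export
match_fragment <- function(fragment, ref, min_identity = 80, k = 13L,
                           stride = 6L, n_diagonals = 3L) {
  if (is.character(ref)) {
    ref <- ani_reference_index(ref, k)
  }
  fc <- ani_query_cache(fragment, k = ref$k, stride = stride)[[1]]
  per_side <- lapply(c(fwd = "fwd", rev = "rev"), function(side) {
    one <- fc
    other <- setdiff(c("fwd", "rev"), side)
    one[[other]]$codes <- numeric(0)
    match_fragment_cached(one, ref, min_identity, n_diagonals)
  })
  ids <- vapply(per_side, `[[`, numeric(1), "identity")
  best <- which.max(ids)
  res <- per_side[[best]]
  tibble::tibble(
    identity = unname(res["identity"]),
    matched = res["matched"] > 0,
    strand = if (res["identity"] > 0) c("+", "-")[best] else NA_character_
  )
}

#' Directed fragment-based similarity between two genomes
#'
#' Fragments the query, matches each fragment against the reference, and
#' reports ANI (mean identity over matched fragments), the aligned fraction
#' AF (matched / total fragments) and the intergenomic similarity
#' `S = ANI x AF` (percent; e.g. ANI 99 with AF 0.99 gives S 98.01).
#'
#' @param query,ref Nucleotide strings.
#' @param fragment_len Fragment window (nt).
#' @param min_identity Fragment match threshold (percent).
#' @return One-row tibble: `ani`, `af`, `s`, `n_fragments_total`,
#'   `n_fragments_matched`.
#' @export
pair_similarity <- function(query, ref, fragment_len = 3000L,
                            min_identity = 80) {
  frags <- fragment_genome(query, fragment_len)
  idx <- ani_reference_index(ref)
  qc <- ani_query_cache(frags$seq)
  r <- directed_similarity(qc, idx, min_identity)
  tibble::tibble(
    ani = unname(r["ani"]), af = unname(r["af"]), s = unname(r["s"]),
    n_fragments_total = as.integer(r["n_total"]),
    n_fragments_matched = as.integer(r["n_matched"])
  )
}

#' Symmetrised intergenomic similarity matrix
#'
#' Computes the directed similarity `S` for every ordered genome pair and
#' averages the two directions; the diagonal is 100 by definition. Values
#' below 0.01 are floored to 0.
#'
#' @param genomes A genome tibble (>= 2 rows) with `genome_id` and `seq`.
#' @param fragment_len,min_identity See [pair_similarity()].
#' @return A `similarity_matrix`: a symmetric numeric matrix (percent) with
#'   genome ids as dimnames and attributes `ani` and `af` holding the
#'   directed components, and `pairs` the long directed results.
#' @export
similarity_matrix <- function(genomes, fragment_len = 3000L,
                              min_identity = 80) {
  n <- nrow(genomes)
  if (n < 2) {
    abort(">= 2 genomes required for a similarity matrix")
  }
  ids <- genomes$genome_id
  if (anyDuplicated(ids)) {
    abort("duplicate genome ids")
  }
  idx <- lapply(genomes$seq, ani_reference_index)
  names(idx) <- ids
  caches <- lapply(genomes$seq, function(s) {
    ani_query_cache(fragment_genome(s, fragment_len)$seq)
  })
  names(caches) <- ids
  pairs <- tidyr::expand_grid(query = ids, ref = ids) |>
    dplyr::filter(.data$query != .data$ref)
  res <- purrr::map2_dfr(pairs$query, pairs$ref, function(q, r) {
    v <- directed_similarity(caches[[q]], idx[[r]], min_identity)
    tibble::tibble(
      query = q, ref = r, ani = unname(v["ani"]), af = unname(v["af"]),
      s = unname(v["s"]),
      n_fragments_total = as.integer(v["n_total"]),
      n_fragments_matched = as.integer(v["n_matched"])
    )
  })
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(res))) {
    m[res$query[i], res$ref[i]] <- res$s[i]
  }
  m <- (m + t(m)) / 2
  diag(m) <- 100
  m[m < 0.01] <- 0
  structure(m,
    class = c("similarity_matrix", "matrix", "array"),
    pairs = res
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", nrow(x), " genomes (S = ANI x AF, percent)\n")
  print(round(unclass(x)[, , drop = FALSE], 2))
  invisible(x)
}

#' Tidy a similarity matrix into long pairs
#'
#' @param x A `similarity_matrix`.
#' @param directed Return the directed per-pair results (with ANI/AF
#'   components) instead of the symmetrised matrix cells.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.similarity_matrix <- function(x, directed = FALSE, ...) {
  if (directed) {
    return(attr(x, "pairs"))
  }
  ids <- rownames(x)
  tidyr::expand_grid(genome_a = ids, genome_b = ids) |>
    dplyr::mutate(s = as.vector(t(unclass(x))))
}

#' Similarity heatmap
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot heatmap with rows/columns ordered by single-linkage
#'   clustering on `100 - S`.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  m <- unclass(object)
  ord <- rownames(m)
  if (nrow(m) > 2) {
    hc <- stats::hclust(stats::as.dist(100 - m), method = "single")
    ord <- rownames(m)[hc$order]
  }
  df <- tidy(object) |>
    dplyr::mutate(
      genome_a = factor(.data$genome_a, levels = ord),
      genome_b = factor(.data$genome_b, levels = ord)
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$genome_a, y = .data$genome_b,
    fill = .data$s
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "S (%)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
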