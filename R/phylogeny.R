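# Concatenated core-protein phylogeny: alignment, distances, NJ, bootstrap,
# midpoint rooting. Alignments are named character vectors (taxon -> gapped
# row); trees are ape "phylo" objects with bootstrap supports as node labels.

#' Multiple sequence alignment of protein sequences
#'
#' Aligns amino-acid sequences with MAFFT (progressive FFT-NS-2: pairwise
#' k-mer distances, guide tree, progressive profile-profile merge with affine
#' gaps; deterministic for fixed input). A single sequence is returned
#' unchanged.
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @return Named character vector of equal-width gapped rows (uppercase).
#' @export
align_proteins <- function(seqs) {
  if (length(seqs) == 0) {
    abort("align_proteins: no sequences")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("align_proteins: sequences must have unique names")
  }
  if (length(seqs) == 1) {
    return(toupper(seqs))
  }
  if (Sys.which("mafft") == "") {
    abort("align_proteins: the 'mafft' executable is not on PATH")
  }
  fin <- tempfile(fileext = ".faa")
  fout <- tempfile(fileext = ".aln")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fin)
  status <- system2("mafft",
    c("--quiet", "--amino", "--retree", "2", "--maxiterate", "0", fin),
    stdout = fout, stderr = FALSE
  )
  if (status != 0) {
    abort(paste0("mafft failed with exit status ", status))
  }
  out <- Biostrings::readAAStringSet(fout)
  aln <- toupper(as.character(out))
  names(aln) <- sub("\\s.*$", "", names(out))
  aln[names(seqs)]
}

#' Concatenate per-cluster alignments into a supermatrix over genomes
#'
#' Each alignment contributes one block; a genome missing from a cluster
#' receives an all-gap block. Block boundaries are recorded as a partition
#' table (1-based inclusive columns).
#'
#' @param alignments Named list of alignments (named character vectors whose
#'   names are genome ids; at most one row per genome).
#' @param genomes Optional genome set for the rows; defaults to the union of
#'   taxa across blocks. A genome absent from every block is an error.
#' @return A list of class `concat_alignment`: `alignment` (named character
#'   vector over genomes) and `partitions` (tibble `cluster_id`, `start`,
#'   `end`).
#' @export
concatenate_alignments <- function(alignments, genomes = NULL) {
  if (length(alignments) == 0) {
    abort("concatenate_alignments: no alignments")
  }
  if (is.null(names(alignments))) {
    names(alignments) <- paste0("block", seq_along(alignments))
  }
  seen <- unique(unlist(lapply(alignments, names)))
  genomes <- genomes %||% sort(seen)
  absent <- setdiff(genomes, seen)
  if (length(absent) > 0) {
    abort(paste0(
      "genome(s) absent from every alignment block: ",
      paste(absent, collapse = ", ")
    ))
  }
  widths <- vapply(
    alignments,
    function(a) unique(nchar(a))[1], numeric(1)
  )
  for (i in seq_along(alignments)) {
    if (length(unique(nchar(alignments[[i]]))) != 1) {
      abort(paste0("ragged alignment block: ", names(alignments)[i]))
    }
  }
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  rows <- vapply(genomes, function(g) {
    paste(vapply(seq_along(alignments), function(i) {
      a <- alignments[[i]]
      if (g %in% names(a)) a[[g]] else strrep("-", widths[i])
    }, character(1)), collapse = "")
  }, character(1))
  structure(
    list(
      alignment = rows,
      partitions = tibble::tibble(
        cluster_id = names(alignments),
        start = as.integer(starts), end = as.integer(ends)
      )
    ),
    class = "concat_alignment"
  )
}

# Alignment (named character vector) to an integer matrix; gaps and X/? are NA.
alignment_matrix <- function(aln) {
  if (inherits(aln, "concat_alignment")) aln <- aln$alignment
  chars <- strsplit(aln, "")
  w <- unique(lengths(chars))
  if (length(w) != 1) {
    abort("alignment rows have unequal widths")
  }
  lv <- strsplit("ACDEFGHIKLMNPQRSTVWY*", "")[[1]]
  m <- matrix(
    match(unlist(chars), lv),
    nrow = length(aln), byrow = TRUE,
    dimnames = list(names(aln), NULL)
  )
  m
}

#' Poisson-corrected protein distance matrix
#'
#' Pairwise p-distance over columns where neither row has a gap or ambiguous
#' residue (pairwise deletion), Poisson-corrected as `d = -ln(1 - p)`.
#' `p >= 0.95` is clamped to 0.95 with a warning (distance saturation).
#'
#' @param aln An alignment (named character vector) or a
#'   [concatenate_alignments()] result.
#' @param correction `"poisson"` (default) or `"p"` for the raw p-distance.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
protein_distance <- function(aln, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  m <- alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2) {
    abort("protein_distance: >= 2 sequences required")
  }
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  clamped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      nc <- sum(ok)
      if (nc == 0) {
        abort(paste0(
          "no comparable columns between '", rownames(m)[i],
          "' and '", rownames(m)[j], "'"
        ))
      }
      p <- sum(m[i, ok] != m[j, ok]) / nc
      if (correction == "poisson") {
        if (p >= 0.95) {
          p <- 0.95
          clamped <- TRUE
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  if (clamped) {
    warn("protein_distance: p-distance >= 0.95 clamped (saturation)")
  }
  d
}

# Redistribute negative NJ branch lengths: each negative edge is set to zero
# and its (negative) excess moved onto the sibling edge(s) at the same node,
# preserving path lengths through the parent as far as possible.
fix_negative_branches <- function(tree) {
  for (pass in 1:3) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    for (i in neg) {
      excess <- tree$edge.length[i]
      sib <- setdiff(which(tree$edge[, 1] == tree$edge[i, 1]), i)
      if (length(sib) > 0) {
        tree$edge.length[sib] <- tree$edge.length[sib] + excess / length(sib)
      }
      tree$edge.length[i] <- 0
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (exact on additive distances); negative branch
#' lengths are clamped to zero with the excess moved to the sibling edge.
#'
#' @param dist A symmetric distance matrix with labelled dimnames (n >= 2).
#' @return An unrooted `ape::phylo` tree (rooted two-taxon tree for n = 2).
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) {
    abort("nj_tree: distance matrix must be symmetric")
  }
  n <- nrow(dist)
  if (n < 2) {
    abort("nj_tree: >= 2 taxa required")
  }
  if (n == 2) {
    lab <- rownames(dist)
    txt <- sprintf(
      "(%s:%f,%s:%f);", lab[1], dist[1, 2] / 2, lab[2],
      dist[1, 2] / 2
    )
    return(ape::read.tree(text = txt))
  }
  fix_negative_branches(ape::nj(stats::as.dist(dist)))
}

#' Column-resampling bootstrap supports for the NJ pipeline
#'
#' Recomputes distance + NJ on alignments whose columns are resampled with
#' replacement; the support of each internal bipartition of the full-data
#' tree is the percentage of replicates containing it. Supports are attached
#' as node labels.
#'
#' @param aln An alignment (named character vector) or
#'   [concatenate_alignments()] result, >= 3 taxa.
#' @param n_reps Number of replicates (>= 1).
#' @param seed RNG seed (recorded in the result as attribute `seed`).
#' @param correction Distance correction, see [protein_distance()].
#' @return The full-data NJ tree with `node.label` giving percent support
#'   (`NA` for the root).
#' @export
bootstrap_tree <- function(aln, n_reps = 100L, seed = 1L,
                           correction = "poisson") {
  m_full <- if (inherits(aln, "concat_alignment")) aln$alignment else aln
  main <- nj_tree(protein_distance(m_full, correction))
  chars <- strsplit(m_full, "")
  w <- unique(lengths(chars))[1]
  boot <- with_local_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(w, w, replace = TRUE)
      res <- vapply(
        chars, function(x) paste(x[cols], collapse = ""),
        character(1)
      )
      tryCatch(
        nj_tree(suppressWarnings(protein_distance(res, correction))),
        error = function(e) NULL
      )
    })
  })
  boot <- boot[!vapply(boot, is.null, logical(1))]
  counts <- ape::prop.clades(main, boot, rooted = FALSE)
  supports <- round(100 * counts / length(boot), 1)
  main$node.label <- ifelse(is.na(supports), "", as.character(supports))
  attr(main, "seed") <- seed
  attr(main, "n_reps") <- n_reps
  main
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path,
#' preserving all pairwise leaf path lengths. Node labels (bootstrap
#' supports) are carried through.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return A rooted `ape::phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (ape::Ntip(tree) < 2) {
    abort("midpoint_root: >= 2 leaves required")
  }
  if (ape::Ntip(tree) == 2) {
    return(tree)
  }
  has_labels <- !is.null(tree$node.label)
  phangorn::midpoint(tree,
    node.labels = if (has_labels) "support" else "delete"
  )
}

#' Leaf sets of the two child clades of a rooted tree's root
#'
#' @param tree A rooted `ape::phylo`.
#' @return A list of character vectors (one per root child), with an
#'   attribute `support` giving the numeric support of the root bipartition
#'   (`NA` when no internal child carries a label).
#' @export
root_bipartition <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  clades <- lapply(kids, function(k) {
    if (k <= ntip) {
      tree$tip.label[k]
    } else {
      ape::extract.clade(tree, k)$tip.label
    }
  })
  sup <- NA_real_
  internal <- kids[kids > ntip]
  if (!is.null(tree$node.label) && length(internal) > 0) {
    vals <- suppressWarnings(
      as.numeric(tree$node.label[internal - ntip])
    )
    if (any(!is.na(vals))) sup <- max(vals, na.rm = TRUE)
  }
  attr(clades, "support") <- sup
  clades
}
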