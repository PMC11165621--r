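# Independent oracles and small fixture builders used across tests.

# --- union-find (independent of igraph) -------------------------------------
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) {
  while (p[i] != i) i <- p[i]
  i
}
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i)
  rj <- uf_find(p, j)
  if (ri != rj) p[rj] <- ri
  p
}

# Brute-force connected-component clustering over all protein pairs using
# pairwise_identity() one pair at a time (no prefilter, no batching).
brute_force_clusters <- function(proteins, identity_threshold, coverage_threshold) {
  n <- nrow(proteins)
  p <- uf_new(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- pairwise_identity(proteins$seq[i], proteins$seq[j])
      if (pid$identity >= identity_threshold &&
        pid$coverage_a >= coverage_threshold &&
        pid$coverage_b >= coverage_threshold) {
        p <- uf_union(p, i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(p, i), integer(1))
  split(proteins$protein_id, roots)
}

# Canonical form of a partition (set of sorted member sets), so two
# partitions can be compared irrespective of labels.
canonical_partition <- function(groups) {
  unname(sort(vapply(
    groups,
    function(g) paste(sort(g), collapse = "|"), character(1)
  )))
}

# partition tibble/vector -> canonical form
partition_of <- function(labels, ids) {
  canonical_partition(split(ids, labels))
}

# --- random protein generator ----------------------------------------------
random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
    collapse = ""
  )
}

mutate_protein <- function(seq, n_subs) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), n_subs)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(aas, v[p]), 1)
  paste(v, collapse = "")
}

# A protein set with planted families: `n_fam` base proteins, each with
# copies at the given substitution counts, plus unrelated singletons.
planted_protein_set <- function(n_fam = 8, copies = 2, sub_frac = 0.1,
                                len = 80, n_single = 10, seed = 1) {
  set.seed(seed)
  out <- list()
  for (f in seq_len(n_fam)) {
    base <- random_protein(len)
    out[[length(out) + 1]] <- tibble::tibble(
      protein_id = sprintf("f%02d_m0", f),
      genome_id = "g1", seq = base, family = f
    )
    for (c in seq_len(copies)) {
      out[[length(out) + 1]] <- tibble::tibble(
        protein_id = sprintf("f%02d_m%d", f, c),
        genome_id = paste0("g", c + 1),
        seq = mutate_protein(base, round(sub_frac * len)), family = f
      )
    }
  }
  for (s in seq_len(n_single)) {
    out[[length(out) + 1]] <- tibble::tibble(
      protein_id = sprintf("s%02d", s),
      genome_id = "g1", seq = random_protein(len), family = NA
    )
  }
  dplyr::bind_rows(out)
}

# --- exhaustive three-sequence alignment oracle -----------------------------
# Maximum sum-of-pairs score over all three-way alignments, by dynamic
# programming over the (n1+1) x (n2+1) x (n3+1) lattice with linear gap
# costs. Small inputs only.
sp_score_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (a == "-" && b == "-") {
    return(0)
  }
  if (a == "-" || b == "-") {
    return(gap)
  }
  if (a == b) match else mismatch
}

exhaustive_msa3_score <- function(s1, s2, s3, match = 1, mismatch = -1,
                                  gap = -2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  c3 <- strsplit(s3, "")[[1]]
  n1 <- length(a)
  n2 <- length(b)
  n3 <- length(c3)
  D <- array(-Inf, dim = c(n1 + 1, n2 + 1, n3 + 1))
  D[1, 1, 1] <- 0
  moves <- expand.grid(i = 0:1, j = 0:1, k = 0:1)
  moves <- moves[rowSums(moves) > 0, ]
  for (i in 0:n1) {
    for (j in 0:n2) {
      for (k in 0:n3) {
        if (i == 0 && j == 0 && k == 0) next
        best <- -Inf
        for (m in seq_len(nrow(moves))) {
          di <- moves$i[m]
          dj <- moves$j[m]
          dk <- moves$k[m]
          pi <- i - di
          pj <- j - dj
          pk <- k - dk
          if (pi < 0 || pj < 0 || pk < 0) next
          ca <- if (di == 1) a[i] else "-"
          cb <- if (dj == 1) b[j] else "-"
          cc <- if (dk == 1) c3[k] else "-"
          sc <- D[pi + 1, pj + 1, pk + 1] +
            sp_score_pair(ca, cb, match, mismatch, gap) +
            sp_score_pair(ca, cc, match, mismatch, gap) +
            sp_score_pair(cb, cc, match, mismatch, gap)
          if (sc > best) best <- sc
        }
        D[i + 1, j + 1, k + 1] <- best
      }
    }
  }
  D[n1 + 1, n2 + 1, n3 + 1]
}

# Sum-of-pairs score of a given alignment under the same scoring scheme.
alignment_sp_score <- function(aln, match = 1, mismatch = -1, gap = -2) {
  rows <- strsplit(aln, "")
  w <- length(rows[[1]])
  total <- 0
  for (i in seq_along(rows)) {
    for (j in seq_len(i - 1)) {
      for (col in seq_len(w)) {
        total <- total + sp_score_pair(rows[[i]][col], rows[[j]][col],
          match, mismatch, gap
        )
      }
    }
  }
  total
}

# --- trees ------------------------------------------------------------------
# Path-length matrix between leaves of an ape tree.
leaf_distances <- function(tree) {
  d <- ape::dist.nodes(tree)[seq_along(tree$tip.label), seq_along(tree$tip.label)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# --- misc -------------------------------------------------------------------
tiny_taxa <- function() {
  tibble::tibble(
    genome_id = sprintf("t%02d", 1:6),
    family = "famA",
    subfamily = "sfA",
    genus = rep(c("gA", "gB"), each = 3),
    species = c("sp1", "sp1", "sp2", "sp3", "sp3", "sp4")
  )
}

tiny_clade <- function(seed = 11) {
  spec <- clade_spec(
    tiny_taxa(),
    core_families = 4L,
    accessory = list(
      family = 4L, subfamily = 3L, genus = 6L,
      species = 3L, strain_gain = 1L
    )
  )
  simulate_clade(spec, seed)
}
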