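test_that("pairwise identity matches hand-computed cases", {
  id <- pairwise_identity(strrep("ACDEFGHIKL", 10), strrep("ACDEFGHIKL", 10))
  expect_equal(id$identity, 100)
  expect_equal(id$coverage_a, 1)
  expect_equal(id$coverage_b, 1)

  # single substitution, no gaps possible at the optimum: 8/9 matches
  id <- pairwise_identity("ACDEFGHIK", "ACDEFGHIR")
  expect_equal(id$identity, 100 * 8 / 9, tolerance = 1e-9)

  expect_lt(pairwise_identity("AAAA", "CCCC")$identity, 1)
  expect_error(pairwise_identity("", "AC"), "empty")
})

test_that("connected-component clustering equals the brute-force union-find oracle", {
  prot <- planted_protein_set(
    n_fam = 8, copies = 2, sub_frac = 0.12,
    len = 80, n_single = 10, seed = 1
  ) # 34 proteins
  prot <- prot[seq_len(min(nrow(prot), 50)), ]
  for (thr in c(70, 50)) {
    oracle <- brute_force_clusters(prot, thr, 0.8)
    got <- cluster_proteins(prot, thr, 0.8)
    expect_equal(
      partition_of(got$cluster_id, got$protein_id),
      canonical_partition(oracle)
    )
  }
})

test_that("prefiltered clustering equals exhaustive all-vs-all clustering", {
  prot <- planted_protein_set(n_fam = 6, copies = 2, len = 70, n_single = 8, seed = 2)
  a <- cluster_proteins(prot, 70, 0.8, prefilter = TRUE)
  b <- cluster_proteins(prot, 70, 0.8, prefilter = FALSE)
  expect_equal(
    partition_of(a$cluster_id, a$protein_id),
    partition_of(b$cluster_id, b$protein_id)
  )
})

test_that("clustering is transitive through intermediates and order-invariant", {
  # A-B and B-C above threshold, A-C below: one component
  base <- random_protein(60, seed = 5)
  b <- mutate_protein(base, 12)
  c3 <- mutate_protein(b, 12)
  prot <- tibble::tibble(
    protein_id = c("A", "B", "C"), genome_id = "g",
    seq = c(base, b, c3)
  )
  iab <- pairwise_identity(base, b)$identity
  ibc <- pairwise_identity(b, c3)$identity
  iac <- pairwise_identity(base, c3)$identity
  thr <- min(iab, ibc) - 1
  expect_gt(thr, iac) # construction check: A-C really below threshold
  cl <- cluster_proteins(prot, thr, 0.5)
  expect_equal(length(unique(cl$cluster_id)), 1)

  shuf <- prot[c(3, 1, 2), ]
  cl2 <- cluster_proteins(shuf, thr, 0.5)
  expect_equal(
    partition_of(cl$cluster_id, cl$protein_id),
    partition_of(cl2$cluster_id, cl2$protein_id)
  )
})

test_that("lowering the identity threshold only merges clusters", {
  prot <- planted_protein_set(n_fam = 5, copies = 2, len = 70, n_single = 6, seed = 3)
  thresholds <- c(90, 70, 50, 25)
  parts <- lapply(thresholds, function(t) {
    cl <- cluster_proteins(prot, t, 0.5)
    setNames(cl$cluster_id, cl$protein_id)
  })
  for (i in seq_len(length(thresholds) - 1)) {
    fine <- parts[[i]]
    coarse <- parts[[i + 1]]
    # each fine cluster maps into exactly one coarse cluster
    for (cl in unique(fine)) {
      members <- names(fine)[fine == cl]
      expect_equal(length(unique(coarse[members])), 1)
    }
  }
})

test_that("pangenome matrix bookkeeping and core extraction are exact", {
  cl <- tiny_clade(seed = 4)
  clusters <- cluster_proteins(cl$proteins, 70, 0.8)
  pg <- pangenome_matrix(clusters, genomes = cl$genomes$genome_id)
  # column sums equal per-genome protein counts
  expect_equal(
    unname(colSums(pg$matrix)[sort(unique(cl$proteins$genome_id))]),
    unname(as.integer(table(cl$proteins$genome_id)))
  )
  # planted universal families are recovered exactly as core clusters
  truth_core <- cl$presence |>
    dplyr::count(.data$family_id) |>
    dplyr::filter(.data$n == nrow(cl$genomes)) |>
    dplyr::pull(.data$family_id)
  expect_equal(length(core_clusters(pg)), length(truth_core))
  expect_error(core_clusters(pg, character(0)), "empty")
  expect_error(core_clusters(pg, "nope"), "absent")

  # single genome: all its clusters are core
  solo <- cluster_proteins(cl$proteins[cl$proteins$genome_id == "t01", ], 70, 0.8)
  pg1 <- pangenome_matrix(solo)
  expect_equal(length(core_clusters(pg1)), nrow(pg1$matrix))
})

test_that("cluster function labels follow the majority rule with flagged ties", {
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c1", "c1", "c2", "c3", "c3"),
    protein_id = paste0("p", 1:6),
    genome_id = "g"
  )
  ann <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p5", "p6"),
    label = c("terminase", "terminase", "portal", "a", "b")
  )
  fn <- cluster_function(clusters, ann)
  expect_equal(fn$function_label[fn$cluster_id == "c1"], "terminase")
  expect_false(fn$tie_flag[fn$cluster_id == "c1"])
  expect_equal(fn$function_label[fn$cluster_id == "c2"], "unknown function")
  expect_equal(fn$function_label[fn$cluster_id == "c3"], "a")
  expect_true(fn$tie_flag[fn$cluster_id == "c3"])
})

test_that("presence/absence dendrogram uses Jaccard distances", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 0, 1)), 1 - 1 / 3)
  expect_equal(jaccard_distance(c(1, 1), c(1, 1)), 0)

  m <- matrix(
    c(
      1, 1, 0,
      1, 1, 0,
      0, 1, 1
    ),
    nrow = 3, byrow = FALSE,
    dimnames = list(paste0("c", 1:3), c("gA", "gB", "gC"))
  )
  pg <- structure(list(matrix = m, clusters = NULL), class = "pangenome")
  dnd <- presence_absence_dendrogram(pg)
  # identical profiles merge first
  d <- leaf_distances(dnd)
  expect_lt(d["gA", "gB"], d["gA", "gC"])
})

test_that("tidy/glance summaries are consistent with the matrix", {
  cl <- tiny_clade(seed = 4)
  clusters <- cluster_proteins(cl$proteins, 70, 0.8)
  pg <- pangenome_matrix(clusters, genomes = cl$genomes$genome_id)
  td <- tidy(pg)
  expect_equal(nrow(td), nrow(pg$matrix) * ncol(pg$matrix))
  expect_equal(sum(td$n_members), sum(pg$matrix))
  gl <- glance(pg)
  expect_equal(gl$n_clusters, nrow(pg$matrix))
  expect_equal(gl$n_core, length(core_clusters(pg)))
})
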