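sim_from_matrix <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  diag(m) <- 100
  structure((m + t(m)) / 2,
    class = c("similarity_matrix", "matrix", "array")
  )
}

test_that("threshold clustering is single-linkage through intermediates", {
  # a borderline strain linked to the species core via intermediates
  ids <- paste0("B", 1:9)
  m <- matrix(97, 9, 9)
  m[4, c(1, 9)] <- m[c(1, 9), 4] <- 93 # B4 below 95 vs B1/B9 only
  sim <- sim_from_matrix(m, ids)
  part <- cluster_by_threshold(sim, 95, "sp")
  expect_equal(length(unique(part$taxon)), 1)

  # a pair at 99.36 with threshold 95: same species
  m2 <- matrix(99.36, 2, 2)
  part2 <- cluster_by_threshold(sim_from_matrix(m2, c("p1", "p2")), 95, "sp")
  expect_equal(length(unique(part2$taxon)), 1)

  # all pairs below threshold: singletons
  m3 <- matrix(10, 4, 4)
  part3 <- cluster_by_threshold(sim_from_matrix(m3, paste0("g", 1:4)), 95, "sp")
  expect_equal(length(unique(part3$taxon)), 4)
})

test_that("a higher threshold always refines the lower-threshold partition", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 8
    m <- matrix(runif(n * n, 0, 100), n, n)
    sim <- sim_from_matrix(m, paste0("g", 1:n))
    fine <- cluster_by_threshold(sim, 95, "a")
    coarse <- cluster_by_threshold(sim, 70, "b")
    fv <- setNames(fine$taxon, fine$genome_id)
    cv <- setNames(coarse$taxon, coarse$genome_id)
    for (taxon in unique(fv)) {
      members <- names(fv)[fv == taxon]
      expect_equal(length(unique(cv[members])), 1)
    }
  }
})

test_that("families come from shared-cluster connectivity, outliers stand alone", {
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c1", "c2", "c2", "c3"),
    protein_id = paste0("p", 1:5),
    genome_id = c("g1", "g2", "g2", "g3", "gX")
  )
  pg <- pangenome_matrix(clusters)
  fam <- assign_family(pg)
  fv <- setNames(fam$family, fam$genome_id)
  expect_equal(length(unique(fv[c("g1", "g2", "g3")])), 1) # linked via g2
  expect_false(fv[["gX"]] %in% fv[c("g1", "g2", "g3")])

  # fully connected sharing graph: one family
  all_shared <- tibble::tibble(
    cluster_id = "c1", protein_id = paste0("q", 1:3),
    genome_id = paste0("g", 1:3)
  )
  fam2 <- assign_family(pangenome_matrix(all_shared))
  expect_equal(length(unique(fam2$family)), 1)
})

test_that("the outlier link diagnostic reports the highest connecting identity level", {
  set.seed(37)
  base <- random_protein(120)
  prot <- tibble::tibble(
    protein_id = c("a|1", "b|1", "x|1"),
    genome_id = c("a", "b", "x"),
    seq = c(base, mutate_protein(base, 6), mutate_protein(base, 60))
  )
  diag <- outlier_link_threshold(prot, "x", coverage_threshold = 0.8)
  true_best <- max(
    pairwise_identity(prot$seq[3], prot$seq[1])$identity,
    pairwise_identity(prot$seq[3], prot$seq[2])$identity
  )
  expect_equal(diag$max_identity, true_best, tolerance = 1e-6)
  expect_equal(diag$link_threshold, 5 * floor(true_best / 5))
  expect_error(outlier_link_threshold(prot, "zz"), "not found")
})

test_that("subfamilies follow the supported root bipartition with a fallback", {
  tr <- ape::read.tree(text = "((a:1,b:1)100:3,(c:1,d:1)100:3);")
  tr$node.label <- c("", "100", "100")
  sf <- assign_subfamily(tr, c("a", "b", "c", "d"), min_support = 95)
  expect_equal(length(sf), 2)
  expect_setequal(
    vapply(sf, function(x) paste(sort(x), collapse = ","), character(1)),
    c("a,b", "c,d")
  )

  tr$node.label <- c("", "60", "60") # weak support: stay one subfamily
  expect_warning(
    sf2 <- assign_subfamily(tr, c("a", "b", "c", "d"), min_support = 95),
    "support"
  )
  expect_equal(length(sf2), 1)

  expect_equal(assign_subfamily(NULL, "solo"), list("solo"))
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(length(assign_subfamily(two, c("a", "b"))), 1)
})

test_that("build_taxonomy produces nested ranks with deterministic labels", {
  ids <- c("g1", "g2", "g3", "g4", "gX")
  m <- matrix(0, 5, 5)
  m[1, 2] <- m[2, 1] <- 97 # one species
  m[3, 4] <- m[4, 3] <- 80 # same genus, two species
  m[1, 3] <- m[3, 1] <- m[1, 4] <- m[2, 3] <- 0
  sim <- sim_from_matrix(m, ids)
  families <- tibble::tibble(
    genome_id = ids,
    family = c("fam1", "fam1", "fam1", "fam1", "fam2")
  )
  tax <- build_taxonomy(sim, families)
  expect_s3_class(tax, "taxonomy_assignment")
  expect_equal(length(unique(tax$species)), 4)
  expect_equal(length(unique(tax$genus)), 3)
  expect_equal(length(unique(tax$family)), 2)
  tv <- setNames(tax$species, tax$genome_id)
  expect_equal(tv[["g1"]], tv[["g2"]])
  gv <- setNames(tax$genus, tax$genome_id)
  expect_equal(gv[["g3"]], gv[["g4"]])
  expect_true(all(tax$order == "order1"))

  # determinism
  tax2 <- build_taxonomy(sim, families)
  expect_identical(tibble::as_tibble(tax), tibble::as_tibble(tax2))

  # name map renames placeholders
  tax3 <- build_taxonomy(sim, families,
    name_map = c(fam1 = "Gutmegaviridae")
  )
  expect_true("Gutmegaviridae" %in% tax3$family)
})

test_that("nesting violations are hard errors naming the genomes", {
  ids <- c("g1", "g2")
  m <- matrix(96, 2, 2) # one species
  sim <- sim_from_matrix(m, ids)
  families <- tibble::tibble(genome_id = ids, family = c("famA", "famB"))
  expect_error(build_taxonomy(sim, families), "nesting violation.*g1.*g2")
})

test_that("wide taxonomy table mirrors the rank-by-species layout", {
  ids <- c("g1", "g2", "g3")
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 98
  sim <- sim_from_matrix(m, ids)
  fam <- tibble::tibble(genome_id = ids, family = c("f1", "f1", "f1"))
  tax <- build_taxonomy(sim, fam)
  wide <- taxonomy_wide(tax)
  expect_equal(wide$rank, c("order", "family", "subfamily", "genus", "species", "strains"))
  strains <- unlist(wide[wide$rank == "strains", -1])
  expect_setequal(strains, c("g1,g2", "g3"))

  tf <- withr::local_tempfile(fileext = ".tsv")
  tw <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, tf, tw)
  expect_equal(nrow(readr::read_tsv(tf, show_col_types = FALSE)), 3)
})
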