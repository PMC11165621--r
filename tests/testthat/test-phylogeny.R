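test_that("protein alignment degaps to its inputs and handles trivial cases", {
  expect_equal(align_proteins(c(x = "MKLV")), c(x = "MKLV"))
  seqs <- c(a = "MKKLVDE", b = "MKKLVDE", c = "MKKLVDE")
  aln <- align_proteins(seqs)
  expect_equal(unname(nchar(aln)), rep(7L, 3)) # identical: gapless block
  set.seed(13)
  seqs <- c(
    a = random_protein(40), b = random_protein(35),
    c = random_protein(45)
  )
  aln <- align_proteins(seqs)
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_equal(gsub("-", "", aln), seqs) # degapping recovers inputs
  expect_error(align_proteins(character(0)), "no sequences")
})

test_that("alignment sum-of-pairs score is near the exhaustive three-sequence optimum", {
  set.seed(17)
  for (rep in 1:3) {
    base <- random_protein(12)
    s <- c(
      a = base, b = mutate_protein(base, 2),
      c = substr(mutate_protein(base, 2), 1, 10)
    )
    opt <- exhaustive_msa3_score(s[["a"]], s[["b"]], s[["c"]])
    got <- alignment_sp_score(align_proteins(s))
    if (opt > 0) expect_gte(got, 0.9 * opt) else expect_gte(got, opt)
  }
})

test_that("concatenation records partitions and gap-fills missing genomes", {
  blocks <- list(
    c1 = c(g1 = "MKL-V", g2 = "MKLAV"),
    c2 = c(g1 = "DE", g3 = "DE")
  )
  cc <- concatenate_alignments(blocks)
  expect_equal(cc$alignment[["g1"]], "MKL-VDE")
  expect_equal(cc$alignment[["g2"]], "MKLAV--")
  expect_equal(cc$alignment[["g3"]], "-----DE")
  expect_equal(cc$partitions$start, c(1L, 6L))
  expect_equal(cc$partitions$end, c(5L, 7L))
  expect_equal(
    cc$partitions$end - cc$partitions$start + 1,
    c(5, 2)
  )
  expect_error(
    concatenate_alignments(blocks, genomes = c("g1", "g9")),
    "absent from every alignment"
  )
})

test_that("Poisson-corrected distances match the closed form", {
  aln <- c(a = strrep("A", 100), b = strrep("A", 100))
  expect_equal(protein_distance(aln)["a", "b"], 0)

  # p = 0.1 -> d = -ln(0.9)
  b <- paste0(strrep("C", 10), strrep("A", 90))
  d <- protein_distance(c(a = strrep("A", 100), b = b))
  expect_equal(d["a", "b"], -log(0.9), tolerance = 1e-9)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), c(0, 0))

  # gapped columns are pairwise-deleted
  d2 <- protein_distance(c(a = "AAAA--AA", b = "AAAACCAA", c = "AAAACC--"))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 0)
  expect_gt(d2["b", "c"], -1e-12)

  expect_error(
    protein_distance(c(a = "AA--", b = "--CC")),
    "no comparable columns"
  )
  expect_warning(
    protein_distance(c(a = strrep("A", 100), b = strrep("C", 100))),
    "clamped"
  )
})

test_that("neighbor joining is exact on additive matrices", {
  # two taxa: single split edge
  d2 <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sum(t2$edge.length), 0.3)

  # three taxa: terminal branch a = (dab + dac - dbc) / 2
  d3 <- matrix(
    c(
      0, .4, .6,
      .4, 0, .5,
      .6, .5, 0
    ), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  t3 <- nj_tree(d3)
  ld <- leaf_distances(t3)
  expect_equal(ld["a", "b"], 0.4, tolerance = 1e-9)
  expect_equal(ld["a", "c"], 0.6, tolerance = 1e-9)
  expect_equal(ld["b", "c"], 0.5, tolerance = 1e-9)

  # additive matrices from random trees up to 8 taxa: exact recovery
  set.seed(23)
  for (n in c(5, 8)) {
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    true <- ape::unroot(true)
    d <- leaf_distances(true)
    got <- nj_tree(d[true$tip.label, true$tip.label])
    expect_equal(ape::dist.topo(got, true), structure(0, names = "PH85"),
      ignore_attr = TRUE
    )
    expect_equal(leaf_distances(got)[rownames(d), colnames(d)], d,
      tolerance = 1e-8
    )
  }

  bad <- d3
  bad[1, 2] <- 0.9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("bootstrap supports are deterministic, bounded and decisive for clear splits", {
  # two clearly separated 3-taxon clades over 1000 columns
  set.seed(29)
  blockA <- random_protein(1000)
  blockB <- random_protein(1000)
  mut <- function(s, n) mutate_protein(s, n)
  aln <- c(
    a1 = mut(blockA, 10), a2 = mut(blockA, 12), a3 = mut(blockA, 14),
    b1 = mut(blockB, 10), b2 = mut(blockB, 12), b3 = mut(blockB, 14)
  )
  tr <- suppressWarnings(bootstrap_tree(aln, n_reps = 50, seed = 7))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  rooted <- midpoint_root(tr)
  parts <- root_bipartition(rooted)
  expect_setequal(
    vapply(parts, function(x) paste(sort(x), collapse = ","), character(1)),
    c("a1,a2,a3", "b1,b2,b3")
  )
  expect_equal(attr(parts, "support"), 100)

  tr2 <- suppressWarnings(bootstrap_tree(aln, n_reps = 50, seed = 7))
  expect_identical(tr$node.label, tr2$node.label) # same seed, same supports
})

test_that("midpoint rooting preserves leaf path lengths and bisects the diameter", {
  # caterpillar with known diameter
  cat_tree <- ape::read.tree(text = "(((a:1,b:0.2):0.5,c:0.2):0.5,d:1);")
  rooted <- midpoint_root(cat_tree)
  d_before <- leaf_distances(cat_tree)
  d_after <- leaf_distances(rooted)[rownames(d_before), colnames(d_before)]
  expect_equal(d_after, d_before, tolerance = 1e-9)
  # root-to-farthest-leaf distance = diameter / 2 on both sides
  ntip <- ape::Ntip(rooted)
  dn <- ape::dist.nodes(rooted)
  root <- ntip + 1
  expect_equal(max(dn[root, 1:ntip]), max(d_before) / 2, tolerance = 1e-9)
})

test_that("newick serialisation round-trips topology, lengths and supports", {
  set.seed(3)
  aln <- c(
    a = random_protein(300), b = random_protein(300),
    c = random_protein(300), d = random_protein(300)
  )
  tr <- suppressWarnings(bootstrap_tree(aln, n_reps = 10, seed = 1))
  tf <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, tf)
  back <- ape::read.tree(tf)
  expect_equal(ape::dist.topo(back, tr), structure(0, names = "PH85"),
    ignore_attr = TRUE
  )
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)
  expect_setequal(back$node.label, tr$node.label)
})
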