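test_that("clade simulation is byte-identical under a fixed seed", {
  a <- tiny_clade(seed = 8)
  b <- tiny_clade(seed = 8)
  expect_identical(a$genomes$seq, b$genomes$seq)
  expect_identical(a$proteins, b$proteins)
  c3 <- tiny_clade(seed = 9)
  expect_false(identical(a$genomes$seq, c3$genomes$seq))
})

test_that("the clade spec validates nesting and rates", {
  taxa <- tiny_taxa()
  bad <- taxa
  bad$genus[1] <- "gB" # species sp1 now spans two genera
  expect_error(clade_spec(bad), "not nested")
  bad2 <- taxa
  bad2$genome_id[2] <- bad2$genome_id[1]
  expect_error(clade_spec(bad2), "duplicate")
})

test_that("planted proteins are traceable in the emitted genomes", {
  cl <- tiny_clade(seed = 10)
  p <- cl$proteins
  for (i in sample(nrow(p), 10)) {
    g <- cl$genomes$seq[cl$genomes$genome_id == p$genome_id[i]]
    nt <- substr(g, p$start[i] + 1, p$end[i])
    if (p$strand[i] == "-") nt <- phagetax:::revcomp(nt)
    expect_equal(substr(nt, 1, 3), "ATG")
    expect_equal(substr(nt, nchar(nt) - 2, nchar(nt)), "TAA")
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(substr(nt, 1, nchar(nt) - 3)),
      genetic.code = Biostrings::getGeneticCode("15"), no.init.codon = TRUE
    ))
    expect_equal(aa, p$seq[i])
  }
  # presence truth matches the emitted protein table
  emitted <- dplyr::count(p, .data$genome_id, name = "emitted")
  planted <- dplyr::count(cl$presence, .data$genome_id, name = "planted")
  cmp <- dplyr::left_join(emitted, planted, by = "genome_id")
  expect_equal(cmp$emitted, cmp$planted)
})

test_that("zero divergence yields identical genomes within a species", {
  spec <- clade_spec(
    tibble::tibble(
      genome_id = c("a", "b"), family = "f", subfamily = "sf",
      genus = "g", species = "sp"
    ),
    core_families = 5L,
    accessory = list(
      family = 2L, subfamily = 2L, genus = 2L, species = 2L,
      strain_gain = 0L
    ),
    nt_divergence = list(species = 0, strain = 0)
  )
  cl <- simulate_clade(spec, seed = 2)
  expect_identical(cl$genomes$seq[1], cl$genomes$seq[2])
})

test_that("pairwise genome divergence is exact for simulated pairs", {
  for (d in c(0, 5)) {
    g <- simulate_genome_pair(20000, divergence = d, seed = 4)
    v1 <- strsplit(g$seq[1], "")[[1]]
    v2 <- strsplit(g$seq[2], "")[[1]]
    expect_equal(100 * mean(v1 != v2), d)
  }
})

test_that("realised within-genus divergence is within three standard errors", {
  cl <- tiny_clade(seed = 12)
  exp_d <- cl$expected_divergence
  # compare on shared core genes (nucleotide level), same species pair
  taxa <- cl$taxonomy
  same_sp <- which(outer(taxa$species, taxa$species, "==") &
    upper.tri(exp_d), arr.ind = TRUE)
  i <- same_sp[1, 1]
  j <- same_sp[1, 2]
  gi <- taxa$genome_id[i]
  gj <- taxa$genome_id[j]
  pi <- cl$proteins[cl$proteins$genome_id == gi, ]
  pj <- cl$proteins[cl$proteins$genome_id == gj, ]
  shared <- intersect(pi$family_id, pj$family_id)
  diffs <- 0
  sites <- 0
  for (f in shared) {
    si <- cl$genomes$seq[cl$genomes$genome_id == gi]
    sj <- cl$genomes$seq[cl$genomes$genome_id == gj]
    ri <- pi[pi$family_id == f, ]
    rj <- pj[pj$family_id == f, ]
    a <- substr(si, ri$start + 1, ri$end)
    b <- substr(sj, rj$start + 1, rj$end)
    if (ri$strand == "-") a <- phagetax:::revcomp(a)
    if (rj$strand == "-") b <- phagetax:::revcomp(b)
    if (nchar(a) != nchar(b)) next
    va <- utf8ToInt(a)
    vb <- utf8ToInt(b)
    diffs <- diffs + sum(va != vb)
    sites <- sites + length(va)
  }
  p_hat <- diffs / sites
  p_exp <- exp_d[i, j]
  se <- sqrt(p_exp * (1 - p_exp) / sites)
  expect_lt(abs(p_hat - p_exp), 3 * se + 1e-6)
})

test_that("genome GC tracks the requested target across the low-GC window", {
  for (tgt in c(0.27, 0.30)) {
    spec <- clade_spec(tiny_taxa(), gc = tgt)
    cl <- simulate_clade(spec, seed = 3)
    expect_true(all(abs(cl$genomes$gc - 100 * tgt) < 1))
  }
})

test_that("recoded genomes carry TAG glutamines; unrecoded carry none", {
  g_rec <- simulate_coding_genome(n_genes = 8, recode = TRUE, seed = 6)
  g_std <- simulate_coding_genome(n_genes = 8, recode = FALSE, seed = 6)
  count_tag <- function(g) {
    p <- g$proteins
    total <- 0
    for (i in seq_len(nrow(p))) {
      nt <- substr(g$seq, p$start[i] + 1, p$end[i])
      if (p$strand[i] == "-") nt <- phagetax:::revcomp(nt)
      cods <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
      total <- total + sum(cods == "TAG")
    }
    total
  }
  expect_gt(count_tag(g_rec), 0)
  expect_equal(count_tag(g_std), 0)
  expect_equal(g_rec$table_id, 15L)
  expect_equal(g_std$table_id, 11L)
})

test_that("the benchmark clade matches its declared design", {
  taxa <- phagetax:::benchmark_taxa()
  expect_equal(nrow(taxa), 23)
  expect_equal(length(unique(taxa$family)), 2)
  expect_equal(length(unique(taxa$subfamily)), 3)
  expect_equal(length(unique(taxa$genus)), 4)
  expect_equal(length(unique(taxa$species)), 9)
  expect_setequal(as.integer(table(taxa$species)), c(4, 1, 1, 1, 2, 2, 9, 2, 1))
  expect_equal(
    sort(as.integer(table(taxa$genus)), decreasing = TRUE),
    c(11, 9, 2, 1)
  )
})

test_that("clade artifacts can be written to disk", {
  cl <- tiny_clade(seed = 5)
  dir <- withr::local_tempdir()
  write_clade(cl, dir)
  expect_true(file.exists(file.path(dir, "genomes.fasta")))
  back <- read_genome_fasta(file.path(dir, "genomes.fasta"))
  expect_equal(back$seq, cl$genomes$seq)
})
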