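# Synthetic megaphage-clade generator: genomes with known taxonomy, known
# genetic code, known pangenome structure and controlled pairwise divergence.
#
# Evolution model (documented in the methods vignette):
#  * deep edges (family/subfamily/genus) apply amino-acid substitutions at an
#    edge rate and then redraw every codon synonymously ("scramble"), so
#    protein identity decays slowly while nucleotide identity between taxa
#    separated by a deep edge collapses to background -- emulating saturation
#    of silent sites between genera;
#  * shallow edges (species/strain) apply single-nucleotide substitutions:
#    synonymous-only within genes (third-position changes preserving the
#    amino acid under the genome's code), free in intergenic spacers, plus a
#    small amino-acid substitution rate on species edges;
#  * gene content evolves by rank-level gain (each accessory family "homes"
#    at a clade) and edge-level loss, plus strain-specific gene gains;
#  * recoded families have a fraction of glutamine codons written as TAG, the
#    table-15 reassignment that fragments genes under table 11.

# amino-acid frequencies used for gene generation: an AT-rich-proteome
# profile (Lys/Ile/Asn-enriched, as in low-GC phage genomes) with glutamine
# moderately enriched, as expected in TAG-recoded megaphage proteomes
AA_FREQ <- c(
  A = 5.0, C = 1.0, D = 5.0, E = 6.0, F = 5.0, G = 5.5, H = 1.8, I = 8.5,
  K = 9.0, L = 9.5, M = 2.5, N = 7.0, P = 3.0, Q = 6.0, R = 3.0, S = 6.5,
  T = 5.0, V = 5.0, W = 0.8, Y = 4.5
)

# Codon machinery for a code/GC pair: codons per aa (no stops; Gln restricted
# to CAA/CAG so TAG arises only via explicit recoding), GC-derived codon
# weights, single-nucleotide synonymous neighbours, and the codon->aa map.
codon_tables <- function(gc_weight, table_id = 15L) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  ok <- map != "*" & !(names(map) == "TAG")
  by_aa <- split(names(map)[ok], map[ok])
  bw <- c(A = (1 - gc_weight) / 2, C = gc_weight / 2,
          G = gc_weight / 2, T = (1 - gc_weight) / 2)
  w_by_aa <- lapply(by_aa, function(cs) {
    w <- vapply(strsplit(cs, ""), function(b) prod(bw[b]), numeric(1))
    w / sum(w)
  })
  bases <- c("A", "C", "G", "T")
  syn <- lapply(names(map), function(cod) {
    if (map[[cod]] == "*") {
      return(character(0))
    }
    b <- strsplit(cod, "")[[1]]
    out <- character(0)
    for (p in 1:3) {
      for (nb in setdiff(bases, b[p])) {
        v <- b
        v[p] <- nb
        vc <- paste(v, collapse = "")
        if (map[[vc]] == map[[cod]]) out <- c(out, vc)
      }
    }
    out
  })
  names(syn) <- names(map)
  codon_w <- vapply(
    strsplit(names(map), ""), function(b) prod(bw[b]),
    numeric(1)
  )
  names(codon_w) <- names(map)
  # total substitution rate out of each codon (sum of neighbour weights);
  # with sites hit proportionally to this, the chain is reversible with the
  # GC-weighted codon distribution as its stationary law
  syn_rate <- vapply(names(map), function(cod) {
    sum(codon_w[syn[[cod]]])
  }, numeric(1))
  list(map = map, by_aa = by_aa, w_by_aa = w_by_aa, syn = syn,
       codon_w = codon_w, syn_rate = syn_rate,
       base_w = bw, table_id = table_id)
}

# Solve for the base-composition weight giving genes an expected GC equal to
# `target` (fraction), given the fixed amino-acid skeleton.
calibrate_gc_weight <- function(target) {
  freq <- AA_FREQ / sum(AA_FREQ)
  gene_gc <- function(g) {
    tabs <- codon_tables(g, 15L)
    gc_of <- function(cs) stringr::str_count(cs, "[GC]") / 3
    e <- vapply(names(freq), function(a) {
      sum(tabs$w_by_aa[[a]] * gc_of(tabs$by_aa[[a]]))
    }, numeric(1))
    sum(freq * e)
  }
  lo <- gene_gc(0.02)
  hi <- gene_gc(0.98)
  if (target <= lo) {
    return(0.02)
  }
  if (target >= hi) {
    return(0.98)
  }
  stats::uniroot(function(g) gene_gc(g) - target, c(0.02, 0.98))$root
}

random_spacer_raw <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ), collapse = "")
}

# Intergenic spacer with guaranteed translation terminators: a 12-nt
# cassette carrying stop codons in all six reading frames (it is its own
# reverse complement) sits 2 nt in from each end of the spacer, as the
# stop-dense intergenic regions of AT-rich phage genomes would provide.
# Without the cassettes, adjacent same-strand in-frame genes would read
# through the spacer and be called as one fused ORF; anchoring one near
# each end also bounds spurious upstream ORF extensions to a few nt, so
# the extensions of two divergently transcribed neighbours can never
# overlap enough to shadow a real gene during non-redundant selection.
# The spacer body is drawn GC-enriched to offset the AT-only cassettes.
STOP_CASSETTE <- "TTAATTAATTAA"

random_spacer <- function(len, gc) {
  cw <- nchar(STOP_CASSETTE)
  if (len <= 2 * cw + 4) {
    body_gc <- min(0.97, gc * len / max(1, len - cw))
    body <- random_spacer_raw(max(0, len - cw), body_gc)
    at <- sample.int(nchar(body) + 1L, 1) - 1L
    out <- paste0(
      substr(body, 1, at), STOP_CASSETTE,
      substr(body, at + 1, nchar(body))
    )
    return(substr(out, 1, len))
  }
  body_gc <- min(0.97, gc * len / (len - 2 * cw))
  body <- random_spacer_raw(len - 2 * cw, body_gc)
  n <- nchar(body)
  paste0(
    substr(body, 1, 2), STOP_CASSETTE,
    substr(body, 3, n - 2), STOP_CASSETTE,
    substr(body, n - 1, n)
  )
}

draw_codons <- function(aa, tabs) {
  out <- character(length(aa))
  for (a in unique(aa)) {
    i <- which(aa == a)
    cs <- tabs$by_aa[[a]]
    out[i] <- if (length(cs) == 1) cs else {
      sample(cs, length(i), replace = TRUE, prob = tabs$w_by_aa[[a]])
    }
  }
  out
}

random_gene <- function(len_codons, tabs) {
  aa <- c("M", sample(names(AA_FREQ), len_codons - 1,
    replace = TRUE,
    prob = AA_FREQ
  ))
  list(aa = aa, codons = draw_codons(aa, tabs))
}

# amino-acid substitutions at `rate` per site (start Met fixed), codon
# redrawn for hit sites
aa_substitute <- function(gene, rate, tabs) {
  if (rate <= 0) {
    return(gene)
  }
  L <- length(gene$aa)
  n <- stats::rbinom(1, L - 1, rate)
  if (n == 0) {
    return(gene)
  }
  pos <- sample(2:L, min(n, L - 1))
  for (p in pos) {
    old <- gene$aa[p]
    new <- sample(names(AA_FREQ)[names(AA_FREQ) != old], 1,
      prob = AA_FREQ[names(AA_FREQ) != old]
    )
    gene$aa[p] <- new
    gene$codons[p] <- draw_codons(new, tabs)
  }
  gene
}

# full synonymous redraw of every codon (silent-site scramble)
syn_scramble <- function(gene, tabs) {
  gene$codons <- draw_codons(gene$aa, tabs)
  gene
}

# single-nucleotide synonymous substitutions at an expected per-site rate
syn_substitute <- function(gene, rate, tabs) {
  if (rate <= 0) {
    return(gene)
  }
  L <- length(gene$codons)
  n <- stats::rbinom(1, 3L * L, rate)
  if (n == 0) {
    return(gene)
  }
  rates <- tabs$syn_rate[gene$codons]
  elig <- which(rates > 0)
  if (length(elig) == 0) {
    return(gene)
  }
  n <- min(n, length(elig))
  pos <- elig[sample.int(length(elig), n, prob = rates[elig])]
  for (p in pos) {
    nbs <- tabs$syn[[gene$codons[p]]]
    w <- tabs$codon_w[nbs]
    gene$codons[p] <- nbs[sample.int(length(nbs), 1, prob = w)]
  }
  gene
}

mutate_spacer <- function(seq, rate, gc = 0.5) {
  if (rate <= 0 || nchar(seq) == 0) {
    return(seq)
  }
  n <- stats::rbinom(1, nchar(seq), rate)
  if (n == 0) {
    return(seq)
  }
  bw <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  v <- strsplit(seq, "")[[1]]
  # site mutability = total weight of the three alternative bases, so the
  # process is reversible with base frequencies `bw` as stationary law
  rates <- (sum(bw) - bw[v])
  pos <- sample.int(nchar(seq), min(n, nchar(seq)), prob = rates)
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), v[p])
    v[p] <- sample(alt, 1, prob = bw[alt])
  }
  paste(v, collapse = "")
}

# rewrite `fraction` of glutamine codons as TAG (table-15 reassignment)
recode_gene <- function(gene, fraction) {
  q <- which(gene$aa == "Q")
  if (length(q) == 0) {
    return(gene)
  }
  hit <- q[stats::runif(length(q)) < fraction]
  gene$codons[hit] <- "TAG"
  gene
}

#' Specification of a synthetic megaphage clade
#'
#' Collects the taxonomy design and evolutionary parameters consumed by
#' [simulate_clade()]. Defaults encode a Lak-like regime: AT-rich genomes
#' (GC ~ 28.5 %), genes of 150-450 codons at ~89 % coding density, deep
#' silent-site saturation between genera, and table-15 recoding with 15 % of
#' glutamine codons written as TAG.
#'
#' @param taxa Tibble with `genome_id`, `family`, `subfamily`, `genus`,
#'   `species` (one row per genome; ranks must nest).
#' @param core_families Number of gene families present in every genome.
#' @param accessory Named list of accessory family counts homed at each rank:
#'   `family`, `subfamily`, `genus`, `species` (counts per taxon of that
#'   rank) and `strain_gain` (novel genes per genome).
#' @param loss Named list of per-edge loss probabilities for higher-rank
#'   accessory families: `subfamily`, `genus`, `species`.
#' @param aa_divergence Named list of per-edge amino-acid substitution rates:
#'   `family` (scalar or named per family), `subfamily`, `genus`, `species`.
#' @param nt_divergence Named list of per-edge nucleotide substitution rates
#'   (synonymous-constrained in genes): `species`, `strain`.
#' @param gene_length_range Gene lengths in codons (uniform draw per family).
#' @param island_gene_length_range Lengths (codons) of species-accessory and
#'   strain-gained genes. These recent acquisitions are kept short and the
#'   species-level ones contiguous (an accessory island), mirroring how
#'   young accessory content clusters in phage genomes; this also keeps the
#'   aligned fraction of within-genus pairs from being dominated by content
#'   differences at reduced genome scale.
#' @param spacer_length_range Intergenic spacer lengths in nt.
#' @param gc Target genomic GC fraction.
#' @param recode_flags Logical, scalar or named per family: write a fraction
#'   of Gln codons as TAG (genome uses translation table 15).
#' @param recode_fraction Fraction of Gln codons recoded to TAG.
#' @param genome_length Optional target genome length in nt (scalar). When
#'   set, spacers are sized to meet it; an error is raised if the requested
#'   genes cannot fit.
#' @return A `clade_spec` list.
#' @export
clade_spec <- function(taxa,
                       core_families = 7L,
                       accessory = list(
                         family = 12L, subfamily = 10L, genus = 16L,
                         species = 6L, strain_gain = 1L
                       ),
                       loss = list(subfamily = 0.10, genus = 0.10, species = 0),
                       aa_divergence = list(
                         family = 0, subfamily = 0.045, genus = 0.05,
                         species = 0.002
                       ),
                       nt_divergence = list(species = 0.04, strain = 0.005),
                       gene_length_range = c(150L, 450L),
                       island_gene_length_range = c(100L, 150L),
                       spacer_length_range = c(40L, 180L),
                       gc = 0.285,
                       recode_flags = TRUE,
                       recode_fraction = 0.15,
                       genome_length = NULL) {
  stopifnot(all(c("genome_id", "family", "subfamily", "genus", "species")
  %in% names(taxa)))
  if (anyDuplicated(taxa$genome_id)) {
    abort("clade_spec: duplicate genome ids")
  }
  for (pair in list(
    c("species", "genus"), c("genus", "subfamily"),
    c("subfamily", "family")
  )) {
    bad <- taxa |>
      dplyr::group_by(.data[[pair[1]]]) |>
      dplyr::filter(dplyr::n_distinct(.data[[pair[2]]]) > 1)
    if (nrow(bad) > 0) {
      abort(paste0("clade_spec: rank '", pair[1], "' not nested in '", pair[2], "'"))
    }
  }
  fams <- unique(taxa$family)
  if (length(recode_flags) == 1 && is.null(names(recode_flags))) {
    recode_flags <- setNames(rep(recode_flags, length(fams)), fams)
  }
  fam_aa <- aa_divergence$family
  if (length(fam_aa) == 1 && is.null(names(fam_aa))) {
    aa_divergence$family <- setNames(rep(fam_aa, length(fams)), fams)
  }
  structure(
    list(
      taxa = taxa, core_families = core_families, accessory = accessory,
      loss = loss, aa_divergence = aa_divergence,
      nt_divergence = nt_divergence,
      gene_length_range = gene_length_range,
      island_gene_length_range = island_gene_length_range,
      spacer_length_range = spacer_length_range, gc = gc,
      recode_flags = recode_flags, recode_fraction = recode_fraction,
      genome_length = genome_length
    ),
    class = "clade_spec"
  )
}

# shared-9-mer screen so novel genes never collide with existing families:
# any pair above ~70 % identity over most of its length would share many
# exact 9-aa words, while unrelated random proteins share none
fresh_gene <- function(len, tabs, pool_env, max_shared = 0L) {
  repeat {
    g <- random_gene(len, tabs)
    km <- gene_kmers(g)
    if (sum(km %in% pool_env$kmers) <= max_shared) {
      pool_env$kmers <- c(pool_env$kmers, km)
      return(g)
    }
  }
}

gene_kmers <- function(gene, k = 9L) {
  s <- paste(gene$aa, collapse = "")
  unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
}

#' Simulate a megaphage clade with known ground truth
#'
#' Generates one genome per row of the spec's taxonomy design under the
#' evolution model described in the package vignette. Fully reproducible
#' from `seed` (byte-identical FASTA on regeneration).
#'
#' @param spec A [clade_spec()].
#' @param seed Integer seed for all randomness.
#' @return A list of class `synthetic_clade`:
#'   `genomes` (tibble `genome_id`, `seq`, `length`, `gc`, `table_id`),
#'   `taxonomy` (truth labels per genome),
#'   `proteins` (planted proteins: `protein_id`, `genome_id`, `family_id`,
#'   `start`, `end`, `strand`, `seq`),
#'   `presence` (genome x gene-family truth),
#'   `expected_divergence` (pairwise expected nt divergence; `NA` where a
#'   deep scrambled edge separates the pair), and `spec`.
#' @export
simulate_clade <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "clade_spec"))
  with_local_seed(seed, simulate_clade_impl(spec, seed))
}

simulate_clade_impl <- function(spec, seed) {
  taxa <- spec$taxa
  gw <- calibrate_gc_weight(spec$gc)
  tabs <- codon_tables(gw, 15L)
  pool <- new.env(parent = emptyenv())
  pool$kmers <- character(0)
  glr <- spec$gene_length_range
  iglr <- spec$island_gene_length_range

  # ---- gene-family registry -------------------------------------------
  fams <- unique(taxa$family)
  registry <- list() # family_id -> list(home_rank, home, len)
  add_fams <- function(n, rank, home, tag) {
    ids <- sprintf("%s_%02d", tag, seq_len(n))
    # species/strain-homed genes are short (recent island acquisitions)
    rng <- if (rank %in% c("species", "strain")) iglr else glr
    for (id in ids) {
      registry[[id]] <<- list(
        home_rank = rank, home = home,
        len = sample(rng[1]:rng[2], 1)
      )
    }
    ids
  }
  core_ids <- add_fams(spec$core_families, "root", "root", "core")
  acc <- spec$accessory
  fam_acc <- lapply(setNames(fams, fams), function(f) {
    add_fams(acc$family, "family", f, paste0("accF.", f))
  })
  sfs <- unique(taxa$subfamily)
  sf_acc <- lapply(setNames(sfs, sfs), function(s) {
    add_fams(acc$subfamily, "subfamily", s, paste0("accS.", s))
  })
  gens <- unique(taxa$genus)
  gen_acc <- lapply(setNames(gens, gens), function(g) {
    add_fams(acc$genus, "genus", g, paste0("accG.", g))
  })
  sps <- unique(taxa$species)
  sp_acc <- lapply(setNames(sps, sps), function(s) {
    add_fams(acc$species, "species", s, paste0("accP.", s))
  })

  # ---- presence plan (edge-level losses; strain gains added later) ----
  lineage <- function(g) taxa[taxa$genome_id == g, ]
  lost_on <- list() # edge key -> family ids lost
  draw_loss <- function(eligible, p) eligible[stats::runif(length(eligible)) < p]
  for (s in sfs) {
    f <- unique(taxa$family[taxa$subfamily == s])
    lost_on[[paste0("sf:", s)]] <- draw_loss(fam_acc[[f]], spec$loss$subfamily)
  }
  for (g in gens) {
    row <- taxa[taxa$genus == g, ][1, ]
    elig <- c(fam_acc[[row$family]], sf_acc[[row$subfamily]])
    lost_on[[paste0("gen:", g)]] <- draw_loss(elig, spec$loss$genus)
  }
  for (s in sps) {
    row <- taxa[taxa$species == s, ][1, ]
    elig <- c(
      fam_acc[[row$family]], sf_acc[[row$subfamily]],
      gen_acc[[row$genus]]
    )
    lost_on[[paste0("sp:", s)]] <- draw_loss(elig, spec$loss$species)
  }
  presence_of_species <- function(sp_row) {
    base <- c(
      core_ids, fam_acc[[sp_row$family]], sf_acc[[sp_row$subfamily]],
      gen_acc[[sp_row$genus]], sp_acc[[sp_row$species]]
    )
    lost <- c(
      lost_on[[paste0("sf:", sp_row$subfamily)]],
      lost_on[[paste0("gen:", sp_row$genus)]],
      lost_on[[paste0("sp:", sp_row$species)]]
    )
    setdiff(base, lost)
  }
  # force family-homed accessory families to be non-universal within their
  # family (so the planted core count is exact); removal is applied at the
  # deepest rank with >= 2 taxa so that within-genus gene content -- and
  # hence the aligned fraction between close relatives -- is unaffected
  for (f in fams) {
    f_species <- unique(taxa$species[taxa$family == f])
    f_genera <- unique(taxa$genus[taxa$family == f])
    if (length(f_species) < 2) next
    pres <- lapply(f_species, function(s) {
      presence_of_species(taxa[taxa$species == s, ][1, ])
    })
    universal <- Reduce(intersect, pres)
    for (fa in intersect(universal, fam_acc[[f]])) {
      if (length(f_genera) >= 2) {
        key <- paste0("gen:", sample(f_genera, 1))
      } else {
        key <- paste0("sp:", sample(f_species, 1))
      }
      lost_on[[key]] <- c(lost_on[[key]], fa)
    }
  }

  # ---- deep-edge sequence evolution -----------------------------------
  aa_div <- spec$aa_divergence
  evolve_deep <- function(genes, rate) {
    lapply(genes, function(g) syn_scramble(aa_substitute(g, rate, tabs), tabs))
  }
  root_genes <- setNames(
    lapply(core_ids, function(id) random_gene(registry[[id]]$len, tabs)),
    core_ids
  )
  for (g in root_genes) {
    pool$kmers <- c(pool$kmers, gene_kmers(g))
  }

  genomes_out <- list()
  proteins_out <- list()
  presence_out <- list()

  for (f in fams) {
    fam_core <- evolve_deep(root_genes, aa_div$family[[f]])
    fam_own <- setNames(
      lapply(fam_acc[[f]], function(id) {
        fresh_gene(registry[[id]]$len, tabs, pool)
      }),
      fam_acc[[f]]
    )
    recode <- isTRUE(spec$recode_flags[[f]])
    table_id <- if (recode) 15L else 11L
    for (s in unique(taxa$subfamily[taxa$family == f])) {
      sf_genes <- evolve_deep(c(fam_core, fam_own), aa_div$subfamily)
      sf_own <- setNames(
        lapply(sf_acc[[s]], function(id) {
          fresh_gene(registry[[id]]$len, tabs, pool)
        }),
        sf_acc[[s]]
      )
      for (gn in unique(taxa$genus[taxa$subfamily == s])) {
        gen_genes <- evolve_deep(c(sf_genes, sf_own), aa_div$genus)
        gen_own <- setNames(
          lapply(gen_acc[[gn]], function(id) {
            fresh_gene(registry[[id]]$len, tabs, pool)
          }),
          gen_acc[[gn]]
        )
        gn_species <- unique(taxa$species[taxa$genus == gn])
        genus_pool <- c(gen_genes, gen_own)
        # genus ancestor layout (species-homed island genes are inserted per
        # species below): order, strand, spacers, recoding
        present_any <- unique(unlist(lapply(gn_species, function(ss) {
          presence_of_species(taxa[taxa$species == ss, ][1, ])
        })))
        layout_ids <- sample(intersect(names(genus_pool), present_any))
        elements <- list()
        spacers <- spacer_lengths(spec, layout_ids, registry)
        elements[[1]] <- list(type = "spacer", seq = random_spacer(spacers[1], spec$gc))
        for (i in seq_along(layout_ids)) {
          id <- layout_ids[i]
          gene <- genus_pool[[id]]
          if (recode) gene <- recode_gene(gene, spec$recode_fraction)
          elements[[2 * i]] <- list(
            type = "gene", family_id = id,
            strand = sample(c("+", "-"), 1), gene = gene
          )
          elements[[2 * i + 1]] <- list(
            type = "spacer",
            seq = random_spacer(spacers[i + 1], spec$gc)
          )
        }
        for (ss in gn_species) {
          sp_row <- taxa[taxa$species == ss, ][1, ]
          keep <- presence_of_species(sp_row)
          sp_elements <- Filter(function(e) {
            e$type == "spacer" || e$family_id %in% keep
          }, elements)
          # species-specific accessory island: short fresh genes inserted as
          # one contiguous block at a random inter-gene junction
          if (length(sp_acc[[ss]]) > 0) {
            island <- list()
            for (id in sp_acc[[ss]]) {
              gene <- fresh_gene(registry[[id]]$len, tabs, pool)
              if (recode) gene <- recode_gene(gene, spec$recode_fraction)
              island <- c(island, list(
                list(
                  type = "gene", family_id = id,
                  strand = sample(c("+", "-"), 1), gene = gene
                ),
                list(type = "spacer", seq = random_spacer(
                  sample(spec$spacer_length_range[1]:spec$spacer_length_range[2], 1),
                  spec$gc
                ))
              ))
            }
            at <- sample(seq(1, length(sp_elements), by = 2), 1)
            sp_elements <- append(sp_elements, island, after = at)
          }
          sp_elements <- mutate_elements(
            sp_elements, spec$nt_divergence$species,
            aa_div$species, tabs, spec$gc
          )
          strains <- taxa$genome_id[taxa$species == ss]
          for (st in strains) {
            st_elements <- mutate_elements(
              sp_elements, spec$nt_divergence$strain, 0, tabs, spec$gc
            )
            gains <- character(0)
            if (acc$strain_gain > 0) {
              gain_ids <- add_fams(
                acc$strain_gain, "strain", st,
                paste0("accX.", st)
              )
              for (gid in gain_ids) {
                gene <- fresh_gene(registry[[gid]]$len, tabs, pool)
                if (recode) gene <- recode_gene(gene, spec$recode_fraction)
                at <- sample(seq(1, length(st_elements), by = 2), 1)
                st_elements <- append(st_elements, list(
                  list(
                    type = "gene", family_id = gid,
                    strand = sample(c("+", "-"), 1), gene = gene
                  ),
                  list(type = "spacer", seq = random_spacer(
                    sample(spec$spacer_length_range[1]:spec$spacer_length_range[2], 1),
                    spec$gc
                  ))
                ), after = at)
                gains <- c(gains, gid)
              }
            }
            asm <- assemble_genome(st, st_elements, tabs)
            genomes_out[[st]] <- tibble::tibble(
              genome_id = st, seq = asm$seq, length = nchar(asm$seq),
              gc = gc_content(asm$seq), table_id = table_id
            )
            proteins_out[[st]] <- asm$proteins
            presence_out[[st]] <- tibble::tibble(
              genome_id = st,
              family_id = c(
                intersect(keep, c(names(genus_pool), sp_acc[[ss]])),
                gains
              )
            )
          }
        }
      }
    }
  }

  genomes <- dplyr::bind_rows(genomes_out[taxa$genome_id])
  taxonomy <- dplyr::mutate(taxa, order = "order1", table_id = genomes$table_id)
  structure(
    list(
      genomes = genomes,
      taxonomy = taxonomy,
      proteins = dplyr::bind_rows(proteins_out[taxa$genome_id]),
      presence = dplyr::bind_rows(presence_out[taxa$genome_id]),
      expected_divergence = expected_divergence_matrix(spec),
      spec = spec, seed = seed
    ),
    class = "synthetic_clade"
  )
}

# spacer lengths for a layout: drawn from the spacer range, or sized to meet
# a requested genome length
spacer_lengths <- function(spec, layout_ids, registry) {
  n <- length(layout_ids) + 1L
  if (is.null(spec$genome_length)) {
    return(sample(spec$spacer_length_range[1]:spec$spacer_length_range[2],
      n,
      replace = TRUE
    ))
  }
  coding <- sum(vapply(layout_ids, function(id) {
    3L * (registry[[id]]$len + 1L)
  }, numeric(1)))
  budget <- spec$genome_length - coding
  if (budget < 10L * n) {
    abort(paste0(
      "cannot place ", length(layout_ids), " genes (", coding,
      " nt coding) in genome_length ", spec$genome_length
    ))
  }
  base <- budget %/% n
  out <- rep(base, n)
  out[seq_len(budget - base * n)] <- base + 1L
  out
}

# species/strain edge: synonymous nt substitutions in genes, free in
# spacers, plus optional amino-acid substitutions
mutate_elements <- function(elements, nt_rate, aa_rate, tabs, gc = 0.5) {
  lapply(elements, function(e) {
    if (e$type == "spacer") {
      e$seq <- mutate_spacer(e$seq, nt_rate, gc)
    } else {
      e$gene <- syn_substitute(e$gene, nt_rate, tabs)
      if (aa_rate > 0) e$gene <- aa_substitute(e$gene, aa_rate, tabs)
    }
    e
  })
}

assemble_genome <- function(genome_id, elements, tabs) {
  parts <- character(length(elements))
  prot <- list()
  pos <- 0L
  pi <- 0L
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    if (e$type == "spacer") {
      parts[i] <- e$seq
      pos <- pos + nchar(e$seq)
    } else {
      nt <- paste0(paste(e$gene$codons, collapse = ""), "TAA")
      if (e$strand == "-") nt <- revcomp(nt)
      parts[i] <- nt
      pi <- pi + 1L
      prot[[pi]] <- tibble::tibble(
        protein_id = paste0(genome_id, "|", e$family_id),
        genome_id = genome_id, family_id = e$family_id,
        start = pos, end = pos + nchar(nt), strand = e$strand,
        seq = paste(e$gene$aa, collapse = "")
      )
      pos <- pos + nchar(nt)
    }
  }
  list(seq = paste(parts, collapse = ""), proteins = dplyr::bind_rows(prot))
}

# expected pairwise nucleotide divergence from shallow-edge rates; NA where
# the path crosses a scrambled (deep) edge
expected_divergence_matrix <- function(spec) {
  taxa <- spec$taxa
  ids <- taxa$genome_id
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 0
  sp_rate <- spec$nt_divergence$species
  st_rate <- spec$nt_divergence$strain
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- taxa[i, ]
      b <- taxa[j, ]
      if (a$species == b$species) {
        m[i, j] <- m[j, i] <- 2 * st_rate
      } else if (a$genus == b$genus) {
        m[i, j] <- m[j, i] <- 2 * st_rate + 2 * sp_rate
      }
    }
  }
  m
}

#' @export
print.synthetic_clade <- function(x, ...) {
  cat(
    "<synthetic_clade>", nrow(x$genomes), "genomes;",
    length(unique(x$taxonomy$family)), "families;",
    length(unique(x$taxonomy$species)), "species; seed", x$seed, "\n"
  )
  invisible(x)
}

#' The 23-genome benchmark clade design
#'
#' A fixed taxonomy design mirroring a published megaphage clade: one large
#' family of 22 genomes carrying two subfamilies (genera of 11, 9 and 2
#' genomes; species of sizes 4,1,1,1,2,2 / 9 / 2) plus a single-genome
#' outlier family whose proteome diverges to ~50 % identity, with uniform
#' table-15 recoding across all genomes. Genome lengths are ~10x reduced
#' relative to real megaphages at the default `scale = 0.1` so the full
#' pipeline runs at desk scale; `scale = 1` approximates full size.
#'
#' @param seed Integer seed.
#' @param scale Gene-count scale factor (0.1 = reduced, 1 = full size).
#' @return A `synthetic_clade` (see [simulate_clade()]).
#' @export
simulate_benchmark_clade <- function(seed = 1L, scale = 0.1) {
  taxa <- benchmark_taxa()
  k <- function(x) max(1L, as.integer(round(x * scale * 10)))
  spec <- clade_spec(
    taxa,
    core_families = k(7),
    accessory = list(
      family = k(12), subfamily = k(10), genus = k(16),
      species = k(6), strain_gain = k(1)
    ),
    aa_divergence = list(
      family = c(famA = 0, famB = 0.5),
      subfamily = 0.045, genus = 0.05, species = 0.002
    ),
    recode_flags = c(famA = TRUE, famB = TRUE)
  )
  simulate_clade(spec, seed)
}

benchmark_taxa <- function() {
  sp <- function(genus, subfam, fam, species, n, offset) {
    tibble::tibble(
      genome_id = sprintf("mg%02d", offset + seq_len(n)),
      family = fam, subfamily = subfam, genus = genus, species = species
    )
  }
  dplyr::bind_rows(
    sp("gG1", "sfA1", "famA", "spA", 4, 0),
    sp("gG1", "sfA1", "famA", "spB", 1, 4),
    sp("gG1", "sfA1", "famA", "spC", 1, 5),
    sp("gG1", "sfA1", "famA", "spD", 1, 6),
    sp("gG1", "sfA1", "famA", "spE", 2, 7),
    sp("gG1", "sfA1", "famA", "spF", 2, 9),
    sp("gG2", "sfA1", "famA", "spG", 9, 11),
    sp("gG3", "sfA2", "famA", "spH", 2, 20),
    sp("gG4", "sfB1", "famB", "spI", 1, 22)
  )
}

#' Simulate a diverged genome pair with exact nucleotide divergence
#'
#' A random genome and a copy with `divergence` percent of positions
#' substituted (distinct positions, new base always different), giving a
#' pair whose true ANI is exactly `100 - divergence`.
#'
#' @param length Genome length in nt.
#' @param divergence Percent of substituted positions.
#' @param seed Integer seed.
#' @param gc GC fraction of the random genome.
#' @return A two-row genome tibble (`genome_id`, `seq`).
#' @export
simulate_genome_pair <- function(length = 100000L, divergence = 5,
                                 seed = 1L, gc = 0.285) {
  with_local_seed(seed, {
    a <- random_spacer(length, gc)
    v <- strsplit(a, "")[[1]]
    n <- round(length * divergence / 100)
    bw <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    pos <- sample.int(length, n)
    for (p in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), v[p])
      v[p] <- sample(alt, 1, prob = bw[alt])
    }
    tibble::tibble(
      genome_id = c("ref", "div"),
      seq = c(a, paste(v, collapse = ""))
    )
  })
}

#' Simulate a single protein-coding genome
#'
#' Spacer-separated, codon-structured genes (ATG start, single TAA stop),
#' optionally recoded so that a fraction of glutamine codons are TAG --
#' readable only under translation table 15. Used to exercise the
#' coding-capacity recoding detector with known truth.
#'
#' @param n_genes Number of genes.
#' @param recode Write Gln codons as TAG (table-15 genome)?
#' @param seed Integer seed.
#' @param gc GC fraction.
#' @param recode_fraction Fraction of Gln codons recoded.
#' @param gene_length_range,spacer_length_range As in [clade_spec()].
#' @return A list: `seq`, `table_id`, `proteins` (planted protein tibble).
#' @export
simulate_coding_genome <- function(n_genes = 55L, recode = TRUE, seed = 1L,
                                   gc = 0.285, recode_fraction = 0.15,
                                   gene_length_range = c(150L, 450L),
                                   spacer_length_range = c(40L, 180L)) {
  with_local_seed(seed, {
    gw <- calibrate_gc_weight(gc)
    tabs <- codon_tables(gw, 15L)
    elements <- list(list(
      type = "spacer",
      seq = random_spacer(sample(
        spacer_length_range[1]:spacer_length_range[2], 1
      ), gc)
    ))
    for (i in seq_len(n_genes)) {
      gene <- random_gene(sample(gene_length_range[1]:gene_length_range[2], 1), tabs)
      if (recode) gene <- recode_gene(gene, recode_fraction)
      elements[[2 * i]] <- list(
        type = "gene", family_id = sprintf("gene%03d", i),
        strand = sample(c("+", "-"), 1), gene = gene
      )
      elements[[2 * i + 1]] <- list(
        type = "spacer",
        seq = random_spacer(sample(
          spacer_length_range[1]:spacer_length_range[2], 1
        ), gc)
      )
    }
    asm <- assemble_genome("sim", elements, tabs)
    list(
      seq = asm$seq, table_id = if (recode) 15L else 11L,
      proteins = asm$proteins
    )
  })
}

#' Write a synthetic clade's artifacts to disk
#'
#' @param clade A [simulate_clade()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(clade$genomes, file.path(dir, "genomes.fasta"))
  write_protein_fasta(clade$proteins, file.path(dir, "proteins.faa"))
  readr::write_tsv(clade$taxonomy, file.path(dir, "taxonomy_truth.tsv"))
  readr::write_tsv(clade$presence, file.path(dir, "gene_families_truth.tsv"))
  readr::write_tsv(
    clade$genomes[, c("genome_id", "length", "gc", "table_id")],
    file.path(dir, "genomes_truth.tsv")
  )
  invisible(dir)
}
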