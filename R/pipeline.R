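# End-to-end orchestration: code check -> ORFs -> pangenome -> families ->
# core-protein trees -> intergenomic similarity -> ranked taxonomy.

#' Pipeline configuration
#'
#' Collects every tunable of the classification pipeline with its default.
#' Thresholds are percent unless noted.
#'
#' @param identity_threshold Protein clustering identity (pangenome/core).
#' @param coverage_threshold Bidirectional aligned-span coverage for cluster
#'   edges (fraction).
#' @param core_low_threshold Low identity level used to diagnose outlier
#'   families (a proteome-level outlier is expected to connect only near
#'   this level).
#' @param species_threshold,genus_threshold Similarity demarcations on
#'   `S = ANI x AF`.
#' @param fragment_len ANI fragment window (nt).
#' @param min_fragment_identity Fragment match threshold (percent).
#' @param min_orf_len Minimum ORF length (nt, incl. stop codon).
#' @param max_overlap Maximum tolerated ORF overlap (nt).
#' @param delta_threshold Coding-capacity differential (percentage points)
#'   assigning translation table 15.
#' @param bootstrap_reps Bootstrap replicates for the core-protein tree.
#' @param min_subfamily_support Minimum root-bipartition support (percent) to
#'   split a family into subfamilies.
#' @param start_codons ORF start codons.
#' @param seed Seed for the bootstrap resampler.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(identity_threshold = 70, coverage_threshold = 0.8,
                       core_low_threshold = 25, species_threshold = 95,
                       genus_threshold = 70, fragment_len = 3000L,
                       min_fragment_identity = 80, min_orf_len = 90L,
                       max_overlap = 30L, delta_threshold = 10,
                       bootstrap_reps = 100L, min_subfamily_support = 95,
                       start_codons = "ATG", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    identity_threshold >= 0, identity_threshold <= 100,
    coverage_threshold >= 0, coverage_threshold <= 1,
    species_threshold >= genus_threshold,
    fragment_len >= 100, min_orf_len >= 3
  )
  structure(cfg, class = "run_config")
}

pipeline_stage <- function(stage, log_env, expr) {
  log_env$lines <- c(
    log_env$lines,
    paste0(format(Sys.time(), "%H:%M:%S"), " stage: ", stage)
  )
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full classification pipeline
#'
#' Executes every stage on a genome set: genetic-code assignment per genome
#' (so mixed table-11/15 inputs are handled), ORF prediction under the
#' assigned code, connected-component protein clustering, family assignment
#' from shared clusters, per-family core-protein extraction and concatenated
#' NJ phylogeny with bootstrap + midpoint rooting, fragment-based
#' intergenomic similarity, and rank demarcation.
#'
#' @param genomes A genome tibble (see [read_genome_fasta()]) or a path to a
#'   nucleotide FASTA.
#' @param config A [run_config()].
#' @param annotations Optional tibble (`protein_id`, `label`) of functional
#'   annotations, e.g. best PHROG hits.
#' @param output_dir Optional directory; when given, every intermediate
#'   artifact and a summary report are written there.
#' @return A list of class `taxonomy_run` with elements `genome_stats`,
#'   `code_calls`, `proteins`, `pangenome`, `families`, `core`,
#'   `family_diagnostics`, `trees`, `similarity`, `taxonomy`, `config`,
#'   `log`.
#' @export
run_taxonomy_pipeline <- function(genomes, config = run_config(),
                                  annotations = NULL, output_dir = NULL) {
  if (is.character(genomes) && length(genomes) == 1) {
    genomes <- read_genome_fasta(genomes)
  }
  lg <- new.env(parent = emptyenv())
  lg$lines <- character(0)

  stats_tbl <- pipeline_stage("genome_stats", lg, genome_stats(genomes))

  calls <- pipeline_stage("codecheck", lg, call_genetic_code(
    genomes, config$delta_threshold, config$min_orf_len,
    config$max_overlap, config$start_codons
  ))

  proteins <- pipeline_stage("orfs", lg, predict_proteome(
    genomes, calls$assigned_table, config$min_orf_len,
    config$max_overlap, config$start_codons
  ))

  pg <- pipeline_stage("cluster", lg, {
    clusters <- cluster_proteins(
      proteins,
      identity_threshold = config$identity_threshold,
      coverage_threshold = config$coverage_threshold
    )
    pangenome_matrix(clusters, genomes = genomes$genome_id)
  })

  families <- pipeline_stage("families", lg, assign_family(pg))

  fam_members <- split(families$genome_id, families$family)

  diagnostics <- pipeline_stage("family_diagnostics", lg, {
    singletons <- names(fam_members)[lengths(fam_members) == 1]
    if (length(singletons) > 0 && length(fam_members) > 1) {
      purrr::map_dfr(
        unlist(fam_members[singletons]),
        function(g) {
          outlier_link_threshold(proteins, g,
            coverage_threshold = config$coverage_threshold,
            grid = seq(config$identity_threshold, 5, by = -5)
          )
        }
      )
    } else {
      tibble::tibble(
        outlier_genome = character(0), max_identity = numeric(0),
        link_threshold = numeric(0)
      )
    }
  })

  core <- pipeline_stage("core", lg, {
    lapply(fam_members, function(mem) core_clusters(pg, mem))
  })

  trees <- pipeline_stage("tree", lg, {
    out <- list()
    for (f in names(fam_members)) {
      mem <- fam_members[[f]]
      if (length(mem) < 3 || length(core[[f]]) == 0) next
      blocks <- core_alignments(proteins, pg$clusters, core[[f]], mem)
      concat <- concatenate_alignments(blocks, genomes = mem)
      tree <- bootstrap_tree(concat,
        n_reps = config$bootstrap_reps,
        seed = config$seed
      )
      out[[f]] <- midpoint_root(tree)
    }
    out
  })

  sim <- pipeline_stage("ani", lg, similarity_matrix(
    genomes,
    fragment_len = config$fragment_len,
    min_identity = config$min_fragment_identity
  ))

  taxonomy <- pipeline_stage("classify", lg, {
    subfams <- lapply(setNames(names(fam_members), names(fam_members)), function(f) {
      assign_subfamily(trees[[f]], fam_members[[f]],
        min_support = config$min_subfamily_support
      )
    })
    build_taxonomy(sim, families,
      subfamilies = subfams,
      species_threshold = config$species_threshold,
      genus_threshold = config$genus_threshold
    )
  })

  run <- structure(
    list(
      genome_stats = stats_tbl, code_calls = calls, proteins = proteins,
      pangenome = pg, families = families, core = core,
      family_diagnostics = diagnostics, trees = trees, similarity = sim,
      taxonomy = taxonomy, config = config, log = lg$lines
    ),
    class = "taxonomy_run"
  )
  if (!is.null(output_dir)) {
    write_taxonomy_run(run, output_dir)
  }
  run
}

# per-cluster alignments of per-genome representatives (longest member)
core_alignments <- function(proteins, clusters, core_ids, members) {
  prot <- dplyr::left_join(
    clusters[clusters$cluster_id %in% core_ids, ],
    proteins[, c("protein_id", "seq")],
    by = "protein_id"
  )
  prot <- prot[prot$genome_id %in% members, ]
  reps <- prot |>
    dplyr::group_by(.data$cluster_id, .data$genome_id) |>
    dplyr::slice_max(nchar(.data$seq), n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  lapply(
    setNames(sort(unique(reps$cluster_id)), sort(unique(reps$cluster_id))),
    function(cl) {
      sub <- reps[reps$cluster_id == cl, ]
      align_proteins(setNames(sub$seq, sub$genome_id))
    }
  )
}

#' Write every pipeline artifact to a run directory
#'
#' @param run A [run_taxonomy_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_taxonomy_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f))
  w(run$genome_stats, "genome_stats.tsv")
  w(run$code_calls, "code_calls.tsv")
  w(
    run$proteins[, setdiff(names(run$proteins), "seq")],
    "orf_coordinates.tsv"
  )
  write_protein_fasta(run$proteins, file.path(dir, "proteins.faa"))
  w(tibble::as_tibble(run$pangenome$clusters), "cluster_membership.tsv")
  m <- run$pangenome$matrix
  w(
    dplyr::bind_cols(
      tibble::tibble(cluster_id = rownames(m)),
      tibble::as_tibble(m)
    ),
    "pangenome_matrix.tsv"
  )
  w(
    tibble::tibble(
      family = rep(names(run$core), lengths(run$core)),
      cluster_id = unlist(run$core, use.names = FALSE)
    ),
    "core_clusters.tsv"
  )
  w(run$family_diagnostics, "family_diagnostics.tsv")
  w(tidy(run$similarity, directed = TRUE), "similarity_long.tsv")
  sm <- unclass(run$similarity)
  w(
    dplyr::bind_cols(
      tibble::tibble(genome_id = rownames(sm)),
      tibble::as_tibble(sm)
    ),
    "similarity_matrix.tsv"
  )
  for (f in names(run$trees)) {
    ape::write.tree(run$trees[[f]], file.path(dir, paste0("tree_", f, ".nwk")))
  }
  write_taxonomy(
    run$taxonomy, file.path(dir, "taxonomy_long.tsv"),
    file.path(dir, "taxonomy_wide.tsv")
  )
  cfg <- run$config
  w(
    tibble::tibble(
      key = names(cfg),
      value = vapply(cfg, function(v) paste(v, collapse = ","), character(1))
    ),
    "config.tsv"
  )
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.taxonomy_run <- function(x, ...) {
  cat("<taxonomy_run>", nrow(x$genome_stats), "genomes\n")
  cat(
    " assigned tables:",
    paste(names(table(x$code_calls$assigned_table)),
      table(x$code_calls$assigned_table),
      sep = ":", collapse = " "
    ), "\n"
  )
  cat(
    " clusters:", nrow(x$pangenome$matrix),
    "| families:", length(unique(x$families$family)),
    "| species:", length(unique(x$taxonomy$species)), "\n"
  )
  invisible(x)
}

#' Tidy a pipeline run into per-genome assignments
#'
#' @param x A `taxonomy_run`.
#' @param ... Unused.
#' @return The taxonomy tibble joined with per-genome statistics and code
#'   calls.
#' @export
tidy.taxonomy_run <- function(x, ...) {
  tibble::as_tibble(x$taxonomy) |>
    dplyr::left_join(x$genome_stats, by = "genome_id") |>
    dplyr::left_join(
      x$code_calls[, c("genome_id", "cc11", "cc15", "delta", "assigned_table")],
      by = "genome_id"
    )
}

#' One-row summary of a pipeline run
#'
#' @param x A `taxonomy_run`.
#' @param ... Unused.
#' @return A tibble with taxon counts per rank and pangenome totals.
#' @export
glance.taxonomy_run <- function(x, ...) {
  tx <- x$taxonomy
  tibble::tibble(
    n_genomes = nrow(tx),
    n_species = length(unique(tx$species)),
    n_genera = length(unique(tx$genus)),
    n_subfamilies = length(unique(tx$subfamily)),
    n_families = length(unique(tx$family)),
    n_clusters = nrow(x$pangenome$matrix),
    n_recoded = sum(x$code_calls$assigned_table == 15L)
  )
}

#' Similarity heatmap annotated by assigned ranks
#'
#' @param object A `taxonomy_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.taxonomy_run <- function(object, ...) {
  autoplot(object$similarity) +
    ggplot2::labs(
      title = "Intergenomic similarity (ANI x aligned fraction)",
      subtitle = paste0(
        length(unique(object$taxonomy$species)), " species / ",
        length(unique(object$taxonomy$genus)), " genera / ",
        length(unique(object$taxonomy$family)), " families"
      )
    )
}
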