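# Rank demarcation: similarity thresholds (species/genus), shared-cluster
# connectivity (family), root bipartition of the core-protein tree
# (subfamily), nested-partition assembly (full taxonomy).

#' Single-linkage partition of genomes at a similarity threshold
#'
#' Builds a graph with an edge wherever `S >= threshold` and returns its
#' connected components, so near-threshold members join a taxon via
#' intermediates (the behaviour that keeps borderline strains inside their
#' species).
#'
#' @param sim A [similarity_matrix()] (symmetric, diagonal 100).
#' @param threshold Percent similarity demarcating the rank (species 95,
#'   genus 70 by ICTV convention).
#' @param prefix Label prefix for the resulting taxa.
#' @return A tibble with `genome_id` and `taxon`, ordered by genome id;
#'   labels are deterministic (component size desc, then smallest member).
#' @export
cluster_by_threshold <- function(sim, threshold, prefix = "taxon") {
  m <- unclass(as.matrix(sim))
  adj <- (m >= threshold) * 1
  g <- igraph::graph_from_adjacency_matrix(adj,
    mode = "undirected",
    diag = FALSE
  )
  comp <- igraph::components(g)$membership
  groups <- label_partition(split(names(comp), comp), prefix)
  partition_tibble(groups, "genome_id", "taxon")
}

#' Family assignment from shared protein clusters
#'
#' Two genomes are linked iff they share at least one protein cluster at the
#' pangenome's identity threshold; families are the connected components of
#' that genome graph. A genome sharing no cluster with any other (a
#' proteome-level outlier) becomes its own family.
#'
#' @param pangenome A [pangenome_matrix()] object (typically built at 70 %
#'   identity).
#' @param genomes Optional genome id vector (defaults to matrix columns).
#' @param prefix Label prefix.
#' @return A tibble with `genome_id` and `family`.
#' @export
assign_family <- function(pangenome, genomes = NULL, prefix = "fam") {
  m <- pangenome$matrix
  genomes <- genomes %||% colnames(m)
  bin <- m[, genomes, drop = FALSE] >= 1
  shared <- crossprod(bin) # genomes x genomes shared-cluster counts
  adj <- (shared >= 1) * 1
  g <- igraph::graph_from_adjacency_matrix(adj,
    mode = "undirected",
    diag = FALSE
  )
  comp <- igraph::components(g)$membership
  groups <- label_partition(split(names(comp), comp), prefix)
  partition_tibble(groups, "genome_id", "family")
}

#' Identity level at which an outlier genome connects to the rest
#'
#' For a genome isolated at the working identity threshold, scans a
#' descending threshold grid and reports the highest level at which the
#' outlier's proteome shares at least one qualifying cluster edge with any
#' other genome -- the diagnostic that distinguishes a new family (connects
#' only at low identity) from an unrelated genome (never connects).
#'
#' @param proteins Protein tibble (all genomes).
#' @param outlier_genome The isolated genome id.
#' @param coverage_threshold Bidirectional coverage requirement.
#' @param grid Descending identity thresholds to test.
#' @return One-row tibble: `outlier_genome`, `max_identity` (best qualifying
#'   edge identity, 0 if none), `link_threshold` (highest grid value at which
#'   it connects, `NA` if never).
#' @export
outlier_link_threshold <- function(proteins, outlier_genome,
                                   coverage_threshold = 0.8,
                                   grid = seq(70, 5, by = -5)) {
  is_out <- proteins$genome_id == outlier_genome
  if (!any(is_out) || all(is_out)) {
    abort("outlier_link_threshold: outlier genome not found or is the only genome")
  }
  out_prot <- proteins[is_out, , drop = FALSE]
  other <- proteins[!is_out, , drop = FALSE]
  # coarse k-mer prefilter (k = 4) keeps distant homologs while skipping
  # unrelated pairs; unique sequences are aligned once in batches
  combined <- dplyr::bind_rows(out_prot, other)
  useq <- unique(combined$seq)
  uof <- match(combined$seq, useq)
  no <- nrow(out_prot)
  is_out_u <- tapply(seq_along(uof) <= no, uof, any)
  pairs <- kmer_candidate_pairs(useq, k = 4L)
  best <- 0
  if (nrow(pairs) > 0) {
    cross <- pairs[
      is_out_u[pairs[, 1]] != is_out_u[pairs[, 2]], ,
      drop = FALSE
    ]
    if (nrow(cross) > 0) {
      res <- batch_identity(useq, cross)
      ok <- res$coverage_a >= coverage_threshold &
        res$coverage_b >= coverage_threshold
      if (any(ok)) best <- max(res$identity[ok])
    }
  }
  link <- grid[grid <= best]
  tibble::tibble(
    outlier_genome = outlier_genome,
    max_identity = best,
    link_threshold = if (length(link) > 0) max(link) else NA_real_
  )
}

#' Subfamily assignment from the family tree's root bipartition
#'
#' Splits a family into the two child clades of its midpoint-rooted
#' core-protein tree, accepted iff the root bipartition's bootstrap support
#' reaches `min_support`; otherwise (or for families too small to carry an
#' internal edge) the family stays one subfamily and a warning is issued.
#'
#' @param tree Midpoint-rooted `ape::phylo` with supports as node labels, or
#'   `NULL` for a family without a tree.
#' @param members Genome ids of the family.
#' @param min_support Minimum percent support to accept the split.
#' @return A list of character vectors, one per subfamily.
#' @export
assign_subfamily <- function(tree, members, min_support = 95) {
  if (length(members) <= 1 || is.null(tree)) {
    return(list(members))
  }
  if (ape::Ntip(tree) == 2) {
    # a two-leaf tree has no internal edge to support a split
    return(list(members))
  }
  clades <- root_bipartition(tree)
  sup <- attr(clades, "support")
  if (is.na(sup) || sup < min_support) {
    warn(paste0(
      "root bipartition support ",
      ifelse(is.na(sup), "unavailable", sup),
      " < ", min_support, "; family kept as one subfamily"
    ))
    return(list(members))
  }
  if (!setequal(unlist(clades), members)) {
    abort("assign_subfamily: tree leaves do not match family members")
  }
  clades
}

# Check that partition `fine` refines partition `coarse`; returns offending
# genome ids (empty when nested).
nesting_violations <- function(fine, coarse) {
  tab <- tibble::tibble(id = names(fine), fine = fine, coarse = coarse[names(fine)])
  bad <- tab |>
    dplyr::group_by(.data$fine) |>
    dplyr::filter(dplyr::n_distinct(.data$coarse) > 1) |>
    dplyr::pull(.data$id)
  bad
}

#' Assemble the full ranked taxonomy
#'
#' Combines the family partition (shared clusters), per-family subfamily
#' splits (tree root bipartitions), and the genus/species partitions
#' (similarity thresholds) into nested assignments with stable placeholder
#' labels. A rank that violates nesting (e.g. a species split across genera)
#' is a hard error naming the offending genomes.
#'
#' @param sim A [similarity_matrix()].
#' @param families Family tibble from [assign_family()].
#' @param subfamilies Named list: family label -> list of subfamily member
#'   vectors (from [assign_subfamily()]); families absent from the list
#'   become single subfamilies.
#' @param species_threshold,genus_threshold Similarity demarcations (percent).
#' @param order_label Order membership is an input (all genomes in one run
#'   are assumed to belong to one order).
#' @param name_map Optional named character vector mapping placeholder labels
#'   (e.g. `"sp1"`) to chosen names.
#' @return A tibble of class `taxonomy_assignment`: `genome_id`, `species`,
#'   `genus`, `subfamily`, `family`, `order`, `evidence`.
#' @export
build_taxonomy <- function(sim, families, subfamilies = list(),
                           species_threshold = 95, genus_threshold = 70,
                           order_label = "order1", name_map = NULL) {
  ids <- sort(rownames(sim))
  sp <- cluster_by_threshold(sim, species_threshold, "sp")
  gn <- cluster_by_threshold(sim, genus_threshold, "gen")
  fam <- setNames(families$family, families$genome_id)[ids]
  if (any(is.na(fam))) {
    abort("build_taxonomy: family partition does not cover all genomes")
  }
  # subfamilies: flatten per-family lists, default one subfamily per family
  sf_members <- list()
  for (f in unique(fam)) {
    mem <- ids[fam == f]
    sfs <- subfamilies[[f]] %||% list(mem)
    if (!setequal(unlist(sfs), mem)) {
      abort(paste0("subfamily split of ", f, " does not match its members"))
    }
    sf_members <- c(sf_members, sfs)
  }
  sf_members <- label_partition(sf_members, "subfam")
  sf_tab <- partition_tibble(sf_members, "genome_id", "subfamily")
  spv <- setNames(sp$taxon, sp$genome_id)[ids]
  gnv <- setNames(gn$taxon, gn$genome_id)[ids]
  sfv <- setNames(sf_tab$subfamily, sf_tab$genome_id)[ids]
  # enforce nesting bottom-up
  checks <- list(
    c("species", "genus"), c("genus", "subfamily"),
    c("subfamily", "family")
  )
  parts <- list(
    species = spv, genus = gnv, subfamily = sfv,
    family = setNames(fam, ids)
  )
  for (ch in checks) {
    bad <- nesting_violations(parts[[ch[1]]], parts[[ch[2]]])
    if (length(bad) > 0) {
      abort(paste0(
        "taxonomy nesting violation: ", ch[1], " split across ",
        ch[2], " ranks for genome(s): ", paste(sort(bad), collapse = ", ")
      ))
    }
  }
  rename <- function(x) {
    if (is.null(name_map)) {
      return(x)
    }
    ifelse(x %in% names(name_map), unname(name_map[x]), x)
  }
  n_sf_per_fam <- tapply(sfv, fam, function(x) length(unique(x)))
  out <- tibble::tibble(
    genome_id = ids,
    species = rename(spv),
    genus = rename(gnv),
    subfamily = rename(sfv),
    family = rename(unname(parts$family)),
    order = order_label,
    evidence = paste0(
      "species:S>=", species_threshold,
      ";genus:S>=", genus_threshold,
      ";family:shared_clusters>=1",
      ";subfamily:",
      ifelse(n_sf_per_fam[fam] > 1, "tree_root_bipartition", "whole_family")
    )
  )
  class(out) <- c("taxonomy_assignment", class(out))
  out
}

#' Wide Table-style view of a taxonomy
#'
#' One row per rank, one column per species; mirrors the familiar
#' rank-by-taxon summary table.
#'
#' @param taxonomy A [build_taxonomy()] result.
#' @return A tibble with `rank` and one column per species-level taxon.
#' @export
taxonomy_wide <- function(taxonomy) {
  tx <- tibble::as_tibble(taxonomy)
  per_sp <- tx |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      genus = unique(.data$genus)[1],
      subfamily = unique(.data$subfamily)[1],
      family = unique(.data$family)[1],
      order = unique(.data$order)[1],
      strains = paste(sort(.data$genome_id), collapse = ","),
      .groups = "drop"
    )
  ranks <- c("order", "family", "subfamily", "genus", "species", "strains")
  rows <- lapply(ranks, function(r) {
    vals <- if (r == "species") per_sp$species else per_sp[[r]]
    tibble::as_tibble(setNames(as.list(vals), per_sp$species)) |>
      dplyr::mutate(rank = r, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Write taxonomy tables to TSV
#'
#' @param taxonomy A [build_taxonomy()] result.
#' @param path_long Output path for the long per-genome table.
#' @param path_wide Optional output path for the wide rank-by-species table.
#' @return `path_long`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path_long, path_wide = NULL) {
  readr::write_tsv(tibble::as_tibble(taxonomy), path_long)
  if (!is.null(path_wide)) {
    readr::write_tsv(taxonomy_wide(taxonomy), path_wide)
  }
  invisible(path_long)
}
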