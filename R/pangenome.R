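#' Global protein identity and bidirectional coverage
#'
#' Aligns two amino-acid sequences globally with affine gap penalties
#' (BLOSUM62, gap open 11, extend 1; terminal gaps free). Identity is
#' `100 * matches / aligned columns` with gap columns included; coverage of
#' each sequence is the span of its aligned region divided by its length.
#'
#' @param a,b Amino-acid strings.
#' @return A tibble with `identity`, `coverage_a`, `coverage_b`.
#' @export
#' @examples
#' pairwise_identity("ACDEFGHIK", "ACDEFGHIR")
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("pairwise_identity: empty sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "overlap", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  cols <- Biostrings::nchar(aln) # alignment length incl. gap columns
  tibble::tibble(
    identity = 100 * Biostrings::nmatch(aln) / cols,
    coverage_a = Biostrings::width(aln@pattern@range) / nchar(a),
    coverage_b = Biostrings::width(aln@subject@range) / nchar(b)
  )
}

# BLOSUM62 scoring matrix, loaded once per session
blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Batched global identity for an index-pair list over a sequence vector;
# alignments are grouped by the subject side to amortise call overhead.
batch_identity <- function(seqs, pairs) {
  aa <- Biostrings::AAStringSet(seqs)
  len <- nchar(seqs)
  by_subj <- split(pairs[, 1], pairs[, 2])
  out <- vector("list", length(by_subj))
  subj_idx <- as.integer(names(by_subj))
  for (h in seq_along(by_subj)) {
    j <- subj_idx[h]
    is <- by_subj[[h]]
    aln <- Biostrings::pairwiseAlignment(
      aa[is], aa[[j]],
      type = "overlap", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1
    )
    cols <- Biostrings::nchar(aln)
    out[[h]] <- tibble::tibble(
      ia = is, ib = j,
      identity = 100 * Biostrings::nmatch(aln) / cols,
      coverage_a = Biostrings::width(aln@pattern@range) / len[is],
      coverage_b = Biostrings::width(aln@subject@range) / len[j]
    )
  }
  dplyr::bind_rows(out)
}

# Candidate pairs sharing at least one length-k amino-acid word. Returns a
# two-column integer matrix of protein indices (i < j).
kmer_candidate_pairs <- function(seqs, k = 5L) {
  n <- length(seqs)
  if (n < 2) {
    return(matrix(integer(0), ncol = 2))
  }
  words <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) {
      return(character(0))
    }
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  idx <- rep.int(seq_len(n), lengths(words))
  buckets <- split(idx, unlist(words, use.names = FALSE))
  buckets <- buckets[lengths(buckets) > 1]
  if (length(buckets) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  keys <- unlist(lapply(buckets, function(b) {
    b <- sort.int(unique(b))
    pr <- utils::combn(b, 2)
    pr[1, ] * (n + 1) + pr[2, ]
  }), use.names = FALSE)
  keys <- unique(keys)
  cbind(keys %/% (n + 1), keys %% (n + 1))
}

#' All-vs-all protein identity edges
#'
#' Computes global-identity edges between proteins, optionally restricting the
#' alignment work to pairs that share at least one amino-acid k-mer (an
#' admissible prefilter for the identity levels at which clustering operates;
#' it can be disabled for exhaustive comparison).
#'
#' @param proteins A protein tibble with `protein_id` and `seq`.
#' @param min_identity Only edges with identity >= this are returned.
#' @param min_coverage Both sequences must have aligned-span coverage >= this.
#' @param prefilter Use the shared k-mer prefilter.
#' @param k Word size for the prefilter.
#' @return A tibble of edges: `protein_a`, `protein_b`, `identity`,
#'   `coverage_a`, `coverage_b`.
#' @export
protein_identity_edges <- function(proteins, min_identity = 0,
                                   min_coverage = 0, prefilter = TRUE,
                                   k = 6L) {
  empty <- tibble::tibble(
    protein_a = character(0), protein_b = character(0),
    identity = numeric(0), coverage_a = numeric(0), coverage_b = numeric(0)
  )
  n <- nrow(proteins)
  if (n < 2) {
    return(empty)
  }
  # alignment identity depends only on the sequences, so align unique
  # sequences once and expand to all carriers afterwards
  useq <- unique(proteins$seq)
  uof <- match(proteins$seq, useq)
  carriers <- split(seq_len(n), uof)
  nu <- length(useq)
  if (prefilter) {
    pairs <- kmer_candidate_pairs(useq, k)
  } else if (nu >= 2) {
    pairs <- t(utils::combn(nu, 2))
  } else {
    pairs <- matrix(integer(0), ncol = 2)
  }
  res <- NULL
  if (nrow(pairs) > 0) {
    res <- batch_identity(useq, pairs)
    res <- res[
      res$identity >= min_identity &
        res$coverage_a >= min_coverage & res$coverage_b >= min_coverage, ,
      drop = FALSE
    ]
  }
  pieces <- list()
  if (!is.null(res) && nrow(res) > 0) {
    # expand unique-sequence edges to every carrier pair
    pieces <- lapply(seq_len(nrow(res)), function(r) {
      ca <- carriers[[res$ia[r]]]
      cb <- carriers[[res$ib[r]]]
      grid <- expand.grid(a = ca, b = cb)
      tibble::tibble(
        protein_a = proteins$protein_id[grid$a],
        protein_b = proteins$protein_id[grid$b],
        identity = res$identity[r],
        coverage_a = res$coverage_a[r],
        coverage_b = res$coverage_b[r]
      )
    })
  }
  # identical sequences are trivially 100 % identity / full coverage
  if (min_identity <= 100) {
    dup_groups <- carriers[lengths(carriers) > 1]
    pieces <- c(pieces, lapply(dup_groups, function(g) {
      pr <- utils::combn(g, 2)
      tibble::tibble(
        protein_a = proteins$protein_id[pr[1, ]],
        protein_b = proteins$protein_id[pr[2, ]],
        identity = 100, coverage_a = 1, coverage_b = 1
      )
    }))
  }
  if (length(pieces) == 0) {
    return(empty)
  }
  dplyr::bind_rows(pieces)
}

#' Connected-component protein clustering at an identity threshold
#'
#' Builds a graph with an edge between two proteins when their global
#' identity reaches `identity_threshold` and both aligned-span coverages reach
#' `coverage_threshold`; clusters are the connected components, so chains of
#' near-threshold pairs merge transitively (MMseqs2 cluster-mode-1
#' semantics). Cluster ids are deterministic: ordered by size (descending),
#' ties by lexicographically smallest member.
#'
#' @param proteins A protein tibble with `protein_id`, `genome_id`, `seq`.
#' @param identity_threshold Percent identity threshold (default 70).
#' @param coverage_threshold Bidirectional aligned-span coverage (default 0.8).
#' @param prefilter,k Passed to [protein_identity_edges()].
#' @param edges Optionally, a precomputed edge tibble from
#'   [protein_identity_edges()] (its `identity`/coverage columns are
#'   re-thresholded here), to reuse alignments across thresholds.
#' @return A tibble with `cluster_id`, `protein_id`, `genome_id`, carrying the
#'   thresholds as attributes `identity_threshold`/`coverage_threshold`.
#' @export
cluster_proteins <- function(proteins, identity_threshold = 70,
                             coverage_threshold = 0.8, prefilter = TRUE,
                             k = 5L, edges = NULL) {
  if (nrow(proteins) == 0) {
    abort("cluster_proteins: no proteins supplied")
  }
  if (is.null(edges)) {
    edges <- protein_identity_edges(
      proteins,
      min_identity = identity_threshold,
      min_coverage = coverage_threshold, prefilter = prefilter, k = k
    )
  }
  edges <- edges[
    edges$identity >= identity_threshold &
      edges$coverage_a >= coverage_threshold &
      edges$coverage_b >= coverage_threshold, ,
    drop = FALSE
  ]
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")],
    directed = FALSE,
    vertices = data.frame(name = proteins$protein_id)
  )
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- label_partition(groups, "cluster")
  out <- partition_tibble(groups, "protein_id", "cluster_id")
  out <- dplyr::left_join(
    out, proteins[, c("protein_id", "genome_id")],
    by = "protein_id"
  )
  out <- out[order(out$cluster_id, out$protein_id), ]
  attr(out, "identity_threshold") <- identity_threshold
  attr(out, "coverage_threshold") <- coverage_threshold
  out
}

#' Build a pangenome presence matrix from cluster membership
#'
#' @param clusters A cluster tibble from [cluster_proteins()].
#' @param genomes Optional character vector fixing the genome set (columns);
#'   defaults to the genomes present in `clusters`.
#' @return An object of class `pangenome`: a list with `matrix` (clusters x
#'   genomes member counts), `clusters` (the membership tibble) and the
#'   thresholds used.
#' @export
pangenome_matrix <- function(clusters, genomes = NULL) {
  genomes <- genomes %||% sort(unique(clusters$genome_id))
  cl_ids <- unique(clusters$cluster_id)
  m <- table(
    factor(clusters$cluster_id, levels = cl_ids),
    factor(clusters$genome_id, levels = genomes)
  )
  m <- matrix(as.integer(m),
    nrow = length(cl_ids),
    dimnames = list(cluster_id = cl_ids, genome_id = genomes)
  )
  structure(
    list(
      matrix = m, clusters = clusters,
      identity_threshold = attr(clusters, "identity_threshold"),
      coverage_threshold = attr(clusters, "coverage_threshold")
    ),
    class = "pangenome"
  )
}

#' @export
print.pangenome <- function(x, ...) {
  cat(
    "<pangenome>", nrow(x$matrix), "protein clusters x", ncol(x$matrix),
    "genomes; identity threshold", x$identity_threshold %||% NA, "%\n"
  )
  cat(
    " core clusters (all genomes):",
    length(core_clusters(x)), "\n"
  )
  invisible(x)
}

#' Core protein clusters of a genome set
#'
#' Clusters with at least one member in every genome of `genome_set`.
#'
#' @param pangenome A [pangenome_matrix()] object.
#' @param genome_set Genomes that must all be represented; defaults to every
#'   genome in the matrix.
#' @return Character vector of core cluster ids.
#' @export
core_clusters <- function(pangenome, genome_set = NULL) {
  m <- pangenome$matrix
  genome_set <- genome_set %||% colnames(m)
  if (length(genome_set) == 0) {
    abort("core_clusters: empty genome set")
  }
  missing <- setdiff(genome_set, colnames(m))
  if (length(missing) > 0) {
    abort(paste0(
      "core_clusters: genome(s) absent from matrix: ",
      paste(missing, collapse = ", ")
    ))
  }
  sub <- m[, genome_set, drop = FALSE]
  rownames(sub)[rowSums(sub >= 1) == length(genome_set)]
}

#' Majority functional label per cluster
#'
#' Assigns each cluster the most frequent non-missing annotation among its
#' members (e.g. best PHROG hits supplied as a table); clusters with no
#' annotated member are labelled `"unknown function"`. Ties are broken
#' lexicographically and flagged.
#'
#' @param clusters A cluster tibble from [cluster_proteins()].
#' @param annotations A tibble with `protein_id` and `label`.
#' @return A tibble with `cluster_id`, `function_label`, `tie_flag`.
#' @export
cluster_function <- function(clusters, annotations) {
  ann <- dplyr::left_join(
    clusters,
    annotations[, c("protein_id", "label")],
    by = "protein_id"
  )
  ann |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      function_label = {
        tab <- table(stats::na.omit(.data$label))
        if (length(tab) == 0) {
          "unknown function"
        } else {
          min(names(tab)[tab == max(tab)])
        }
      },
      tie_flag = {
        tab <- table(stats::na.omit(.data$label))
        length(tab) > 1 && sum(tab == max(tab)) > 1
      },
      .groups = "drop"
    )
}

#' Presence/absence dendrogram over genomes
#'
#' Binarises the pangenome matrix, computes Jaccard distances between genome
#' columns and agglomerates with average linkage. Genome order is fixed
#' (sorted ids) so tie-breaking is deterministic.
#'
#' @param pangenome A [pangenome_matrix()] object with >= 2 genomes.
#' @return An `ape::phylo` dendrogram (ultrametric, from `hclust`).
#' @export
presence_absence_dendrogram <- function(pangenome) {
  m <- pangenome$matrix
  if (ncol(m) < 2) {
    abort("presence_absence_dendrogram: need >= 2 genomes")
  }
  bin <- t(m[, sort(colnames(m)), drop = FALSE] >= 1) * 1
  d <- vegan::vegdist(bin, method = "jaccard", binary = TRUE)
  ape::as.phylo(stats::hclust(d, method = "average"))
}

#' Jaccard distance between two presence/absence profiles
#'
#' `1 - |intersection| / |union|` over the clusters present in either genome.
#'
#' @param a,b Logical or 0/1 vectors of equal length.
#' @return The Jaccard distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) {
    return(0)
  }
  1 - sum(a & b) / u
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pangenome into long presence counts
#'
#' @param x A `pangenome` object.
#' @param ... Unused.
#' @return A tibble with `cluster_id`, `genome_id`, `n_members`, `present`.
#' @export
tidy.pangenome <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    cluster_id = rep(rownames(m), times = ncol(m)),
    genome_id = rep(colnames(m), each = nrow(m)),
    n_members = as.integer(m),
    present = as.integer(m) >= 1
  )
}

#' One-row pangenome summary
#'
#' @param x A `pangenome` object.
#' @param ... Unused.
#' @return A tibble with cluster counts and the mean per-genome core fraction
#'   (core clusters as a share of each genome's clusters, averaged).
#' @export
glance.pangenome <- function(x, ...) {
  m <- x$matrix
  core <- core_clusters(x)
  per_genome <- colSums(m >= 1)
  core_frac <- if (nrow(m) == 0) {
    NA_real_
  } else {
    mean(length(core) / per_genome)
  }
  tibble::tibble(
    n_clusters = nrow(m),
    n_genomes = ncol(m),
    n_core = length(core),
    median_proteins_per_genome = stats::median(colSums(m)),
    mean_core_fraction = core_frac
  )
}

#' Presence/absence heatmap of a pangenome
#'
#' @param object A `pangenome` object.
#' @param ... Unused.
#' @return A ggplot tile plot (clusters on x, genomes on y, ordered by the
#'   presence/absence dendrogram when >= 2 genomes).
#' @export
autoplot.pangenome <- function(object, ...) {
  df <- tidy(object)
  if (ncol(object$matrix) >= 2) {
    dnd <- presence_absence_dendrogram(object)
    ord <- dnd$tip.label
    df$genome_id <- factor(df$genome_id, levels = ord)
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cluster_id, y = .data$genome_id,
    fill = .data$present
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "grey20", `FALSE` = "grey95"),
      name = "present"
    ) +
    ggplot2::labs(x = "protein cluster", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
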