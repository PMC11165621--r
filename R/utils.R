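# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data
#' @importFrom stats setNames
NULL

# Reverse complement of a nucleotide string (IUPAC-aware via Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's RNG afterwards so library functions never perturb user streams.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic labelling of a partition: components ordered by size
# (descending) then by lexicographically smallest member.
label_partition <- function(members_by_group, prefix) {
  stopifnot(is.list(members_by_group))
  mins <- vapply(members_by_group, function(m) min(as.character(m)), character(1))
  sizes <- lengths(members_by_group)
  ord <- order(-sizes, mins)
  labels <- paste0(prefix, seq_along(ord))
  out <- members_by_group[ord]
  names(out) <- labels
  out
}

# Flatten a named list of member vectors into a two-column tibble.
partition_tibble <- function(members_by_group, id_col, label_col) {
  tibble::tibble(
    !!label_col := rep(names(members_by_group), lengths(members_by_group)),
    !!id_col := unlist(members_by_group, use.names = FALSE)
  ) |>
    dplyr::arrange(.data[[id_col]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
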