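#' Read a multi-record nucleotide FASTA into a genome tibble
#'
#' Reads a (possibly multi-line) nucleotide FASTA file and returns one row per
#' record. Sequences are uppercased, `U` is mapped to `T`, and IUPAC ambiguity
#' codes other than `N` are converted to `N` with a warning. The record id is
#' the header token up to the first whitespace; the full header is retained in
#' `description`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `genome_id`, `description`, `seq`, `length`
#'   and `gc` (percent GC over non-`N` bases).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "TT", "TT"), tf)
#' read_genome_fasta(tf)
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path))
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(recs))
  seqs <- chartr("U", "T", seqs)
  bad <- stringr::str_locate(seqs, "[^ACGTNRYSWKMBDHV]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(paste0(
      "non-IUPAC character '", substr(seqs[i], bad[i], bad[i]),
      "' in record '", ids[i], "' at position ", bad[i]
    ))
  }
  n_amb <- sum(stringr::str_count(seqs, "[RYSWKMBDHV]"))
  if (n_amb > 0) {
    warn(paste0(n_amb, " IUPAC ambiguity base(s) converted to N"))
    seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  }
  out <- tibble::tibble(
    genome_id = unname(ids),
    description = unname(headers),
    seq = unname(seqs),
    length = unname(nchar(seqs))
  )
  if (any(out$length == 0)) {
    abort(paste0(
      "empty sequence for record(s): ",
      paste(out$genome_id[out$length == 0], collapse = ", ")
    ))
  }
  out$gc <- vapply(out$seq, gc_content, numeric(1), USE.NAMES = FALSE)
  n_frac <- stringr::str_count(out$seq, "N") / out$length
  if (any(n_frac > 0.10)) {
    warn(paste0(
      "genome(s) with >10% N bases: ",
      paste(out$genome_id[n_frac > 0.10], collapse = ", ")
    ))
  }
  out
}

#' Write a genome tibble to FASTA
#'
#' @param genomes A tibble with at least `genome_id` and `seq` columns.
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path, width = 70L) {
  stopifnot(all(c("genome_id", "seq") %in% names(genomes)))
  x <- Biostrings::BStringSet(setNames(genomes$seq, genomes$genome_id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a protein FASTA into a tibble
#'
#' Header tokens of the form `<genome_id>|<orf>` populate `genome_id`;
#' otherwise `genome_id` is `NA`.
#'
#' @param path Path to an amino-acid FASTA file.
#' @return A tibble with columns `protein_id`, `genome_id` and `seq`.
#' @export
read_protein_fasta <- function(path) {
  recs <- Biostrings::readAAStringSet(path)
  if (length(recs) == 0) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate protein id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  tibble::tibble(
    protein_id = unname(ids),
    genome_id = ifelse(grepl("|", ids, fixed = TRUE),
      sub("\\|.*$", "", ids), NA_character_
    ),
    seq = unname(toupper(as.character(recs)))
  )
}

#' Write a protein tibble to FASTA
#'
#' @param proteins A tibble with `protein_id` and `seq` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  stopifnot(all(c("protein_id", "seq") %in% names(proteins)))
  x <- Biostrings::AAStringSet(setNames(proteins$seq, proteins$protein_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Percent GC of a nucleotide sequence
#'
#' GC is computed over unambiguous bases only: `100 * (G + C) / (A + C + G +
#' T)`. `N` bases are excluded from the denominator.
#'
#' @param seq A single nucleotide string.
#' @return GC percentage in `[0, 100]`.
#' @export
#' @examples
#' gc_content("GATC") # 50
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) > 0)
  gc <- stringr::str_count(seq, "[GC]")
  at <- stringr::str_count(seq, "[AT]")
  if (gc + at == 0) {
    abort("GC content undefined: sequence contains no unambiguous bases")
  }
  100 * gc / (gc + at)
}

#' Per-genome descriptive statistics
#'
#' @param genomes A genome tibble (see [read_genome_fasta()]).
#' @return A tibble with `genome_id`, `length_bp` and `gc_percent`.
#' @export
genome_stats <- function(genomes) {
  tibble::tibble(
    genome_id = genomes$genome_id,
    length_bp = nchar(genomes$seq),
    gc_percent = vapply(genomes$seq, gc_content, numeric(1), USE.NAMES = FALSE)
  )
}
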