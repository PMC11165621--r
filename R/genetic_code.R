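#' Genetic code descriptor
#'
#' Builds the codon table used for ORF prediction and translation. Table 11 is
#' the standard bacterial code (stops TAA, TAG, TGA); table 15 reassigns TAG
#' to glutamine (stops TAA, TGA), the recoding reported in Lak-like
#' megaphages.
#'
#' @param table_id NCBI translation table id, one of 11, 15 or 4 (TGA
#'   reassigned to Trp; provided as a configuration hook).
#' @param start_codons Codons accepted as ORF starts.
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `codons` (named codon-to-amino-acid map, stops as `*`), `stop_codons`
#'   and `start_codons`.
#' @export
#' @examples
#' genetic_code(15)$stop_codons
genetic_code <- function(table_id = 11L,
                         start_codons = "ATG") {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(11L, 15L, 4L)) {
    abort("table_id must be one of 11, 15, 4")
  }
  codons <- Biostrings::getGeneticCode(as.character(table_id))
  structure(
    list(
      table_id = table_id,
      codons = codons,
      stop_codons = names(codons)[codons == "*"],
      start_codons = toupper(start_codons)
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(
    "<genetic_code> table", x$table_id,
    "| stops:", paste(x$stop_codons, collapse = ","),
    "| starts:", paste(x$start_codons, collapse = ","), "\n"
  )
  invisible(x)
}

# Scan one strand of a sequence: for each stop-to-stop interval in each of the
# three frames, emit the ORF running from the first in-frame start codon to
# the codon before the stop (or the contig end). Coordinates are 0-based
# half-open on the scanned strand; the caller maps minus-strand hits back.
scan_frames <- function(s, code, min_orf_len) {
  L <- nchar(s)
  out <- vector("list", 3L)
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3
    if (n_codons < 1) next
    pos <- frame + 1 + 3 * (seq_len(n_codons) - 1)
    codons <- substring(s, pos, pos + 2)
    is_stop <- codons %in% code$stop_codons
    is_start <- codons %in% code$start_codons
    stop_idx <- which(is_stop)
    # segment s spans codons (bnd[s]+1) .. (bnd[s+1]-1); bnd[last] is a
    # virtual stop just past the contig end
    bnd <- c(0L, stop_idx, n_codons + 1L)
    start_idx <- which(is_start & !is_stop)
    if (length(start_idx) == 0) next
    seg_of_start <- findInterval(start_idx, bnd)
    first_start <- start_idx[!duplicated(seg_of_start)]
    seg <- seg_of_start[!duplicated(seg_of_start)]
    seg_end_bnd <- bnd[seg + 1L] # codon index of terminating stop (or virtual)
    has_stop <- seg_end_bnd <= n_codons
    last_codon <- seg_end_bnd - 1L
    # min-length filter applies to the start-to-stop span including the stop
    # codon; reported interval and length exclude the stop codon.
    span_nt <- (last_codon - first_start + 1L + as.integer(has_stop)) * 3L
    keep <- span_nt >= min_orf_len & last_codon >= first_start
    if (!any(keep)) next
    out[[frame + 1L]] <- tibble::tibble(
      start = frame + 3L * (first_start[keep] - 1L),
      end = frame + 3L * last_codon[keep],
      frame = frame,
      has_stop = has_stop[keep]
    )
  }
  dplyr::bind_rows(out)
}

#' Six-frame ORF prediction under a genetic code
#'
#' Rule-based ORF caller: in each of the six reading frames, every
#' stop-delimited interval yields at most one ORF, running from the first
#' in-frame start codon to the codon preceding the stop (contigs are treated
#' as linear, so intervals may end at the contig edge). Codons containing
#' ambiguous bases never act as starts or stops. The minimum-length filter is
#' applied to the start-to-stop span including the stop codon; the reported
#' coordinates and `length_nt` exclude the stop codon.
#'
#' @param seq A single nucleotide string.
#' @param code A [genetic_code()].
#' @param min_orf_len Minimum ORF length in nt (>= 3, divisible by 3).
#' @return A tibble with 0-based half-open forward-strand coordinates:
#'   `start`, `end`, `strand`, `frame`, `length_nt`, `has_stop`.
#' @export
#' @examples
#' find_orfs("ATGAAAAAATAGATGCCCTAA", genetic_code(11), min_orf_len = 9)
find_orfs <- function(seq, code = genetic_code(11), min_orf_len = 90L) {
  stopifnot(is.character(seq), length(seq) == 1)
  min_orf_len <- as.integer(min_orf_len)
  if (min_orf_len < 3L || min_orf_len %% 3L != 0L) {
    abort("min_orf_len must be >= 3 and divisible by 3")
  }
  L <- nchar(seq)
  empty <- tibble::tibble(
    start = integer(), end = integer(), strand = character(),
    frame = integer(), length_nt = integer(), has_stop = logical()
  )
  if (L < min_orf_len) {
    return(empty)
  }
  seq <- toupper(seq)
  fwd <- scan_frames(seq, code, min_orf_len)
  rev <- scan_frames(revcomp(seq), code, min_orf_len)
  if (nrow(fwd) > 0) fwd$strand <- "+"
  if (nrow(rev) > 0) {
    # map [start, end) on the reverse strand back to forward coordinates
    tmp_start <- L - rev$end
    rev$end <- L - rev$start
    rev$start <- tmp_start
    rev$strand <- "-"
  }
  out <- dplyr::bind_rows(fwd, rev)
  if (nrow(out) == 0) {
    return(empty)
  }
  out$length_nt <- out$end - out$start
  out[order(out$start, out$end, out$strand), c(
    "start", "end", "strand", "frame", "length_nt", "has_stop"
  )]
}

#' Greedy non-redundant ORF selection
#'
#' Selects ORFs longest-first; a candidate is kept iff it overlaps every
#' already-kept ORF by at most `max_overlap` nt. Ties on length are broken by
#' smaller start, then by `+` strand. This guarantees that summed ORF lengths
#' cannot exceed the genome length (for `max_overlap = 0`).
#'
#' @param orfs An ORF tibble from [find_orfs()] (one genome).
#' @param max_overlap Maximum tolerated pairwise overlap in nt.
#' @return The kept subset of `orfs`, ordered by `start`.
#' @export
select_orfs <- function(orfs, max_overlap = 30L) {
  if (nrow(orfs) == 0) {
    return(orfs)
  }
  ord <- order(-orfs$length_nt, orfs$start, orfs$strand != "+")
  s <- orfs$start[ord]
  e <- orfs$end[ord]
  keep <- logical(length(ord))
  ks <- integer(0)
  ke <- integer(0)
  for (i in seq_along(ord)) {
    ov <- pmin(ke, e[i]) - pmax(ks, s[i])
    if (length(ov) == 0 || all(ov <= max_overlap)) {
      keep[i] <- TRUE
      ks <- c(ks, s[i])
      ke <- c(ke, e[i])
    }
  }
  kept <- orfs[sort(ord[keep]), , drop = FALSE]
  kept[order(kept$start, kept$end), , drop = FALSE]
}

#' Coding capacity of a genome under a genetic code
#'
#' The summed length of the selected (non-redundant) predicted ORFs as a
#' percentage of genome length -- the statistic whose differential between
#' translation tables exposes stop-codon reassignment.
#'
#' @inheritParams find_orfs
#' @inheritParams select_orfs
#' @return Percent in `[0, 100]`.
#' @export
coding_capacity <- function(seq, code = genetic_code(11), min_orf_len = 90L,
                            max_overlap = 30L) {
  orfs <- select_orfs(find_orfs(seq, code, min_orf_len), max_overlap)
  if (nrow(orfs) == 0) {
    return(0)
  }
  100 * sum(orfs$length_nt) / nchar(seq)
}

#' Genetic-code assignment from the coding-capacity differential
#'
#' For each genome, computes coding capacity under tables 11 and 15 with
#' identical ORF-calling parameters and assigns table 15 iff the differential
#' `delta = cc15 - cc11` reaches `delta_threshold` percentage points. A genome
#' recoded to read TAG as glutamine has its genes fragmented under table 11,
#' depressing cc11; a standard-code genome shows only a small differential.
#'
#' @param genomes A genome tibble (see [read_genome_fasta()]) or a single
#'   sequence string.
#' @param delta_threshold Assignment threshold in percentage points.
#' @param min_orf_len,max_overlap ORF-calling parameters shared by both codes.
#' @param start_codons Codons accepted as ORF starts.
#' @return A tibble with `genome_id`, `cc11`, `cc15`, `delta`,
#'   `assigned_table` and `delta_threshold`.
#' @export
call_genetic_code <- function(genomes, delta_threshold = 10, min_orf_len = 90L,
                              max_overlap = 30L,
                              start_codons = "ATG") {
  if (is.character(genomes)) {
    genomes <- tibble::tibble(
      genome_id = names(genomes) %||% paste0("g", seq_along(genomes)),
      seq = unname(genomes)
    )
  }
  code11 <- genetic_code(11, start_codons)
  code15 <- genetic_code(15, start_codons)
  purrr::map2_dfr(genomes$genome_id, genomes$seq, function(id, s) {
    cc11 <- coding_capacity(s, code11, min_orf_len, max_overlap)
    cc15 <- coding_capacity(s, code15, min_orf_len, max_overlap)
    delta <- cc15 - cc11
    tibble::tibble(
      genome_id = id, cc11 = cc11, cc15 = cc15, delta = delta,
      assigned_table = ifelse(delta >= delta_threshold, 15L, 11L),
      delta_threshold = delta_threshold
    )
  })
}

#' Code assignment from precomputed coding capacities
#'
#' The pure decision rule behind [call_genetic_code()]: the differential
#' `delta = cc15 - cc11` assigns table 15 iff it reaches the threshold
#' (e.g. capacities of 90 % under table 15 and 70 % under table 11 give a
#' differential of 20 points, a clear table-15 call).
#'
#' @param cc11,cc15 Coding capacities (percent) under tables 11 and 15.
#' @param delta_threshold Assignment threshold in percentage points.
#' @return A tibble with `cc11`, `cc15`, `delta`, `assigned_table`,
#'   `delta_threshold`.
#' @export
#' @examples
#' assign_code_from_capacities(70, 90)
assign_code_from_capacities <- function(cc11, cc15, delta_threshold = 10) {
  delta <- cc15 - cc11
  tibble::tibble(
    cc11 = cc11, cc15 = cc15, delta = delta,
    assigned_table = ifelse(delta >= delta_threshold, 15L, 11L),
    delta_threshold = delta_threshold
  )
}

# Translate a forward-strand nucleotide interval (0-based half-open, minus
# strand handled) under `code`; fuzzy codons become X.
translate_interval <- function(seq, start, end, strand, code) {
  nt <- substr(seq, start + 1L, end)
  if (strand == "-") nt <- revcomp(nt)
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    genetic.code = code$codons, if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

#' Predict the proteome of one or more genomes
#'
#' Runs the ORF caller under each genome's assigned translation table,
#' applies non-redundant selection, and translates the selected ORFs. ORFs
#' whose translation would be shorter than 10 aa or that lack a terminating
#' stop and a start are retained as long as they pass the length filter.
#'
#' @param genomes A genome tibble.
#' @param table_ids Integer vector (recycled) of translation tables per
#'   genome, e.g. from [call_genetic_code()]`$assigned_table`.
#' @param min_orf_len,max_overlap ORF-calling parameters.
#' @param start_codons Codons accepted as ORF starts.
#' @return A protein tibble: `protein_id` (`genome|orfNNNN`), `genome_id`,
#'   `start`, `end`, `strand`, `frame`, `length_nt`, `table_id`, `seq`.
#' @export
predict_proteome <- function(genomes, table_ids = 11L, min_orf_len = 90L,
                             max_overlap = 30L,
                             start_codons = "ATG") {
  table_ids <- rep_len(as.integer(table_ids), nrow(genomes))
  purrr::pmap_dfr(
    list(genomes$genome_id, genomes$seq, table_ids),
    function(id, s, tid) {
      code <- genetic_code(tid, start_codons)
      orfs <- select_orfs(find_orfs(s, code, min_orf_len), max_overlap)
      if (nrow(orfs) == 0) {
        return(tibble::tibble())
      }
      nt <- substring(s, orfs$start + 1L, orfs$end)
      minus <- orfs$strand == "-"
      if (any(minus)) nt[minus] <- revcomp(nt[minus])
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(nt),
        genetic.code = code$codons, if.fuzzy.codon = "X",
        no.init.codon = TRUE
      ))
      tibble::tibble(
        protein_id = sprintf("%s|orf%04d", id, seq_len(nrow(orfs))),
        genome_id = id,
        start = orfs$start, end = orfs$end, strand = orfs$strand,
        frame = orfs$frame, length_nt = orfs$length_nt,
        table_id = tid, seq = aa
      )
    }
  )
}
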