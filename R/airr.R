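# AIRR rearrangement table I/O and the two-stage UMI collapsing.

AIRR_REQUIRED <- c("sequence_id", "sequence", "sequence_alignment",
                   "germline_alignment", "v_call", "j_call", "junction",
                   "junction_length", "c_call", "subject_id",
                   "duplicate_count")

#' Read an AIRR rearrangement TSV
#'
#' Checks for the mandatory columns and preserves any additional ones.
#' The round trip through [writeAirr()] is lossless for all columns.
#'
#' @param path TSV file path.
#' @param required character vector of mandatory columns.
#' @return data.frame of rearrangements.
#' @export
readAirr <- function(path, required = AIRR_REQUIRED) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(sequence_id = "character"))
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("AIRR table is missing mandatory columns: ",
         paste(missing, collapse = ", "))
  tab
}

#' @rdname readAirr
#' @param table data.frame of rearrangements.
#' @export
writeAirr <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Collapse UMI-tagged reads into unique sequences
#'
#' Stage 1 groups reads by UMI (splitting groups of discordant read lengths
#' by length first) and emits a per-group majority-vote consensus, ties
#' resolved by alphabetical base order; each group counts as one mRNA
#' molecule. Stage 2 merges consensus records with identical full-length
#' sequence and identical constant primer, summing molecule counts into
#' `duplicate_count`. The output row count therefore equals the number of
#' distinct (consensus sequence, constant primer) pairs. Reads sharing a UMI
#' by collision are treated as one molecule.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `umi`,
#'   `constant_primer_id`, `subject_id` (single subject).
#' @return data.frame with `sequence_id`, `sequence`, `constant_primer_id`,
#'   `subject_id`, `duplicate_count`.
#' @export
collapseReads <- function(reads) {
  need <- c("sequence", "umi", "constant_primer_id", "subject_id")
  missing <- setdiff(need, names(reads))
  if (length(missing))
    stop("read table is missing columns: ", paste(missing, collapse = ", "))
  if (length(unique(reads$subject_id)) > 1L)
    stop("collapseReads expects reads from a single subject")
  # stage 1: per (umi, read length) consensus
  key <- paste(reads$umi, nchar(reads$sequence), sep = "|")
  groups <- split(seq_len(nrow(reads)), key)
  cons <- vapply(groups, function(idx) {
    .consensus(reads$sequence[idx])
  }, character(1))
  primer <- vapply(groups, function(idx) {
    reads$constant_primer_id[idx][1]
  }, character(1))
  # stage 2: merge identical (sequence, primer), one molecule per UMI group
  key2 <- paste(primer, cons, sep = "|")
  agg <- aggregate(list(duplicate_count = rep(1L, length(cons))),
                   by = list(key2 = key2), FUN = sum)
  ord <- order(agg$key2)
  agg <- agg[ord, , drop = FALSE]
  split2 <- regmatches(agg$key2, regexpr("|", agg$key2, fixed = TRUE),
                       invert = TRUE)
  data.frame(
    sequence_id = sprintf("collapsed%05d", seq_len(nrow(agg))),
    sequence = vapply(split2, `[`, "", 2L),
    constant_primer_id = vapply(split2, `[`, "", 1L),
    subject_id = reads$subject_id[1],
    duplicate_count = agg$duplicate_count,
    stringsAsFactors = FALSE)
}

# majority-vote consensus of equal-length strings; ties by alphabetical base
.consensus <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  paste(apply(m, 2L, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]   # ties: first alphabetically (table is sorted)
  }), collapse = "")
}

#' Flag and drop unproductive rearrangements
#'
#' A record is productive when its junction length is a multiple of 3 and
#' the translation of `sequence_alignment` contains no stop codon.
#'
#' @param table AIRR rearrangement data.frame.
#' @return the productive subset, with a `productive` column added.
#' @export
filterProductive <- function(table) {
  prod <- vapply(seq_len(nrow(table)), function(i) {
    table$junction_length[i] %% 3L == 0L &&
      !grepl("*", translateNt(table$sequence_alignment[i]), fixed = TRUE)
  }, logical(1))
  table$productive <- prod
  table[prod, , drop = FALSE]
}
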