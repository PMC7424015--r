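# VH4-34 self-reactivity motifs: the Ala-Val-Tyr (AVY) hydrophobic patch in
# FWR1 and the Asn-X-Ser N-glycosylation sequon (NHS, X = His in germline)
# in CDR2. Mutation of these germline-encoded motifs marks tolerance-driven
# redemption away from self-reactivity.

# locate a translated pattern inside a region of the germline; returns the
# 1-based nt start of the first matching codon
.find_motif_nt <- function(germSeq, regions, regionName, aaPattern) {
  r <- regions[regions$region == regionName, , drop = FALSE]
  if (!nrow(r)) stop("region ", regionName, " absent from region table")
  aa <- translateNt(substr(germSeq, r$start, r$end))
  hit <- regexpr(aaPattern, aa)
  if (hit == -1L)
    stop("motif ", aaPattern, " not found in ", regionName,
         " of the germline (gene mis-specified?)")
  r$start + (as.integer(hit) - 1L) * 3L
}

#' Score the AVY and NHS motifs of a VH4-34(-like) sequence
#'
#' The motif codon positions are located in the germline via a translated
#' pattern search (AVY in the FWR1 translation; N-x-S in the CDR2
#' translation). The AVY patch is `intact` when the observed translation of
#' its three codons equals the germline translation and `mutated` on any
#' amino-acid difference (synonymous nucleotide changes leave it intact).
#' The NHS sequon follows the canonical sequon rule: it is destroyed only
#' when the first position is no longer Asn, the third no longer Ser, or
#' the middle residue becomes Pro. Either state is `unscored` when a motif
#' codon overlaps a gap or `N`.
#'
#' @param seqAlign aligned observed sequence.
#' @param germAlign aligned germline sequence.
#' @param regions region table of the called V gene ([glRegions()]).
#' @return list with `avy_state`, `nhs_state` and `category` (one of
#'   `both_unmutated`, `avy_only_mutated`, `nhs_only_mutated`,
#'   `both_mutated`; `NA` when either motif is unscored).
#' @export
scoreVH434Motifs <- function(seqAlign, germAlign, regions) {
  avyStart <- .find_motif_nt(germAlign, regions, "FWR1", "AVY")
  nhsStart <- .find_motif_nt(germAlign, regions, "CDR2", "N.S")

  codons <- function(s, start) substring(s, start + c(0L, 3L, 6L),
                                         start + c(2L, 5L, 8L))
  score <- function(start, rule) {
    obs <- codons(seqAlign, start)
    germ <- codons(germAlign, start)
    if (any(!strsplit(paste(obs, collapse = ""), "")[[1]] %in% DNA_BASES))
      return("unscored")
    obsAA <- vapply(obs, .translate_codon, "")
    germAA <- vapply(germ, .translate_codon, "")
    rule(obsAA, germAA)
  }
  avy <- score(avyStart, function(obsAA, germAA) {
    if (all(obsAA == germAA)) "intact" else "mutated"
  })
  nhs <- score(nhsStart, function(obsAA, germAA) {
    if (obsAA[1] == "N" && obsAA[3] == "S" && obsAA[2] != "P")
      "intact" else "mutated"
  })
  category <- if (avy == "unscored" || nhs == "unscored") NA_character_
  else if (avy == "intact" && nhs == "intact") "both_unmutated"
  else if (avy == "mutated" && nhs == "intact") "avy_only_mutated"
  else if (avy == "intact" && nhs == "mutated") "nhs_only_mutated"
  else "both_mutated"
  list(avy_state = avy, nhs_state = nhs, category = category)
}

MOTIF_CATEGORIES <- c("both_unmutated", "avy_only_mutated",
                      "nhs_only_mutated", "both_mutated")

#' Score all VH4-34-like sequences of a table
#'
#' @param table AIRR rearrangement data.frame.
#' @param db a [GermlineDatabase].
#' @param vGene the VH4-34-like gene name.
#' @return data.frame: `sequence_id`, `avy_state`, `nhs_state`, `category`
#'   for the sequences calling `vGene`.
#' @export
scoreMotifTable <- function(table, db, vGene = "IGHV4-34S") {
  sel <- which(getGene(table$v_call) == vGene)
  regions <- glRegions(db, vGene)
  rows <- lapply(sel, function(i) {
    st <- scoreVH434Motifs(table$sequence_alignment[i],
                           table$germline_alignment[i], regions)
    data.frame(sequence_id = table$sequence_id[i],
               avy_state = st$avy_state, nhs_state = st$nhs_state,
               category = st$category, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(sequence_id = character(), avy_state = character(),
                      nhs_state = character(), category = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Motif category proportions by group
#'
#' Per group (for instance age group by subset), the proportions of the four
#' mutation-status categories among scored VH4-34 sequences. Proportions sum
#' to 1 per group; groups without scored sequences are omitted.
#'
#' @param status data.frame from [scoreMotifTable()] joined with grouping
#'   columns.
#' @param groupCols character vector of grouping column names.
#' @return long data.frame: grouping columns, `category`, `n`, `prop`.
#' @export
motifCategoryProportions <- function(status, groupCols) {
  scored <- status[!is.na(status$category), , drop = FALSE]
  if (!nrow(scored))
    return(data.frame())
  key <- do.call(paste, c(scored[groupCols], sep = "|"))
  out <- lapply(split(seq_len(nrow(scored)), key), function(idx) {
    tab <- table(factor(scored$category[idx], levels = MOTIF_CATEGORIES))
    df <- scored[idx[1], groupCols, drop = FALSE]
    df <- df[rep(1L, length(MOTIF_CATEGORIES)), , drop = FALSE]
    df$category <- MOTIF_CATEGORIES
    df$n <- as.integer(tab)
    df$prop <- as.numeric(tab) / length(idx)
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
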