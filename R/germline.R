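# Embedded toy germline reference. Synthetic genes, IMGT-like in structure:
# V genes carry explicit codon-aligned FWR1/CDR1/FWR2/CDR2/FWR3 boundaries
# followed by the conserved Cys-104 codon and a short trimmable 3' tail;
# J genes are a trimmable 5' part, the conserved Trp-118 codon and an
# in-frame FR4 remainder.

# non-stop codons, fixed order for deterministic construction
.sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  sort(setdiff(all3, c("TAA", "TAG", "TGA")))
})

# minimal multiplicative congruential generator so that database construction
# never touches R's global RNG stream
.lcg_new <- function(state) {
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}
.lcg_int <- function(gen, n, max) {
  out <- integer(n)
  for (i in seq_len(n)) {
    gen$state <- (48271 * gen$state) %% 2147483647
    out[i] <- as.integer(gen$state %% max) + 1L
  }
  out
}

.V_BOUNDS <- data.frame(
  region = c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3"),
  start = c(1L, 76L, 100L, 151L, 175L),
  end = c(75L, 99L, 150L, 174L, 288L)
)

#' Build the embedded toy germline database
#'
#' Deterministically constructs a self-contained IMGT-like reference with
#' eight V genes spanning families V1-V4 (including a VH1-8-like gene and a
#' VH4-34-like gene whose FWR1 translation contains the Ala-Val-Tyr
#' hydrophobic patch and whose CDR2 translation contains the Asn-His-Ser
#' N-glycosylation sequon), three D genes and six J genes of which the
#' J6-like gene is the longest. All V-gene regions are codon aligned and the
#' coding frame is free of stop codons. Repeated calls return identical
#' databases; the global RNG state is not consumed.
#'
#' @return a [GermlineDatabase].
#' @export
buildToyGermlineDb <- function() {
  gen <- .lcg_new(20200806)
  v_genes <- c("IGHV1-2S", "IGHV1-8S", "IGHV1-69S", "IGHV2-5S",
               "IGHV3-7S", "IGHV3-23S", "IGHV4-34S", "IGHV4-59S")
  seqs <- character()
  meta <- data.frame(gene = character(), type = character(),
                     anchor = integer())
  regions <- data.frame(gene = character(), region = character(),
                        start = integer(), end = integer())
  for (g in v_genes) {
    codons <- .sense_codons[.lcg_int(gen, 96L, length(.sense_codons))]
    if (g == "IGHV4-34S") {
      codons[8:10] <- c("GCT", "GTT", "TAT")    # A-V-Y in FWR1
      codons[52:54] <- c("AAT", "CAT", "TCT")   # N-H-S in CDR2 (codons 2-4)
    }
    body <- paste(codons, collapse = "")
    tail_nt <- paste(DNA_BASES[.lcg_int(gen, 7L, 4L)], collapse = "")
    seqs[g] <- paste0(body, "TGT", tail_nt)
    meta <- rbind(meta, data.frame(gene = g, type = "V", anchor = 289L))
    regions <- rbind(
      regions,
      cbind(gene = g, .V_BOUNDS),
      data.frame(gene = g, region = "CYS104", start = 289L, end = 291L)
    )
  }
  d_genes <- c("IGHD2-2S" = 16L, "IGHD3-10S" = 20L, "IGHD6-19S" = 12L)
  for (g in names(d_genes)) {
    seqs[g] <- paste(DNA_BASES[.lcg_int(gen, d_genes[[g]], 4L)], collapse = "")
    meta <- rbind(meta, data.frame(gene = g, type = "D", anchor = NA_integer_))
  }
  fr4 <- "GGCCAAGGGACCACGGTCACCGTCTCCTCA"  # 30 nt, in frame, no stops
  j5 <- c("IGHJ1S" = 9L, "IGHJ2S" = 12L, "IGHJ3S" = 12L,
          "IGHJ4S" = 15L, "IGHJ5S" = 15L, "IGHJ6S" = 33L)
  for (g in names(j5)) {
    up <- paste(DNA_BASES[.lcg_int(gen, j5[[g]], 4L)], collapse = "")
    seqs[g] <- paste0(up, "TGG", fr4)
    meta <- rbind(meta, data.frame(gene = g, type = "J",
                                   anchor = j5[[g]] + 1L))
    regions <- rbind(regions,
                     data.frame(gene = g, region = "TRP118",
                                start = j5[[g]] + 1L, end = j5[[g]] + 3L))
  }
  new("GermlineDatabase",
      sequences = Biostrings::DNAStringSet(seqs),
      meta = meta, regions = regions)
}

#' Read a germline reference from FASTA plus a region table
#'
#' The regions TSV must have columns `gene`, `type`, `region`, `start`,
#' `end`, with one row per FWR/CDR region of each V gene (1-based inclusive
#' nucleotide coordinates on the ungapped germline) and optional `CYS104`
#' (V) and `TRP118` (J) anchor rows. Every FASTA id must appear in the
#' regions table's `gene`/`type` listing.
#'
#' @param fastaPath path to the germline FASTA.
#' @param regionsPath path to the regions TSV.
#' @return a [GermlineDatabase].
#' @export
readGermline <- function(fastaPath, regionsPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  reg <- read.delim(regionsPath, stringsAsFactors = FALSE)
  need <- c("gene", "type", "region", "start", "end")
  if (!all(need %in% names(reg)))
    stop("regions table must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(names(seqs), reg$gene)
  if (length(missing))
    stop("FASTA ids absent from regions table: ",
         paste(missing, collapse = ", "))
  meta <- unique(reg[, c("gene", "type")])
  anchor <- vapply(meta$gene, function(g) {
    a <- reg$start[reg$gene == g & reg$region %in% c("CYS104", "TRP118")]
    if (length(a)) as.integer(a[1]) else NA_integer_
  }, integer(1))
  meta$anchor <- anchor
  regions <- reg[, c("gene", "region", "start", "end")]
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  new("GermlineDatabase", sequences = seqs,
      meta = meta[, c("gene", "type", "anchor")], regions = regions)
}

#' Write a germline database to FASTA plus a region table
#'
#' Inverse of [readGermline()]: round-trips all genes, region boundaries and
#' anchor codons.
#'
#' @param db a [GermlineDatabase].
#' @param fastaPath output FASTA path.
#' @param regionsPath output regions TSV path.
#' @return invisibly, the two paths.
#' @export
writeGermline <- function(db, fastaPath, regionsPath) {
  stopifnot(is(db, "GermlineDatabase"))
  Biostrings::writeXStringSet(db@sequences, fastaPath)
  regions <- db@regions
  # genes without region annotation (D genes) still need a row so that the
  # gene/type listing round-trips
  bare <- setdiff(names(db@sequences), regions$gene)
  if (length(bare))
    regions <- rbind(regions,
                     data.frame(gene = bare, region = "SPAN", start = 1L,
                                end = Biostrings::width(db@sequences[bare])))
  reg <- merge(regions, db@meta[, c("gene", "type")], by = "gene",
               sort = FALSE)
  reg <- reg[order(reg$gene, reg$start), c("gene", "type", "region",
                                           "start", "end")]
  write.table(reg, regionsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastaPath, regionsPath))
}
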