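#' @import methods
#' @importFrom stats rbinom rgeom rnorm rpois runif setNames aggregate
#'   binom.test kruskal.test wilcox.test lm pf prcomp sd var complete.cases
#'   coef residuals
#' @importFrom utils read.delim write.table head
#' @importFrom grDevices chull
NULL

DNA_BASES <- c("A", "C", "G", "T")

# codon -> amino acid lookup, "*" for stop
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Translate a nucleotide string codon-by-codon
#'
#' Positions containing characters other than A/C/G/T (e.g. `N` or the IMGT
#' gap `.`) yield `X` for the affected codon. Trailing bases that do not fill
#' a codon are dropped.
#'
#' @param nt single nucleotide string.
#' @return single amino-acid string (`*` marks stop codons).
#' @export
translateNt <- function(nt) {
  if (!is.character(nt) || length(nt) != 1L)
    stop("translateNt expects a single character string")
  n <- nchar(nt)
  if (n < 3L) return("")
  n <- n - n %% 3L
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .codon_table[toupper(codons)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.translate_codon <- function(codon) {
  aa <- .codon_table[toupper(codon)]
  ifelse(is.na(aa), "X", aa)
}

# hamming distance between equal-length strings; positions where either side
# is not A/C/G/T are skipped
.hamming <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(x) == length(y))
  ok <- x %in% DNA_BASES & y %in% DNA_BASES
  sum(x[ok] != y[ok])
}

# pairwise hamming distance matrix for equal-length strings (exact positions,
# no skipping) -- used for CDR3 clustering where sequences are plain ACGT
.hamming_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 1L) return(matrix(0L, 1L, 1L))
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  D <- matrix(0L, n, n)
  for (p in seq_len(L)) {
    D <- D + outer(m[, p], m[, p], "!=")
  }
  D
}

#' Extract the gene from an AIRR-style call
#'
#' Strips the allele designation (`*01`) and, for ambiguous comma-separated
#' multi-gene calls, keeps the first listed call.
#'
#' @param call character vector of V/D/J calls (e.g. `"IGHV1-8*01,IGHV1-2*02"`).
#' @return character vector of gene names (e.g. `"IGHV1-8"`).
#' @export
getGene <- function(call) {
  first <- sub(",.*$", "", call)
  sub("\\*.*$", "", first)
}

#' Extract the gene family from a V call
#'
#' @param call character vector of V calls.
#' @return family labels such as `"V1"` for `"IGHV1-8"`.
#' @export
getFamily <- function(call) {
  sub("^IGH(V[0-9]+).*$", "\\1", getGene(call))
}

AGE_GROUP_LEVELS <- c("0-3", "4-8", "9-16", "17-25", "26-39", "40+")

#' Assign ages to the six study age groups
#'
#' Groups are 0-3, 4-8, 9-16, 17-25, 26-39 years and 40+.
#'
#' @param age numeric vector of ages in years.
#' @return factor with the six age-group levels.
#' @export
assignAgeGroup <- function(age) {
  stopifnot(is.numeric(age), all(age >= 0))
  idx <- findInterval(age, c(0, 4, 9, 17, 26, 40))
  factor(AGE_GROUP_LEVELS[idx], levels = AGE_GROUP_LEVELS)
}

# run code with a private RNG stream, restoring the caller's .Random.seed
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a 32-bit-safe child seed from a master seed and an index
.child_seed <- function(seed, index) {
  (as.numeric(seed) * 1103L + as.numeric(index) * 7919) %% 2147483647
}
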