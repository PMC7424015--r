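#' GermlineDatabase: reference V/D/J genes with region annotation
#'
#' Holds ungapped germline nucleotide sequences together with, for V genes,
#' 1-based inclusive FWR1/CDR1/FWR2/CDR2/FWR3 boundaries and the conserved
#' Cys-104 codon, and for J genes the conserved Trp-118 codon. All boundary
#' coordinates are on the ungapped germline sequence and regions must be
#' codon-aligned (length divisible by 3) and non-overlapping.
#'
#' @slot sequences [Biostrings::DNAStringSet] of germline genes, named.
#' @slot meta data.frame with columns `gene`, `type` (`"V"`, `"D"`, `"J"`)
#'   and `anchor` (start of the conserved Cys codon for V genes, of the
#'   conserved Trp codon for J genes, `NA` for D genes).
#' @slot regions data.frame with columns `gene`, `region`, `start`, `end`
#'   (V-gene FWR/CDR boundaries, 1-based inclusive).
#' @export
setClass("GermlineDatabase",
  representation(
    sequences = "DNAStringSet",
    meta = "data.frame",
    regions = "data.frame"
  )
)

V_REGIONS <- c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3")

setValidity("GermlineDatabase", function(object) {
  msg <- character()
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "sequences must be uniquely named")
  if (!all(c("gene", "type", "anchor") %in% names(object@meta)))
    msg <- c(msg, "meta must have columns gene, type, anchor")
  if (!setequal(object@meta$gene, nm))
    msg <- c(msg, "meta genes must match sequence names")
  if (!all(object@meta$type %in% c("V", "D", "J")))
    msg <- c(msg, "gene type must be V, D or J")
  r <- object@regions
  if (nrow(r)) {
    if (!all(c("gene", "region", "start", "end") %in% names(r)))
      msg <- c(msg, "regions must have columns gene, region, start, end")
    else {
      if (!all(r$gene %in% nm))
        msg <- c(msg, "region gene not present in sequences")
      fw <- r$region %in% V_REGIONS
      bad <- fw & (r$end - r$start + 1L) %% 3L != 0L
      if (any(bad))
        msg <- c(msg, sprintf("region %s of %s is not a codon multiple",
                              r$region[bad][1], r$gene[bad][1]))
      for (g in unique(r$gene)) {
        rg <- r[r$gene == g & r$region %in% V_REGIONS, , drop = FALSE]
        rg <- rg[order(rg$start), , drop = FALSE]
        if (nrow(rg) > 1 && any(rg$start[-1] <= rg$end[-nrow(rg)]))
          msg <- c(msg, sprintf("overlapping regions for gene %s", g))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GermlineDatabase compact display
#' @param object a `GermlineDatabase`.
#' @export
setMethod("show", "GermlineDatabase", function(object) {
  tab <- table(object@meta$type)
  cat("GermlineDatabase with", length(object@sequences), "genes (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
})

#' Accessors for GermlineDatabase
#'
#' `glGenes` lists gene names (optionally by type), `glSequence` returns the
#' ungapped nucleotide sequence of one gene as a character string,
#' `glRegions` the FWR/CDR boundary table of one V gene, `glAnchor` the
#' conserved-codon start (Cys-104 for V, Trp-118 for J), and `vSegmentEnd`
#' the last nucleotide of FWR3 (the 3' end of the mutation-scored V segment).
#'
#' @param db a `GermlineDatabase`.
#' @param type optional gene type filter (`"V"`, `"D"`, `"J"`).
#' @param gene gene name.
#' @return see individual descriptions.
#' @export
glGenes <- function(db, type = NULL) {
  stopifnot(is(db, "GermlineDatabase"))
  if (is.null(type)) return(db@meta$gene)
  db@meta$gene[db@meta$type %in% type]
}

#' @rdname glGenes
#' @export
glSequence <- function(db, gene) {
  stopifnot(gene %in% names(db@sequences))
  as.character(db@sequences[[gene]])
}

#' @rdname glGenes
#' @export
glRegions <- function(db, gene) {
  r <- db@regions[db@regions$gene == gene & db@regions$region %in% V_REGIONS, ,
                  drop = FALSE]
  r <- r[order(r$start), c("region", "start", "end"), drop = FALSE]
  rownames(r) <- NULL
  r
}

#' @rdname glGenes
#' @export
glAnchor <- function(db, gene) {
  db@meta$anchor[match(gene, db@meta$gene)]
}

#' @rdname glGenes
#' @export
vSegmentEnd <- function(db, gene) {
  r <- glRegions(db, gene)
  if (!nrow(r)) stop("no region annotation for gene ", gene)
  max(r$end)
}

#' LineageTree: clonal lineage with trunk length and Gini index
#'
#' A rooted tree over the unique sequences of one clone. The root is the
#' germline reconstruction (germline V and J with the junction-internal
#' N region masked as ambiguous); the most recent common ancestor (MRCA) of
#' the observed sequences is inferred by position-wise consensus of shared
#' non-germline bases. The trunk length is the nucleotide distance from the
#' root to the MRCA counting only unmasked positions; the Gini index
#' summarises inequality of per-sequence copy counts.
#'
#' @slot cloneId clone identifier.
#' @slot nodes data.frame with columns `id`, `sequence`, `copy_count`,
#'   `observed` (`FALSE` for the germline root and, where distinct from all
#'   observed sequences, the inferred MRCA).
#' @slot edges data.frame with columns `from`, `to`, `weight` (nt distance).
#' @slot trunkLength numeric, nt distance root to MRCA.
#' @slot gini numeric in [0, 1).
#' @export
setClass("LineageTree",
  representation(
    cloneId = "character",
    nodes = "data.frame",
    edges = "data.frame",
    trunkLength = "numeric",
    gini = "numeric"
  )
)

setValidity("LineageTree", function(object) {
  msg <- character()
  n <- object@nodes
  e <- object@edges
  if (!all(c("id", "sequence", "copy_count", "observed") %in% names(n)))
    msg <- c(msg, "nodes must have id, sequence, copy_count, observed")
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% n$id))
      msg <- c(msg, "edge endpoints must be node ids")
    if (nrow(e) != nrow(n) - 1L)
      msg <- c(msg, "a tree on k nodes must have k - 1 edges")
  }
  if (length(object@trunkLength) != 1L || object@trunkLength < 0)
    msg <- c(msg, "trunkLength must be a single non-negative number")
  if (length(object@gini) != 1L || object@gini < 0 || object@gini >= 1)
    msg <- c(msg, "gini must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn LineageTree compact display
#' @param object a `LineageTree`.
#' @export
setMethod("show", "LineageTree", function(object) {
  cat("LineageTree", object@cloneId, "-",
      sum(object@nodes$observed), "observed sequences;",
      "trunk", object@trunkLength, "nt; Gini",
      signif(object@gini, 3), "\n")
})

#' @rdname trunkLength
#' @export
setGeneric("trunkLength", function(x) standardGeneric("trunkLength"))

#' Trunk length of a lineage tree
#'
#' Nucleotide distance from the germline root to the most recent common
#' ancestor of the observed sequences, a proxy for lineage maturity.
#'
#' @param x a `LineageTree`.
#' @return numeric trunk length in nt.
#' @export
setMethod("trunkLength", "LineageTree", function(x) x@trunkLength)

#' @rdname asNewick
#' @export
setGeneric("asNewick", function(x) standardGeneric("asNewick"))

#' Serialise a lineage tree to Newick
#'
#' Branch lengths are nucleotide distances. Observed internal sequences are
#' written as internal node labels.
#'
#' @param x a `LineageTree`.
#' @return single Newick string terminated by `;`.
#' @export
setMethod("asNewick", "LineageTree", function(x) {
  kids <- split(x@edges$to, x@edges$from)
  len <- setNames(x@edges$weight, x@edges$to)
  root <- setdiff(x@nodes$id, x@edges$to)
  rec <- function(id) {
    ch <- kids[[id]]
    lab <- id
    if (is.null(ch)) return(sprintf("%s:%g", lab, len[[id]]))
    inner <- paste(vapply(ch, rec, ""), collapse = ",")
    if (id == root) sprintf("(%s)%s", inner, lab)
    else sprintf("(%s)%s:%g", inner, lab, len[[id]])
  }
  paste0(rec(root), ";")
})
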