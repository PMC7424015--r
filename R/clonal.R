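# Clonal clustering, lineage trees, trunk length and Gini index.

#' Extract the CDR3 nucleotide sequence from an IMGT junction
#'
#' CDR3 is the junction minus its first (conserved Cys) and last (conserved
#' Trp) codons.
#'
#' @param junction character vector of junction sequences.
#' @return character vector of CDR3 sequences.
#' @export
cdr3FromJunction <- function(junction) {
  substr(junction, 4L, nchar(junction) - 3L)
}

#' Group sequences into clones
#'
#' Clonally related sequences are required to share V gene, J gene (at gene
#' level, alleles ignored) and CDR3 length; within such a bin, sequences
#' whose CDR3s differ by at most 1 mismatch in 15 nucleotides
#' (`floor(L * mismatchRate)` for CDR3 length `L`) are linked, and clones
#' are the single-linkage connected components of that graph. Clustering is
#' per subject unless `bySubject = FALSE` (used for the cross-individual
#' sharing analysis).
#'
#' @param table AIRR rearrangement data.frame with `v_call`, `j_call`,
#'   `junction`, `subject_id`.
#' @param mismatchRate allowed CDR3 mismatch fraction (default 1/15).
#' @param bySubject cluster within subjects (default) or across the pooled
#'   table.
#' @return the table with a `clone_id` column added.
#' @export
clusterClones <- function(table, mismatchRate = 1 / 15, bySubject = TRUE) {
  cdr3 <- cdr3FromJunction(table$junction)
  binkey <- paste(getGene(table$v_call), getGene(table$j_call),
                  nchar(cdr3), sep = "|")
  if (bySubject) binkey <- paste(table$subject_id, binkey, sep = "|")
  clone <- integer(nrow(table))
  nextId <- 0L
  for (bin in split(seq_len(nrow(table)), binkey)) {
    L <- nchar(cdr3[bin[1]])
    thr <- floor(L * mismatchRate)
    comp <- .single_linkage(cdr3[bin], thr)
    clone[bin] <- nextId + comp
    nextId <- nextId + max(comp)
  }
  table$clone_id <- sprintf("clone%05d", clone)
  table
}

# single-linkage connected components under a hamming threshold
.single_linkage <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 1L) return(1L)
  # collapse identical strings first to keep the distance matrix small
  uniq <- unique(seqs)
  map <- match(seqs, uniq)
  m <- length(uniq)
  if (m == 1L) return(rep(1L, n))
  D <- .hamming_matrix(uniq)
  adj <- D <= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  comp[map]
}

#' Gini index of copy counts
#'
#' `G = sum_ij |x_i - x_j| / (2 n sum_i x_i)`; 0 for equal counts and for a
#' single observation, approaching 1 when one variant dominates.
#'
#' @param x positive numeric vector of copy counts (or a [LineageTree]).
#' @return numeric Gini index in [0, 1).
#' @export
setGeneric("giniIndex", function(x) standardGeneric("giniIndex"))

#' @rdname giniIndex
#' @export
setMethod("giniIndex", "numeric", function(x) {
  if (!length(x)) stop("empty copy-count vector")
  if (any(x <= 0)) stop("copy counts must be positive")
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n * sum(x))
})

#' @rdname giniIndex
#' @export
setMethod("giniIndex", "LineageTree", function(x) x@gini)

#' Build the lineage tree of one clone
#'
#' Unique member sequences (identical alignments merged, copy counts summed)
#' are joined by a minimum-spanning tree under hamming distance on the
#' aligned V segment plus CDR3. The root is the clone's germline
#' reconstruction (`germline_alignment`, whose junction-internal N region is
#' masked as ambiguous and excluded from all distances to the root). The
#' most recent common ancestor (MRCA) of the observed sequences is inferred
#' by position-wise consensus: at each unmasked position where every member
#' carries the same non-germline base, the MRCA carries that base. The trunk
#' length is the distance from root to MRCA over unmasked positions.
#'
#' @param clone data.frame of one clone's rearrangements (shared
#'   `germline_alignment` layout).
#' @param cloneId identifier stored in the tree.
#' @return a [LineageTree].
#' @export
buildLineage <- function(clone, cloneId = clone$clone_id[1]) {
  stopifnot(nrow(clone) >= 1L)
  if (is.null(cloneId) || is.na(cloneId)) cloneId <- "clone"
  germ <- clone$germline_alignment[1]
  # merge identical sequences
  agg <- aggregate(list(copy_count = clone$duplicate_count),
                   by = list(sequence = clone$sequence_alignment), FUN = sum)
  agg <- agg[order(agg$sequence), , drop = FALSE]
  seqs <- agg$sequence
  if (length(seqs) == 1L) {
    # singleton clone: the member is its own MRCA
    trunk <- .hamming(germ, seqs)
    rootId <- paste0(cloneId, "_germline")
    nodeId <- sprintf("%s_n001", cloneId)
    return(new("LineageTree", cloneId = as.character(cloneId),
               nodes = data.frame(id = c(rootId, nodeId),
                                  sequence = c(germ, seqs),
                                  copy_count = c(0L, agg$copy_count),
                                  observed = c(FALSE, TRUE),
                                  stringsAsFactors = FALSE),
               edges = data.frame(from = rootId, to = nodeId,
                                  weight = trunk, stringsAsFactors = FALSE),
               trunkLength = as.numeric(trunk), gini = 0))
  }
  gch <- strsplit(germ, "", fixed = TRUE)[[1]]
  unmasked <- gch %in% DNA_BASES
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  # inferred MRCA: unanimous non-germline base at unmasked positions
  mrca <- gch
  for (p in which(unmasked)) {
    col <- mat[, p]
    if (all(col == col[1]) && col[1] != gch[p] && col[1] %in% DNA_BASES)
      mrca[p] <- col[1]
  }
  # at masked positions the MRCA takes the member consensus so that
  # member-MRCA distances do not count junction N-region positions twice
  for (p in which(!unmasked)) {
    tab <- sort(table(mat[, p]), decreasing = TRUE)
    mrca[p] <- names(tab)[1]
  }
  mrcaSeq <- paste(mrca, collapse = "")
  trunk <- sum(mrca[unmasked] != gch[unmasked])

  mrcaIdx <- match(mrcaSeq, seqs)
  nodeSeqs <- seqs
  nodeIds <- sprintf("%s_n%03d", cloneId, seq_along(seqs))
  observed <- rep(TRUE, length(seqs))
  copy <- agg$copy_count
  if (is.na(mrcaIdx)) {
    nodeSeqs <- c(mrcaSeq, nodeSeqs)
    nodeIds <- c(paste0(cloneId, "_mrca"), nodeIds)
    observed <- c(FALSE, observed)
    copy <- c(0L, copy)
    mrcaIdx <- 1L
  } else {
    mrcaIdx <- mrcaIdx
  }
  k <- length(nodeSeqs)
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (k > 1L) {
    D <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      D[i, j] <- D[j, i] <- .hamming(nodeSeqs[i], nodeSeqs[j])
    }
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    mstg <- igraph::mst(g)
    em <- igraph::as_edgelist(mstg)
    ew <- igraph::E(mstg)$weight
    # orient edges away from the MRCA
    adj <- lapply(seq_len(k), function(i) integer())
    for (e in seq_len(nrow(em))) {
      a <- as.integer(em[e, 1]); b <- as.integer(em[e, 2])
      adj[[a]] <- c(adj[[a]], e); adj[[b]] <- c(adj[[b]], e)
    }
    visited <- rep(FALSE, k); visited[mrcaIdx] <- TRUE
    queue <- mrcaIdx
    from <- character(); to <- character(); w <- numeric()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        a <- as.integer(em[e, 1]); b <- as.integer(em[e, 2])
        other <- if (a == v) b else a
        if (!visited[other]) {
          visited[other] <- TRUE
          queue <- c(queue, other)
          from <- c(from, nodeIds[v]); to <- c(to, nodeIds[other])
          w <- c(w, ew[e])
        }
      }
    }
    edges <- data.frame(from = from, to = to, weight = w,
                        stringsAsFactors = FALSE)
  }
  rootId <- paste0(cloneId, "_germline")
  nodes <- data.frame(
    id = c(rootId, nodeIds),
    sequence = c(germ, nodeSeqs),
    copy_count = c(0L, copy),
    observed = c(FALSE, observed),
    stringsAsFactors = FALSE)
  edges <- rbind(data.frame(from = rootId, to = nodeIds[mrcaIdx],
                            weight = trunk, stringsAsFactors = FALSE),
                 edges)
  gini <- giniIndex(as.numeric(copy[observed][copy[observed] > 0]))
  new("LineageTree", cloneId = as.character(cloneId), nodes = nodes,
      edges = edges, trunkLength = as.numeric(trunk), gini = gini)
}

#' Subsample a repertoire to a fixed depth
#'
#' Uniform sampling of unique sequences without replacement, used to
#' normalise read depth before lineage metrics. The default depth of 25,609
#' corresponds to the smallest sample. Tables at or below the target size
#' are returned unchanged with a warning.
#'
#' @param table AIRR rearrangement data.frame.
#' @param n target number of rows.
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @return subsampled data.frame.
#' @export
subsampleRepertoire <- function(table, n = 25609L, seed = 1L) {
  if (nrow(table) < n) {
    warning("table has fewer than ", n, " rows; returned unchanged")
    return(table)
  }
  idx <- .with_seed(seed, sample.int(nrow(table), n))
  table[sort(idx), , drop = FALSE]
}

#' Effective representative sequence of a clone
#'
#' Position-wise majority consensus over the clone members' aligned
#' sequences (ties resolved by alphabetical base order). The representative
#' carries the summed copy count; its mutation profile must be recomputed
#' against the germline by the caller (see [aggregateSelection()]).
#'
#' @param clone data.frame of one clone's rearrangements.
#' @return one-row data.frame: the first member with `sequence_alignment`
#'   replaced by the consensus and `duplicate_count` summed.
#' @export
effectiveSequence <- function(clone) {
  stopifnot(nrow(clone) >= 1L)
  rep <- clone[1L, , drop = FALSE]
  if (nrow(clone) > 1L) {
    stopifnot(length(unique(nchar(clone$sequence_alignment))) == 1L)
    rep$sequence_alignment <- .consensus(clone$sequence_alignment)
    rep$sequence <- rep$sequence_alignment
  }
  rep$duplicate_count <- sum(clone$duplicate_count)
  rep
}

#' Per-clone lineage metrics
#'
#' Builds a lineage tree for every clone of the (clustered) table and
#' tabulates size, trunk length and Gini index.
#'
#' @param table clustered AIRR data.frame with `clone_id`.
#' @return data.frame: `subject_id`, `clone_id`, `size`, `trunk_length`,
#'   `gini`.
#' @export
cloneMetrics <- function(table) {
  stopifnot("clone_id" %in% names(table))
  key <- paste(table$subject_id, table$clone_id, sep = "|")
  out <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    tr <- buildLineage(table[idx, , drop = FALSE],
                       cloneId = table$clone_id[idx[1]])
    data.frame(subject_id = table$subject_id[idx[1]],
               clone_id = table$clone_id[idx[1]],
               size = length(idx),
               trunk_length = trunkLength(tr),
               gini = giniIndex(tr),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id, res$clone_id), , drop = FALSE]
}
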