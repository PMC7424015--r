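# V-gene mutation counting, B cell subset assignment, and usage/junction
# summaries.

#' Count V-gene mutations of one sequence against its germline
#'
#' Compares `seqAlign` and `germAlign` within the V segment (FWR1 start
#' through FWR3 end). A mismatch is replacement (R) when the mutated codon
#' translates differently from the germline codon, where the codon context
#' is the germline codon with all observed mutations of that codon applied;
#' otherwise it is silent (S). Positions where either alignment carries a
#' gap or `N` are skipped (indels are not counted as mutations).
#'
#' @param seqAlign aligned observed sequence.
#' @param germAlign aligned germline sequence (equal length).
#' @param regions V-gene region table as returned by [glRegions()].
#' @return a one-row data.frame (mutation profile) with `r_cdr`, `s_cdr`,
#'   `r_fwr`, `s_fwr`, `n_total` and per-region counts
#'   (`n_fwr1`, `n_cdr1`, `n_fwr2`, `n_cdr2`, `n_fwr3`).
#' @export
countVMutations <- function(seqAlign, germAlign, regions) {
  if (nchar(seqAlign) != nchar(germAlign))
    stop("sequence and germline alignments differ in length")
  ev <- .mutation_events_from_alignment(seqAlign, germAlign, regions)
  .profile_from_events(ev)
}

.mutation_events_from_alignment <- function(seqAlign, germAlign, regions) {
  vEnd <- min(max(regions$end), nchar(seqAlign))
  s <- strsplit(seqAlign, "", fixed = TRUE)[[1]]
  g <- strsplit(germAlign, "", fixed = TRUE)[[1]]
  idx <- seq_len(vEnd)
  ok <- s[idx] %in% DNA_BASES & g[idx] %in% DNA_BASES
  pos <- idx[ok & s[idx] != g[idx]]
  .annotate_events(seqAlign, germAlign, regions, pos)
}

.profile_from_events <- function(ev) {
  isCdr <- ev$region %in% c("CDR1", "CDR2")
  out <- data.frame(
    r_cdr = sum(isCdr & ev$r_or_s == "R"),
    s_cdr = sum(isCdr & ev$r_or_s == "S"),
    r_fwr = sum(!isCdr & ev$r_or_s == "R"),
    s_fwr = sum(!isCdr & ev$r_or_s == "S"))
  out$n_total <- out$r_cdr + out$s_cdr + out$r_fwr + out$s_fwr
  for (reg in V_REGIONS)
    out[[paste0("n_", tolower(reg))]] <- sum(ev$region == reg)
  out
}

#' Annotate a rearrangement table with mutation profiles
#'
#' Adds `n_v_mutations`, `r_cdr`, `s_cdr`, `r_fwr`, `s_fwr` and `v_family`
#' columns, computed per sequence against the called V gene's region
#' boundaries.
#'
#' @param table AIRR rearrangement data.frame.
#' @param db a [GermlineDatabase].
#' @return the annotated data.frame.
#' @export
annotateMutations <- function(table, db) {
  genes <- getGene(table$v_call)
  regsByGene <- lapply(setNames(nm = unique(genes)),
                       function(g) glRegions(db, g))
  profs <- lapply(seq_len(nrow(table)), function(i) {
    countVMutations(table$sequence_alignment[i], table$germline_alignment[i],
                    regsByGene[[genes[i]]])
  })
  profs <- do.call(rbind, profs)
  table$n_v_mutations <- profs$n_total
  table$r_cdr <- profs$r_cdr
  table$s_cdr <- profs$s_cdr
  table$r_fwr <- profs$r_fwr
  table$s_fwr <- profs$s_fwr
  table$v_family <- getFamily(table$v_call)
  table
}

SUBSET_LEVELS <- c("naive_IgDM", "memory_IgDM", "IgG1", "IgG2", "IgG3",
                   "IgA1", "IgA2")

#' Assign sequences to B cell subsets
#'
#' IgM/IgD sequences with at most 2 nt mutations across the entire V gene
#' are "unmutated" (naive); IgM/IgD with 3 or more are IgD/IgM memory. All
#' class-switched sequences are antigen-experienced irrespective of their
#' mutation count and keep their subclass label. IgE and IgG4 are excluded
#' (label `"excluded"`).
#'
#' @param cCall character vector of subclass labels.
#' @param nMutations integer vector of V-gene mutation counts.
#' @return character vector of subset labels.
#' @export
classifySubset <- function(cCall, nMutations) {
  known <- c(SUBCLASSES, "IgG4", "IgE")
  if (any(!cCall %in% known))
    stop("unknown c_call: ",
         paste(unique(cCall[!cCall %in% known]), collapse = ", "))
  out <- ifelse(cCall %in% c("IgE", "IgG4"), "excluded",
         ifelse(cCall %in% c("IgM", "IgD"),
                ifelse(nMutations <= 2L, "naive_IgDM", "memory_IgDM"),
                cCall))
  out
}

#' @rdname classifySubset
#' @param table annotated AIRR data.frame (needs `c_call`,
#'   `n_v_mutations`).
#' @return `annotateSubsets`: the table with a `subset` column, excluded
#'   isotypes removed.
#' @export
annotateSubsets <- function(table) {
  table$subset <- classifySubset(table$c_call, table$n_v_mutations)
  table[table$subset != "excluded", , drop = FALSE]
}

#' Gene usage frequencies per subject and subset
#'
#' Proportions of sequences assigned to each category (V family, J gene or
#' V gene) for every (subject, subset) combination. Zero-count categories
#' are present with frequency 0; frequencies sum to 1 per combination.
#' Empty (subject, subset) combinations are omitted.
#'
#' @param table annotated AIRR data.frame with `subset`.
#' @param level one of `"v_family"`, `"j_gene"`, `"v_gene"`.
#' @param categories optional fixed category universe; defaults to all
#'   categories observed in `table`.
#' @return long data.frame: `subject_id`, `subset`, `category`, `n`, `freq`.
#' @export
usageProfile <- function(table, level = c("v_family", "j_gene", "v_gene"),
                         categories = NULL) {
  level <- match.arg(level)
  cat_of <- switch(level,
    v_family = getFamily(table$v_call),
    j_gene = getGene(table$j_call),
    v_gene = getGene(table$v_call))
  if (is.null(categories)) categories <- sort(unique(cat_of))
  tab <- base::table(subject_id = table$subject_id, subset = table$subset,
                     category = factor(cat_of, levels = categories))
  df <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  tot <- aggregate(n ~ subject_id + subset, df, sum)
  names(tot)[3] <- "total"
  df <- merge(df, tot, by = c("subject_id", "subset"), sort = FALSE)
  df <- df[df$total > 0L, , drop = FALSE]
  df$freq <- df$n / df$total
  df$total <- NULL
  df[order(df$subject_id, df$subset, df$category), , drop = FALSE]
}

#' Mean junction length per subject and subset
#'
#' Arithmetic mean of `junction_length` in nt, optionally restricted to one
#' J gene before averaging. Combinations with no sequences after filtering
#' are absent from the result (never reported as zero).
#'
#' @param table annotated AIRR data.frame with `subset`.
#' @param jGene optional J gene restriction (e.g. `"IGHJ6S"`).
#' @return data.frame: `subject_id`, `subset`, `mean_junction_length`, `n`.
#' @export
junctionSummary <- function(table, jGene = NULL) {
  if (!is.null(jGene))
    table <- table[getGene(table$j_call) == jGene, , drop = FALSE]
  if (!nrow(table))
    return(data.frame(subject_id = character(), subset = character(),
                      mean_junction_length = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  agg <- aggregate(junction_length ~ subject_id + subset, table, mean)
  names(agg)[3] <- "mean_junction_length"
  cnt <- aggregate(junction_length ~ subject_id + subset, table, length)
  agg$n <- cnt$junction_length
  agg
}
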