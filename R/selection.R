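# Antigen-driven selection statistics: R/S ratios with the zero-silent rule
# and a focused binomial test against an expected-mutability baseline.

#' Expected mutability of a germline V segment
#'
#' Enumerates all `3L` single-nucleotide substitutions of the L-nt V segment
#' (FWR1 through FWR3), classifies each as (CDR/FWR, R/S), and converts the
#' tallies to probabilities: the chance that a random substitution falls in
#' each class. With `weighting = "hotspot"` each substitution is weighted by
#' a 5-mer context factor from `hotspotTable` (named by the 5-mer centred on
#' the mutated position; unlisted contexts weigh 1).
#'
#' `p_focused = p_cdr_r / (p_cdr_r + p_cdr_s)` is the null probability that
#' a CDR mutation is a replacement, the baseline of [selectionTest()].
#'
#' @param germSeq ungapped germline V sequence.
#' @param regions region table as returned by [glRegions()].
#' @param weighting `"uniform"` (default) or `"hotspot"`.
#' @param hotspotTable named numeric vector of 5-mer weights.
#' @return list with `p_cdr_r`, `p_cdr_s`, `p_fwr_r`, `p_fwr_s` (summing to
#'   1) and `p_focused`.
#' @export
expectedMutability <- function(germSeq, regions,
                               weighting = c("uniform", "hotspot"),
                               hotspotTable = NULL) {
  weighting <- match.arg(weighting)
  vEnd <- max(regions$end)
  g <- strsplit(substr(germSeq, 1L, vEnd), "", fixed = TRUE)[[1]]
  tal <- c(cdr_r = 0, cdr_s = 0, fwr_r = 0, fwr_s = 0)
  for (p in seq_len(vEnd)) {
    if (!g[p] %in% DNA_BASES) next
    reg <- regions$region[regions$start <= p & regions$end >= p]
    if (!length(reg)) next
    isCdr <- reg[1] %in% c("CDR1", "CDR2")
    c0 <- ((p - 1L) %/% 3L) * 3L + 1L
    germCodon <- g[c0:(c0 + 2L)]
    w <- 1
    if (weighting == "hotspot" && !is.null(hotspotTable)) {
      ctx <- paste(g[pmax(1L, p - 2L):min(vEnd, p + 2L)], collapse = "")
      if (!is.na(hotspotTable[ctx])) w <- hotspotTable[[ctx]]
    }
    for (alt in setdiff(DNA_BASES, g[p])) {
      mut <- germCodon
      mut[p - c0 + 1L] <- alt
      silent <- .translate_codon(paste(mut, collapse = "")) ==
        .translate_codon(paste(germCodon, collapse = ""))
      cls <- paste0(if (isCdr) "cdr" else "fwr", if (silent) "_s" else "_r")
      tal[cls] <- tal[cls] + w
    }
  }
  pr <- tal / sum(tal)
  list(p_cdr_r = pr[["cdr_r"]], p_cdr_s = pr[["cdr_s"]],
       p_fwr_r = pr[["fwr_r"]], p_fwr_s = pr[["fwr_s"]],
       p_focused = pr[["cdr_r"]] / (pr[["cdr_r"]] + pr[["cdr_s"]]))
}

#' Replacement/silent mutation ratio
#'
#' R/S ratio for one region with the zero-silent rule: when a unit has
#' replacement but no silent mutations the silent count is set to 1; when
#' both counts are zero the ratio is undefined (`NA`, excluded from means).
#'
#' @param r replacement count(s).
#' @param s silent count(s).
#' @return numeric vector of ratios (NA where undefined).
#' @export
rsRatio <- function(r, s) {
  ifelse(r == 0L & s == 0L, NA_real_, r / pmax(s, 1L))
}

#' Focused binomial test for antigen-driven selection
#'
#' Under the null of no selection, the number of replacement mutations among
#' a unit's CDR mutations is `Binomial(n = cdrR + cdrS, p = p_focused)`.
#' Reports the two-sided exact binomial p-value and a selection strength
#' `sigma = log((cdrR + 1/2) / (cdrS + 1/2)) - log(p / (1 - p))`
#' (log-odds of the observed replacement fraction against the baseline,
#' with Haldane-Anscombe corrections); `sigma > 0` indicates replacement
#' enrichment in CDRs (positive selection).
#'
#' @param cdrR observed CDR replacement count.
#' @param cdrS observed CDR silent count.
#' @param expected an expected-mutability list from [expectedMutability()],
#'   or a bare `p_focused` value.
#' @return list with `cdr_r`, `cdr_s`, `p_focused`, `sigma`, `p_value`.
#' @export
selectionTest <- function(cdrR, cdrS, expected) {
  p <- if (is.list(expected)) expected$p_focused else expected
  n <- cdrR + cdrS
  if (n < 1L) stop("selectionTest requires at least one CDR mutation")
  stopifnot(p > 0, p < 1)
  pv <- binom.test(cdrR, n, p)$p.value
  sigma <- log((cdrR + 0.5) / (cdrS + 0.5)) - log(p / (1 - p))
  list(cdr_r = cdrR, cdr_s = cdrS, p_focused = p, sigma = sigma,
       p_value = pv)
}

#' Selection statistics at sequence, clone or subject-subset level
#'
#' Individual sequences within a clone are not independent events, so the
#' clone level first reduces each clone to its effective representative
#' sequence ([effectiveSequence()]) and recomputes its mutation profile; the
#' subject-subset level pools the representatives' CDR counts before
#' testing, using an n-weighted average of the per-gene `p_focused` values.
#'
#' @param table annotated, clustered AIRR data.frame (needs `r_cdr`,
#'   `s_cdr`, `clone_id` for clone level, `subset` for subject-subset
#'   level).
#' @param db a [GermlineDatabase].
#' @param level `"sequence"`, `"clone"` or `"subject_subset"`.
#' @param weighting passed to [expectedMutability()].
#' @return data.frame with `unit_id`, counts, `rs_cdr`, `rs_fwr`,
#'   `p_focused`, `sigma`, `p_value` (`NA` for units without CDR
#'   mutations).
#' @export
aggregateSelection <- function(table, db,
                               level = c("sequence", "clone",
                                         "subject_subset"),
                               weighting = "uniform") {
  level <- match.arg(level)
  expCache <- new.env(parent = emptyenv())
  expFor <- function(gene) {
    if (is.null(expCache[[gene]]))
      expCache[[gene]] <- expectedMutability(glSequence(db, gene),
                                             glRegions(db, gene),
                                             weighting = weighting)
    expCache[[gene]]
  }
  units <- switch(level,
    sequence = {
      lapply(seq_len(nrow(table)), function(i) {
        list(id = table$sequence_id[i], gene = getGene(table$v_call[i]),
             r_cdr = table$r_cdr[i], s_cdr = table$s_cdr[i],
             r_fwr = table$r_fwr[i], s_fwr = table$s_fwr[i])
      })
    },
    clone = ,
    subject_subset = {
      stopifnot("clone_id" %in% names(table))
      key <- paste(table$subject_id, table$clone_id, sep = "|")
      reps <- lapply(split(seq_len(nrow(table)), key), function(idx) {
        rep <- effectiveSequence(table[idx, , drop = FALSE])
        gene <- getGene(rep$v_call)
        prof <- countVMutations(rep$sequence_alignment,
                                rep$germline_alignment, glRegions(db, gene))
        list(id = paste(rep$subject_id, rep$clone_id, sep = "|"),
             subject = rep$subject_id,
             subset = if ("subset" %in% names(rep)) rep$subset else NA,
             gene = gene,
             r_cdr = prof$r_cdr, s_cdr = prof$s_cdr,
             r_fwr = prof$r_fwr, s_fwr = prof$s_fwr)
      })
      if (level == "clone") reps else {
        pools <- split(reps, vapply(reps, function(u)
          paste(u$subject, u$subset, sep = "|"), ""))
        lapply(pools, function(us) {
          ns <- vapply(us, function(u) u$r_cdr + u$s_cdr, numeric(1))
          ps <- vapply(us, function(u) expFor(u$gene)$p_focused, numeric(1))
          pPool <- if (sum(ns) > 0) sum(ps * ns) / sum(ns) else mean(ps)
          list(id = us[[1]]$subject_subset_id %||%
                 paste(us[[1]]$subject, us[[1]]$subset, sep = "|"),
               gene = NA, p_override = pPool,
               r_cdr = sum(vapply(us, `[[`, numeric(1), "r_cdr")),
               s_cdr = sum(vapply(us, `[[`, numeric(1), "s_cdr")),
               r_fwr = sum(vapply(us, `[[`, numeric(1), "r_fwr")),
               s_fwr = sum(vapply(us, `[[`, numeric(1), "s_fwr")))
        })
      }
    })
  rows <- lapply(units, function(u) {
    p <- if (!is.null(u$p_override)) u$p_override else expFor(u$gene)$p_focused
    n <- u$r_cdr + u$s_cdr
    if (n >= 1L) {
      st <- selectionTest(u$r_cdr, u$s_cdr, p)
      sigma <- st$sigma; pv <- st$p_value
    } else {
      sigma <- NA_real_; pv <- NA_real_
    }
    data.frame(unit_id = u$id, cdr_r = u$r_cdr, cdr_s = u$s_cdr,
               fwr_r = u$r_fwr, fwr_s = u$s_fwr,
               rs_cdr = rsRatio(u$r_cdr, u$s_cdr),
               rs_fwr = rsRatio(u$r_fwr, u$s_fwr),
               p_focused = p, sigma = sigma, p_value = pv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
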