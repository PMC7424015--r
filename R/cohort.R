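# Cohort-level synthesis: cross-individual cluster sharing, per-subject
# feature matrices, age-group hypothesis tests, logarithmic trend fits and
# PCA stratification.

#' Cross-individual cluster sharing spectrum
#'
#' Pools all subjects, applies the clonal clustering criterion globally
#' (same V gene, J gene and CDR3 length; CDR3 hamming distance at most
#' `floor(L/15)`; single-linkage across subjects), and computes for every
#' subject the fraction of that subject's clusters shared with exactly
#' `n - 1` other individuals: the number of its clusters with
#' subject-multiplicity `n` divided by the total number of clusters
#' containing the subject.
#'
#' @param table pooled AIRR data.frame covering at least two subjects.
#' @param mismatchRate CDR3 mismatch fraction (default 1/15).
#' @return data.frame: `subject_id`, `n_subjects` (multiplicity), `n_clusters`,
#'   `fraction`; per subject the fractions sum to 1.
#' @export
sharingSpectrum <- function(table, mismatchRate = 1 / 15) {
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < 2L)
    stop("sharing requires at least two subjects")
  tab <- clusterClones(table, mismatchRate = mismatchRate, bySubject = FALSE)
  members <- split(tab$subject_id, tab$clone_id)
  mult <- vapply(members, function(x) length(unique(x)), integer(1))
  nS <- length(subjects)
  rows <- lapply(subjects, function(s) {
    mine <- mult[vapply(members, function(x) s %in% x, logical(1))]
    counts <- tabulate(mine, nbins = nS)
    data.frame(subject_id = s, n_subjects = seq_len(nS),
               n_clusters = counts, fraction = counts / length(mine),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

FEATURE_FAMILIES <- c("IgDM_mutated", "IgG", "IgA")

.family_of_subset <- function(subset) {
  ifelse(subset == "memory_IgDM", "IgDM_mutated",
  ifelse(subset %in% c("IgG1", "IgG2", "IgG3"), "IgG",
  ifelse(subset %in% c("IgA1", "IgA2"), "IgA", NA_character_)))
}

#' Per-subject repertoire feature matrix
#'
#' One row per (subject, subset family) with the age-sensitive features:
#' mean V-gene mutation count, mean CDR R/S ratio, mean junction length,
#' V1-family and J6 frequencies, proportion mutated (memory fraction of
#' IgD/IgM for the IgDM family; fraction with 3+ mutations for IgG/IgA),
#' subclass proportions (IgG2 of IgG; IgA1 of IgA), and mean trunk length
#' and Gini index of the family's clones. Families without sequences for a
#' subject are absent rather than zero-filled.
#'
#' @param table annotated, subset-labelled, clustered AIRR data.frame.
#' @param metrics per-clone metrics from [cloneMetrics()] (optional; trunk
#'   and Gini columns are `NA` when missing).
#' @param subjects data.frame with `subject_id`, `age` (as produced by
#'   [simulateRepertoire()]).
#' @param j6Gene name of the J6-like gene.
#' @return data.frame of per-(subject, family) features.
#' @export
buildFeatureMatrix <- function(table, metrics = NULL, subjects,
                               j6Gene = "IGHJ6S") {
  table$family <- .family_of_subset(table$subset)
  # IgDM proportion mutated is computed over all IgD/IgM (naive + memory)
  igdm <- table$subset %in% c("naive_IgDM", "memory_IgDM")
  rows <- list()
  for (s in subjects$subject_id) {
    st <- table[table$subject_id == s, , drop = FALSE]
    for (fam in FEATURE_FAMILIES) {
      ft <- st[!is.na(st$family) & st$family == fam, , drop = FALSE]
      if (!nrow(ft)) next
      propMut <- if (fam == "IgDM_mutated") {
        pool <- st[st$subset %in% c("naive_IgDM", "memory_IgDM"), ,
                   drop = FALSE]
        mean(pool$subset == "memory_IgDM")
      } else mean(ft$n_v_mutations >= 3L)
      subProp <- if (fam == "IgG") mean(ft$c_call == "IgG2")
      else if (fam == "IgA") mean(ft$c_call == "IgA1") else NA_real_
      trunk <- gini <- NA_real_
      if (!is.null(metrics)) {
        cl <- metrics[metrics$subject_id == s &
                      metrics$clone_id %in% unique(ft$clone_id), ,
                      drop = FALSE]
        if (nrow(cl)) {
          trunk <- mean(cl$trunk_length)
          gini <- mean(cl$gini)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s,
        age = subjects$age[subjects$subject_id == s],
        family = fam,
        mean_mutations = mean(ft$n_v_mutations),
        mean_rs_cdr = mean(rsRatio(ft$r_cdr, ft$s_cdr), na.rm = TRUE),
        mean_junction_length = mean(ft$junction_length),
        v1_freq = mean(getFamily(ft$v_call) == "V1"),
        j6_freq = mean(getGene(ft$j_call) == j6Gene),
        prop_mutated = propMut,
        subclass_prop = subProp,
        mean_trunk_length = trunk,
        mean_gini = gini,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$age_group <- as.character(assignAgeGroup(out$age))
  out
}

#' Age-group hypothesis tests for one feature
#'
#' Pairwise Wilcoxon rank-sum tests of each age group against the reference
#' (youngest) group, plus a Kruskal-Wallis omnibus test across groups.
#' Significance stars: `*` below 0.05, `**` below 0.01, `***` below 0.001.
#'
#' @param features data.frame with `age_group` and the feature column.
#' @param variable feature column name.
#' @param reference reference age group (default `"0-3"`).
#' @return list with `pairwise` (data.frame `group`, `n`, `p_value`,
#'   `stars`) and `omnibus` (Kruskal-Wallis p-value).
#' @export
compareAgeGroups <- function(features, variable, reference = "0-3") {
  y <- features[[variable]]
  g <- as.character(features$age_group)
  keep <- !is.na(y)
  y <- y[keep]; g <- g[keep]
  groups <- intersect(AGE_GROUP_LEVELS, unique(g))
  if (length(groups) < 2L) stop("need at least two age groups")
  if (!reference %in% groups) stop("reference group has no observations")
  stars <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
           ifelse(p < 0.05, "*", "")))
  }
  ref <- y[g == reference]
  pw <- lapply(setdiff(groups, reference), function(grp) {
    yy <- y[g == grp]
    p <- if (length(yy) >= 2L && length(ref) >= 2L)
      suppressWarnings(wilcox.test(yy, ref)$p.value) else NA_real_
    data.frame(group = grp, n = length(yy), p_value = p,
               stars = ifelse(is.na(p), "", stars(p)),
               stringsAsFactors = FALSE)
  })
  omni <- kruskal.test(y, factor(g, levels = groups))$p.value
  list(pairwise = do.call(rbind, pw), omnibus = omni)
}

#' Fit a logarithmic age trend
#'
#' Least-squares fit of `y = a + b * log(age)`, the saturating curve used
#' for age trends of repertoire features. Returns the coefficients, the
#' coefficient of determination and the p-value of the model F test as a
#' goodness measure; a constant response returns `b = 0`, `R2 = 0`,
#' `p = 1`.
#'
#' @param age ages in years (positive).
#' @param y feature values.
#' @return list with `a`, `b`, `r_squared`, `p_value`.
#' @export
fitLogTrend <- function(age, y) {
  stopifnot(length(age) == length(y), length(y) >= 3L, all(age > 0))
  if (length(unique(age)) < 2L) stop("singular design: all ages identical")
  fit <- lm(y ~ log(age))
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  ssTot <- sum((y - mean(y))^2)
  ssRes <- sum(residuals(fit)^2)
  if (ssTot < .Machine$double.eps) {
    return(list(a = mean(y), b = 0, r_squared = 0, p_value = 1))
  }
  r2 <- 1 - ssRes / ssTot
  fstat <- suppressWarnings(summary(fit))$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(a = a, b = b, r_squared = r2, p_value = p)
}

#' PCA stratification of subject features
#'
#' Standardises the complete-case feature rows of one subset family to zero
#' mean and unit variance, extracts the first two principal components, and
#' returns per-age-group convex hulls and hull centres. Zero-variance
#' columns are dropped before standardisation.
#'
#' @param features feature data.frame from [buildFeatureMatrix()] (one
#'   family).
#' @param featureCols columns to use; defaults to the numeric feature set.
#' @return list with `scores` (subject_id, age_group, PC1, PC2), `centers`
#'   (per-group hull centres), `hulls` (per-group convex-hull point
#'   indices into `scores`), `sdev` and `rotation` from the PCA.
#' @export
pcaStratify <- function(features,
                        featureCols = c("mean_mutations", "mean_rs_cdr",
                                        "mean_junction_length", "v1_freq",
                                        "j6_freq", "prop_mutated",
                                        "subclass_prop",
                                        "mean_trunk_length", "mean_gini")) {
  featureCols <- intersect(featureCols, names(features))
  x <- features[, featureCols, drop = FALSE]
  cc <- complete.cases(x)
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < 3L) stop("PCA requires at least three complete-case rows")
  keep <- vapply(x, function(col) var(col) > 0, logical(1))
  if (!all(keep))
    warning("dropping zero-variance features: ",
            paste(names(x)[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  pc <- prcomp(as.matrix(x), center = TRUE, scale. = TRUE)
  scores <- data.frame(
    subject_id = features$subject_id[cc],
    age_group = features$age_group[cc],
    PC1 = pc$x[, 1], PC2 = pc$x[, 2],
    stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  hulls <- lapply(split(seq_len(nrow(scores)), scores$age_group),
                  function(idx) {
    if (length(idx) < 3L) return(idx)
    idx[grDevices::chull(scores$PC1[idx], scores$PC2[idx])]
  })
  centers <- do.call(rbind, lapply(names(hulls), function(grp) {
    idx <- hulls[[grp]]
    data.frame(age_group = grp, PC1 = mean(scores$PC1[idx]),
               PC2 = mean(scores$PC2[idx]), stringsAsFactors = FALSE)
  }))
  list(scores = scores, centers = centers, hulls = hulls,
       sdev = pc$sdev, rotation = pc$rotation)
}
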