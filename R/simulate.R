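#' SimulationConfig: generative parameters for synthetic IgH repertoires
#'
#' Encodes the study conditions used to emulate an age-structured cohort:
#' per-age-band V and J gene usage weights (V1-family and J6 usage decreasing
#' with age), J-conditional junction-length models (the J6-like gene drawing
#' the longest junctions), a saturating somatic hypermutation load
#' `mu(age) = a + b*log(1 + age)` per compartment (IgD/IgM, IgG, IgA),
#' age-decreasing naive fractions for IgD/IgM lineages, power-law clone
#' sizes, and per-age-band isotype subclass weights with IgG2/IgA2
#' proportions shifting upward with age. Age bands are 0-3, 4-8, 9-16,
#' 17-25, 26-39 and 40+ years.
#'
#' @slot nSubjects number of subjects.
#' @slot ages subject ages in years (within 0.5-50).
#' @slot seed master seed; subjects receive independent derived streams.
#' @slot vUsage,jUsage age-band x gene weight matrices (rows sum to 1).
#' @slot junctionMean named mean junction length (nt) per J gene.
#' @slot junctionSd junction length SD in nt.
#' @slot shmA,shmB per-compartment intercept/slope of the SHM-age curve.
#' @slot naiveFraction per-band probability an IgD/IgM lineage is unmutated.
#' @slot cloneCount mean clones per subject.
#' @slot cloneSizeAlpha,cloneSizeMax power-law exponent and cap for clone size.
#' @slot trunkFraction fraction of lineage SHM load placed on the trunk.
#' @slot branchRate mean additional mutations per lineage branch.
#' @slot copyGeomProb geometric parameter for per-sequence copy counts.
#' @slot subclassProbs age-band x subclass weight matrix (rows sum to 1) over
#'   IgM, IgD, IgG1, IgG2, IgG3, IgA1, IgA2.
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "integer", ages = "numeric", seed = "integer",
    vUsage = "matrix", jUsage = "matrix",
    junctionMean = "numeric", junctionSd = "numeric",
    shmA = "numeric", shmB = "numeric",
    naiveFraction = "numeric",
    cloneCount = "numeric", cloneSizeAlpha = "numeric",
    cloneSizeMax = "integer",
    trunkFraction = "numeric", branchRate = "numeric",
    copyGeomProb = "numeric",
    subclassProbs = "matrix"
  )
)

SUBCLASSES <- c("IgM", "IgD", "IgG1", "IgG2", "IgG3", "IgA1", "IgA2")
COMPARTMENTS <- c("IgDM", "IgG", "IgA")

.compartment_of <- function(subclass) {
  ifelse(subclass %in% c("IgM", "IgD"), "IgDM",
         ifelse(grepl("^IgG", subclass), "IgG", "IgA"))
}

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@ages) != object@nSubjects)
    msg <- c(msg, "ages must have one entry per subject")
  if (any(object@ages < 0.5 | object@ages > 50))
    msg <- c(msg, "ages must lie within [0.5, 50] years")
  for (nmat in c("vUsage", "jUsage", "subclassProbs")) {
    m <- slot(object, nmat)
    if (nrow(m) != 6L)
      msg <- c(msg, paste(nmat, "must have one row per age band"))
    if (any(abs(rowSums(m) - 1) > 1e-9))
      msg <- c(msg, paste(nmat, "rows must sum to 1 within 1e-9"))
    if (any(m < 0)) msg <- c(msg, paste(nmat, "weights must be non-negative"))
  }
  if (!identical(colnames(object@subclassProbs), SUBCLASSES))
    msg <- c(msg, "subclassProbs columns must be the seven subclasses")
  if (length(object@naiveFraction) != 6L ||
      any(object@naiveFraction < 0 | object@naiveFraction > 1))
    msg <- c(msg, "naiveFraction must be six probabilities")
  if (!all(COMPARTMENTS %in% names(object@shmA)) ||
      !all(COMPARTMENTS %in% names(object@shmB)))
    msg <- c(msg, "shmA and shmB must be named for IgDM, IgG, IgA")
  if (length(msg)) msg else TRUE
})

.default_v_usage <- function() {
  genes <- c("IGHV1-2S", "IGHV1-8S", "IGHV1-69S", "IGHV2-5S",
             "IGHV3-7S", "IGHV3-23S", "IGHV4-34S", "IGHV4-59S")
  m <- rbind(
    c(.11, .14, .11, .10, .18, .20, .08, .08),
    c(.09, .13, .09, .11, .20, .21, .08, .09),
    c(.08, .11, .08, .12, .21, .22, .08, .10),
    c(.07, .10, .07, .13, .22, .23, .08, .10),
    c(.07, .09, .06, .13, .23, .24, .08, .10),
    c(.06, .08, .06, .14, .23, .24, .08, .11)
  )
  dimnames(m) <- list(AGE_GROUP_LEVELS, genes)
  m
}

.default_j_usage <- function() {
  genes <- paste0("IGHJ", 1:6, "S")
  m <- rbind(
    c(.08, .12, .14, .22, .14, .30),
    c(.09, .13, .15, .23, .14, .26),
    c(.10, .14, .16, .24, .14, .22),
    c(.11, .14, .16, .25, .14, .20),
    c(.11, .15, .17, .25, .14, .18),
    c(.11, .15, .17, .26, .14, .17)
  )
  dimnames(m) <- list(AGE_GROUP_LEVELS, genes)
  m
}

.default_subclass_probs <- function() {
  m <- rbind(
    c(.45, .15, .14, .03, .05, .14, .04),
    c(.42, .14, .14, .05, .05, .14, .06),
    c(.40, .13, .14, .07, .05, .13, .08),
    c(.38, .12, .14, .09, .04, .13, .10),
    c(.36, .11, .14, .11, .04, .12, .12),
    c(.34, .10, .14, .13, .04, .12, .13)
  )
  dimnames(m) <- list(AGE_GROUP_LEVELS, SUBCLASSES)
  m
}

#' Construct a simulation configuration
#'
#' Defaults encode the cohort conditions the generator emulates: 18 subjects
#' (three per age band, 0.5-50 years), V1-family and J6 usage decreasing
#' with age, longer junctions for J6 rearrangements, SHM load saturating
#' with age per compartment, naive IgD/IgM fraction falling from 0.90 to
#' 0.62, and IgG2/IgA2 subclass proportions rising with age.
#'
#' @param nSubjects number of subjects.
#' @param ages ages in years; defaults to three per age band.
#' @param seed master seed.
#' @param vUsage,jUsage,subclassProbs 6-row weight matrices (per age band).
#' @param junctionMean named per-J mean junction length in nt.
#' @param junctionSd junction length SD in nt.
#' @param shmA,shmB per-compartment SHM curve parameters
#'   (`mu = shmA + shmB * log(1 + age)` expected V mutations).
#' @param naiveFraction per-band naive probability for IgD/IgM lineages.
#' @param cloneCount mean clones per subject.
#' @param cloneSizeAlpha,cloneSizeMax clone-size power law `P(k) ~ k^-alpha`
#'   truncated at `cloneSizeMax`.
#' @param trunkFraction fraction of the SHM load shared on the trunk.
#' @param branchRate mean extra mutations per lineage branch.
#' @param copyGeomProb geometric parameter for copy counts
#'   (`duplicate_count = rgeom(p) + 1`).
#' @return a [SimulationConfig].
#' @export
simulationConfig <- function(
    nSubjects = 18L,
    ages = c(1, 2, 3.5, 4.5, 6, 8, 9.5, 12, 16, 18, 21, 25,
             27, 32, 38, 40, 45, 50),
    seed = 42L,
    vUsage = .default_v_usage(),
    jUsage = .default_j_usage(),
    junctionMean = c("IGHJ1S" = 45, "IGHJ2S" = 48, "IGHJ3S" = 48,
                     "IGHJ4S" = 48, "IGHJ5S" = 51, "IGHJ6S" = 63),
    junctionSd = 4.5,
    shmA = c(IgDM = 4, IgG = 2, IgA = 3),
    shmB = c(IgDM = 2, IgG = 5, IgA = 5),
    naiveFraction = c(0.90, 0.82, 0.75, 0.70, 0.66, 0.62),
    cloneCount = 60,
    cloneSizeAlpha = 2.5,
    cloneSizeMax = 20L,
    trunkFraction = 0.55,
    branchRate = 1.5,
    copyGeomProb = 0.4,
    subclassProbs = .default_subclass_probs()) {
  new("SimulationConfig",
      nSubjects = as.integer(nSubjects), ages = ages, seed = as.integer(seed),
      vUsage = vUsage, jUsage = jUsage,
      junctionMean = junctionMean, junctionSd = junctionSd,
      shmA = shmA, shmB = shmB, naiveFraction = naiveFraction,
      cloneCount = cloneCount, cloneSizeAlpha = cloneSizeAlpha,
      cloneSizeMax = as.integer(cloneSizeMax),
      trunkFraction = trunkFraction, branchRate = branchRate,
      copyGeomProb = copyGeomProb, subclassProbs = subclassProbs)
}

#' @describeIn simulationConfig compact display
#' @param object a `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSubjects, "subjects, ages",
      min(object@ages), "-", max(object@ages), "y, seed", object@seed, "\n")
})

#' Read/write a simulation configuration as YAML
#'
#' Matrices are stored as named row lists; `readSimulationConfig` rebuilds
#' the full [SimulationConfig] (validity-checked).
#'
#' @param path YAML file path.
#' @param config a [SimulationConfig].
#' @return `readSimulationConfig`: a [SimulationConfig];
#'   `writeSimulationConfig`: the path, invisibly.
#' @export
readSimulationConfig <- function(path) {
  x <- yaml::read_yaml(path)
  as_mat <- function(lst) {
    m <- do.call(rbind, lapply(lst, unlist))
    rownames(m) <- AGE_GROUP_LEVELS
    m
  }
  simulationConfig(
    nSubjects = x$n_subjects, ages = x$ages, seed = x$seed,
    vUsage = as_mat(x$v_usage), jUsage = as_mat(x$j_usage),
    junctionMean = unlist(x$junction_mean), junctionSd = x$junction_sd,
    shmA = unlist(x$shm_a), shmB = unlist(x$shm_b),
    naiveFraction = unlist(x$naive_fraction),
    cloneCount = x$clone_count, cloneSizeAlpha = x$clone_size_alpha,
    cloneSizeMax = x$clone_size_max, trunkFraction = x$trunk_fraction,
    branchRate = x$branch_rate, copyGeomProb = x$copy_geom_prob,
    subclassProbs = as_mat(x$subclass_probs))
}

#' @rdname readSimulationConfig
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  as_rows <- function(m) {
    lst <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
    names(lst) <- rownames(m)
    lst
  }
  yaml::write_yaml(list(
    n_subjects = config@nSubjects, ages = config@ages, seed = config@seed,
    v_usage = as_rows(config@vUsage), j_usage = as_rows(config@jUsage),
    junction_mean = as.list(config@junctionMean),
    junction_sd = config@junctionSd,
    shm_a = as.list(config@shmA), shm_b = as.list(config@shmB),
    naive_fraction = config@naiveFraction,
    clone_count = config@cloneCount,
    clone_size_alpha = config@cloneSizeAlpha,
    clone_size_max = config@cloneSizeMax,
    trunk_fraction = config@trunkFraction,
    branch_rate = config@branchRate,
    copy_geom_prob = config@copyGeomProb,
    subclass_probs = as_rows(config@subclassProbs)), path)
  invisible(path)
}

# ---- VDJ recombination ------------------------------------------------------

# precompute per-gene strings and coordinates once per repertoire so that the
# per-clone loop avoids repeated DNAStringSet extraction
.gene_cache <- function(db) {
  cache <- list()
  for (g in glGenes(db, "V")) {
    seq <- glSequence(db, g)
    vEnd <- vSegmentEnd(db, g)
    cys <- glAnchor(db, g)
    cache[[g]] <- list(type = "V", seq = seq, vEnd = vEnd,
                       body = substr(seq, 1L, vEnd),
                       tail = substr(seq, cys + 3L, nchar(seq)),
                       regions = glRegions(db, g))
  }
  for (g in glGenes(db, "D"))
    cache[[g]] <- list(type = "D", seq = glSequence(db, g))
  for (g in glGenes(db, "J")) {
    seq <- glSequence(db, g)
    trp <- glAnchor(db, g)
    cache[[g]] <- list(type = "J", seq = seq,
                       j5 = substr(seq, 1L, trp - 1L),
                       fr4 = substr(seq, trp + 3L, nchar(seq)))
  }
  cache
}

.sim_rearr <- function(cache, config, band, composition = NULL,
                       maxTries = 100L) {
  vGene <- sample(colnames(config@vUsage), 1L, prob = config@vUsage[band, ])
  dGenes <- names(cache)[vapply(cache, `[[`, "", "type") == "D"]
  dGene <- sample(dGenes, 1L)
  jGene <- sample(colnames(config@jUsage), 1L, prob = config@jUsage[band, ])
  V <- cache[[vGene]]; D <- cache[[dGene]]; J <- cache[[jGene]]

  for (try in seq_len(maxTries)) {
    if (is.null(composition)) {
      L <- 3L * max(7L, round(rnorm(1L, config@junctionMean[[jGene]] / 3,
                                    config@junctionSd / 3)))
      interior <- L - 6L
      vExtra <- sample(0:min(4L, nchar(V$tail), interior), 1L)
      rem <- interior - vExtra
      jExtra <- sample(0:min(nchar(J$j5), rem), 1L)
      rem <- rem - jExtra
      dLen <- min(sample(2:8, 1L), nchar(D$seq), rem)
      dStart <- if (dLen < nchar(D$seq))
        sample(seq_len(nchar(D$seq) - dLen + 1L), 1L) else 1L
      nTotal <- rem - dLen
      n1 <- if (nTotal > 0L) sample(0:nTotal, 1L) else 0L
      n2 <- nTotal - n1
    } else {
      vExtra <- composition$vExtra; dStart <- composition$dStart
      dLen <- composition$dLen; jExtra <- composition$jExtra
      n1 <- composition$n1; n2 <- composition$n2
    }
    nIns <- function(k) if (k > 0L)
      paste(sample(DNA_BASES, k, replace = TRUE), collapse = "") else ""
    junction <- paste0(
      "TGT",
      substr(V$tail, 1L, vExtra),
      nIns(n1),
      if (dLen > 0L) substr(D$seq, dStart, dStart + dLen - 1L) else "",
      nIns(n2),
      if (jExtra > 0L)
        substr(J$j5, nchar(J$j5) - jExtra + 1L, nchar(J$j5)) else "",
      "TGG")
    seqFull <- paste0(V$body, junction, J$fr4)
    # fixed compositions are an exact-construction hook: emit as built,
    # without the in-frame/productivity rejection step
    if (!is.null(composition) ||
        (nchar(junction) %% 3L == 0L &&
         !grepl("*", translateNt(seqFull), fixed = TRUE))) {
      germAlign <- paste0(V$body, "TGT", strrep("N", nchar(junction) - 6L),
                          "TGG", J$fr4)
      return(list(
        v_call = paste0(vGene, "*01"), d_call = paste0(dGene, "*01"),
        j_call = paste0(jGene, "*01"),
        v_gene = vGene, j_gene = jGene,
        junction = junction, junction_length = nchar(junction),
        sequence = seqFull, sequence_alignment = seqFull,
        germline_alignment = germAlign))
    }
  }
  stop("junction length model infeasible: no productive rearrangement after ",
       maxTries, " attempts")
}

#' Simulate one VDJ rearrangement
#'
#' Picks V, D and J genes according to the age band's usage weights, draws a
#' junction length from the J-conditional model, trims gene ends and inserts
#' untemplated N nucleotides to hit it. The junction is in frame (length a
#' multiple of 3), starts at the V gene's conserved Cys codon, ends at the J
#' gene's conserved Trp codon, and the full sequence is productive (no stop
#' codons); unproductive draws are rejection-resampled.
#'
#' Consumes the current RNG stream: seed beforehand for reproducibility.
#'
#' @param db a [GermlineDatabase].
#' @param config a [SimulationConfig].
#' @param age subject age in years (selects the usage age band).
#' @param composition optional fixed junction composition for testing: a list
#'   with `vExtra`, `dStart`, `dLen`, `jExtra`, `n1`, `n2` (nt counts); when
#'   given, the junction length follows from the composition.
#' @param maxTries rejection-resampling cap; exceeding it signals an
#'   infeasible junction length model.
#' @return a list of AIRR-style fields (`v_call`, `d_call`, `j_call`,
#'   `junction`, `junction_length`, `sequence`, `sequence_alignment`,
#'   `germline_alignment`) plus `v_gene`, `j_gene`.
#' @export
simulateRearrangement <- function(db, config, age, composition = NULL,
                                  maxTries = 100L) {
  band <- as.integer(assignAgeGroup(age))
  .sim_rearr(.gene_cache(db), config, band, composition = composition,
             maxTries = maxTries)
}

# ---- somatic hypermutation --------------------------------------------------

#' Apply somatic hypermutation to the V segment
#'
#' Places `nMut` distinct single-nucleotide substitutions at uniformly chosen
#' positions of the V segment (positions 1..`vEnd` of the alignment),
#' optionally excluding already-mutated positions. Region and
#' replacement/silent status of each event are determined from the final
#' sequence: an event is R when the fully mutated codon translates
#' differently from the germline codon.
#'
#' Consumes the current RNG stream.
#'
#' @param seq nucleotide string (alignment coordinates).
#' @param germ germline string of equal length (for event annotation).
#' @param regions region table as returned by [glRegions()].
#' @param nMut number of substitutions to place.
#' @param exclude positions that must not be mutated.
#' @return list with `sequence` (mutated string) and `events` (data.frame
#'   `position`, `from`, `to`, `region`, `r_or_s` for the new events).
#' @export
applySHM <- function(seq, germ, regions, nMut, exclude = integer()) {
  vEnd <- max(regions$end)
  avail <- setdiff(seq_len(vEnd), exclude)
  if (nMut > length(avail))
    stop("nMut exceeds the number of mutable V-segment positions")
  if (nMut == 0L)
    return(list(sequence = seq, events = .empty_events()))
  pos <- sort(sample(avail, nMut))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  mutated <- paste(chars, collapse = "")
  list(sequence = mutated,
       events = .annotate_events(mutated, germ, regions, pos))
}

.empty_events <- function() {
  data.frame(position = integer(), from = character(), to = character(),
             region = character(), r_or_s = character(),
             stringsAsFactors = FALSE)
}

# annotate given mutated positions with region and R/S status; codon context
# is the germline codon with all observed mutations of that codon applied
.annotate_events <- function(seq, germ, regions, pos) {
  if (!length(pos)) return(.empty_events())
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  g <- strsplit(germ, "", fixed = TRUE)[[1]]
  region <- vapply(pos, function(p) {
    hit <- regions$region[regions$start <= p & regions$end >= p]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  r_or_s <- vapply(pos, function(p) {
    c0 <- ((p - 1L) %/% 3L) * 3L + 1L
    idx <- c0:(c0 + 2L)
    germCodon <- paste(g[idx], collapse = "")
    obsCodon <- paste(ifelse(s[idx] %in% DNA_BASES, s[idx], g[idx]),
                      collapse = "")
    if (.translate_codon(obsCodon) == .translate_codon(germCodon)) "S" else "R"
  }, character(1))
  data.frame(position = pos, from = g[pos], to = s[pos],
             region = region, r_or_s = r_or_s, stringsAsFactors = FALSE)
}

# encode events compactly for the truth TSV sidecar
.encode_events <- function(events) {
  if (!nrow(events)) return("")
  paste(sprintf("%d:%s>%s:%s:%s", events$position, events$from, events$to,
                events$region, events$r_or_s), collapse = ";")
}

#' Parse an encoded mutation-event string from the truth sidecar
#'
#' @param x character vector of encoded event strings
#'   (`"pos:from>to:region:R_or_S"` joined by `;`).
#' @return list of event data.frames.
#' @export
parseMutationEvents <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(.empty_events())
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    sub <- strsplit(vapply(parts, `[`, "", 2L), ">", fixed = TRUE)
    data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
               from = vapply(sub, `[`, "", 1L),
               to = vapply(sub, `[`, "", 2L),
               region = vapply(parts, `[`, "", 3L),
               r_or_s = vapply(parts, `[`, "", 4L),
               stringsAsFactors = FALSE)
  })
}

# ---- lineage growth ---------------------------------------------------------

#' Simulate a clonal lineage from a founder rearrangement
#'
#' Applies `trunkMutations` shared substitutions to the founder to form the
#' most recent common ancestor (emitted as the first member), then grows a
#' random branching tree: each subsequent member attaches to a uniformly
#' chosen existing node and adds `rpois(branchRate)` new mutations at
#' positions not previously mutated anywhere in the lineage (no back
#' mutation). All members share the founder's V call, J call and junction;
#' per-member copy counts are geometric for downstream Gini testing.
#'
#' Consumes the current RNG stream.
#'
#' @param founder list as returned by [simulateRearrangement()].
#' @param db a [GermlineDatabase].
#' @param nMembers number of members (>= 1).
#' @param trunkMutations shared mutations between germline and the MRCA.
#' @param branchRate mean new mutations per branch.
#' @param copyGeomProb geometric parameter for copy counts.
#' @return list with `sequences` (character), `copyCounts` (integer),
#'   `parent` (integer vector, 0 for the MRCA), and `truth` (data.frame with
#'   `n_mutations_true`, `trunk_length_true`, `events` encoded strings).
#' @export
simulateLineage <- function(founder, db, nMembers, trunkMutations,
                            branchRate = 1.5, copyGeomProb = 0.4) {
  stopifnot(nMembers >= 1L)
  regions <- glRegions(db, founder$v_gene)
  lin <- .sim_lineage(founder, regions, nMembers, trunkMutations,
                      branchRate, copyGeomProb)
  list(sequences = lin$sequences, copyCounts = lin$copyCounts,
       parent = lin$parent,
       truth = data.frame(n_mutations_true = lin$nMut,
                          trunk_length_true = trunkMutations,
                          events = lin$events, stringsAsFactors = FALSE))
}

# lineage growth core: returns flat vectors for the repertoire accumulator
.sim_lineage <- function(founder, regions, nMembers, trunkMutations,
                         branchRate, copyGeomProb) {
  germ <- founder$germline_alignment
  vEnd <- max(regions$end)
  used <- integer()
  mrca <- applySHM(founder$sequence_alignment, germ, regions,
                   trunkMutations, exclude = used)
  used <- c(used, mrca$events$position)
  seqs <- mrca$sequence
  parent <- 0L
  if (nMembers > 1L) {
    for (i in 2:nMembers) {
      p <- sample.int(i - 1L, 1L)
      k <- min(rpois(1L, branchRate), vEnd - length(used))
      child <- applySHM(seqs[p], germ, regions, k, exclude = used)
      used <- c(used, child$events$position)
      seqs <- c(seqs, child$sequence)
      parent <- c(parent, p)
    }
  }
  copyCounts <- rgeom(nMembers, copyGeomProb) + 1L
  g <- strsplit(germ, "", fixed = TRUE)[[1]]
  nMut <- integer(nMembers)
  events <- character(nMembers)
  for (i in seq_len(nMembers)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- which(s[seq_len(vEnd)] != g[seq_len(vEnd)])
    ev <- .annotate_events(seqs[i], germ, regions, pos)
    nMut[i] <- nrow(ev)
    events[i] <- .encode_events(ev)
  }
  list(sequences = seqs, copyCounts = copyCounts, parent = parent,
       nMut = nMut, events = events)
}

# truncated power-law clone size
.draw_clone_size <- function(n, alpha, maxSize) {
  sizes <- seq_len(maxSize)
  sample(sizes, n, replace = TRUE, prob = sizes^(-alpha))
}

# ---- full repertoire --------------------------------------------------------

#' Simulate an age-structured cohort of IgH repertoires
#'
#' For each subject: draws a clone count, simulates lineages with the
#' subject's age-band gene usage and SHM load, assigns isotype subclasses
#' per sequence within the clone's compartment, and fills all AIRR fields
#' including `germline_alignment`. A ground-truth sidecar records true clone
#' membership, mutation events, trunk lengths and subsets. Subjects receive
#' independent RNG streams derived from the master seed, so output is
#' byte-identical for identical configurations.
#'
#' @param config a [SimulationConfig].
#' @param db a [GermlineDatabase]; defaults to the embedded toy reference.
#' @return list with `airr` (AIRR rearrangement data.frame), `truth`
#'   (sidecar data.frame) and `subjects` (subject_id, age, age_group).
#' @export
simulateRepertoire <- function(config, db = buildToyGermlineDb()) {
  stopifnot(is(config, "SimulationConfig"))
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(config@nSubjects)),
    age = config@ages,
    age_group = as.character(assignAgeGroup(config@ages)),
    stringsAsFactors = FALSE)
  airr_all <- list(); truth_all <- list()
  for (s in seq_len(config@nSubjects)) {
    res <- .with_seed(.child_seed(config@seed, s), {
      .simulate_subject(config, db, subjects$subject_id[s], subjects$age[s])
    })
    airr_all[[s]] <- res$airr
    truth_all[[s]] <- res$truth
  }
  list(airr = do.call(rbind, airr_all),
       truth = do.call(rbind, truth_all),
       subjects = subjects)
}

.simulate_subject <- function(config, db, subjectId, age) {
  band <- as.integer(assignAgeGroup(age))
  cache <- .gene_cache(db)
  nClones <- max(1L, rpois(1L, config@cloneCount))
  sizes <- .draw_clone_size(nClones, config@cloneSizeAlpha,
                            config@cloneSizeMax)
  nTotal <- sum(sizes)
  # flat accumulators: one data.frame construction per subject
  col <- function(proto) rep(proto, nTotal)
  sequence <- col(NA_character_); germline <- col(NA_character_)
  v_call <- col(NA_character_); d_call <- col(NA_character_)
  j_call <- col(NA_character_); junction <- col(NA_character_)
  junction_length <- col(NA_integer_); c_call <- col(NA_character_)
  dup <- col(NA_integer_); cloneTrue <- col(NA_character_)
  nMut <- col(NA_integer_); trunkTrue <- col(NA_integer_)
  subsetTrue <- col(NA_character_); events <- col(NA_character_)
  probs <- config@subclassProbs[band, ]
  off <- 0L
  for (cl in seq_len(nClones)) {
    n <- sizes[cl]
    idx <- off + seq_len(n)
    off <- off + n
    subclass0 <- sample(SUBCLASSES, 1L, prob = probs)
    comp <- .compartment_of(subclass0)
    founder <- .sim_rearr(cache, config, band)
    mutated <- if (comp == "IgDM")
      runif(1L) > config@naiveFraction[band] else TRUE
    if (mutated) {
      mu <- config@shmA[[comp]] + config@shmB[[comp]] * log(1 + age)
      trunk <- rpois(1L, config@trunkFraction * mu)
      brate <- config@branchRate
    } else {
      trunk <- 0L; brate <- 0
    }
    lin <- .sim_lineage(founder, cache[[founder$v_gene]]$regions, n, trunk,
                        brate, config@copyGeomProb)
    # subclass per sequence, conditional on the clone's compartment
    inComp <- SUBCLASSES[.compartment_of(SUBCLASSES) == comp]
    cCalls <- sample(inComp, n, replace = TRUE, prob = probs[inComp])
    sequence[idx] <- lin$sequences
    germline[idx] <- founder$germline_alignment
    v_call[idx] <- founder$v_call; d_call[idx] <- founder$d_call
    j_call[idx] <- founder$j_call
    junction[idx] <- founder$junction
    junction_length[idx] <- founder$junction_length
    c_call[idx] <- cCalls
    dup[idx] <- lin$copyCounts
    cloneTrue[idx] <- sprintf("%s_trueclone%04d", subjectId, cl)
    nMut[idx] <- lin$nMut
    trunkTrue[idx] <- trunk
    subsetTrue[idx] <- if (comp == "IgDM") {
      if (mutated) "memory_IgDM" else "naive_IgDM"
    } else cCalls
    events[idx] <- lin$events
  }
  ids <- sprintf("%s_seq%06d", subjectId, seq_len(nTotal))
  list(
    airr = data.frame(
      sequence_id = ids, sequence = sequence,
      sequence_alignment = sequence, germline_alignment = germline,
      v_call = v_call, d_call = d_call, j_call = j_call,
      junction = junction, junction_length = junction_length,
      c_call = c_call, subject_id = subjectId, duplicate_count = dup,
      stringsAsFactors = FALSE),
    truth = data.frame(
      sequence_id = ids, subject_id = subjectId,
      clone_id_true = cloneTrue, n_mutations_true = nMut,
      trunk_length_true = trunkTrue, subset_true = subsetTrue,
      events = events, stringsAsFactors = FALSE))
}

# ---- UMI read emission ------------------------------------------------------

#' Expand unique sequences into UMI-tagged read records
#'
#' Each rearrangement row represents `duplicate_count` mRNA molecules; every
#' molecule receives its own 14-nt UMI and is read `dupRate` times, with
#' optional per-base substitution errors. This produces both collapsing
#' scenarios handled downstream: reads sharing a UMI (same molecule) and
#' distinct molecules carrying the identical sequence under different UMIs.
#'
#' Consumes the current RNG stream.
#'
#' @param table AIRR rearrangement data.frame (needs `sequence`, `c_call`,
#'   `subject_id`, `duplicate_count`).
#' @param dupRate reads per molecule (>= 1).
#' @param errorRate per-base substitution error probability.
#' @return data.frame of read records (`read_id`, `sequence`, `umi`,
#'   `constant_primer_id`, `subject_id`).
#' @export
simulateReadsWithUMI <- function(table, dupRate = 3L, errorRate = 0) {
  stopifnot(dupRate >= 1L)
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(table))) {
    primer <- if (table$c_call[i] %in% c("IgM", "IgD"))
      "cprimer_MD" else "cprimer_AGE"
    for (mol in seq_len(table$duplicate_count[i])) {
      umi <- paste(sample(DNA_BASES, 14L, replace = TRUE), collapse = "")
      for (r in seq_len(dupRate)) {
        sq <- table$sequence[i]
        if (errorRate > 0) {
          chars <- strsplit(sq, "", fixed = TRUE)[[1]]
          hit <- which(runif(length(chars)) < errorRate)
          for (p in hit)
            chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
          sq <- paste(chars, collapse = "")
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          read_id = sprintf("read%07d", k), sequence = sq, umi = umi,
          constant_primer_id = primer, subject_id = table$subject_id[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
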