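regions18 <- glRegions(toy_db, "IGHV1-8S")

test_that("mutation counting matches hand-built codon cases", {
  r <- make_rearrangement()
  prof0 <- countVMutations(r$sequence_alignment, r$germline_alignment,
                           regions18)
  expect_identical(prof0$n_total, 0L)
  expect_identical(prof0$r_cdr + prof0$s_cdr + prof0$r_fwr + prof0$s_fwr, 0L)

  # place a synonymous change in FWR1: find a germline codon where a third-
  # position swap keeps the amino acid
  g <- glSequence(toy_db, "IGHV1-8S")
  hit <- NULL
  for (c0 in seq(1, 73, 3)) {
    codon <- substr(g, c0, c0 + 2)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      cand <- paste0(substr(codon, 1, 2), alt)
      if (translateNt(cand) == translateNt(codon)) {
        hit <- list(pos = c0 + 2, base = alt); break
      }
    }
    if (!is.null(hit)) break
  }
  mut <- make_rearrangement(mutations = setNames(list(hit$base),
                                                 as.character(hit$pos)))
  prof <- countVMutations(mut$sequence_alignment, mut$germline_alignment,
                          regions18)
  expect_identical(prof$s_fwr, 1L)
  expect_identical(prof$n_total, 1L)
  expect_identical(prof$r_cdr + prof$s_cdr + prof$r_fwr, 0L)
  expect_identical(prof$n_fwr1, 1L)

  expect_error(countVMutations("ACGT", "ACGTA", regions18), "length")
})

test_that("positions with N or gaps are skipped", {
  g10 <- substr(glSequence(toy_db, "IGHV1-8S"), 10, 10)
  alt10 <- setdiff(c("A", "C", "G", "T"), g10)[1]
  r <- make_rearrangement(mutations = setNames(list("N", alt10),
                                               c("5", "10")))
  prof <- countVMutations(r$sequence_alignment, r$germline_alignment,
                          regions18)
  expect_identical(prof$n_total, 1L)  # only position 10 counted
})

test_that("profile totals equal simulator truth on hundreds of sequences", {
  cfgT <- small_config(nSubjects = 4L, ages = c(2, 15, 30, 45), seed = 77L,
                       cloneCount = 70)
  sim <- simulateRepertoire(cfgT, toy_db)
  expect_gt(nrow(sim$airr), 500)
  ann <- annotateMutations(sim$airr, toy_db)
  truth <- sim$truth[match(ann$sequence_id, sim$truth$sequence_id), ]
  expect_identical(ann$n_v_mutations, truth$n_mutations_true)
  # per-class totals also agree with the recorded events
  ev <- parseMutationEvents(truth$events)
  expect_identical(ann$r_cdr, vapply(ev, function(e)
    sum(e$region %in% c("CDR1", "CDR2") & e$r_or_s == "R"), integer(1)))
  expect_identical(ann$s_fwr, vapply(ev, function(e)
    sum(!e$region %in% c("CDR1", "CDR2") & e$r_or_s == "S"), integer(1)))
})

test_that("mutation counting agrees with a brute-force re-translation oracle", {
  set.seed(14)
  for (i in 1:50) {
    re <- simulateRearrangement(toy_db, small_config(), 25)
    regions <- glRegions(toy_db, getGene(re$v_call))
    mut <- applySHM(re$sequence_alignment, re$germline_alignment, regions,
                    sample(0:15, 1))
    prof <- countVMutations(mut$sequence, re$germline_alignment, regions)
    # oracle: exhaustive per-codon comparison over the V segment
    s <- strsplit(mut$sequence, "")[[1]]
    g <- strsplit(re$germline_alignment, "")[[1]]
    r_cdr <- s_cdr <- r_fwr <- s_fwr <- 0L
    for (k in seq_len(nrow(regions))) {
      cdr <- grepl("^CDR", regions$region[k])
      for (c0 in seq(regions$start[k], regions$end[k], 3)) {
        idx <- c0:(c0 + 2)
        nmut <- sum(s[idx] != g[idx])
        if (!nmut) next
        repl <- translateNt(paste(s[idx], collapse = "")) !=
          translateNt(paste(g[idx], collapse = ""))
        if (cdr) {
          if (repl) r_cdr <- r_cdr + nmut else s_cdr <- s_cdr + nmut
        } else {
          if (repl) r_fwr <- r_fwr + nmut else s_fwr <- s_fwr + nmut
        }
      }
    }
    expect_identical(c(prof$r_cdr, prof$s_cdr, prof$r_fwr, prof$s_fwr),
                     c(r_cdr, s_cdr, r_fwr, s_fwr))
  }
})

test_that("subset classification follows the 2-mutation naive rule", {
  expect_identical(classifySubset("IgM", 2L), "naive_IgDM")
  expect_identical(classifySubset("IgM", 3L), "memory_IgDM")
  expect_identical(classifySubset("IgD", 0L), "naive_IgDM")
  expect_identical(classifySubset("IgG1", 0L), "IgG1")  # class-switched:
  # antigen-experienced irrespective of mutation count
  expect_identical(classifySubset("IgA2", 40L), "IgA2")
  expect_identical(classifySubset("IgE", 5L), "excluded")
  expect_identical(classifySubset("IgG4", 5L), "excluded")
  expect_error(classifySubset("IgZ", 1L), "IgZ")
})

test_that("every non-excluded sequence lands in exactly one subset", {
  sim <- simulateRepertoire(small_config(), toy_db)
  tab <- annotateSubsets(annotateMutations(sim$airr, toy_db))
  expect_true(all(tab$subset %in% c("naive_IgDM", "memory_IgDM", "IgG1",
                                    "IgG2", "IgG3", "IgA1", "IgA2")))
  expect_identical(nrow(tab), nrow(sim$airr))  # simulator emits no IgE/IgG4
})

test_that("memory fraction of IgD/IgM rises with age under the SHM trend", {
  cfgM <- simulationConfig(nSubjects = 20L,
                           ages = seq(1, 48, length.out = 20), seed = 19L,
                           cloneCount = 40)
  sim <- simulateRepertoire(cfgM, toy_db)
  tab <- annotateSubsets(annotateMutations(sim$airr, toy_db))
  igdm <- tab[tab$subset %in% c("naive_IgDM", "memory_IgDM"), ]
  frac <- vapply(split(igdm$subset, igdm$subject_id),
                 function(x) mean(x == "memory_IgDM"), numeric(1))
  age <- cfgM@ages[match(names(frac), sprintf("S%02d", 1:20))]
  expect_gt(cor(age, frac, method = "spearman"), 0)
})

test_that("usage profiles are normalised frequency vectors", {
  sim <- simulateRepertoire(small_config(), toy_db)
  tab <- annotateSubsets(annotateMutations(sim$airr, toy_db))
  up <- usageProfile(tab, "v_family")
  sums <- aggregate(freq ~ subject_id + subset, up, sum)
  expect_true(all(abs(sums$freq - 1) < 1e-9))
  # zero-count categories present with frequency 0
  counts <- aggregate(n ~ subject_id + subset, up, length)
  expect_true(all(counts$n == length(unique(getFamily(tab$v_call)))))
  # a subject with only V1 sequences has V1 frequency 1
  v1only <- tab[getFamily(tab$v_call) == "V1" & tab$subject_id == "S01", ]
  upv <- usageProfile(v1only, "v_family")
  expect_true(all(upv$freq[upv$category == "V1"] == 1))
})

test_that("simulated usage recovers configured gene weights within 2%", {
  cfgU <- simulationConfig(nSubjects = 1L, ages = 20, seed = 23L,
                           cloneCount = 5500, cloneSizeMax = 2L)
  sim <- simulateRepertoire(cfgU, toy_db)
  band <- as.integer(assignAgeGroup(20))
  # gene draws are per clone; tally unique clones to match the multinomial
  first <- !duplicated(sim$truth$clone_id_true)
  vg <- getGene(sim$airr$v_call[first])
  emp <- table(factor(vg, levels = colnames(cfgU@vUsage))) / sum(first)
  expect_true(all(abs(as.numeric(emp) - cfgU@vUsage[band, ]) <= 0.02))
  jg <- getGene(sim$airr$j_call[first])
  empj <- table(factor(jg, levels = colnames(cfgU@jUsage))) / sum(first)
  expect_true(all(abs(as.numeric(empj) - cfgU@jUsage[band, ]) <= 0.02))
})

test_that("junction summaries average correctly and honour restrictions", {
  rows <- rbind(
    make_rearrangement(id = "a", cdr3n = 39L),   # 45-nt junction
    make_rearrangement(id = "b", cdr3n = 39L),
    make_rearrangement(id = "c", jGene = "IGHJ6S", cdr3n = 57L))
  rows$subset <- "naive_IgDM"
  js <- junctionSummary(rows)
  expect_identical(js$mean_junction_length,
                   mean(c(45, 45, 63)))
  j4 <- junctionSummary(rows, jGene = "IGHJ4S")
  expect_identical(j4$mean_junction_length, 45)
  # empty filter result: absent entry, not zero
  expect_identical(nrow(junctionSummary(rows, jGene = "IGHJ1S")), 0L)
})

test_that("J6-restricted junctions are longer than J4 in a default cohort", {
  sim <- simulateRepertoire(small_config(seed = 33L), toy_db)
  tab <- annotateSubsets(annotateMutations(sim$airr, toy_db))
  j6 <- junctionSummary(tab, jGene = "IGHJ6S")
  j4 <- junctionSummary(tab, jGene = "IGHJ4S")
  expect_gt(mean(j6$mean_junction_length), mean(j4$mean_junction_length))
})
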