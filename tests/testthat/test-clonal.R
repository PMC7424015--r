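test_that("the CDR3 mismatch threshold is floor(L/15)", {
  # CDR3 length 30: threshold floor(30/15) = 2
  base <- strrep("GCA", 10)
  mut2 <- paste0("TT", substr(base, 3, 30))
  mut3 <- paste0("TTT", substr(base, 4, 30))
  tab <- rbind(make_rearrangement(id = "a", cdr3 = base),
               make_rearrangement(id = "b", cdr3 = mut2))
  cl <- clusterClones(tab)
  expect_identical(cl$clone_id[1], cl$clone_id[2])
  tab2 <- rbind(make_rearrangement(id = "a", cdr3 = base),
                make_rearrangement(id = "c", cdr3 = mut3))
  cl2 <- clusterClones(tab2)
  expect_false(cl2$clone_id[1] == cl2$clone_id[2])
})

test_that("sequences differing in V, J or CDR3 length never share a clone", {
  tab <- rbind(
    make_rearrangement(id = "a"),
    make_rearrangement(id = "b", vGene = "IGHV3-7S"),
    make_rearrangement(id = "c", jGene = "IGHJ6S"),
    make_rearrangement(id = "d", cdr3n = 27L))
  cl <- clusterClones(tab)
  expect_identical(length(unique(cl$clone_id)), 4L)
})

test_that("clustering equals brute-force single-linkage components", {
  set.seed(41)
  for (rep in 1:10) {
    L <- sample(c(15L, 24L, 30L), 1)
    n <- 60L
    # seed a few centers and scatter mutated copies around them
    centers <- vapply(1:6, function(i)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), "")
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(sample(centers, 1), "")[[1]]
      k <- sample(0:4, 1)
      pos <- sample(L, k)
      s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste(s, collapse = "")
    }, "")
    tab <- do.call(rbind, lapply(seq_len(n), function(i)
      make_rearrangement(id = sprintf("s%02d", i), cdr3 = seqs[i])))
    cl <- clusterClones(tab)
    oracle <- brute_force_components(seqs, floor(L / 15))
    expect_true(same_partition(cl$clone_id, oracle))
  }
})

test_that("the clone partition is invariant to input row order", {
  set.seed(43)
  seqs <- vapply(1:40, function(i) {
    s <- strsplit(strrep("GCA", 8), "")[[1]]
    pos <- sample(24, sample(0:3, 1))
    s[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    paste(s, collapse = "")
  }, "")
  tab <- do.call(rbind, lapply(seq_along(seqs), function(i)
    make_rearrangement(id = sprintf("s%02d", i), cdr3 = seqs[i])))
  cl1 <- clusterClones(tab)
  perm <- sample(nrow(tab))
  cl2 <- clusterClones(tab[perm, ])
  expect_true(same_partition(cl1$clone_id[perm], cl2$clone_id))
})

test_that("gini index matches its closed forms", {
  expect_identical(giniIndex(c(5, 5, 5, 5)), 0)
  expect_identical(giniIndex(7), 0)
  expect_equal(giniIndex(c(97, 1, 1, 1)), 0.72, tolerance = 1e-12)
  # scale invariance
  x <- c(3, 9, 1, 14, 2)
  expect_equal(giniIndex(1000 * x), giniIndex(x), tolerance = 1e-12)
  expect_error(giniIndex(numeric()), "empty")
  expect_error(giniIndex(c(1, 0)), "positive")
})

test_that("lineage trunk length follows the MRCA definition", {
  r <- make_rearrangement()
  g <- r$germline_alignment
  mutate_at <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  # singleton with 7 V mutations -> trunk 7
  s1 <- r
  s1$sequence_alignment <- mutate_at(r$sequence_alignment, c(4, 10, 22, 40,
                                                             100, 181, 250))
  tr <- buildLineage(s1, "c1")
  expect_identical(trunkLength(tr), 7)
  # two members sharing 5 mutations, each with 2 private -> trunk 5
  shared <- c(4, 10, 22, 40, 100)
  m1 <- r; m1$sequence_id <- "m1"
  m1$sequence_alignment <- mutate_at(r$sequence_alignment,
                                     c(shared, 130, 140))
  m2 <- r; m2$sequence_id <- "m2"
  m2$sequence_alignment <- mutate_at(r$sequence_alignment,
                                     c(shared, 200, 210))
  tr2 <- buildLineage(rbind(m1, m2), "c2")
  expect_identical(trunkLength(tr2), 5)
  # trunk never exceeds any member's distance to the root
  expect_lte(trunkLength(tr2), 7)
})

test_that("trunk length equals simulated truth when intermediates are observed", {
  set.seed(47)
  cfgL <- small_config()
  for (i in 1:30) {
    f <- simulateRearrangement(toy_db, cfgL, 30)
    trunk <- sample(0:10, 1)
    lin <- simulateLineage(f, toy_db, nMembers = sample(1:8, 1),
                           trunkMutations = trunk, branchRate = 2)
    clone <- do.call(rbind, lapply(seq_along(lin$sequences), function(k) {
      r <- make_rearrangement(id = sprintf("m%d", k))
      r$sequence_alignment <- lin$sequences[k]
      r$germline_alignment <- f$germline_alignment
      r$duplicate_count <- lin$copyCounts[k]
      r
    }))
    expect_identical(trunkLength(buildLineage(clone, "cx")), as.numeric(trunk))
  }
})

test_that("mean trunk length tracks the configured trunk parameter", {
  set.seed(53)
  cfgL <- small_config()
  levels <- 1:10
  means <- vapply(levels, function(tm) {
    mean(vapply(1:12, function(i) {
      f <- simulateRearrangement(toy_db, cfgL, 30)
      lin <- simulateLineage(f, toy_db, nMembers = 4L, trunkMutations = tm,
                             branchRate = 1.5)
      clone <- data.frame(sequence_alignment = lin$sequences,
                          germline_alignment = f$germline_alignment,
                          duplicate_count = lin$copyCounts,
                          stringsAsFactors = FALSE)
      trunkLength(buildLineage(clone, "c"))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(levels, means, method = "spearman"), 0.9)
})

test_that("lineage trees are well-formed and export to Newick", {
  set.seed(59)
  f <- simulateRearrangement(toy_db, small_config(), 30)
  lin <- simulateLineage(f, toy_db, nMembers = 6L, trunkMutations = 4L,
                         branchRate = 2)
  clone <- data.frame(sequence_alignment = lin$sequences,
                      germline_alignment = f$germline_alignment,
                      duplicate_count = lin$copyCounts,
                      stringsAsFactors = FALSE)
  tr <- buildLineage(clone, "c9")
  expect_identical(nrow(tr@edges), nrow(tr@nodes) - 1L)
  expect_gte(trunkLength(tr), 0)
  expect_true(giniIndex(tr) >= 0 && giniIndex(tr) < 1)
  nwk <- asNewick(tr)
  expect_match(nwk, ";$")
  ph <- ape::read.tree(text = nwk)
  expect_s3_class(ph, "phylo")
  # every observed sequence appears as a tip or node label
  labs <- c(ph$tip.label, ph$node.label)
  expect_true(all(tr@nodes$id[tr@nodes$observed] %in% labs))
})

test_that("subsampling is seeded, warned and bounded", {
  sim <- simulateRepertoire(small_config(), toy_db)
  tab <- sim$airr
  expect_warning(out <- subsampleRepertoire(tab, n = 10 * nrow(tab)),
                 "unchanged")
  expect_identical(out, tab)
  s1 <- subsampleRepertoire(tab, n = 50L, seed = 7L)
  s2 <- subsampleRepertoire(tab, n = 50L, seed = 7L)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 50L)
  expect_identical(formals(subsampleRepertoire)$n, 25609L)
})

test_that("effective sequences are majority consensus, idempotent", {
  r1 <- make_rearrangement(id = "a")
  expect_identical(effectiveSequence(r1)$sequence_alignment,
                   r1$sequence_alignment)
  mutate_at <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  r2 <- make_rearrangement(id = "b")
  r2$sequence_alignment <- mutate_at(r2$sequence_alignment, 12)
  clone <- rbind(r1, make_rearrangement(id = "c"), r2)
  eff <- effectiveSequence(clone)
  expect_identical(eff$sequence_alignment, r1$sequence_alignment)  # 2 vs 1
  expect_identical(eff$duplicate_count, 3L)
  # consensus of consensus = consensus
  eff2 <- effectiveSequence(rbind(eff, eff, eff))
  expect_identical(eff2$sequence_alignment, eff$sequence_alignment)
})
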