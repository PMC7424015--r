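# Shared fixtures: the embedded germline reference and small cohort
# configurations used across test files.

toy_db <- buildToyGermlineDb()

small_config <- function(nSubjects = 2L, ages = c(2, 40), seed = 101L, ...) {
  simulationConfig(nSubjects = nSubjects, ages = ages, seed = seed, ...)
}

# minimal rearrangement rows built directly from a germline gene, with a
# fixed junction; optional point mutations given as position -> base
make_rearrangement <- function(db = toy_db, vGene = "IGHV1-8S",
                               jGene = "IGHJ4S", cdr3n = 24L,
                               mutations = NULL, cCall = "IgM",
                               subject = "S01", id = "seq1",
                               dupCount = 1L, cdr3 = NULL) {
  vSeq <- glSequence(db, vGene)
  vEnd <- vSegmentEnd(db, vGene)
  vBody <- substr(vSeq, 1L, vEnd)
  jSeq <- glSequence(db, jGene)
  trp <- glAnchor(db, jGene)
  fr4 <- substr(jSeq, trp + 3L, nchar(jSeq))
  if (is.null(cdr3)) cdr3 <- strrep("GCA", cdr3n / 3L)
  junction <- paste0("TGT", cdr3, "TGG")
  seqFull <- paste0(vBody, junction, fr4)
  germ <- paste0(vBody, "TGT", strrep("N", nchar(cdr3)), "TGG", fr4)
  if (!is.null(mutations)) {
    chars <- strsplit(seqFull, "", fixed = TRUE)[[1]]
    for (p in names(mutations)) chars[as.integer(p)] <- mutations[[p]]
    seqFull <- paste(chars, collapse = "")
  }
  data.frame(
    sequence_id = id, sequence = seqFull, sequence_alignment = seqFull,
    germline_alignment = germ,
    v_call = paste0(vGene, "*01"), d_call = "IGHD2-2S*01",
    j_call = paste0(jGene, "*01"),
    junction = substr(seqFull, vEnd + 1L, vEnd + nchar(junction)),
    junction_length = nchar(junction), c_call = cCall,
    subject_id = subject, duplicate_count = dupCount,
    stringsAsFactors = FALSE)
}

# brute-force single-linkage connected components by repeated frontier
# expansion over a pairwise "linked" predicate; independent of the
# igraph-based implementation
brute_force_linkage <- function(n, linked) {
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- integer()
      for (f in frontier) for (j in seq_len(n)) {
        if (is.na(comp[j]) && linked(f, j)) {
          comp[j] <- cur
          nxt <- c(nxt, j)
        }
      }
      frontier <- nxt
    }
  }
  comp
}

brute_force_components <- function(seqs, threshold) {
  ch <- strsplit(seqs, "", fixed = TRUE)
  brute_force_linkage(length(seqs), function(i, j)
    sum(ch[[i]] != ch[[j]]) <= threshold)
}

# planted sharing design: every subject carries nPrivate private clones plus
# the same nShared universal clones; CDR3s are kept far apart so that no
# accidental cross-linking occurs
planted_cohort <- function(nSubjects = 10L, nPrivate = 50L, nShared = 5L) {
  set.seed(89)
  rand_cdr3 <- function(n, existing = character()) {
    out <- character(0)
    pool <- c(existing)
    while (length(out) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                    collapse = "")
      far <- all(vapply(c(pool, out), function(x)
        sum(strsplit(x, "")[[1]] != strsplit(cand, "")[[1]]) > 6,
        logical(1)))
      if (far) out <- c(out, cand)
    }
    out
  }
  shared <- rand_cdr3(nShared)
  rows <- list()
  for (s in seq_len(nSubjects)) {
    priv <- rand_cdr3(nPrivate, existing = shared)
    for (k in seq_along(priv))
      rows[[length(rows) + 1L]] <-
        make_rearrangement(id = sprintf("S%02d_p%02d", s, k),
                           subject = sprintf("S%02d", s), cdr3 = priv[k])
    for (k in seq_along(shared))
      rows[[length(rows) + 1L]] <-
        make_rearrangement(id = sprintf("S%02d_sh%02d", s, k),
                           subject = sprintf("S%02d", s), cdr3 = shared[k])
  }
  do.call(rbind, rows)
}

# partition equality up to label renaming
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
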