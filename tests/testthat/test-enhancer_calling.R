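test_that("candidate regions merge marks across the merge gap", {
  mk <- function(s, e) GenomicRanges::GRanges("mm", IRanges::IRanges(s, e))
  locus <- mk(1, 100000)
  t1 <- mark_track("a", "mouse", mk(1000, 2000))
  t2 <- mark_track("b", "mouse", mk(2000, 3000))    # 1 bp overlap
  out <- build_candidate_regions(list(t1, t2), locus)
  expect_length(out, 1)
  expect_equal(GenomicRanges::start(out), 1000)
  expect_equal(GenomicRanges::end(out), 3000)

  t3 <- mark_track("c", "mouse", mk(5000, 5100))
  t4 <- mark_track("d", "mouse", mk(6101, 6200))    # 1 kb gap > 500
  out2 <- build_candidate_regions(list(t3, t4), locus, merge_gap = 500)
  expect_length(out2, 2)

  t5 <- mark_track("e", "human", mk(1, 10))
  expect_error(build_candidate_regions(list(t1, t5), locus), "species")
})

test_that("candidate merging equals a brute-force endpoint-sweep oracle", {
  set.seed(23)
  locus <- GenomicRanges::GRanges("mm", IRanges::IRanges(1, 20000))
  for (rep in 1:10) {
    gap <- sample(c(0, 100, 500), 1)
    s <- sample.int(19000, 50, replace = TRUE)
    e <- s + sample.int(800, 50, replace = TRUE)
    tr <- mark_track("x", "mouse", GenomicRanges::GRanges("mm",
                                                          IRanges::IRanges(s, e)))
    got <- build_candidate_regions(list(tr), locus, merge_gap = gap)
    # oracle: sort by start, sweep, fuse when gap <= merge_gap
    o <- order(s); ms <- s[o]; me <- e[o]
    rs <- ms[1]; re <- me[1]; starts <- c(); ends <- c()
    for (i in seq_along(ms)[-1]) {
      if (ms[i] - re - 1 <= gap) re <- max(re, me[i])
      else { starts <- c(starts, rs); ends <- c(ends, re); rs <- ms[i]; re <- me[i] }
    }
    starts <- c(starts, rs); ends <- c(ends, re)
    expect_equal(GenomicRanges::start(got), starts)
    expect_equal(GenomicRanges::end(got), ends)
  }
})

test_that("mark evidence matches a quadratic all-pairs overlap oracle", {
  set.seed(31)
  orth <- data.frame(src_seq = "mm", src_start = 0, src_end = 10000,
                     tgt_seq = "hs", tgt_start = 0, tgt_end = 10000)
  for (rep in 1:10) {
    tracks <- lapply(names(STUDY_DATASETS), function(ds) {
      sp <- STUDY_DATASETS[[ds]]
      n <- sample(0:6, 1)
      s <- sample.int(9500, n, replace = TRUE)
      gr <- GenomicRanges::GRanges(
        rep(if (sp == "mouse") "mm" else "hs", n),
        IRanges::IRanges(s + 1, s + sample.int(400, n, replace = TRUE)))
      mark_track(ds, sp, gr)
    })
    rs <- sample.int(9000, 1); re <- rs + 500
    region <- GenomicRanges::GRanges("mm", IRanges::IRanges(rs + 1, re))
    ev <- collect_mark_evidence(region, tracks, orth)
    for (i in seq_along(tracks)) {
      iv <- tracks[[i]]$intervals
      expected <- any(oracle_any_overlap(
        rs, re, GenomicRanges::start(iv) - 1, GenomicRanges::end(iv)))
      expect_identical(ev$present[i], expected)
    }
  }
})

test_that("unmappable regions record human datasets false with a note", {
  tracks <- list(
    mark_track("H_histone", "human",
               GenomicRanges::GRanges("hs", IRanges::IRanges(1, 1000))),
    mark_track("M_artery_ATAC", "mouse",
               GenomicRanges::GRanges("mm", IRanges::IRanges(1, 1000))))
  region <- GenomicRanges::GRanges("mm", IRanges::IRanges(10, 500))
  ev <- collect_mark_evidence(region, tracks, orthology = NULL)
  expect_false(ev$present[ev$species == "human"])
  expect_equal(ev$note[ev$species == "human"], "unmapped")
  expect_true(ev$present[ev$species == "mouse"])
})

test_that("non-EC-specific marks count as evidence but carry the flag", {
  gr <- GenomicRanges::GRanges("mm", IRanges::IRanges(1, 1000))
  S4Vectors::mcols(gr)$ec_specific <- FALSE
  tr <- mark_track("M_E11_p300", "mouse", gr)
  region <- GenomicRanges::GRanges("mm", IRanges::IRanges(10, 500))
  ev <- collect_mark_evidence(region, list(tr), NULL)
  expect_true(ev$present)
  expect_true(ev$nonspecific)
})

test_that("the putative call reproduces the printed evidence patterns", {
  # the one known enhancer failing the both-species criterion: human marks
  # only (H histone), no mouse dataset positive
  pdgfrb <- evidence_frame(c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(call_putative(pdgfrb, TRUE)$decision, "below_threshold")
  # all five datasets positive
  dll4in3 <- evidence_frame(rep(TRUE, 5))
  expect_equal(call_putative(dll4in3, TRUE)$decision, "putative")
  # poorly transcribed gene: two mouse marks, no human marks
  relaxed <- evidence_frame(c(FALSE, FALSE, TRUE, TRUE, FALSE))
  call <- call_putative(relaxed, FALSE)
  expect_equal(call$decision, "putative")
  expect_equal(call$rule_used, "mouse_only_relaxed")
  # no evidence at all
  expect_equal(call_putative(evidence_frame(rep(FALSE, 5)), TRUE)$decision,
               "below_threshold")
})

test_that("the putative rule equals the exhaustive truth table", {
  grid <- expand.grid(replicate(5, c(FALSE, TRUE), simplify = FALSE))
  for (tx in c(TRUE, FALSE)) {
    for (i in seq_len(nrow(grid))) {
      present <- as.logical(grid[i, ])
      got <- call_putative(evidence_frame(present), tx)
      n_h <- sum(present[1:2]); n_m <- sum(present[3:5])
      want <- if (tx) (n_m >= 1 && n_h >= 1) else n_m >= 2
      expect_identical(got$decision == "putative", want)
    }
  }
})

test_that("adding a true mark never flips putative to below_threshold", {
  set.seed(5)
  for (i in 1:40) {
    present <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    tx <- sample(c(TRUE, FALSE), 1)
    base <- call_putative(evidence_frame(present), tx)$decision
    off <- which(!present)
    if (length(off) == 0) next
    present[sample(off, 1)] <- TRUE
    more <- call_putative(evidence_frame(present), tx)$decision
    expect_false(base == "putative" && more == "below_threshold")
  }
})

test_that("retrospective aggregation over the known-enhancer table", {
  mk <- read_mark_matrix(fixture_path("known_enhancers_marks.tsv"),
                         STUDY_DATASETS)
  expect_equal(nrow(mk), 32)
  s <- retrospective_mark_summary(mk, class_col = "arterial",
                                  class_value = TRUE)
  expect_equal(s$n_total, 32)
  expect_equal(s$n_with_mark_both_species, 31)
  expect_equal(s$class_n_total, 8)
  expect_equal(s$class_n_with_mark_both_species, 8)
  # empty input gives zero counts
  empty <- retrospective_mark_summary(mk[0, ], STUDY_DATASETS)
  expect_equal(empty$n_total, 0)
  expect_equal(empty$n_with_mark_both_species, 0)
  # incomplete evidence errors naming the record
  broken <- mk
  broken$H_DNaseI[3] <- NA
  expect_error(retrospective_mark_summary(broken, STUDY_DATASETS),
               broken$name[3], fixed = TRUE)
})
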