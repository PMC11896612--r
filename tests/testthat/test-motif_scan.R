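test_that("consensus scanning finds the documented example hits", {
  h <- scan_consensus("ATGGGAAT", "TGGGAA")
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 1); expect_equal(h$end, 7)
  expect_equal(h$strand, "+")
  expect_equal(h$matched_sequence, "TGGGAA")

  # reverse complement of ACTTCCTG contains AGGAAG (H=A, R=G)
  h2 <- scan_consensus("ACTTCCTG", "HGGAAR")
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$matched_sequence, "AGGAAG")

  expect_equal(nrow(scan_consensus("", "TGGGAA")), 0)
  expect_error(scan_consensus("ACGT", "QQQ"), "IUPAC")
})

test_that("a palindromic match is reported once per strand", {
  h <- scan_consensus("TTGGCGCCTT", "GGCGCC")
  expect_equal(nrow(h), 2)
  expect_setequal(h$strand, c("-", "+"))
  expect_equal(unique(h$start), 2)
})

test_that("N in the sequence matches only an N consensus position", {
  expect_equal(nrow(scan_consensus("TGGGNA", "TGGGAA")), 0)
  expect_equal(nrow(scan_consensus("TGNGAA", "TGNGAA")), 1)
})

test_that("scanning equals the brute-force window oracle", {
  set.seed(77)
  consensi <- c("HGGAAR", "TGGGAA", "WWCAAW", "RYAAAYA", "GGCGCC",
                "CTTTGWW")
  for (cons in consensi) {
    for (rep in 1:3) {
      s <- random_dna(sample(c(200, 500, 2000), 1))
      got <- scan_consensus(s, cons)
      want <- oracle_scan(s, cons)
      expect_equal(got$start, want$start, info = cons)
      expect_equal(got$end, want$end, info = cons)
      expect_equal(got$strand, want$strand, info = cons)
    }
  }
})

test_that("scanning the reverse complement mirrors the hit set", {
  set.seed(13)
  for (rep in 1:5) {
    s <- random_dna(300)
    rc <- oracle_revcomp(s)
    fwd <- scan_consensus(s, "HGGAAR")
    rev <- scan_consensus(rc, "HGGAAR")
    L <- nchar(s)
    mirrored <- data.frame(
      start = L - rev$end, end = L - rev$start,
      strand = as.character(ifelse(rev$strand == "+", "-", "+")),
      stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$strand, mirrored$strand)
  }
})

test_that("FOX:ETS composites are flagged by gap, strand and orientation", {
  hits <- rbind(
    data.frame(enhancer = "e", family = "FOX", start = 10, end = 17,
               strand = "+", matched_sequence = "ATAAATA", tier = NA,
               composite_member = FALSE),
    data.frame(enhancer = "e", family = "ETS", start = 18, end = 24,
               strand = "+", matched_sequence = "AGGAAG", tier = NA,
               composite_member = FALSE),
    data.frame(enhancer = "e", family = "ETS", start = 80, end = 86,
               strand = "+", matched_sequence = "AGGAAG", tier = NA,
               composite_member = FALSE))
  out <- detect_composite_fox_ets(hits, window = 2)
  expect_true(all(out$composite_member[1:2]))
  expect_false(out$composite_member[3])

  # opposite strands never pair
  hits$strand[2] <- "-"
  out2 <- detect_composite_fox_ets(hits, window = 2)
  expect_false(any(out2$composite_member[1:2]))

  # on the minus strand, 5' of the ETS core means to its right
  mhits <- rbind(
    data.frame(enhancer = "e", family = "ETS", start = 10, end = 16,
               strand = "-", matched_sequence = "AGGAAG", tier = NA,
               composite_member = FALSE),
    data.frame(enhancer = "e", family = "FOX", start = 17, end = 24,
               strand = "-", matched_sequence = "ATAAATA", tier = NA,
               composite_member = FALSE))
  out3 <- detect_composite_fox_ets(mhits, window = 2)
  expect_true(all(out3$composite_member))
})

test_that("composite detection equals a quadratic all-pairs oracle", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 12
    hits <- data.frame(
      enhancer = "e",
      family = sample(c("FOX", "ETS"), n, replace = TRUE),
      start = sample.int(300, n), strand = sample(c("+", "-"), n, TRUE),
      tier = NA, composite_member = FALSE, stringsAsFactors = FALSE)
    hits$end <- hits$start + ifelse(hits$family == "FOX", 7L, 6L)
    hits$matched_sequence <- ""
    got <- detect_composite_fox_ets(hits, window = 2)
    want <- rep(FALSE, n)
    for (i in which(hits$family == "FOX")) {
      for (j in which(hits$family == "ETS")) {
        if (hits$strand[i] != hits$strand[j]) next
        gap <- if (hits$strand[i] == "+") hits$start[j] - hits$end[i]
               else hits$start[i] - hits$end[j]
        if (gap >= 0 && gap <= 2) want[c(i, j)] <- TRUE
      }
    }
    expect_identical(got$composite_member, want)
  }
})

make_profile <- function(core, rows) {
  alignment_profile(c(mouse = core, rows))
}

test_that("conservation tiers follow the depth rule", {
  #             0123456789
  core <- "TTTTGGGAATTTT"   # RBPJ TGGGAA at [3,9)
  hit <- scan_consensus(core, "TGGGAA", family = "RBPJ")
  expect_equal(hit$start, 3)
  # conserved to full depth: every aligning species keeps the motif
  p_strong <- make_profile(core, c(human = "TTATGGGAATTAT",
                                   dog = "ATTTGGGAATATT",
                                   chicken = "TATTGGGAATTTA"))
  expect_equal(classify_conservation_tier(hit, p_strong, "TGGGAA"), "strong")
  # human keeps it, dog aligns but lost it -> weak
  p_weak <- make_profile(core, c(human = "TTATGGGAATTAT",
                                 dog = "ATTTGCGAATATT"))
  expect_equal(classify_conservation_tier(hit, p_weak, "TGGGAA"), "weak")
  # human row lost the motif -> none, whatever the others do
  p_none <- make_profile(core, c(human = "TTATGCGAATTAT",
                                 dog = "ATTTGGGAATATT"))
  expect_equal(classify_conservation_tier(hit, p_none, "TGGGAA"), "none")
  # gaps in the human motif columns fail the match
  p_gap <- make_profile(core, c(human = "TTAT--GAATTAT"))
  expect_equal(classify_conservation_tier(hit, p_gap, "TGGGAA"), "none")
  # no human row at all -> none
  p_solo <- alignment_profile(c(mouse = core))
  expect_equal(classify_conservation_tier(hit, p_solo, "TGGGAA"), "none")
  # a species mostly gapped does not count toward the depth
  p_shallow <- make_profile(core, c(human = "TTATGGGAATTAT",
                                    dog = "-----------TT"))
  expect_equal(classify_conservation_tier(hit, p_shallow, "TGGGAA"),
               "strong")
})

test_that("tier classification is monotone in the matching species set", {
  # upgrading one aligning species from mismatch to match never downgrades
  core <- "TTTTGGGAATTTT"
  hit <- scan_consensus(core, "TGGGAA", family = "RBPJ")
  rank <- c(none = 0, weak = 1, strong = 2)
  match_row <- "ATATGGGAATATA"; mismatch_row <- "ATATGCGAATATA"
  set.seed(3)
  others <- c("dog", "cow", "opossum")
  for (i in 1:20) {
    human_match <- sample(c(TRUE, FALSE), 1)
    state <- sample(c(TRUE, FALSE), 3, replace = TRUE)
    build <- function(hm, st) {
      rows <- c(human = if (hm) match_row else mismatch_row,
                setNames(ifelse(st, match_row, mismatch_row), others))
      make_profile(core, rows)
    }
    base <- classify_conservation_tier(hit, build(human_match, state),
                                       "TGGGAA")
    flip <- which(!state)
    if (length(flip)) {
      state2 <- state; state2[sample(flip, 1)] <- TRUE
      up <- classify_conservation_tier(hit, build(human_match, state2),
                                       "TGGGAA")
      expect_gte(rank[[up]], rank[[base]])
    }
    down <- classify_conservation_tier(hit, build(FALSE, state), "TGGGAA")
    expect_lte(rank[[down]], rank[[base]])
  }
})

test_that("per-enhancer status takes M over m and sets aside composites", {
  hits <- rbind(
    data.frame(enhancer = "e", family = "ETS", start = c(1, 20, 40),
               end = c(7, 26, 46), strand = "+", matched_sequence = "x",
               tier = c("strong", "weak", "weak"),
               composite_member = FALSE),
    data.frame(enhancer = "e", family = "FOX", start = 60, end = 67,
               strand = "+", matched_sequence = "x", tier = "strong",
               composite_member = TRUE))
  st <- summarize_motifs_per_enhancer(hits)
  expect_equal(st$status[st$family == "ETS"], "M")
  # the only FOX hit is a composite member: independent FOX absent
  expect_equal(st$status[st$family == "FOX"], "absent")
  expect_equal(st$status[st$family == "FOX:ETS"], "M")
  # no hits at all
  st0 <- summarize_motifs_per_enhancer(hits[0, ], families = c("ETS"))
  expect_equal(st0$status, "absent")
})
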