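status_long <- function(statuses, family = "MEF2") {
  data.frame(enhancer = names(statuses), family = family,
             status = unname(statuses), stringsAsFactors = FALSE)
}

test_that("status tabulation counts (k, n) per family and class", {
  classes <- setNames(rep(c("arterial", "pan_EC"), c(23, 13)),
                      paste0("e", 1:36))
  # all 23 arterial enhancers with strong ETS motifs
  st <- status_long(setNames(rep(c("M", "absent"), c(23, 13)),
                             names(classes)), "ETS")
  tab <- tabulate_status(st, classes, status_set = "M")
  expect_equal(tab$k["ETS", "arterial"], 23L)
  expect_equal(tab$n["ETS", "arterial"], 23L)
  expect_equal(tab$k["ETS", "pan_EC"], 0L)
  # 9/23 arterial vs 1/13 pan-EC with conserved MEF2 motifs, {M, m}
  mef2 <- setNames(c(rep("M", 8), "m", rep("absent", 14),
                     "m", rep("absent", 12)), names(classes))
  tab2 <- tabulate_status(status_long(mef2), classes,
                          status_set = c("M", "m"))
  expect_equal(tab2$k["MEF2", "arterial"], 9L)
  expect_equal(tab2$k["MEF2", "pan_EC"], 1L)
  # {M, m} dominates {M} cell-wise
  tabM <- tabulate_status(status_long(mef2), classes, status_set = "M")
  expect_true(all(tab2$k >= tabM$k))
  # unlabelled enhancer errors
  expect_error(tabulate_status(status_long(c(zz = "M")), classes, "M"),
               "zz")
})

test_that("enrichment contrast matches exhaustive hypergeometric sums", {
  classes <- setNames(rep(c("arterial", "pan_EC"), c(23, 13)),
                      paste0("e", 1:36))
  mef2 <- setNames(c(rep("M", 9), rep("absent", 14),
                     "M", rep("absent", 12)), names(classes))
  tab <- tabulate_status(status_long(mef2), classes, status_set = c("M", "m"))
  out <- enrichment_contrast(tab, "MEF2", "arterial", "pan_EC")
  expect_gt(out$odds_ratio, 1)   # arterial-skewed
  # oracle: sum of all equally-or-less-probable 2x2 tables
  k <- 9; n_a <- 23; kb <- 1; n_b <- 13
  total_pos <- k + kb
  support <- max(0, total_pos - n_b):min(n_a, total_pos)
  probs <- dhyper(support, n_a, n_b, total_pos)
  p_oracle <- sum(probs[probs <= dhyper(k, n_a, n_b, total_pos) * (1 + 1e-7)])
  expect_equal(out$p_value, p_oracle, tolerance = 1e-10)
})

test_that("degenerate contrasts behave as expected", {
  classes <- setNames(rep(c("a", "b"), c(10, 10)), paste0("e", 1:20))
  # identical fractions -> odds ratio 1
  st <- status_long(setNames(rep(c("M", "absent"), 10), names(classes)))
  tab <- tabulate_status(st, classes, "M")
  out <- enrichment_contrast(tab, "MEF2", "a", "b")
  expect_equal(out$odds_ratio, 1)
  # zero positives on both sides -> p = 1 (Haldane-corrected OR finite)
  st0 <- status_long(setNames(rep("absent", 20), names(classes)))
  tab0 <- tabulate_status(st0, classes, "M")
  out0 <- enrichment_contrast(tab0, "MEF2", "a", "b")
  expect_equal(out0$p_value, 1)
  expect_true(is.finite(out0$odds_ratio))
})

test_that("concordance reproduces the in vivo vs in silico tabulation", {
  tab <- read_assay_counts(fixture_path("transgenesis_assay.tsv"))
  validated <- tab[tab$in_vivo_class == "arterial" &
                   tab$cohort == "novel" & !is.na(tab$n_injected), ]
  expect_equal(nrow(validated), 15)
  cc <- concordance(validated)
  expect_equal(cc$counts["arterial", "Arterial enhancer"], 3L)
  expect_equal(cc$counts["arterial", "Common EC enhancer"], 5L)
  expect_equal(sum(cc$counts["arterial", c("Arterial TSS",
                                           "Common EC TSS")]), 4L)
  expect_equal(cc$counts["arterial", "Uncalled"], 3L)
  expect_equal(unname(cc$row_totals["arterial"]), 15L)
  published <- tab[tab$in_vivo_class == "arterial" &
                   tab$cohort == "published", ]
  cp <- concordance(published)
  expect_equal(cp$counts["arterial", "Common EC enhancer"], 7L)
  expect_equal(unname(cp$row_totals["arterial"]), 8L)
  # single record gives a 1x1 table
  one <- concordance(validated[1, ])
  expect_equal(dim(one$counts), c(1L, 1L))
  # missing labels error with the record name
  broken <- validated
  broken$in_silico_class[2] <- NA
  expect_error(concordance(broken), broken$name[2], fixed = TRUE)
})

test_that("tables are invariant under permuting the input order", {
  tab <- read_assay_counts(fixture_path("transgenesis_assay.tsv"))
  validated <- tab[tab$in_vivo_class == "arterial" &
                   tab$cohort == "novel" & !is.na(tab$n_injected), ]
  set.seed(61)
  shuffled <- validated[sample(nrow(validated)), ]
  expect_equal(concordance(validated)$counts, concordance(shuffled)$counts)
})

test_that("the status grid renders M/m and C/c symbols", {
  ms <- data.frame(enhancer = c("e1", "e1", "e2"),
                   family = c("ETS", "SOX", "ETS"),
                   status = c("M", "m", "absent"))
  bs <- data.frame(enhancer = c("e1", "e2"), family = c("ETS", "ETS"),
                   status = c("C", "c"))
  g <- render_status_grid(ms, bs)
  expect_equal(g["e1", "ETS"], "MC")
  expect_equal(g["e1", "SOX"], "m")
  expect_equal(g["e2", "ETS"], "c")
})
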