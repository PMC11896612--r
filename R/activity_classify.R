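# Activity classification of mosaic transgenic reporter assays.
# An enhancer is active when GFP appears in vascular endothelium of
# strictly more than 5% of injected embryos; weak activity (faint GFP or
# GFP limited to a few endothelial cells) is a qualitative input flag, not
# a computed quantity.

#' Read a transgenesis assay-count table
#'
#' Tab-separated with header; required columns `name`, `n_injected`,
#' `n_gfp_positive`; optional `weak_flag` (logical), `pattern_label`,
#' `in_vivo_class`, `in_silico_class`, `cohort`. Rows with `NA` counts
#' (assays reported only in earlier publications) are retained; they are
#' skipped by [cohort_activity_summary()].
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_assay_counts <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "n_injected", "n_gfp_positive")
  if (!all(need %in% names(tab))) {
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$weak_flag)) tab$weak_flag <- FALSE
  tab$weak_flag[is.na(tab$weak_flag)] <- FALSE
  has <- !is.na(tab$n_injected)
  if (any(has & tab$n_injected <= 0)) stop("n_injected must be positive")
  if (any(has & (tab$n_gfp_positive > tab$n_injected), na.rm = TRUE)) {
    stop("n_gfp_positive exceeds n_injected for: ",
         tab$name[which(has & tab$n_gfp_positive > tab$n_injected)[1L]])
  }
  tab
}

#' Classify one assay outcome
#'
#' Active iff `n_gfp_positive / n_injected > threshold` (strict: exactly
#' the threshold is inactive). Active assays split into `active_weak` when
#' the qualitative weak flag is set, `active_strong` otherwise.
#'
#' @param n_injected Number of injected embryos (positive).
#' @param n_gfp_positive Number showing vascular GFP (0..n_injected).
#' @param weak_flag Qualitative weak-expression flag.
#' @param threshold Activity threshold on the positive fraction
#'   (default 0.05).
#' @param name Enhancer name recorded on the call.
#' @return A list of class `activity_call`: `enhancer`,
#'   `fraction_positive`, `decision` in
#'   `{active_strong, active_weak, inactive}`.
#' @export
classify_activity <- function(n_injected, n_gfp_positive, weak_flag = FALSE,
                              threshold = 0.05, name = NA_character_) {
  if (is.na(n_injected) || n_injected <= 0) {
    stop("n_injected must be a positive count")
  }
  stopifnot(n_gfp_positive >= 0, n_gfp_positive <= n_injected,
            threshold > 0, threshold < 1)
  frac <- n_gfp_positive / n_injected
  decision <- if (frac > threshold) {
    if (isTRUE(weak_flag)) "active_weak" else "active_strong"
  } else "inactive"
  structure(list(enhancer = name, fraction_positive = frac,
                 decision = decision),
            class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  cat(sprintf("<activity_call> %s: %.1f%% GFP-positive -> %s\n",
              x$enhancer %||% "?", 100 * x$fraction_positive, x$decision))
  invisible(x)
}

#' Summarize activity calls over an assay cohort
#'
#' Applies [classify_activity()] to every row with printed counts and
#' tallies active (strong + weak), strong-active, and inactive regions.
#'
#' @param counts Assay-count data.frame ([read_assay_counts()]).
#' @param threshold Activity threshold (default 0.05).
#' @return A list of class `activity_summary`: `n_assayed`, `n_active`,
#'   `n_active_strong`, `n_active_weak`, `n_inactive`, and `calls`, a
#'   data.frame of per-enhancer decisions.
#' @export
cohort_activity_summary <- function(counts, threshold = 0.05) {
  counts <- counts[!is.na(counts$n_injected), , drop = FALSE]
  calls <- if (nrow(counts) == 0L) {
    data.frame(enhancer = character(), fraction_positive = numeric(),
               decision = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
      ac <- classify_activity(counts$n_injected[i], counts$n_gfp_positive[i],
                              counts$weak_flag[i], threshold,
                              name = counts$name[i])
      data.frame(enhancer = ac$enhancer,
                 fraction_positive = ac$fraction_positive,
                 decision = ac$decision, stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    n_assayed = nrow(calls),
    n_active = sum(calls$decision != "inactive"),
    n_active_strong = sum(calls$decision == "active_strong"),
    n_active_weak = sum(calls$decision == "active_weak"),
    n_inactive = sum(calls$decision == "inactive"),
    threshold = threshold,
    calls = calls
  ), class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf(paste0("<activity_summary> %d assayed: %d active ",
                     "(%d strong, %d weak), %d inactive (threshold %.0f%%)\n"),
              x$n_assayed, x$n_active, x$n_active_strong, x$n_active_weak,
              x$n_inactive, 100 * x$threshold))
  invisible(x)
}
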