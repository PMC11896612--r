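# Peak-based binding calls and peak-set co-occupancy statistics.
# Overlap everywhere means >= 1 bp intersection; peak spans are used as-is
# (no summit extension, no reciprocal-overlap requirement).

#' Construct a peak set
#'
#' @param tf_name Transcription factor name (e.g. `"SOX17"`).
#' @param intervals `GRanges` of called peaks.
#' @param source_id Free-text provenance label.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(tf_name, intervals, source_id = tf_name) {
  stopifnot(is.character(tf_name), length(tf_name) == 1L,
            methods::is(intervals, "GRanges"))
  structure(list(tf_name = tf_name, source_id = source_id,
                 intervals = GenomicRanges::sort(intervals)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s (%s): %d peaks\n",
              x$tf_name, x$source_id, length(x$intervals)))
  invisible(x)
}

#' Call transcription-factor binding at an enhancer
#'
#' An enhancer is bound when its interval overlaps any peak by at least
#' 1 bp. Bound enhancers receive status `"C"` when the factor's family has
#' any motif in the enhancer (strong `M` or weak `m` — a weak motif still
#' corresponds), `"c"` when bound without a corresponding motif, and
#' `"unbound"` otherwise regardless of motif content.
#'
#' @param enhancer `GRanges` of length 1 (the enhancer span).
#' @param peaks A [peak_set()] on the same assembly.
#' @param motif_status `"M"`, `"m"` or `"absent"` for the matching family
#'   (from [summarize_motifs_per_enhancer()]).
#' @param enhancer_name Name recorded on the call.
#' @return A data.frame row of class `binding_call`: `enhancer`, `tf`,
#'   `status`.
#' @export
call_binding <- function(enhancer, peaks, motif_status,
                         enhancer_name = names(enhancer) %||% NA_character_) {
  stopifnot(methods::is(enhancer, "GRanges"), length(enhancer) == 1L,
            inherits(peaks, "peak_set"),
            motif_status %in% c("M", "m", "absent"))
  bound <- length(GenomicRanges::findOverlaps(enhancer, peaks$intervals)) > 0L
  status <- if (!bound) "unbound" else if (motif_status %in% c("M", "m")) "C" else "c"
  out <- data.frame(enhancer = enhancer_name %||% NA_character_,
                    tf = peaks$tf_name, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("binding_call", "data.frame")
  out
}

#' Co-occupancy of a reference peak set with query peak sets
#'
#' For each query set, the fraction of reference peaks overlapped by at
#' least one query peak; additionally the fraction overlapped by the union
#' of all query sets, and by every query set jointly. By construction the
#' union fraction is at least each individual fraction and the joint
#' fraction at most each.
#'
#' @param reference A nonempty [peak_set()].
#' @param queries Named list of [peak_set()] objects.
#' @return A list of class `cooccupancy_stats`: `reference`, `n_reference`,
#'   `per_query` (named fractions), `union_fraction`, `joint_fraction`.
#'   Fractions are exact; round for display.
#' @export
peakset_overlap_fraction <- function(reference, queries) {
  stopifnot(inherits(reference, "peak_set"))
  if (length(reference$intervals) == 0L) stop("reference peak set is empty")
  if (!is.list(queries)) queries <- list(queries)
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- vapply(queries, `[[`, "", "tf_name")
  }
  n <- length(reference$intervals)
  hit_mat <- vapply(queries, function(q) {
    GenomicRanges::countOverlaps(reference$intervals, q$intervals) > 0L
  }, logical(n))
  hit_mat <- matrix(hit_mat, nrow = n)
  colnames(hit_mat) <- names(queries)
  out <- list(
    reference = reference$tf_name,
    n_reference = n,
    per_query = colMeans(hit_mat),
    union_fraction = mean(rowSums(hit_mat) >= 1L),
    joint_fraction = mean(rowSums(hit_mat) == ncol(hit_mat))
  )
  class(out) <- "cooccupancy_stats"
  out
}

#' @export
print.cooccupancy_stats <- function(x, ...) {
  cat(sprintf("<cooccupancy_stats> reference %s (%d peaks)\n",
              x$reference, x$n_reference))
  for (q in names(x$per_query)) {
    cat(sprintf("  %-12s %5.1f%%\n", q, 100 * x$per_query[[q]]))
  }
  cat(sprintf("  %-12s %5.1f%%\n  %-12s %5.1f%%\n",
              "any (union)", 100 * x$union_fraction,
              "all (joint)", 100 * x$joint_fraction))
  invisible(x)
}

#' Fraction of reference peaks overlapping an annotation
#'
#' E.g. the fraction of SOX17 peaks falling in endothelial
#' enhancer/promoter mark regions.
#'
#' @param reference A nonempty [peak_set()].
#' @param annotation `GRanges` of annotation intervals.
#' @return The overlap fraction in `[0, 1]`.
#' @export
annotation_overlap <- function(reference, annotation) {
  stopifnot(inherits(reference, "peak_set"),
            methods::is(annotation, "GRanges"))
  if (length(reference$intervals) == 0L) stop("reference peak set is empty")
  mean(GenomicRanges::countOverlaps(reference$intervals, annotation) > 0L)
}
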