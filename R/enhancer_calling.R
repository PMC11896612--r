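# Candidate construction and the cross-species putative-enhancer call.
#
# Evidence comes from five kinds of mark dataset in the reference analysis:
# open chromatin (ATAC-seq in mouse aortic and retinal ECs, DNaseI
# hypersensitivity in human ECs), EP300 binding (mouse E11.5 endothelium),
# and enhancer-associated histone modification (H3K27Ac/H3K4Me1, HUVEC).
# The decision rule needs only (dataset, species, overlap) triples, so
# datasets are configured in a manifest and the rule is dataset-agnostic.

#' Construct a mark track
#'
#' Bundles a mark dataset's intervals with its identity and species.
#' Intervals may carry a logical `ec_specific` metadata column; marks whose
#' enrichment extends to many non-endothelial cell types should be flagged
#' `FALSE` — they still count as evidence but the flag is propagated.
#'
#' @param dataset_id Unique dataset label, e.g. `"M_artery_ATAC"`.
#' @param species `"mouse"` or `"human"`.
#' @param intervals `GRanges` of mark intervals.
#' @param ec_specific Default specificity for intervals lacking their own
#'   `ec_specific` metadata column.
#' @return An object of class `mark_track`.
#' @export
mark_track <- function(dataset_id, species, intervals, ec_specific = TRUE) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L,
            species %in% c("mouse", "human"),
            methods::is(intervals, "GRanges"))
  if (is.null(S4Vectors::mcols(intervals)$ec_specific)) {
    S4Vectors::mcols(intervals)$ec_specific <- rep(ec_specific, length(intervals))
  }
  structure(list(dataset_id = dataset_id, species = species,
                 intervals = intervals),
            class = "mark_track")
}

#' @export
print.mark_track <- function(x, ...) {
  cat(sprintf("<mark_track> %s (%s): %d intervals\n",
              x$dataset_id, x$species, length(x$intervals)))
  invisible(x)
}

#' Build candidate regions from mark tracks over a locus
#'
#' A deterministic surrogate for by-eye region selection: the union of all
#' mark intervals intersecting the locus, with intervals closer than
#' `merge_gap` fused into one region. Regions are returned sorted by start.
#'
#' @param tracks List of [mark_track()] objects, all from one species.
#' @param locus `GRanges` of length 1 delimiting the locus.
#' @param merge_gap Maximum gap (bp) across which adjacent marks are fused;
#'   default 500.
#' @return `GRanges` of candidate regions.
#' @export
build_candidate_regions <- function(tracks, locus, merge_gap = 500) {
  stopifnot(methods::is(locus, "GRanges"), length(locus) == 1L)
  sp <- unique(vapply(tracks, `[[`, "", "species"))
  if (length(sp) > 1L) {
    stop("candidate construction mixes species/assemblies: ",
         paste(sp, collapse = ", "))
  }
  all_marks <- unlist(GenomicRanges::GRangesList(
    lapply(tracks, function(t) GenomicRanges::granges(t$intervals))))
  hits <- GenomicRanges::findOverlaps(all_marks, locus)
  inside <- all_marks[S4Vectors::queryHits(hits)]
  if (length(inside) == 0L) return(empty_granges())
  GenomicRanges::sort(GenomicRanges::reduce(inside, min.gapwidth = merge_gap + 1L))
}

#' Collect per-dataset mark evidence for a region
#'
#' For each configured dataset, records whether the region overlaps (by at
#' least `min_overlap` bp) any mark interval. The region is given in mouse
#' coordinates; human tracks are queried through the orthology block map,
#' and when the region is unmappable every human dataset records `FALSE`
#' with an `"unmapped"` note. A dataset whose only overlapping marks are
#' flagged non-EC-specific records `TRUE` but carries `nonspecific = TRUE`.
#'
#' @param region `GRanges` of length 1, mouse assembly.
#' @param tracks List of [mark_track()] objects (both species).
#' @param orthology Orthology block map ([read_orthology()]), used for
#'   human tracks; may be `NULL` when no human tracks are supplied.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return A data.frame of class `mark_evidence` with one row per dataset:
#'   `dataset_id`, `species`, `present`, `nonspecific`, `note`.
#' @export
collect_mark_evidence <- function(region, tracks, orthology = NULL,
                                  min_overlap = 1L) {
  stopifnot(methods::is(region, "GRanges"), length(region) == 1L)
  rows <- lapply(tracks, function(t) {
    query <- region
    note <- ""
    if (t$species == "human") {
      query <- if (is.null(orthology)) NULL else map_via_orthology(region, orthology)
      if (is.null(query)) {
        return(data.frame(dataset_id = t$dataset_id, species = t$species,
                          present = FALSE, nonspecific = FALSE,
                          note = "unmapped", stringsAsFactors = FALSE))
      }
    }
    # disjoint seqlevels (a region's sequence absent from a track) are a
    # legitimate no-overlap case, not worth a GenomeInfoDb warning
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(query, t$intervals,
                                  minoverlap = min_overlap))
    hit_marks <- unique(S4Vectors::subjectHits(ov))
    present <- length(hit_marks) > 0L
    spec <- S4Vectors::mcols(t$intervals)$ec_specific
    nonspecific <- present && !any(spec[hit_marks])
    data.frame(dataset_id = t$dataset_id, species = t$species,
               present = present, nonspecific = nonspecific,
               note = note, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  class(ev) <- c("mark_evidence", "data.frame")
  ev
}

#' Call a region putative under the cross-species evidence rule
#'
#' For a gene robustly transcribed in the human EC datasets, a putative
#' enhancer is a region with at least one enhancer mark in both mouse and
#' human ECs. For genes poorly transcribed in the human cell lines
#' (`transcribed_human = FALSE`) the definition is relaxed: at least two
#' mouse datasets must carry a mark.
#'
#' @param evidence A `mark_evidence` data.frame from
#'   [collect_mark_evidence()] (or any data.frame with `species` and
#'   `present` columns covering all configured datasets).
#' @param transcribed_human Is the neighbouring gene transcribed in the
#'   human datasets (open chromatin/H3K4Me3 at the promoter)?
#' @return A list of class `putative_call`: `decision` (`"putative"` or
#'   `"below_threshold"`), `rule_used` (`"both_species"` or
#'   `"mouse_only_relaxed"`), and the tallies `n_mouse`, `n_human`.
#' @export
call_putative <- function(evidence, transcribed_human) {
  stopifnot(is.data.frame(evidence),
            all(c("species", "present") %in% names(evidence)),
            is.logical(transcribed_human), length(transcribed_human) == 1L)
  n_mouse <- sum(evidence$present[evidence$species == "mouse"])
  n_human <- sum(evidence$present[evidence$species == "human"])
  if (transcribed_human) {
    decision <- if (n_mouse >= 1L && n_human >= 1L) "putative" else "below_threshold"
    rule <- "both_species"
  } else {
    decision <- if (n_mouse >= 2L) "putative" else "below_threshold"
    rule <- "mouse_only_relaxed"
  }
  structure(list(decision = decision, rule_used = rule,
                 n_mouse = n_mouse, n_human = n_human),
            class = "putative_call")
}

#' @export
print.putative_call <- function(x, ...) {
  cat(sprintf("<putative_call> %s (rule %s; mouse marks %d, human marks %d)\n",
              x$decision, x$rule_used, x$n_mouse, x$n_human))
  invisible(x)
}

#' Read a mark-evidence matrix for known enhancers
#'
#' Tab-separated with header: a `name` column, one logical/Yes-No column
#' per dataset, and optional annotation columns. Dataset columns and their
#' species are declared by `datasets`, a named character vector mapping
#' column name to `"mouse"`/`"human"`.
#'
#' @param path Path to the TSV.
#' @param datasets Named character vector: `c(col = "human", ...)`.
#' @return A data.frame; dataset columns coerced to logical, with
#'   attribute `datasets` retained.
#' @export
read_mark_matrix <- function(path, datasets) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("name", names(datasets)), names(tab))
  if (length(missing_cols)) {
    stop("mark matrix missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in names(datasets)) {
    v <- tab[[col]]
    if (!is.logical(v)) v <- toupper(trimws(v)) %in% c("YES", "TRUE", "1")
    tab[[col]] <- v
  }
  attr(tab, "datasets") <- datasets
  tab
}

#' Retrospective mark aggregation over known enhancers
#'
#' Given a per-enhancer evidence matrix (one logical column per dataset,
#' species declared per dataset), tallies how many enhancers carry at
#' least one mark in both species, plus per-dataset positive counts. When
#' `class_col`/`class_value` are supplied the same tallies are also
#' reported restricted to that class (e.g. the published arterial
#' enhancers).
#'
#' @param marks Data.frame from [read_mark_matrix()], or any data.frame
#'   with a `name` column and the dataset columns.
#' @param datasets Named character vector mapping dataset column to
#'   species; defaults to the `datasets` attribute of `marks`.
#' @param class_col,class_value Optional column/value restricting the
#'   secondary tally.
#' @return A list of class `mark_summary`: `n_total`,
#'   `n_with_mark_both_species`, `per_dataset` (named integer vector),
#'   and, when a class is given, `class_n_total` and
#'   `class_n_with_mark_both_species`.
#' @export
retrospective_mark_summary <- function(marks, datasets = attr(marks, "datasets"),
                                       class_col = NULL, class_value = NULL) {
  if (is.null(datasets)) stop("dataset->species mapping required")
  miss <- setdiff(names(datasets), names(marks))
  if (length(miss)) stop("evidence missing for dataset(s): ",
                         paste(miss, collapse = ", "),
                         if ("name" %in% names(marks) && nrow(marks))
                           paste0(" (first record: ", marks$name[1L], ")") else "")
  na_rows <- which(rowSums(is.na(marks[names(datasets)])) > 0)
  if (length(na_rows)) {
    stop("incomplete evidence for record: ",
         if ("name" %in% names(marks)) marks$name[na_rows[1L]] else na_rows[1L])
  }
  mouse_cols <- names(datasets)[datasets == "mouse"]
  human_cols <- names(datasets)[datasets == "human"]
  both <- function(tab) {
    if (nrow(tab) == 0L) return(0L)
    sum(rowSums(tab[, mouse_cols, drop = FALSE]) >= 1 &
        rowSums(tab[, human_cols, drop = FALSE]) >= 1)
  }
  out <- list(
    n_total = nrow(marks),
    n_with_mark_both_species = both(marks),
    per_dataset = vapply(names(datasets), function(cl) sum(marks[[cl]]), 0L)
  )
  if (!is.null(class_col)) {
    sub <- marks[!is.na(marks[[class_col]]) & marks[[class_col]] == class_value, ,
                 drop = FALSE]
    out$class_value <- class_value
    out$class_n_total <- nrow(sub)
    out$class_n_with_mark_both_species <- both(sub)
  }
  class(out) <- "mark_summary"
  out
}

#' @export
print.mark_summary <- function(x, ...) {
  cat(sprintf("<mark_summary> %d/%d enhancers with >=1 mark in both species\n",
              x$n_with_mark_both_species, x$n_total))
  if (!is.null(x$class_n_total)) {
    cat(sprintf("  class '%s': %d/%d\n", x$class_value,
                x$class_n_with_mark_both_species, x$class_n_total))
  }
  invisible(x)
}
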