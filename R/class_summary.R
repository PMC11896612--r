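# Class-wise cross-tabulation of motif/binding status, exact enrichment
# contrasts between enhancer classes, and the in vivo vs in silico
# concordance table.

#' Tabulate per-family status counts by enhancer class
#'
#' Cell (family, class) holds `(k, n)`: the number of enhancers of that
#' class whose status lies in `status_set`, over the class size. Use
#' `status_set = "M"` for strongly conserved motifs only, `c("M", "m")`
#' for any conserved motif, `"C"` or `c("C", "c")` for binding calls.
#'
#' @param status Long-format data.frame with columns `enhancer`, `family`,
#'   `status` (rows may be motif statuses `M`/`m`/`absent` or binding
#'   statuses `C`/`c`/`unbound`).
#' @param classes Named character vector mapping enhancer name to class
#'   label (e.g. `arterial`, `pan_EC`, `venous`).
#' @param status_set Statuses counting as positive.
#' @return A list of class `status_table` with `k` and `n` integer
#'   matrices (rows = families, columns = classes).
#' @export
tabulate_status <- function(status, classes, status_set = "M") {
  stopifnot(all(c("enhancer", "family", "status") %in% names(status)))
  unknown <- setdiff(unique(status$enhancer), names(classes))
  if (length(unknown)) {
    stop("no class label for enhancer: ", unknown[1L])
  }
  families <- sort(unique(status$family))
  class_levels <- sort(unique(unname(classes)))
  class_sizes <- table(factor(unname(classes), levels = class_levels))
  k <- matrix(0L, length(families), length(class_levels),
              dimnames = list(families, class_levels))
  n <- matrix(as.integer(class_sizes), length(families), length(class_levels),
              byrow = TRUE, dimnames = dimnames(k))
  for (f in families) {
    sub <- status[status$family == f, , drop = FALSE]
    dup <- sub$enhancer[duplicated(sub$enhancer)]
    if (length(dup)) {
      stop("multiple status rows for enhancer '", dup[1L],
           "', family '", f, "'")
    }
    # a family absent from an enhancer's rows counts as status "absent"
    pos <- sub$enhancer[sub$status %in% status_set]
    tab <- table(factor(classes[pos], levels = class_levels))
    k[f, ] <- as.integer(tab)
  }
  structure(list(k = k, n = n, status_set = status_set),
            class = "status_table")
}

#' @export
print.status_table <- function(x, ...) {
  cat(sprintf("<status_table> status in {%s}\n",
              paste(x$status_set, collapse = ", ")))
  disp <- matrix(sprintf("%d/%d", x$k, x$n), nrow = nrow(x$k),
                 dimnames = dimnames(x$k))
  print(as.data.frame(disp))
  invisible(x)
}

#' Exact enrichment contrast between two enhancer classes
#'
#' Compares the positive fraction of one family between two classes with a
#' two-sided exact (hypergeometric) test on the 2x2 table
#' `(k_a, n_a - k_a; k_b, n_b - k_b)` — two-sided by summation of tables
#' with probability no greater than the observed one. The odds ratio is
#' the sample odds ratio, with a Haldane correction of 0.5 added to every
#' cell when any cell is zero. The underlying study reports raw fractions
#' only; this test is an extension and is labelled as such in reports.
#'
#' @param table A [tabulate_status()] result.
#' @param family Family (row) to contrast.
#' @param class_a,class_b Class (column) labels.
#' @return A list: `k_a`, `n_a`, `k_b`, `n_b`, `odds_ratio`, `p_value`,
#'   `note`.
#' @export
enrichment_contrast <- function(table, family, class_a, class_b) {
  stopifnot(inherits(table, "status_table"))
  k_a <- table$k[family, class_a]; n_a <- table$n[family, class_a]
  k_b <- table$k[family, class_b]; n_b <- table$n[family, class_b]
  if (n_a == 0L || n_b == 0L) stop("empty class in contrast: ",
                                   if (n_a == 0L) class_a else class_b)
  m <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), 2L, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  or <- if (any(m == 0L)) {
    ((m[1, 1] + 0.5) * (m[2, 2] + 0.5)) / ((m[1, 2] + 0.5) * (m[2, 1] + 0.5))
  } else {
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  }
  list(family = family, class_a = class_a, class_b = class_b,
       k_a = k_a, n_a = n_a, k_b = k_b, n_b = n_b,
       odds_ratio = or, p_value = p,
       note = "exact test is an extension; the source analysis reports raw fractions")
}

#' Concordance of in vivo activity classes with in silico labels
#'
#' Full contingency table of the in vivo classification (from the
#' transgenic assay) against the in silico label (from relative
#' enhancer/promoter marks in arterial vs venous ECs), with marginals.
#'
#' @param records Data.frame with columns `name`, `in_vivo_class`,
#'   `in_silico_class`.
#' @return A list of class `concordance_table`: `counts` (matrix, rows =
#'   in vivo classes, columns = in silico labels), `row_totals`,
#'   `col_totals`.
#' @export
concordance <- function(records) {
  need <- c("name", "in_vivo_class", "in_silico_class")
  stopifnot(all(need %in% names(records)))
  bad <- which(is.na(records$in_vivo_class) | is.na(records$in_silico_class) |
               !nzchar(records$in_vivo_class) | !nzchar(records$in_silico_class))
  if (length(bad)) {
    stop("missing class label for enhancer: ", records$name[bad[1L]])
  }
  counts <- table(records$in_vivo_class, records$in_silico_class)
  counts <- unclass(counts)
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table> in vivo (rows) x in silico (columns)\n")
  print(x$counts)
  invisible(x)
}

#' Render the per-enhancer motif/binding grid as plain text
#'
#' Mirrors the compact status grid used in figure summaries: one row per
#' enhancer, one column per family, `M`/`m` for strong/weak motifs and
#' `C`/`c` appended for binding with/without a corresponding motif.
#'
#' @param motif_status Long data.frame `enhancer`, `family`, `status`
#'   (`M`/`m`/`absent`).
#' @param binding_status Optional long data.frame `enhancer`, `family`,
#'   `status` (`C`/`c`/`unbound`).
#' @return A character matrix (enhancers x families).
#' @export
render_status_grid <- function(motif_status, binding_status = NULL) {
  enh <- sort(unique(motif_status$enhancer))
  fam <- sort(unique(motif_status$family))
  grid <- matrix("", length(enh), length(fam), dimnames = list(enh, fam))
  for (i in seq_len(nrow(motif_status))) {
    s <- motif_status$status[i]
    if (s %in% c("M", "m")) {
      grid[motif_status$enhancer[i], motif_status$family[i]] <- s
    }
  }
  if (!is.null(binding_status)) {
    for (i in seq_len(nrow(binding_status))) {
      s <- binding_status$status[i]
      if (s %in% c("C", "c") &&
          binding_status$enhancer[i] %in% enh &&
          binding_status$family[i] %in% fam) {
        cur <- grid[binding_status$enhancer[i], binding_status$family[i]]
        grid[binding_status$enhancer[i], binding_status$family[i]] <-
          paste0(cur, s)
      }
    }
  }
  grid
}
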