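# Pipeline orchestration: a flat key-value run manifest, up-front
# validation that reports every problem at once, and a run-all driver
# executing call-enhancers -> scan-motifs -> call-binding ->
# classify-activity -> summarize, each stage writing TSVs with a
# provenance header and the run ending in a JSON report.

MANIFEST_KEYS <- c("loci", "marks_manifest", "orthology", "cores_fasta",
                   "alignments_dir", "motifs", "peaks_manifest",
                   "assay_counts", "enhancers", "outdir", "seed",
                   "merge_gap", "activity_threshold", "composite_window",
                   "coverage_threshold")

#' Read a flat key-value run manifest
#'
#' One `key<TAB>value` pair per line; `#` lines are comments. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return A named list of class `run_manifest` (paths resolved, numeric
#'   parameters coerced).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(kv) < 2L)
  if (length(bad)) stop("malformed manifest line ", bad[1L])
  m <- stats::setNames(lapply(kv, function(x) paste(x[-1L], collapse = "\t")),
                       vapply(kv, `[`, "", 1L))
  base <- dirname(normalizePath(path))
  for (k in c("loci", "marks_manifest", "orthology", "cores_fasta",
              "alignments_dir", "motifs", "peaks_manifest", "assay_counts",
              "enhancers", "outdir")) {
    if (!is.null(m[[k]]) && !grepl("^/", m[[k]])) {
      m[[k]] <- file.path(base, m[[k]])
    }
  }
  for (k in c("seed", "merge_gap", "activity_threshold", "composite_window",
              "coverage_threshold")) {
    if (!is.null(m[[k]])) m[[k]] <- as.numeric(m[[k]])
  }
  m$path <- path
  class(m) <- "run_manifest"
  m
}

#' Validate a run manifest
#'
#' Checks all required keys, referenced files, and parameter ranges, and
#' returns every finding at once rather than failing on the first.
#'
#' @param manifest A `run_manifest` ([read_manifest()]).
#' @return Character vector of findings; empty iff the manifest is
#'   runnable.
#' @export
validate_manifest <- function(manifest) {
  findings <- character()
  need <- c("loci", "marks_manifest", "assay_counts", "enhancers", "outdir")
  for (k in need) {
    if (is.null(manifest[[k]])) {
      findings <- c(findings, paste0("missing required key: ", k))
    }
  }
  for (k in c("loci", "marks_manifest", "orthology", "cores_fasta",
              "motifs", "peaks_manifest", "assay_counts", "enhancers")) {
    p <- manifest[[k]]
    if (!is.null(p) && !file.exists(p)) {
      findings <- c(findings, paste0("file not found for '", k, "': ", p))
    }
  }
  if (!is.null(manifest$alignments_dir) && !dir.exists(manifest$alignments_dir)) {
    findings <- c(findings, paste0("alignments_dir not found: ",
                                   manifest$alignments_dir))
  }
  for (k in c("activity_threshold", "coverage_threshold")) {
    v <- manifest[[k]]
    if (!is.null(v) && (is.na(v) || v <= 0 || v >= 1)) {
      findings <- c(findings, paste0("parameter '", k,
                                     "' outside (0, 1): ", v))
    }
  }
  for (k in c("merge_gap", "composite_window")) {
    v <- manifest[[k]]
    if (!is.null(v) && (is.na(v) || v < 0)) {
      findings <- c(findings, paste0("parameter '", k, "' negative: ", v))
    }
  }
  findings
}

#' Run the full pipeline from a manifest
#'
#' Executes, in order: candidate construction and the cross-species
#' putative call per locus; motif scanning with conservation tiers over
#' the enhancer cores; binding calls against the peak sets; activity
#' classification of the assay counts; and the class-wise summary with
#' the in vivo/in silico concordance table. Each stage writes a TSV with
#' a provenance comment header into `outdir`; a `report.json` aggregates
#' headline counts. Rerunning on unchanged inputs reproduces identical
#' outputs.
#'
#' @param manifest A `run_manifest` or path to one.
#' @param log Logging function for stage messages (default writes to
#'   `stderr`).
#' @return Invisibly, the report list.
#' @export
run_all <- function(manifest, log = function(...) message(...)) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  findings <- validate_manifest(manifest)
  if (length(findings)) {
    stop("manifest validation failed:\n  ",
         paste(findings, collapse = "\n  "))
  }
  outdir <- manifest$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance_header(manifest)
  report <- list()

  log("[call-enhancers] building candidates and calling putative enhancers")
  loci <- read.delim(manifest$loci, comment.char = "#",
                     stringsAsFactors = FALSE)
  mm <- read.delim(manifest$marks_manifest, comment.char = "#",
                   stringsAsFactors = FALSE)
  mdir <- dirname(manifest$marks_manifest)
  tracks <- lapply(seq_len(nrow(mm)), function(i) {
    p <- mm$path[i]
    if (!grepl("^/", p)) p <- file.path(mdir, p)
    mark_track(mm$dataset_id[i], mm$species[i], read_bed(p),
               ec_specific = isTRUE(mm$ec_specific[i]))
  })
  orthology <- if (!is.null(manifest$orthology)) {
    read_orthology(manifest$orthology)
  } else NULL
  merge_gap <- manifest$merge_gap %||% 500
  putative <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    locus <- GenomicRanges::GRanges(loci$seq_id[i],
               IRanges::IRanges(loci$start[i] + 1, loci$end[i]))
    mouse_tracks <- Filter(function(t) t$species == "mouse", tracks)
    cand <- build_candidate_regions(mouse_tracks, locus, merge_gap)
    if (length(cand) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(cand), function(j) {
      ev <- collect_mark_evidence(cand[j], tracks, orthology)
      call <- call_putative(ev, isTRUE(loci$transcribed_human[i]))
      out <- data.frame(
        gene = loci$gene[i],
        name = name_enhancer(loci$gene[i], loci$tss[i], loci$strand[i],
                             cand[j]),
        seq_id = loci$seq_id[i],
        start = GenomicRanges::start(cand[j]) - 1L,
        end = GenomicRanges::end(cand[j]),
        decision = call$decision, rule_used = call$rule_used,
        n_mouse = call$n_mouse, n_human = call$n_human,
        stringsAsFactors = FALSE)
      for (d in seq_len(nrow(ev))) out[[ev$dataset_id[d]]] <- ev$present[d]
      out
    }))
  }))
  if (is.null(putative)) {
    putative <- data.frame(gene = character(), name = character(),
                           seq_id = character(), start = integer(),
                           end = integer(), decision = character(),
                           rule_used = character(), n_mouse = integer(),
                           n_human = integer())
  }
  write_report_tsv(putative, file.path(outdir, "putative_calls.tsv"), prov)
  report$n_candidate_regions <- nrow(putative)
  report$n_putative <- sum(putative$decision == "putative")

  log("[scan-motifs] scanning enhancer cores and classifying tiers")
  motifs <- if (!is.null(manifest$motifs)) read_motifs(manifest$motifs)
            else default_motifs()
  motif_hits <- motif_hit_frame()
  motif_status <- data.frame(enhancer = character(), family = character(),
                             status = character(), stringsAsFactors = FALSE)
  if (!is.null(manifest$cores_fasta) && file.exists(manifest$cores_fasta) &&
      file.size(manifest$cores_fasta) > 0) {
    cores <- read_fasta(manifest$cores_fasta)
    cov <- manifest$coverage_threshold %||% 0.5
    for (n in names(cores)) {
      hits <- scan_core(as.character(cores[[n]]), motifs, enhancer = n)
      afa <- file.path(manifest$alignments_dir %||% "", paste0(n, ".afa"))
      if (!is.null(manifest$alignments_dir) && file.exists(afa)) {
        hits <- classify_tiers(hits, read_alignment(afa), motifs,
                               coverage = cov)
      }
      motif_hits <- rbind(motif_hits, hits)
      st <- summarize_motifs_per_enhancer(hits, families = motifs$family)
      if (nrow(st)) {
        motif_status <- rbind(motif_status,
                              cbind(enhancer = n, st,
                                    stringsAsFactors = FALSE)[,
                                    c("enhancer", "family", "status")])
      }
    }
  }
  write_report_tsv(motif_hits, file.path(outdir, "motif_hits.tsv"), prov)
  write_report_tsv(motif_status, file.path(outdir, "motif_status.tsv"), prov)
  report$n_motif_hits <- nrow(motif_hits)

  log("[call-binding] intersecting enhancers with peak sets")
  enh_tab <- read_enhancer_table(manifest$enhancers)
  binding <- data.frame(enhancer = character(), tf = character(),
                        status = character(), stringsAsFactors = FALSE)
  if (!is.null(manifest$peaks_manifest) && file.exists(manifest$peaks_manifest)) {
    pm <- read.delim(manifest$peaks_manifest, comment.char = "#",
                     stringsAsFactors = FALSE)
    pdir <- dirname(manifest$peaks_manifest)
    gr <- enhancer_granges(enh_tab)
    for (i in seq_len(nrow(pm))) {
      p <- pm$path[i]
      if (!grepl("^/", p)) p <- file.path(pdir, p)
      ps <- peak_set(pm$tf[i], read_bed(p))
      fam <- tf_to_family(pm$tf[i])
      for (j in seq_along(gr)) {
        ms <- motif_status$status[motif_status$enhancer == names(gr)[j] &
                                  motif_status$family == fam]
        ms <- if (length(ms)) ms[1L] else "absent"
        if (!ms %in% c("M", "m")) ms <- "absent"
        binding <- rbind(binding,
                         call_binding(gr[j], ps, ms, names(gr)[j]))
      }
    }
  }
  write_report_tsv(binding, file.path(outdir, "binding_calls.tsv"), prov)
  report$n_bound <- sum(binding$status %in% c("C", "c"))

  log("[classify-activity] applying the >5% activity rule")
  counts <- read_assay_counts(manifest$assay_counts)
  act <- cohort_activity_summary(counts,
                                 manifest$activity_threshold %||% 0.05)
  write_report_tsv(act$calls, file.path(outdir, "activity_calls.tsv"), prov)
  report$n_assayed <- act$n_assayed
  report$n_active <- act$n_active
  report$n_active_strong <- act$n_active_strong

  log("[summarize] class tables and concordance")
  have_classes <- all(c("in_vivo_class", "in_silico_class") %in%
                      names(enh_tab)) &&
                  nrow(enh_tab) > 0 &&
                  !any(is.na(enh_tab$in_vivo_class))
  if (have_classes) {
    conc <- concordance(enh_tab)
    conc_df <- as.data.frame.table(as.table(conc$counts),
                                   stringsAsFactors = FALSE)
    names(conc_df) <- c("in_vivo_class", "in_silico_class", "count")
    write_report_tsv(conc_df, file.path(outdir, "concordance.tsv"), prov)
    if (nrow(motif_status)) {
      classes <- stats::setNames(enh_tab$in_vivo_class, enh_tab$name)
      ms <- motif_status[motif_status$enhancer %in% names(classes), ,
                         drop = FALSE]
      if (nrow(ms)) {
        tab <- tabulate_status(ms, classes[unique(ms$enhancer)],
                               status_set = c("M", "m"))
        stat_df <- data.frame(
          family = rep(rownames(tab$k), ncol(tab$k)),
          class = rep(colnames(tab$k), each = nrow(tab$k)),
          k = as.vector(tab$k), n = as.vector(tab$n),
          stringsAsFactors = FALSE)
        write_report_tsv(stat_df, file.path(outdir, "status_by_class.tsv"),
                         prov)
      }
    }
    report$concordance <- conc$counts
  }

  report$version <- as.character(utils::packageVersion("artenh"))
  report$seed <- manifest$seed
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("[done] report written to ", file.path(outdir, "report.json"))
  invisible(report)
}

# map a TF name to its motif family (SOX7/SOX17/SOX18 -> SOX, ERG/ETS1 ->
# ETS, FOXO1 -> FOX, MEF2A/C -> MEF2, ...); unknown names map to
# themselves
tf_to_family <- function(tf) {
  up <- toupper(tf)
  if (grepl("^SOX", up)) return("SOX")
  if (up %in% c("ERG", "ETS1", "ETV2", "FLI1") || grepl("^ETS|^ETV", up)) {
    return("ETS")
  }
  if (grepl("^FOX", up)) return("FOX")
  if (grepl("^MEF2", up)) return("MEF2")
  if (up %in% c("RBPJ", "RBPJK")) return("RBPJ")
  if (up %in% c("NR2F2", "COUPTFII")) return("NR2F2")
  if (grepl("^SMAD", up)) return("SMAD")
  if (up %in% c("TCF7", "TCF7L1", "TCF7L2", "LEF1")) return("TCF_LEF")
  if (up == "KLF4") return("KLF4")
  tf
}

provenance_header <- function(manifest) {
  hash <- tryCatch(unname(tools::md5sum(manifest$path)),
                   error = function(e) NA_character_)
  c(sprintf("# artenh %s", utils::packageVersion("artenh")),
    sprintf("# manifest_md5: %s", hash %||% "NA"),
    sprintf("# seed: %s", manifest$seed %||% "NA"))
}

write_report_tsv <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
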