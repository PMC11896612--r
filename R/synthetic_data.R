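# Synthetic two-species loci with planted ground truth.
#
# The generator emulates the input side of the arterial-enhancer screen:
# a mouse locus sequence carrying planted enhancer cores with concrete
# motif instances, per-dataset mark intervals over the planted spans plus
# single-dataset noise marks, an orthology block map to a human locus,
# per-enhancer multi-species alignments realizing each planted
# conservation tier, TF peak sets with positional jitter, and binomial
# transgenesis assay counts. Everything is deterministic given the seed.

SYNTH_DATASETS <- c(M_artery_ATAC = "mouse", M_retina_ATAC = "mouse",
                    M_E11_p300 = "mouse", H_DNaseI = "human",
                    H_histone = "human")

SYNTH_SPECIES <- c(mouse = 0, human = 0.10, dog = 0.16, cow = 0.22,
                   opossum = 0.32, chicken = 0.42)

#' Specify a synthetic locus
#'
#' @param gene Gene symbol anchoring the locus.
#' @param length Locus length in bp (default 60000).
#' @param tss TSS position within the locus, 0-based (default
#'   `length / 2`).
#' @param gene_strand `"+"` or `"-"`.
#' @param transcribed_human Is the gene transcribed in the human datasets
#'   (controls which putative-enhancer rule applies)?
#' @param enhancers List of planted enhancers; each element a list with
#'   `offset` (bp from TSS, signed), `width`, `class` (`arterial`,
#'   `pan_EC`, `venous`), `marks` (character vector of dataset ids
#'   carrying a mark over the span; see names of `SYNTH_DATASETS`),
#'   `motifs` (data.frame `family`, `pos` (0-based within core),
#'   `strand`, `tier`), `peaks` (character vector of TF names whose peak
#'   sets cover the span), `rate` (true assay activity rate), `weak_flag`,
#'   and optionally `align_species` (species whose rows align; default all).
#' @return A list of class `locus_spec`.
#' @export
locus_spec <- function(gene, length = 60000L, tss = NULL,
                       gene_strand = "+", transcribed_human = TRUE,
                       enhancers = list()) {
  tss <- tss %||% as.integer(length / 2)
  stopifnot(tss >= 0L, tss < length, gene_strand %in% c("+", "-"))
  for (e in enhancers) {
    stopifnot(!is.null(e$offset), !is.null(e$width))
    s <- tss + e$offset
    if (s < 0L || s + e$width > length) {
      stop("planted enhancer outside locus in gene ", gene)
    }
    if (!is.null(e$motifs) && nrow(e$motifs)) {
      stopifnot(all(e$motifs$pos >= 0), all(e$motifs$tier %in%
                  c("strong", "weak", "none")))
    }
  }
  structure(list(gene = gene, length = as.integer(length),
                 tss = as.integer(tss), gene_strand = gene_strand,
                 transcribed_human = transcribed_human,
                 enhancers = enhancers),
            class = "locus_spec")
}

#' Generate a synthetic locus bundle
#'
#' Realizes a [locus_spec()]: sequences, mark tracks, orthology map,
#' per-enhancer alignments, peak sets, assay counts, and a truth table.
#' Planted motif instances are written into the reference sequence;
#' orthologous alignment rows preserve or disrupt each instance exactly
#' according to its planted tier (strong: intact in every aligning
#' species; weak: intact in human only; none: disrupted in human).
#' Enhancer cores are scrubbed of incidental consensus matches so the
#' recovered hit set equals the plant specification.
#'
#' @param spec A [locus_spec()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param motifs Motif table used for planting and scrubbing.
#' @param species Named numeric vector of per-species substitution rates,
#'   reference (rate 0) first; default `SYNTH_SPECIES`.
#' @param noise List: `n_marks` noise marks per track (default 2),
#'   `mark_len` mean noise-mark length (default 400), `peak_jitter_sd`
#'   sd in bp of peak boundary jitter (default 50), `gc` background GC
#'   content (default 0.45), `n_injected` embryos per assay (default 100).
#' @return A list of class `locus_bundle` with elements `sequences`
#'   (named character: mouse and human locus ids), `core_seqs` (named
#'   character, per enhancer), `tracks` (list of [mark_track()]),
#'   `orthology` (block map data.frame), `alignments` (named list of
#'   [alignment_profile()]), `peak_sets` (named list of [peak_set()]),
#'   `assay_counts` (data.frame), `truth` (data.frame), `truth_motifs`
#'   (data.frame), `spec`, `seed`.
#' @export
generate_locus <- function(spec, seed, motifs = default_motifs(),
                           species = SYNTH_SPECIES, noise = list()) {
  stopifnot(inherits(spec, "locus_spec"))
  noise <- utils::modifyList(list(n_marks = 2L, mark_len = 400L,
                                  peak_jitter_sd = 50, gc = 0.45,
                                  n_injected = 100L), noise)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  mm_id <- paste0(spec$gene, "_mm")
  hs_id <- paste0(spec$gene, "_hs")
  L <- spec$length
  seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - noise$gc) / 2, noise$gc / 2,
                          noise$gc / 2, (1 - noise$gc) / 2))

  # resolve planted enhancer spans (0-based half-open, absolute)
  enh <- lapply(spec$enhancers, function(e) {
    e$start <- as.integer(spec$tss + e$offset)
    e$end <- as.integer(e$start + e$width)
    e$name <- name_enhancer(spec$gene, spec$tss, spec$gene_strand,
                            c(e$start, e$end))
    e$align_species <- e$align_species %||% names(species)
    e
  })
  nm <- vapply(enh, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("planted enhancers collide in name: ",
                              nm[duplicated(nm)][1L])

  # plant motif instances into the reference sequence
  cons_of <- stats::setNames(motifs$consensus, motifs$family)
  for (e in enh) {
    if (is.null(e$motifs) || nrow(e$motifs) == 0L) next
    spans <- cbind(e$motifs$pos,
                   e$motifs$pos + nchar(cons_of[e$motifs$family]))
    o <- order(spans[, 1])
    if (any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)])) {
      stop("planted motifs overlap within enhancer ", e$name)
    }
    for (i in seq_len(nrow(e$motifs))) {
      fam <- e$motifs$family[i]
      inst <- concretize_consensus(cons_of[[fam]])
      if (e$motifs$strand[i] == "-") inst <- revcomp(inst)
      at <- e$start + e$motifs$pos[i]
      seqv[(at + 1):(at + nchar(inst))] <- strsplit(inst, "")[[1L]]
    }
  }

  # scrub incidental matches from each core so recovery is exact
  for (j in seq_along(enh)) {
    e <- enh[[j]]
    idx <- (e$start + 1):e$end
    core <- seqv[idx]
    planted <- if (is.null(e$motifs)) motif_hit_frame()[0, ] else e$motifs
    core <- scrub_core(core, planted, motifs)
    seqv[idx] <- core
    enh[[j]]$core <- paste(core, collapse = "")
  }

  # mark tracks: planted marks over enhancer spans + single-dataset noise.
  # Noise marks avoid planted spans (padded past the merge gap) on both
  # species and avoid each other, so they stay single-dataset singletons
  # and cannot fabricate cross-species or two-dataset evidence.
  enh_spans <- function(chrom) {
    if (!length(enh)) return(empty_granges())
    GenomicRanges::GRanges(chrom, IRanges::IRanges(
      pmax(1L, vapply(enh, `[[`, 0L, "start") + 1L - 600L),
      vapply(enh, `[[`, 0L, "end") + 600L))
  }
  avoid <- list(mouse = enh_spans(mm_id), human = enh_spans(hs_id))
  tracks <- list()
  for (ds in names(SYNTH_DATASETS)) {
    sp <- SYNTH_DATASETS[[ds]]
    chrom <- if (sp == "mouse") mm_id else hs_id
    planted <- Filter(function(e) ds %in% (e$marks %||% character()), enh)
    gr <- if (length(planted)) {
      GenomicRanges::GRanges(chrom, IRanges::IRanges(
        vapply(planted, `[[`, 0L, "start") + 1,
        vapply(planted, `[[`, 0L, "end")))
    } else GenomicRanges::GRanges()
    if (noise$n_marks > 0L) {
      ns <- place_noise_marks(noise$n_marks, noise$mark_len, L,
                              avoid[[sp]], chrom)
      gr <- c(gr, ns)
      # pad past the candidate merge gap so noise marks from different
      # tracks can never fuse into a multi-dataset candidate
      if (length(ns)) avoid[[sp]] <- c(avoid[[sp]], ns + 600L)
    }
    tracks[[ds]] <- mark_track(ds, sp, GenomicRanges::sort(gr))
  }

  # orthology: one block per planted enhancer, same offsets on the human id
  orthology <- if (length(enh)) {
    data.frame(src_seq = mm_id,
               src_start = vapply(enh, `[[`, 0L, "start"),
               src_end = vapply(enh, `[[`, 0L, "end"),
               tgt_seq = hs_id,
               tgt_start = vapply(enh, `[[`, 0L, "start"),
               tgt_end = vapply(enh, `[[`, 0L, "end"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(src_seq = character(), src_start = integer(),
               src_end = integer(), tgt_seq = character(),
               tgt_start = integer(), tgt_end = integer())
  }

  # per-enhancer alignments realizing the planted tiers
  alignments <- lapply(enh, function(e) {
    simulate_alignment(e, species, cons_of, motifs)
  })
  names(alignments) <- nm

  # peak sets with boundary jitter
  tfs <- unique(unlist(lapply(enh, `[[`, "peaks")))
  peak_sets <- lapply(tfs, function(tf) {
    covered <- Filter(function(e) tf %in% (e$peaks %||% character()), enh)
    st <- vapply(covered, `[[`, 0L, "start")
    en <- vapply(covered, `[[`, 0L, "end")
    js <- pmax(0, st + round(stats::rnorm(length(st), 0, noise$peak_jitter_sd)))
    je <- pmin(L, en + round(stats::rnorm(length(en), 0, noise$peak_jitter_sd)))
    js <- pmin(js, en - 1)  # keep >= 1 bp overlap with the planted span
    je <- pmax(je, st + 1)
    peak_set(tf, GenomicRanges::GRanges(mm_id,
             IRanges::IRanges(js + 1, je)), source_id = "synthetic")
  })
  names(peak_sets) <- tfs

  # binomial assay counts at the true activity rates
  assay_counts <- if (length(enh)) {
    data.frame(
      name = nm,
      n_injected = noise$n_injected,
      n_gfp_positive = vapply(enh, function(e) {
        stats::rbinom(1L, noise$n_injected, e$rate %||% 0)
      }, 0L),
      weak_flag = vapply(enh, function(e) isTRUE(e$weak_flag), TRUE),
      stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), n_injected = integer(),
               n_gfp_positive = integer(), weak_flag = logical())
  }

  truth <- if (length(enh)) {
    data.frame(
      gene = spec$gene, name = nm, seq_id = mm_id,
      start = vapply(enh, `[[`, 0L, "start"),
      end = vapply(enh, `[[`, 0L, "end"),
      class = vapply(enh, function(e) e$class %||% NA_character_, ""),
      rate = vapply(enh, function(e) e$rate %||% 0, 0),
      weak_flag = vapply(enh, function(e) isTRUE(e$weak_flag), TRUE),
      n_mouse_marks = vapply(enh, function(e) {
        sum(SYNTH_DATASETS[e$marks %||% character()] == "mouse")
      }, 0L),
      n_human_marks = vapply(enh, function(e) {
        sum(SYNTH_DATASETS[e$marks %||% character()] == "human")
      }, 0L),
      stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), name = character(), seq_id = character(),
               start = integer(), end = integer(), class = character(),
               rate = numeric(), weak_flag = logical(),
               n_mouse_marks = integer(), n_human_marks = integer())
  }
  truth$putative_truth <- if (nrow(truth)) {
    if (spec$transcribed_human) {
      truth$n_mouse_marks >= 1 & truth$n_human_marks >= 1
    } else truth$n_mouse_marks >= 2
  } else logical()

  truth_motifs <- do.call(rbind, lapply(enh, function(e) {
    if (is.null(e$motifs) || nrow(e$motifs) == 0L) return(NULL)
    data.frame(enhancer = e$name, family = e$motifs$family,
               pos = e$motifs$pos, strand = e$motifs$strand,
               tier = e$motifs$tier, stringsAsFactors = FALSE)
  })) %||% data.frame(enhancer = character(), family = character(),
                      pos = integer(), strand = character(),
                      tier = character())

  structure(list(
    sequences = stats::setNames(c(paste(seqv, collapse = "")), mm_id),
    core_seqs = stats::setNames(vapply(enh, `[[`, "", "core"), nm),
    tracks = tracks, orthology = orthology, alignments = alignments,
    peak_sets = peak_sets, assay_counts = assay_counts,
    truth = truth, truth_motifs = truth_motifs,
    transcribed_human = spec$transcribed_human,
    spec = spec, seed = seed
  ), class = "locus_bundle")
}

#' Default cohort specification
#'
#' Eight loci named for the arterial genes of the reference screen, with
#' 41 planted putative enhancers in total (plus decoy regions carrying a
#' single mark that must fail the putative call). Three genes (Cxcr4,
#' Cxcl12, Gja5) are flagged poorly transcribed in human cells so their
#' enhancers exercise the relaxed two-mouse-mark rule.
#'
#' @param n_injected Embryos per synthetic assay (default 100).
#' @return List of [locus_spec()] objects.
#' @export
default_cohort_specs <- function(n_injected = 100L) {
  genes <- c("Cxcr4", "Efnb2", "Gja4", "Unc5b", "Acvrl1", "Cxcl12",
             "Gja5", "Nrp1")
  n_enh <- c(6L, 6L, 5L, 5L, 5L, 5L, 5L, 4L)   # sums to 41
  low_tx <- c("Cxcr4", "Cxcl12", "Gja5")
  mouse_ds <- names(SYNTH_DATASETS)[SYNTH_DATASETS == "mouse"]
  human_ds <- names(SYNTH_DATASETS)[SYNTH_DATASETS == "human"]
  specs <- lapply(seq_along(genes), function(g) {
    tx <- !(genes[g] %in% low_tx)
    enh <- lapply(seq_len(n_enh[g]), function(i) {
      cls <- c("arterial", "pan_EC", "venous")[1L + (i %% 3L)]
      marks <- if (tx) c(mouse_ds[1L + (i %% 3L)], human_ds[1L + (i %% 2L)])
               else mouse_ds[c(1L + (i %% 3L), 1L + ((i + 1L) %% 3L))]
      list(offset = -25000L + i * 7000L, width = 320L + 20L * i,
           class = cls, marks = marks,
           motifs = data.frame(
             family = c("ETS", "RBPJ"),
             pos = c(40L + 10L * i, 150L + 10L * i),
             strand = c("+", "-"),
             tier = c("strong", if (i %% 2L) "weak" else "none"),
             stringsAsFactors = FALSE),
           peaks = if (cls == "arterial") c("SOX17", "ERG") else "ERG",
           rate = if (cls == "arterial") 0.5 else if (cls == "pan_EC") 0.3
                  else 0.01,
           weak_flag = FALSE)
    })
    # one decoy region with a single mouse mark: must stay below threshold
    decoy <- list(offset = 26000L, width = 300L, class = "decoy",
                  marks = mouse_ds[1L], motifs = NULL, peaks = NULL,
                  rate = 0, weak_flag = FALSE)
    locus_spec(genes[g], length = 64000L, gene_strand = "+",
               transcribed_human = tx, enhancers = c(enh, list(decoy)))
  })
  specs
}

#' Generate a cohort and write it as pipeline-ready files
#'
#' Writes, under `dir`: `loci.tsv`, one BED per mark track plus
#' `marks_manifest.tsv`, `orthology.tsv`, `cores.fa`, aligned FASTAs under
#' `alignments/`, `motifs.tsv`, peak BEDs plus `peaks_manifest.tsv`,
#' `assay_counts.tsv`, `enhancers.tsv`, `truth.tsv`, `truth_motifs.tsv`,
#' and a flat key-value `manifest.txt` consumable by [run_all()].
#'
#' @param specs List of [locus_spec()] (default [default_cohort_specs()]).
#' @param dir Output directory (created).
#' @param seed Integer seed; per-locus seeds are derived from it.
#' @param motifs Motif table.
#' @param noise Noise parameters, see [generate_locus()].
#' @return Invisibly, the manifest path.
#' @export
generate_cohort <- function(specs = default_cohort_specs(), dir, seed,
                            motifs = default_motifs(), noise = list()) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  for (sub in c("marks", "peaks", "alignments")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  bundles <- lapply(seq_along(specs), function(i) {
    generate_locus(specs[[i]], seed = (seed * 131L + i) %% 2147483647L,
                   motifs = motifs, noise = noise)
  })

  # loci table
  loci <- do.call(rbind, lapply(bundles, function(b) {
    data.frame(gene = b$spec$gene, seq_id = names(b$sequences)[1L],
               start = 0L, end = b$spec$length, tss = b$spec$tss,
               strand = b$spec$gene_strand,
               transcribed_human = b$transcribed_human,
               stringsAsFactors = FALSE)
  })) %||% data.frame(gene = character(), seq_id = character(),
                      start = integer(), end = integer(), tss = integer(),
                      strand = character(), transcribed_human = logical())
  write_plain_tsv(loci, file.path(dir, "loci.tsv"))

  # mark tracks: concatenate per dataset across loci
  for (ds in names(SYNTH_DATASETS)) {
    gr <- unlist(GenomicRanges::GRangesList(lapply(bundles, function(b) {
      GenomicRanges::granges(b$tracks[[ds]]$intervals)
    })))
    write_bed(gr, file.path(dir, "marks", paste0(ds, ".bed")))
  }
  marks_manifest <- data.frame(
    dataset_id = names(SYNTH_DATASETS),
    species = unname(SYNTH_DATASETS),
    path = file.path("marks", paste0(names(SYNTH_DATASETS), ".bed")),
    ec_specific = TRUE, stringsAsFactors = FALSE)
  write_plain_tsv(marks_manifest, file.path(dir, "marks_manifest.tsv"))

  orthology <- do.call(rbind, lapply(bundles, `[[`, "orthology")) %||%
    data.frame(src_seq = character(), src_start = integer(),
               src_end = integer(), tgt_seq = character(),
               tgt_start = integer(), tgt_end = integer())
  write_plain_tsv(orthology, file.path(dir, "orthology.tsv"))

  cores <- unlist(lapply(bundles, `[[`, "core_seqs"))
  if (length(cores)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cores),
                                file.path(dir, "cores.fa"))
  } else file.create(file.path(dir, "cores.fa"))

  for (b in bundles) {
    for (n in names(b$alignments)) {
      writeLines(paste0(">", names(b$alignments[[n]]), "\n",
                        as.character(b$alignments[[n]])),
                 file.path(dir, "alignments", paste0(n, ".afa")))
    }
  }

  write_plain_tsv(motifs, file.path(dir, "motifs.tsv"))

  tfs <- unique(unlist(lapply(bundles, function(b) names(b$peak_sets))))
  for (tf in tfs) {
    gr <- unlist(GenomicRanges::GRangesList(lapply(bundles, function(b) {
      if (tf %in% names(b$peak_sets)) b$peak_sets[[tf]]$intervals
      else GenomicRanges::GRanges()
    })))
    write_bed(gr, file.path(dir, "peaks", paste0(tf, ".bed")))
  }
  peaks_manifest <- data.frame(
    tf = tfs %||% character(),
    path = if (length(tfs)) file.path("peaks", paste0(tfs, ".bed"))
           else character(),
    stringsAsFactors = FALSE)
  write_plain_tsv(peaks_manifest, file.path(dir, "peaks_manifest.tsv"))

  assay <- do.call(rbind, lapply(bundles, `[[`, "assay_counts")) %||%
    data.frame(name = character(), n_injected = integer(),
               n_gfp_positive = integer(), weak_flag = logical())
  write_plain_tsv(assay, file.path(dir, "assay_counts.tsv"))

  truth <- do.call(rbind, lapply(bundles, `[[`, "truth")) %||%
    data.frame(gene = character(), name = character(), seq_id = character(),
               start = integer(), end = integer(), class = character(),
               rate = numeric(), weak_flag = logical(),
               n_mouse_marks = integer(), n_human_marks = integer(),
               putative_truth = logical())
  write_plain_tsv(truth, file.path(dir, "truth.tsv"))
  truth_motifs <- do.call(rbind, lapply(bundles, `[[`, "truth_motifs")) %||%
    data.frame(enhancer = character(), family = character(),
               pos = integer(), strand = character(), tier = character())
  write_plain_tsv(truth_motifs, file.path(dir, "truth_motifs.tsv"))

  enh_tab <- if (!is.null(truth) && nrow(truth)) {
    data.frame(name = truth$name, species = "mouse", seq_id = truth$seq_id,
               start = truth$start, end = truth$end, strand = ".",
               gene = truth$gene, in_vivo_class = truth$class,
               in_silico_class = truth$class, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), species = character(),
               seq_id = character(), start = integer(), end = integer(),
               strand = character(), gene = character(),
               in_vivo_class = character(), in_silico_class = character())
  }
  write_plain_tsv(enh_tab, file.path(dir, "enhancers.tsv"))

  manifest <- c(
    loci = "loci.tsv", marks_manifest = "marks_manifest.tsv",
    orthology = "orthology.tsv", cores_fasta = "cores.fa",
    alignments_dir = "alignments", motifs = "motifs.tsv",
    peaks_manifest = "peaks_manifest.tsv",
    assay_counts = "assay_counts.tsv", enhancers = "enhancers.tsv",
    outdir = "results", seed = as.character(seed),
    merge_gap = "500", activity_threshold = "0.05",
    composite_window = "2", coverage_threshold = "0.5")
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(dir, "manifest.txt"))
  invisible(file.path(dir, "manifest.txt"))
}

# -- internal helpers ---------------------------------------------------

IUPAC_SET <- strsplit(c(A = "A", C = "C", G = "G", T = "T",
                        R = "AG", Y = "CT", S = "CG", W = "AT",
                        K = "GT", M = "AC", B = "CGT", D = "AGT",
                        H = "ACT", V = "ACG", N = "ACGT"), "")

concretize_consensus <- function(consensus) {
  ch <- strsplit(toupper(consensus), "")[[1L]]
  paste(vapply(ch, function(c) {
    set <- IUPAC_SET[[c]]
    set[sample.int(length(set), 1L)]
  }, ""), collapse = "")
}

# mutate one constrained position of a motif instance so it no longer
# matches the consensus on the given strand
disrupt_instance <- function(inst_chars, consensus, strand) {
  cons <- strsplit(toupper(consensus), "")[[1L]]
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
              D = "H", H = "D", N = "N")
    cons <- rev(unname(comp[cons]))           # consensus as seen on + strand
  }
  constrained <- which(lengths(IUPAC_SET[cons]) < 4L)
  if (length(constrained) == 0L) {
    stop("cannot disrupt all-N consensus: ", consensus)
  }
  p <- constrained[1L + (length(constrained) - 1L) %/% 2L]
  allowed <- IUPAC_SET[[cons[p]]]
  inst_chars[p] <- setdiff(c("A", "C", "G", "T"), allowed)[1L]
  inst_chars
}

# remove incidental consensus matches from a core, leaving planted spans
# untouched; errors if an unbreakable spurious match persists
scrub_core <- function(core_chars, planted, motifs, max_iter = 300L) {
  width_of <- stats::setNames(nchar(motifs$consensus), motifs$family)
  protected <- rep(FALSE, length(core_chars))
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      w <- width_of[[planted$family[i]]]
      protected[(planted$pos[i] + 1):(planted$pos[i] + w)] <- TRUE
    }
  }
  is_planted <- function(fam, start, strand) {
    nrow(planted) && any(planted$family == fam & planted$pos == start &
                         planted$strand == strand)
  }
  for (iter in seq_len(max_iter)) {
    seq_str <- paste(core_chars, collapse = "")
    dirty <- FALSE
    for (i in seq_len(nrow(motifs))) {
      hits <- scan_consensus(seq_str, motifs$consensus[i], motifs$family[i])
      for (h in seq_len(nrow(hits))) {
        if (is_planted(hits$family[h], hits$start[h], hits$strand[h])) next
        span <- (hits$start[h] + 1):hits$end[h]
        free <- span[!protected[span]]
        if (length(free) == 0L) next   # spurious hit inside a planted span
        cons <- strsplit(motifs$consensus[i], "")[[1L]]
        comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                  S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                  D = "H", H = "D", N = "N")
        # randomized position/replacement choice avoids substitution
        # cycles where breaking one family's match creates another's
        free <- free[sample.int(length(free))]
        for (p in free) {
          off <- p - hits$start[h]     # 1-based offset within the hit
          code <- if (hits$strand[h] == "+") cons[off]
                  else comp[[cons[length(cons) - off + 1L]]]
          repl <- setdiff(c("A", "C", "G", "T"), IUPAC_SET[[code]])
          if (length(repl) == 0L) next # all-N position, try another
          core_chars[p] <- repl[sample.int(length(repl), 1L)]
          dirty <- TRUE
          break
        }
        if (dirty) break
      }
      if (dirty) break
    }
    if (!dirty) return(core_chars)
  }
  warning("core scrub did not converge; incidental motif matches remain")
  core_chars
}

place_noise_marks <- function(n, mean_len, locus_len, avoid, chrom) {
  placed <- GenomicRanges::GRanges()
  tries <- 0L
  while (length(placed) < n && tries < 200L) {
    tries <- tries + 1L
    w <- max(50L, as.integer(stats::rnorm(1L, mean_len, mean_len / 4)))
    s <- as.integer(stats::runif(1L, 0, max(1, locus_len - w)))
    cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, s + w))
    if (length(avoid) && length(GenomicRanges::findOverlaps(cand, avoid))) next
    if (length(placed) &&
        length(GenomicRanges::findOverlaps(cand + 600L, placed))) next
    placed <- c(placed, cand)
  }
  placed
}

# aligned rows for one enhancer: reference first, then each species either
# fully gapped (not aligning) or the mutated core with motif columns set
# intact/disrupted per the planted tier
simulate_alignment <- function(e, species, cons_of, motifs) {
  core <- strsplit(e$core, "")[[1L]]
  w <- length(core)
  ref_name <- names(species)[1L]
  rows <- list()
  rows[[ref_name]] <- e$core
  motif_cols <- rep(FALSE, w)
  plants <- e$motifs
  if (!is.null(plants) && nrow(plants)) {
    for (i in seq_len(nrow(plants))) {
      mw <- nchar(cons_of[[plants$family[i]]])
      motif_cols[(plants$pos[i] + 1):(plants$pos[i] + mw)] <- TRUE
    }
  }
  for (sp in names(species)[-1L]) {
    if (!(sp %in% e$align_species)) {
      rows[[sp]] <- paste(rep("-", w), collapse = "")
      next
    }
    row <- core
    mut <- which(stats::runif(w) < species[[sp]] & !motif_cols)
    if (length(mut)) {
      row[mut] <- vapply(row[mut], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, "")
    }
    if (!is.null(plants) && nrow(plants)) {
      for (i in seq_len(nrow(plants))) {
        fam <- plants$family[i]
        mw <- nchar(cons_of[[fam]])
        span <- (plants$pos[i] + 1):(plants$pos[i] + mw)
        keep <- switch(plants$tier[i],
                       strong = TRUE,
                       weak = (sp == "human"),
                       none = FALSE)
        if (keep) {
          row[span] <- core[span]
        } else {
          row[span] <- disrupt_instance(core[span], cons_of[[fam]],
                                        plants$strand[i])
        }
      }
    }
    rows[[sp]] <- paste(row, collapse = "")
  }
  # scrub mutated rows is unnecessary: tier classification inspects only
  # the planted motif columns, which are set explicitly above
  alignment_profile(unlist(rows))
}

write_plain_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
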