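# Consensus motif scanning with IUPAC semantics, FOX:ETS composite
# detection, and the three-tier conservation classification of each hit
# against a multi-species alignment of the enhancer core.
#
# Hit coordinates are 0-based half-open positions within the scanned core.

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGTN]")

#' Default transcription-factor family consensus set
#'
#' The RBPJ (TGGGAA) and ETS (HGGAAR) consensi are the ones used in the
#' arterial-enhancer analysis this package implements; the remaining
#' families carry standard literature consensi and should be overridden
#' with a project-specific motif table ([read_motifs()]) whenever exact
#' published tallies are to be reproduced. FOX additionally declares the
#' FOX:ETS composite (FOX half immediately 5' of an ETS core, <= 2 bp gap).
#'
#' @return A data.frame with columns `family`, `consensus`,
#'   `composite_with`, `composite_window`, and attribute
#'   `provenance = "default_placeholder"`.
#' @export
default_motifs <- function() {
  m <- data.frame(
    family = c("ETS", "RBPJ", "SOX", "FOX", "MEF2", "NR2F2", "KLF4",
               "TCF_LEF", "SMAD"),
    consensus = c("HGGAAR", "TGGGAA", "WWCAAW", "RYAAAYA", "CTAWWWWTAG",
                  "TGACCT", "GGGGNGGGG", "CTTTGWW", "GGCGCC"),
    composite_with = c(NA, NA, NA, "ETS", NA, NA, NA, NA, NA),
    composite_window = c(NA, NA, NA, 2L, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(m, "provenance") <- "default_placeholder"
  m
}

#' Read a motif definition table
#'
#' Tab-separated with header; columns `family`, `consensus` and optional
#' `composite_with`, `composite_window`. Consensi must be IUPAC strings.
#'
#' @param path Path to the TSV.
#' @return A motif data.frame as in [default_motifs()], with
#'   `provenance = "user"`.
#' @export
read_motifs <- function(path) {
  m <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("family", "consensus") %in% names(m))) {
    stop("motif table must have 'family' and 'consensus' columns")
  }
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", toupper(m$consensus))
  if (any(bad)) stop("invalid IUPAC code in consensus for family ",
                     m$family[which(bad)[1L]])
  m$consensus <- toupper(m$consensus)
  if (is.null(m$composite_with)) m$composite_with <- NA_character_
  if (is.null(m$composite_window)) m$composite_window <- NA_integer_
  attr(m, "provenance") <- "user"
  m
}

#' Scan a sequence for an IUPAC consensus on both strands
#'
#' Every position and strand where the consensus matches under IUPAC
#' semantics yields exactly one hit; overlapping hits are all reported.
#' An `N` in the scanned sequence matches only an `N` consensus position.
#' Hits are sorted by start, then strand (`+` before `-`).
#'
#' @param sequence A nucleotide string (or `DNAString`) over
#'   `{A,C,G,T,N}`.
#' @param consensus IUPAC consensus string.
#' @param family Family label recorded on the hits.
#' @param enhancer Optional enhancer name recorded on the hits.
#' @return A data.frame of motif hits: `enhancer`, `family`, `start`,
#'   `end` (0-based half-open within the sequence), `strand`,
#'   `matched_sequence` (as read on the reported strand), `tier`
#'   (`NA` until classified), `composite_member` (`FALSE`).
#' @export
scan_consensus <- function(sequence, consensus, family = NA_character_,
                           enhancer = NA_character_) {
  consensus <- toupper(as.character(consensus))
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", consensus)) {
    stop("invalid IUPAC code in consensus: ", consensus)
  }
  seq_chr <- toupper(as.character(sequence))
  w <- nchar(consensus)
  if (nchar(seq_chr) < w || w == 0L) return(motif_hit_frame())
  subject <- Biostrings::DNAString(seq_chr)
  pat <- Biostrings::DNAString(consensus)
  # fixed = "subject": consensus ambiguity codes expand, sequence letters
  # (incl. N) are literal, so N only satisfies a consensus N.
  fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
  rc <- Biostrings::reverseComplement(subject)
  rev <- Biostrings::matchPattern(pat, rc, fixed = "subject")
  L <- nchar(seq_chr)
  hits <- rbind(
    if (length(fwd)) data.frame(start = IRanges::start(fwd) - 1L,
                                end = IRanges::end(fwd),
                                strand = "+",
                                matched_sequence = as.character(fwd),
                                stringsAsFactors = FALSE),
    if (length(rev)) data.frame(start = L - IRanges::end(rev),
                                end = L - IRanges::start(rev) + 1L,
                                strand = "-",
                                matched_sequence = as.character(rev),
                                stringsAsFactors = FALSE)
  )
  if (is.null(hits) || nrow(hits) == 0L) return(motif_hit_frame())
  hits <- cbind(enhancer = enhancer, family = family, hits,
                tier = NA_character_, composite_member = FALSE,
                stringsAsFactors = FALSE)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

motif_hit_frame <- function() {
  data.frame(enhancer = character(), family = character(),
             start = integer(), end = integer(), strand = character(),
             matched_sequence = character(), tier = character(),
             composite_member = logical(), stringsAsFactors = FALSE)
}

#' Scan an enhancer core with a motif table
#'
#' Convenience wrapper running [scan_consensus()] for every family in a
#' motif table and flagging FOX:ETS composites where declared.
#'
#' @param sequence Core nucleotide sequence.
#' @param motifs Motif table ([default_motifs()] or [read_motifs()]).
#' @param enhancer Enhancer name recorded on the hits.
#' @return Combined motif-hit data.frame.
#' @export
scan_core <- function(sequence, motifs = default_motifs(),
                      enhancer = NA_character_) {
  hits <- do.call(rbind, lapply(seq_len(nrow(motifs)), function(i) {
    scan_consensus(sequence, motifs$consensus[i], motifs$family[i], enhancer)
  }))
  if (is.null(hits)) hits <- motif_hit_frame()
  comp <- which(!is.na(motifs$composite_with))
  for (i in comp) {
    hits <- detect_composite_fox_ets(
      hits, fox_family = motifs$family[i],
      ets_family = motifs$composite_with[i],
      window = motifs$composite_window[i] %||% 2L)
  }
  hits
}

#' Flag FOX:ETS composite elements among motif hits
#'
#' A FOX hit lying immediately 5' of an ETS hit on the same strand, with a
#' gap of at most `window` bp between the FOX end and the ETS start, is a
#' composite member; both partners are flagged. FOX hits not so flagged
#' are independent FOX sites.
#'
#' @param hits Motif-hit data.frame for one enhancer core (may contain
#'   other families; only `fox_family`/`ets_family` rows are examined).
#' @param fox_family,ets_family Family labels of the two halves.
#' @param window Maximum gap in bp (default 2); negative gaps (overlap)
#'   do not qualify.
#' @return The hit data.frame with `composite_member` updated.
#' @export
detect_composite_fox_ets <- function(hits, fox_family = "FOX",
                                     ets_family = "ETS", window = 2L) {
  if (is.na(window)) window <- 2L
  fox <- which(hits$family == fox_family)
  ets <- which(hits$family == ets_family)
  for (i in fox) {
    for (j in ets) {
      if (hits$strand[i] != hits$strand[j]) next
      gap <- if (hits$strand[i] == "+") hits$start[j] - hits$end[i]
             else hits$start[i] - hits$end[j]   # 5' of ETS on minus strand
      if (!is.na(gap) && gap >= 0L && gap <= window) {
        hits$composite_member[c(i, j)] <- TRUE
      }
    }
  }
  hits
}

#' Read an aligned multi-FASTA alignment profile
#'
#' One record per species, reference species first, all rows the same
#' length; gaps are `-`. Used to classify motif conservation tiers.
#'
#' @param path Path to the aligned FASTA.
#' @return A named character vector of aligned rows (class
#'   `alignment_profile`), reference first.
#' @export
read_alignment <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(raw))
  names(rows) <- sub("\\s.*$", "", names(raw))
  alignment_profile(rows)
}

#' @rdname read_alignment
#' @param rows Named character vector of equal-length aligned rows,
#'   reference species first.
#' @export
alignment_profile <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows must all have equal length")
  }
  structure(rows, class = "alignment_profile")
}

#' Classify the conservation tier of a motif hit
#'
#' The enhancer's conservation depth `D_e` is the set of species whose
#' aligned row covers at least `coverage` (default 50%) of the core with
#' non-gap bases. The motif's depth `D_m` is the set of species whose
#' aligned bases at the hit's columns still match the consensus on the
#' hit's strand (any gap fails). The tier is
#' \describe{
#'   \item{strong}{human in `D_m` and `D_e` a subset of `D_m` — the motif
#'     is conserved to the same depth as the surrounding sequence;}
#'   \item{weak}{human in `D_m` but some aligning species lacks the motif;}
#'   \item{none}{the motif is not conserved in the orthologous human row
#'     (including when no human row is present).}
#' }
#'
#' @param hit One row of a motif-hit data.frame.
#' @param profile An [alignment_profile()]; reference species first. The
#'   reference row, degapped, must equal the scanned core.
#' @param consensus IUPAC consensus of the hit's family.
#' @param human Name of the human row in the profile (default `"human"`).
#' @param coverage Non-gap fraction of the core required for a species to
#'   count as aligning (default 0.5).
#' @return `"strong"`, `"weak"`, or `"none"`.
#' @export
classify_conservation_tier <- function(hit, profile, consensus,
                                       human = "human", coverage = 0.5) {
  stopifnot(inherits(profile, "alignment_profile"))
  ref <- profile[[1L]]
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  core_cols <- which(ref_chars != "-")          # alignment columns of the core
  n_core <- length(core_cols)
  if (hit$end > n_core || hit$start < 0L) {
    stop("hit coordinates fall outside the reference row of the profile")
  }
  hit_cols <- core_cols[(hit$start + 1L):hit$end]
  ref_hit <- paste(ref_chars[hit_cols], collapse = "")
  ref_on_strand <- if (hit$strand == "-") revcomp(ref_hit) else ref_hit
  if (ref_on_strand != toupper(hit$matched_sequence)) {
    stop("reference row disagrees with the hit's matched sequence (",
         ref_on_strand, " vs ", hit$matched_sequence, ")")
  }
  species <- names(profile)
  row_chars <- lapply(profile, function(r) strsplit(r, "", fixed = TRUE)[[1L]])
  D_e <- species[vapply(row_chars, function(ch) {
    mean(ch[core_cols] != "-") >= coverage
  }, logical(1L))]
  D_m <- species[vapply(row_chars, function(ch) {
    s <- paste(ch[hit_cols], collapse = "")
    if (grepl("-", s, fixed = TRUE)) return(FALSE)
    if (hit$strand == "-") s <- revcomp(s)
    iupac_matches(s, consensus)
  }, logical(1L))]
  if (!(human %in% D_m)) return("none")
  if (all(D_e %in% D_m)) "strong" else "weak"
}

#' Classify tiers for a table of hits
#'
#' @param hits Motif-hit data.frame for one enhancer.
#' @param profile Alignment profile for that enhancer.
#' @param motifs Motif table supplying each family's consensus.
#' @inheritParams classify_conservation_tier
#' @return `hits` with the `tier` column filled.
#' @export
classify_tiers <- function(hits, profile, motifs = default_motifs(),
                           human = "human", coverage = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  cons <- stats::setNames(motifs$consensus, motifs$family)
  hits$tier <- vapply(seq_len(nrow(hits)), function(i) {
    classify_conservation_tier(hits[i, ], profile, cons[[hits$family[i]]],
                               human = human, coverage = coverage)
  }, character(1L))
  hits
}

#' Summarize per-family motif status for one enhancer
#'
#' Per family: `M` when at least one strongly conserved hit exists, else
#' `m` when at least one weakly conserved hit exists, else absent. The
#' independent-FOX status excludes composite-member FOX hits; composite
#' FOX:ETS elements are reported under the family `"FOX:ETS"`.
#'
#' @param hits Motif-hit data.frame for one enhancer, tiers classified.
#' @param families Families to report (default: those present plus any in
#'   `motifs`).
#' @param fox_family Family whose composite members are set aside
#'   (default `"FOX"`).
#' @return A data.frame `family`, `status` (`"M"`, `"m"`, `"absent"`).
#' @export
summarize_motifs_per_enhancer <- function(hits, families = NULL,
                                          fox_family = "FOX") {
  if (is.null(families)) families <- unique(hits$family)
  status_of <- function(tiers) {
    if (any(tiers == "strong", na.rm = TRUE)) "M"
    else if (any(tiers == "weak", na.rm = TRUE)) "m"
    else "absent"
  }
  rows <- lapply(families, function(f) {
    sub <- hits[hits$family == f, , drop = FALSE]
    if (f == fox_family) sub <- sub[!sub$composite_member, , drop = FALSE]
    data.frame(family = f, status = status_of(sub$tier),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(family = character(), status = character())
  comp <- hits[hits$family == fox_family & hits$composite_member, , drop = FALSE]
  if (nrow(comp)) {
    out <- rbind(out, data.frame(family = paste0(fox_family, ":ETS"),
                                 status = status_of(comp$tier),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# -- internal helpers ---------------------------------------------------

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  paste(rev(unname(comp[ch])), collapse = "")
}

iupac_matches <- function(s, consensus) {
  if (nchar(s) != nchar(consensus)) return(FALSE)
  rx <- paste0("^", paste(IUPAC_REGEX[strsplit(toupper(consensus), "")[[1L]]],
                          collapse = ""), "$")
  # N in the observed sequence matches only a consensus N
  grepl(rx, s) && !any(strsplit(s, "")[[1L]] == "N" &
                       strsplit(toupper(consensus), "")[[1L]] != "N")
}
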