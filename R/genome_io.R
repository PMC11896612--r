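# Interval and sequence I/O. BED files are 0-based half-open; GRanges are
# 1-based closed, so conversion happens here and only here.

#' Read a BED3/BED6 file into a GRanges
#'
#' Reads tab-separated BED intervals, skipping `track`, `browser` and `#`
#' comment lines. Columns beyond the sixth (e.g. narrowPeak statistics) are
#' ignored, so narrowPeak files are accepted as-is. Input coordinates are
#' 0-based half-open and converted to the 1-based closed convention of
#' \link[GenomicRanges]{GRanges}.
#'
#' @param path Path to a BED file.
#' @return A `GRanges`, one range per data line, with a `name` metadata
#'   column when a fourth column is present.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr2\t119152838\t119153684", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_granges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield < 3L)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], " in ", path,
         ": fewer than 3 tab-separated fields")
  }
  seq_id <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0   <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], " in ", path,
         ": non-numeric or negative coordinates")
  }
  bad <- which(start0 >= end0)
  if (length(bad)) {
    stop("invalid interval at line ", idx[bad[1L]], " in ", path,
         ": start >= end (zero- or negative-width span)")
  }
  name <- ifelse(nfield >= 4L, vapply(fields, function(f) f[4L] %||% ".", ""), NA_character_)
  strand <- ifelse(nfield >= 6L, vapply(fields, function(f) if (length(f) >= 6L) f[6L] else "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(seq_id,
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = strand)
  if (any(!is.na(name))) S4Vectors::mcols(gr)$name <- name
  gr
}

#' Write a GRanges to a BED file
#'
#' The inverse of [read_bed()]: coordinates are emitted 0-based half-open.
#' A `name` metadata column, when present, becomes the fourth BED column
#' (with score 0 and strand making up BED6); otherwise BED3 is written.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  if (length(gr) == 0L) return(invisible(path))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) {
    out <- paste(chrom, s0, e0, sep = "\t")
  } else {
    str <- as.character(GenomicRanges::strand(gr))
    str[str == "*"] <- "."
    out <- paste(chrom, s0, e0, ifelse(is.na(nm), ".", nm), 0L, str, sep = "\t")
  }
  writeLines(out, con)
  invisible(path)
}

empty_granges <- function() {
  GenomicRanges::GRanges(character(), IRanges::IRanges(integer(), integer()))
}

#' Read a FASTA file with strict record checks
#'
#' Wraps \link[Biostrings]{readDNAStringSet}: sequences are uppercased,
#' record ids are truncated at the first whitespace, duplicate ids and
#' non-IUPAC characters are errors.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read as BStringSet first so a clear error names the offending record
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA record id: ", dup[1L])
  seqs <- toupper(as.character(raw))
  ok <- grepl("^[ACGTRYSWKMBDHVN]*$", seqs)
  if (any(!ok)) {
    stop("non-IUPAC characters in FASTA record '", ids[which(!ok)[1L]], "'")
  }
  stats::setNames(Biostrings::DNAStringSet(seqs), ids)
}

#' Name an enhancer by gene and distance from the TSS
#'
#' Enhancers are named `<gene><sign><d>` where `d` is the distance from the
#' enhancer midpoint to the gene's transcriptional start site, rounded to
#' the nearest kilobase (ties away from zero). The sign is `-` when the
#' enhancer lies upstream of the TSS in the direction of transcription and
#' `+` when downstream; a zero-kb distance renders as `+0`. An enhancer
#' whose midpoint is 112 kb upstream of the Efnb2 TSS is thus `Efnb2-112`.
#'
#' @param gene Gene symbol used as the name stem.
#' @param tss_pos TSS position, 0-based (a width-1 anchor).
#' @param gene_strand `"+"` or `"-"`, the direction of transcription.
#' @param enhancer `GRanges` of length 1 (or a numeric `c(start0, end0)`
#'   0-based half-open pair) giving the enhancer span.
#' @param tss_seq,enh_seq Optional sequence names; when both are given they
#'   must agree.
#' @return The enhancer name, a character scalar.
#' @export
name_enhancer <- function(gene, tss_pos, gene_strand, enhancer,
                          tss_seq = NULL, enh_seq = NULL) {
  stopifnot(gene_strand %in% c("+", "-"))
  if (methods::is(enhancer, "GRanges")) {
    stopifnot(length(enhancer) == 1L)
    enh_seq <- enh_seq %||% as.character(GenomicRanges::seqnames(enhancer))
    span0 <- c(GenomicRanges::start(enhancer) - 1L, GenomicRanges::end(enhancer))
  } else {
    stopifnot(is.numeric(enhancer), length(enhancer) == 2L, enhancer[1] < enhancer[2])
    span0 <- enhancer
  }
  if (!is.null(tss_seq) && !is.null(enh_seq) && tss_seq != enh_seq) {
    stop("enhancer and TSS anchor are on different sequences: ",
         enh_seq, " vs ", tss_seq)
  }
  mid <- (span0[1] + span0[2]) / 2
  delta <- mid - tss_pos                      # bp, + = rightwards of TSS
  if (gene_strand == "-") delta <- -delta     # orient by transcription
  kb <- sign(delta) * floor(abs(delta) / 1000 + 0.5)  # ties away from zero
  sign_chr <- if (kb < 0) "-" else "+"
  paste0(gene, sign_chr, abs(kb))
}

#' Read an orthology block map
#'
#' A tab-separated table mapping source-species blocks to target-species
#' blocks (columns `src_seq, src_start, src_end, tgt_seq, tgt_start,
#' tgt_end`, 0-based half-open). This explicit block map stands in for
#' browser-alignment liftover between species.
#'
#' @param path Path to the TSV.
#' @return A data.frame with the six columns above, validated.
#' @export
read_orthology <- function(path) {
  map <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("src_seq", "src_start", "src_end", "tgt_seq", "tgt_start", "tgt_end")
  if (!all(need %in% names(map))) {
    stop("orthology map must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(map) && any(map$src_start >= map$src_end | map$tgt_start >= map$tgt_end)) {
    stop("orthology map contains zero- or negative-width blocks")
  }
  map
}

#' Map an interval to the other species through an orthology block map
#'
#' For every block overlapping the query, the overlapping portion is
#' projected linearly into the block's target span (so a query covering
#' half a source block maps to the corresponding half of the target
#' block). Returns `NULL` when the query hits no block (the region is
#' unmappable).
#'
#' @param gr `GRanges` of length 1 (source species).
#' @param orthology Block map from [read_orthology()].
#' @return A `GRanges` of projected target spans, or `NULL`.
#' @export
map_via_orthology <- function(gr, orthology) {
  stopifnot(methods::is(gr, "GRanges"), length(gr) == 1L)
  if (nrow(orthology) == 0L) return(NULL)
  src <- GenomicRanges::GRanges(orthology$src_seq,
                                IRanges::IRanges(orthology$src_start + 1, orthology$src_end))
  hit <- suppressWarnings(GenomicRanges::findOverlaps(gr, src))
  if (length(hit) == 0L) return(NULL)
  j <- S4Vectors::subjectHits(hit)
  q0 <- GenomicRanges::start(gr) - 1L; q1 <- GenomicRanges::end(gr)
  s0 <- orthology$src_start[j]; s1 <- orthology$src_end[j]
  t0 <- orthology$tgt_start[j]; t1 <- orthology$tgt_end[j]
  i0 <- pmax(q0, s0); i1 <- pmin(q1, s1)        # overlap within each block
  scale <- (t1 - t0) / (s1 - s0)
  p0 <- t0 + floor((i0 - s0) * scale)
  p1 <- t0 + ceiling((i1 - s0) * scale)
  p1 <- pmax(p1, p0 + 1)                        # keep >= 1 bp
  GenomicRanges::GRanges(orthology$tgt_seq[j],
                         IRanges::IRanges(p0 + 1, p1))
}

#' Read a putative/validated enhancer table
#'
#' Tab-separated with header; expected columns include `name`, `species`,
#' `seq_id`, `start`, `end` (0-based half-open), `strand`, `gene`, and the
#' optional class labels `in_vivo_class` and `in_silico_class`.
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_enhancer_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "seq_id", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("enhancer table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) && any(tab$start >= tab$end)) {
    stop("enhancer table contains zero- or negative-width intervals")
  }
  tab
}

#' @rdname read_enhancer_table
#' @param tab Enhancer table (data.frame with `seq_id`, `start`, `end`).
#' @return For `enhancer_granges`, a named `GRanges` of the enhancer spans.
#' @export
enhancer_granges <- function(tab) {
  gr <- GenomicRanges::GRanges(tab$seq_id,
                               IRanges::IRanges(tab$start + 1, tab$end))
  names(gr) <- tab$name
  gr
}
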