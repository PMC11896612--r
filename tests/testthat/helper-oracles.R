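# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T", "N"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_iupac_match <- function(window, consensus) {
  w <- strsplit(window, "")[[1]]
  k <- strsplit(consensus, "")[[1]]
  all(vapply(seq_along(k), function(i) w[i] %in% IUPAC_SETS[[k[i]]],
             logical(1)))
}

# brute-force both-strand window scan; returns 0-based half-open hits
oracle_scan <- function(sequence, consensus) {
  L <- nchar(sequence); w <- nchar(consensus)
  out <- data.frame(start = integer(), end = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  if (L < w) return(out)
  for (s in 0:(L - w)) {
    win <- substr(sequence, s + 1, s + w)
    if (oracle_iupac_match(win, consensus)) {
      out <- rbind(out, data.frame(start = s, end = s + w, strand = "+"))
    }
    if (oracle_iupac_match(oracle_revcomp(win), consensus)) {
      out <- rbind(out, data.frame(start = s, end = s + w, strand = "-"))
    }
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_granges <- function(n, chrom = "chr1", max_pos = 10000,
                           max_len = 300) {
  s <- sample.int(max_pos, n, replace = TRUE)
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(s, s + sample.int(max_len, n, replace = TRUE)))
}

# quadratic all-pairs >=1 bp overlap oracle on 0-based half-open spans
oracle_any_overlap <- function(a_start, a_end, b_start, b_end) {
  vapply(seq_along(a_start), function(i) {
    any(a_start[i] < b_end & b_start < a_end[i])
  }, logical(1))
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "artenh", mustWork = TRUE)
}

STUDY_DATASETS <- c(H_DNaseI = "human", H_histone = "human",
                    M_artery_ATAC = "mouse", M_retina_ATAC = "mouse",
                    M_E11_p300 = "mouse")

# evidence data.frame in the shape collect_mark_evidence() returns
evidence_frame <- function(present) {
  data.frame(dataset_id = names(STUDY_DATASETS),
             species = unname(STUDY_DATASETS),
             present = present, nonspecific = FALSE, note = "",
             stringsAsFactors = FALSE)
}
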