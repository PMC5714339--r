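# Independent oracles and tiny fixture builders, written without reference
# to the implementation paths they check.

suppressPackageStartupMessages({
  library(dplyr)
  library(tidyr)
  library(tibble)
  library(withr)
})

# Brute-force IUPAC scan: position-by-position comparison at every offset,
# both strands, reverse-strand hits reported in forward coordinates.
oracle_scan <- function(sequence, iupac) {
  meaning <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  pat <- strsplit(toupper(iupac), "")[[1]]
  L <- length(seq_chars); k <- length(pat)
  hits <- list()
  for (s in seq_len(max(L - k + 1L, 0L))) {
    window <- seq_chars[s:(s + k - 1L)]
    fwd_ok <- all(vapply(seq_len(k),
                         function(j) window[j] %in% meaning[[pat[j]]],
                         logical(1)))
    # reverse-strand: pattern read 5'->3' on the reverse strand occupies
    # forward positions s..s+k-1 when revcomp(pattern) matches the window
    rc <- rev(unname(comp[pat]))
    rev_ok <- all(vapply(seq_len(k), function(j) {
      allowed <- meaning[[pat[k - j + 1L]]]
      window[j] %in% unname(comp[allowed])
    }, logical(1)))
    if (fwd_ok) hits[[length(hits) + 1L]] <-
        data.frame(start = s, end = s + k - 1L, strand = "forward")
    if (rev_ok) hits[[length(hits) + 1L]] <-
        data.frame(start = s, end = s + k - 1L, strand = "reverse")
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  do.call(rbind, hits)
}

# Textbook chi-square statistic for a 2x2 table, Sum (O - E)^2 / E.
oracle_chi2 <- function(m) {
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - expected)^2 / expected)
}

# Column base-count consensus oracle: per column, the IUPAC code of all
# bases at frequency >= threshold, via a direct 15-entry lookup.
oracle_consensus <- function(sites, threshold) {
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  mat <- do.call(rbind, strsplit(sites, ""))
  out <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    freq <- table(mat[, j]) / nrow(mat)
    keep <- sort(names(freq)[freq >= threshold])
    out[j] <- codes[[paste(keep, collapse = "")]]
  }
  paste(out, collapse = "")
}

# Build a tidy peak tibble for one sample from a named vector of heights
# (names = insert residue indices), plus a standard channel.
make_sample_peaks <- function(heights, condition = "BSA",
                              concentration = 600, replicate = 1L,
                              labeled_strand = "forward",
                              subfragment_id = "SF1", prefix = 69,
                              suffix = 48, insert_length = NULL,
                              standard_heights = c(40, 50, 60)) {
  residues <- as.integer(names(heights))
  offset <- if (labeled_strand == "reverse") suffix else prefix
  signal <- tibble::tibble(
    subfragment_id = subfragment_id, condition = condition,
    concentration = concentration, replicate = as.integer(replicate),
    labeled_strand = labeled_strand, channel = "signal",
    called_size = offset + residues, height = unname(heights))
  standard <- tibble::tibble(
    subfragment_id = subfragment_id, condition = condition,
    concentration = concentration, replicate = as.integer(replicate),
    labeled_strand = labeled_strand, channel = "standard",
    called_size = seq(100, 300, length.out = length(standard_heights)),
    height = standard_heights)
  dplyr::bind_rows(signal, standard)
}

# A small noiseless simulation configuration for exact end-to-end checks.
noiseless_config <- function(...) {
  simulation_config(replicate_cv = 0, dropout = 0, size_jitter_sd = 0,
                    cut_rate_sdlog = 0.5, ...)
}

# Random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
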