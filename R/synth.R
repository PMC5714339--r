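# Synthetic-experiment generator: random fragments with planted protected
# sites, and Peak Scanner-style peak tables with the statistical structure
# the analysis assumes (per-position cut-rate heterogeneity, multiplicative
# replicate noise, dropout, sub-bp size-calling jitter, and a size-standard
# channel).

#' Default planted protected sites
#'
#' Six disjoint sites spread over a 1300 bp region, each at least 9 bp long
#' (the shortest footprint the caller is asked to resolve), carrying a DBE
#' core motif, protection factor 4, visible on both strands.
#'
#' @param region_length Region length (default 1300).
#' @return Tibble `start`, `length`, `end`, `motif`, `protection_factor`,
#'   `strand_visibility`.
#' @export
default_planted_sites <- function(region_length = 1300) {
  tibble(
    start = c(80L, 260L, 480L, 700L, 950L, 1150L),
    length = c(12L, 16L, 9L, 20L, 14L, 12L),
    motif = c("TTGTTT", "TTATTT", "TTGTTT", "TTGTTT", "TTATTT", "TTGTTT"),
    protection_factor = 4,
    strand_visibility = "both"
  ) %>%
    mutate(end = .data$start + .data$length - 1L, .after = "length")
}

#' Simulation configuration
#'
#' Defaults mirror the study design: a 1300 bp region covered by overlapping
#' 300-500 bp subfragments sharing 69 leading / 48 trailing vector residues,
#' five replicates of each of the four binding conditions (BSA and FOXO at
#' 600 and 1200 nM) per labeled strand, log-normal per-position cut-rate
#' heterogeneity (DNase cutting rates vary along any sequence), 10%
#' multiplicative replicate noise, 5% peak dropout, sub-bp size-calling
#' jitter, and an 18-peak size-standard channel.
#'
#' @param region_length Region length in bp.
#' @param subfragments Optional tibble `start`, `length`; default tiles the
#'   region with `subfragment_length` bp fragments overlapping by
#'   `subfragment_overlap`.
#' @param subfragment_length,subfragment_overlap Tiling parameters
#'   (defaults 400 and 100 bp).
#' @param sites Planted sites tibble ([default_planted_sites()]); columns
#'   `start`, `length`, `motif`, `protection_factor` (>= 1),
#'   `strand_visibility` (`forward`/`reverse`/`both`).
#' @param replicates Replicates per sample (default 5).
#' @param cut_rate_sdlog Log-normal sd of per-position cleavage propensity
#'   (default 0.5).
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise (default 0.10).
#' @param dropout Per-peak dropout probability (default 0.05).
#' @param size_jitter_sd Gaussian sd of size calling in bp (default 0.08;
#'   fragment-analysis size calling is sub-bp precise at these lengths).
#' @param vector_prefix_len,vector_suffix_len Shared vector residues
#'   (69/48 bp).
#' @param n_standard_peaks,standard_size_range Size-standard channel
#'   geometry (default 18 peaks over 20-600 bp, LIZ-style).
#' @param standard_height,base_height Expected heights (arbitrary
#'   fluorescence units).
#' @param max_gap Caller clustering gap used to enforce the planted-site
#'   spacing invariant (sites must be separated by at least `2 * max_gap`).
#' @param seed Optional integer seed; fixed seed implies bit-identical
#'   output.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(region_length = 1300,
                              subfragments = NULL,
                              subfragment_length = 400,
                              subfragment_overlap = 100,
                              sites = default_planted_sites(region_length),
                              replicates = 5,
                              cut_rate_sdlog = 0.5,
                              replicate_cv = 0.10,
                              dropout = 0.05,
                              size_jitter_sd = 0.08,
                              vector_prefix_len = 69,
                              vector_suffix_len = 48,
                              n_standard_peaks = 18,
                              standard_size_range = c(20, 600),
                              standard_height = 500,
                              base_height = 1000,
                              max_gap = 4,
                              seed = NULL) {
  if (is.null(subfragments)) {
    starts <- seq(1L, region_length,
                  by = subfragment_length - subfragment_overlap)
    starts <- starts[starts + subfragment_length - 1L <= region_length]
    if (max(starts) + subfragment_length - 1L < region_length) {
      starts <- c(starts, region_length - subfragment_length + 1L)
    }
    subfragments <- tibble(start = as.integer(starts),
                           length = as.integer(subfragment_length))
  }
  if (!"end" %in% names(sites)) {
    sites <- sites %>% mutate(end = .data$start + .data$length - 1L)
  }
  sites <- sites %>% arrange(.data$start)
  if (nrow(sites) > 1L) {
    gaps <- sites$start[-1] - sites$end[-nrow(sites)] - 1L
    if (any(gaps < 2 * max_gap)) {
      abort(paste0("planted sites must be disjoint with spacing >= 2*max_gap",
                   " (= ", 2 * max_gap, " bp)"),
            class = "footcall_config_error")
    }
  }
  if (any(sites$protection_factor < 1)) {
    abort("protection_factor must be >= 1", class = "footcall_config_error")
  }
  if (any(sites$end > region_length)) {
    abort("planted site extends past the region end",
          class = "footcall_config_error")
  }
  stopifnot(dropout >= 0, dropout <= 1, replicate_cv >= 0,
            size_jitter_sd >= 0, replicates >= 1)
  structure(
    list(region_length = as.integer(region_length),
         subfragments = subfragments, sites = sites,
         replicates = as.integer(replicates),
         cut_rate_sdlog = cut_rate_sdlog, replicate_cv = replicate_cv,
         dropout = dropout, size_jitter_sd = size_jitter_sd,
         vector_prefix_len = as.integer(vector_prefix_len),
         vector_suffix_len = as.integer(vector_suffix_len),
         n_standard_peaks = as.integer(n_standard_peaks),
         standard_size_range = standard_size_range,
         standard_height = standard_height, base_height = base_height,
         max_gap = max_gap, seed = seed),
    class = "simulation_config")
}

#' Simulate a region sequence with planted motifs and cut rates
#'
#' Random A/C/G/T background with each site's motif written at the site
#' start (reverse-complemented into the forward sequence when the site is
#' visible only on the reverse strand), plus seeded log-normal per-position
#' per-strand cleavage propensities. The returned truth records the planted
#' intervals and motif coordinates exactly.
#'
#' @param config [simulation_config()].
#' @return List of class `synthetic_region`: `sequence`, `sites`, `motifs`
#'   (truth tibbles), `cut_rates` (2 x region_length matrix, rows forward /
#'   reverse), `config`.
#' @export
simulate_fragment <- function(config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$region_length
  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  motifs <- list()
  for (i in seq_len(nrow(config$sites))) {
    s <- config$sites[i, ]
    motif <- toupper(s$motif)
    strand <- if (identical(s$strand_visibility, "reverse")) "reverse" else "forward"
    embedded <- if (strand == "reverse") revcomp(motif) else motif
    idx <- s$start:(s$start + nchar(motif) - 1L)
    seq_chars[idx] <- strsplit(embedded, "")[[1]]
    motifs[[i]] <- tibble(motif = motif, start = s$start,
                          end = as.integer(s$start + nchar(motif) - 1L),
                          strand = strand)
  }

  cut_rates <- matrix(rlnorm(2L * L, meanlog = 0,
                             sdlog = config$cut_rate_sdlog),
                      nrow = 2, dimnames = list(c("forward", "reverse"), NULL))

  structure(
    list(sequence = paste(seq_chars, collapse = ""),
         sites = config$sites,
         motifs = purrr::list_rbind(motifs),
         cut_rates = cut_rates,
         config = config),
    class = "synthetic_region")
}

#' Simulate Peak Scanner-style peak tables for all samples
#'
#' For every subfragment, labeled strand, condition, concentration and
#' replicate: the expected BSA peak height at residue i is proportional to
#' the cleavage propensity at that position; the expected FOXO height is
#' divided by the site's protection factor at protected, strand-visible
#' positions (a protection factor of 1 everywhere gives an expected
#' BSA/FOXO ratio of 1 - no protection). Each realized peak gets
#' multiplicative log-normal noise (unit mean, CV `replicate_cv`), Bernoulli
#' dropout, and Gaussian jitter of the called size around
#' `vector_offset + residue`. A size-standard channel is emitted per sample
#' with independent noise.
#'
#' @param sim `synthetic_region` from [simulate_fragment()].
#' @param config Configuration (defaults to the one inside `sim`).
#' @return List: `peaks` (tidy peak tibble across all samples), `fragments`
#'   (fragment tibble for [residue_profiles()]), `truth` (`sites`,
#'   `motifs`).
#' @export
simulate_peak_tables <- function(sim, config = sim$config) {
  if (!is.null(config$seed)) set.seed(config$seed + 104729L)
  sdlog <- sqrt(log(1 + config$replicate_cv^2))

  fragments <- config$subfragments %>%
    mutate(
      subfragment_id = paste0("SF", dplyr::row_number()),
      sequence = substr(sim$sequence, .data$start,
                        .data$start + .data$length - 1L),
      insert_length = .data$length,
      vector_prefix_len = config$vector_prefix_len,
      vector_suffix_len = config$vector_suffix_len,
      region_offset = .data$start
    ) %>%
    select("subfragment_id", "sequence", "insert_length",
           "vector_prefix_len", "vector_suffix_len", "region_offset")

  # per-position protection factor per strand
  pf <- matrix(1, nrow = 2, ncol = config$region_length,
               dimnames = list(c("forward", "reverse"), NULL))
  for (i in seq_len(nrow(config$sites))) {
    s <- config$sites[i, ]
    idx <- s$start:s$end
    if (s$strand_visibility %in% c("both", "forward")) {
      pf["forward", idx] <- s$protection_factor
    }
    if (s$strand_visibility %in% c("both", "reverse")) {
      pf["reverse", idx] <- s$protection_factor
    }
  }

  grid <- expand_grid(
    subfragment_id = fragments$subfragment_id,
    labeled_strand = c("forward", "reverse"),
    condition = c("BSA", "FOXO"),
    concentration = c(600, 1200),
    replicate = seq_len(config$replicates)
  )

  std_sizes <- round(seq(config$standard_size_range[1],
                         config$standard_size_range[2],
                         length.out = config$n_standard_peaks), 1)

  peaks <- purrr::pmap(grid, function(subfragment_id, labeled_strand,
                                      condition, concentration, replicate) {
    frag <- fragments[fragments$subfragment_id == subfragment_id, ]
    L <- frag$insert_length
    i <- seq_len(L)
    region_pos <- if (labeled_strand == "forward") {
      frag$region_offset + i - 1L
    } else {
      frag$region_offset + (L - i) # residue i counted from insert 3' end
    }
    offset <- if (labeled_strand == "forward") frag$vector_prefix_len else frag$vector_suffix_len

    expected <- config$base_height * sim$cut_rates[labeled_strand, region_pos]
    if (condition == "FOXO") {
      expected <- expected / pf[labeled_strand, region_pos]
    }
    noise <- if (sdlog > 0) {
      rlnorm(L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, L)
    keep <- if (config$dropout > 0) runif(L) >= config$dropout else rep(TRUE, L)
    jitter <- if (config$size_jitter_sd > 0) {
      rnorm(L, 0, config$size_jitter_sd)
    } else rep(0, L)

    signal <- tibble(
      subfragment_id = subfragment_id, condition = condition,
      concentration = concentration, replicate = as.integer(replicate),
      labeled_strand = labeled_strand, channel = "signal",
      called_size = offset + i + jitter,
      height = expected * noise
    )[keep, ]

    std_noise <- if (sdlog > 0) {
      rlnorm(length(std_sizes), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(std_sizes))
    standard <- tibble(
      subfragment_id = subfragment_id, condition = condition,
      concentration = concentration, replicate = as.integer(replicate),
      labeled_strand = labeled_strand, channel = "standard",
      called_size = std_sizes,
      height = config$standard_height * std_noise
    )
    bind_rows(signal, standard)
  }) %>% purrr::list_rbind()

  list(peaks = peaks, fragments = fragments,
       truth = list(sites = config$sites, motifs = sim$motifs))
}

#' Simulate a complete synthetic footprinting experiment
#'
#' Convenience wrapper: [simulate_fragment()] then [simulate_peak_tables()].
#'
#' @param config [simulation_config()].
#' @return As [simulate_peak_tables()], plus `sequence` and `cut_rates`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  sim <- simulate_fragment(config)
  out <- simulate_peak_tables(sim, config)
  out$sequence <- sim$sequence
  out$cut_rates <- sim$cut_rates
  out
}

#' Compare called footprints against planted truth
#'
#' A planted site counts as recovered when some called footprint matches
#' both of its boundaries within `boundary_tol` bp; a called footprint that
#' overlaps no planted site is a false footprint.
#'
#' @param called Footprint tibble (`start`, `end`).
#' @param truth Planted-site tibble (`start`, `end`).
#' @param boundary_tol Boundary tolerance in bp (default 2).
#' @return One-row tibble `n_true`, `n_called`, `n_recovered`, `recovery`,
#'   `n_false`, `mean_boundary_error`.
#' @export
evaluate_recovery <- function(called, truth, boundary_tol = 2) {
  n_true <- nrow(truth); n_called <- nrow(called)
  if (n_true == 0L) {
    return(tibble(n_true = 0L, n_called = n_called, n_recovered = 0L,
                  recovery = NA_real_, n_false = n_called,
                  mean_boundary_error = NA_real_))
  }
  rec <- logical(n_true); berr <- rep(NA_real_, n_true)
  for (i in seq_len(n_true)) {
    if (n_called == 0L) break
    d_start <- abs(called$start - truth$start[i])
    d_end <- abs(called$end - truth$end[i])
    ok <- d_start <= boundary_tol & d_end <= boundary_tol
    if (any(ok)) {
      rec[i] <- TRUE
      j <- which(ok)[which.min((d_start + d_end)[ok])]
      berr[i] <- (d_start[j] + d_end[j]) / 2
    }
  }
  false <- if (n_called == 0L) 0L else sum(vapply(seq_len(n_called), function(j) {
    all(pmin(called$end[j], truth$end) - pmax(called$start[j], truth$start) + 1L < 1L)
  }, logical(1)))
  tibble(n_true = n_true, n_called = n_called, n_recovered = sum(rec),
         recovery = sum(rec) / n_true, n_false = as.integer(false),
         mean_boundary_error = mean(berr, na.rm = TRUE))
}
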