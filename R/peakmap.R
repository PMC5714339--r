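# Size-to-residue mapping, standard-channel normalization and replicate
# aggregation: raw peak calls -> per-residue mean normalized heights.
#
# Geometry: every forward-labeled read shares vector_prefix_len leading vector
# residues, so insert residue i produces a cleavage product of called size
# ~ prefix + i. Reverse-labeled reads share vector_suffix_len trailing
# residues; residue j counted from the insert 3' end (on the forward strand)
# gives size ~ suffix + j, and maps back to forward-strand position
# L - j + 1.

#' Assign peaks of one sample to insert residues
#'
#' Snaps each signal-channel peak of a single sample (one condition,
#' concentration, labeled strand) to the nearest integer residue within
#' `tolerance` bp of its expected called size. At most one peak per residue
#' per replicate is kept (the tallest wins; ties warn). Peaks outside the
#' insert span are dropped and counted.
#'
#' @param peaks Signal-channel peak tibble for one sample (may span
#'   replicates); needs `called_size`, `height`, `replicate`,
#'   `labeled_strand`.
#' @param fragment One-row fragment tibble (see [labeled_fragment()]).
#' @param tolerance Maximum |called size - expected size| in bp (default 0.5).
#' @return Tibble with `replicate`, `position` (forward-strand insert
#'   coordinate), `height`; attribute `n_dropped` counts unassignable peaks,
#'   so `nrow(result) + n_dropped == nrow(peaks)` minus tie losers is
#'   reported via attribute `n_tie_losers`.
#' @export
assign_peaks_to_residues <- function(peaks, fragment, tolerance = 0.5) {
  stopifnot(nrow(fragment) == 1L)
  strand <- unique(peaks$labeled_strand)
  if (length(strand) > 1L) {
    abort("assign_peaks_to_residues expects peaks from a single labeled strand",
          class = "footcall_validation_error")
  }
  L <- fragment$insert_length
  offset <- if (identical(strand, "reverse")) fragment$vector_suffix_len else fragment$vector_prefix_len

  resid_raw <- peaks$called_size - offset
  resid <- round(resid_raw)
  ok <- abs(resid_raw - resid) <= tolerance & resid >= 1 & resid <= L
  n_dropped <- sum(!ok)

  kept <- peaks[ok, , drop = FALSE]
  kept$residue <- resid[ok]
  kept$position <- if (identical(strand, "reverse")) {
    as.integer(L - kept$residue + 1L)
  } else {
    as.integer(kept$residue)
  }

  before <- nrow(kept)
  keep_cols <- intersect(c("replicate", "position", "height", "norm_height"),
                         names(kept))
  # tallest peak per (replicate, residue) wins a tie
  ord <- order(kept$replicate, kept$position, -kept$height)
  kept <- kept[ord, , drop = FALSE]
  out <- kept[!duplicated(kept[c("replicate", "position")]), keep_cols,
              drop = FALSE] %>% as_tibble()
  n_ties <- before - nrow(out)
  if (n_ties > 0L) {
    warn(paste0(n_ties, " peak(s) snapped to an already-occupied residue; ",
                "kept the taller peak"))
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_tie_losers") <- n_ties
  out
}

#' Normalize peak heights by the size-standard channel
#'
#' Divides every signal-channel height of a sample by that sample's
#' normalization factor: the mean height of all standard-channel peaks,
#' pooled across the sample's replicates. Samples are keyed by
#' (`subfragment_id`, `condition`, `concentration`, `labeled_strand`).
#'
#' @param peaks Peak tibble containing both channels.
#' @param min_standard_peaks Minimum standard peaks per sample (default 3).
#' @return List with `peaks` (signal rows gaining `norm_height`) and
#'   `factors` (one row per sample: key columns + `factor`, `n_standard`).
#' @export
normalize_heights <- function(peaks, min_standard_peaks = 3L) {
  key <- c("subfragment_id", "condition", "concentration", "labeled_strand")
  std <- peaks %>% filter(.data$channel == "standard")
  sig <- peaks %>% filter(.data$channel == "signal")

  factors <- std %>%
    group_by(across(all_of(key))) %>%
    summarise(factor = mean(.data$height), n_standard = n(), .groups = "drop")

  missing <- sig %>%
    distinct(across(all_of(key))) %>%
    anti_join(factors, by = key)
  low <- factors %>% filter(.data$n_standard < min_standard_peaks)
  if (nrow(missing) > 0L || nrow(low) > 0L) {
    abort(paste0("sample(s) without at least ", min_standard_peaks,
                 " size-standard peaks; supply standard-channel peaks, ",
                 "inject a factor, or run with normalize = FALSE"),
          class = "footcall_normalization_error")
  }

  sig <- sig %>%
    left_join(factors %>% select(all_of(key), "factor"), by = key) %>%
    mutate(norm_height = .data$height / .data$factor) %>%
    select(-"factor")
  list(peaks = sig, factors = factors)
}

#' Aggregate replicate residue maps into a residue profile
#'
#' Per residue, the mean over the replicates in which a peak was observed
#' (absence contributes nothing to the mean: it can mean either no cleavage
#' or dropout). Positions observed in fewer than
#' `min_replicates_per_position` replicates are flagged low-support; a
#' position absent from every replicate is emitted with `NA` mean and
#' `n_replicates = 0` so that the profile covers `1..insert_length` exactly
#' once.
#'
#' @param assigned Tibble from [assign_peaks_to_residues()] with a height
#'   column (raw or normalized) named by `value`.
#' @param insert_length Insert length L.
#' @param min_replicates Minimum number of replicate maps required
#'   (default 3).
#' @param min_replicates_per_position Support flag threshold (default 2).
#' @param value Name of the height column to average (default
#'   `"norm_height"`, falling back to `"height"`).
#' @return Tibble `position`, `mean_norm_height`, `n_replicates`,
#'   `low_support`.
#' @export
aggregate_replicates <- function(assigned, insert_length,
                                 min_replicates = 3L,
                                 min_replicates_per_position = 2L,
                                 value = NULL) {
  if (is.null(value)) {
    value <- if ("norm_height" %in% names(assigned)) "norm_height" else "height"
  }
  n_reps <- dplyr::n_distinct(assigned$replicate)
  if (n_reps < min_replicates) {
    abort(paste0("only ", n_reps, " replicate map(s) present; need at least ",
                 min_replicates),
          class = "footcall_replicate_error")
  }
  agg <- assigned %>%
    group_by(.data$position) %>%
    summarise(mean_norm_height = mean(.data[[value]]),
              n_replicates = dplyr::n_distinct(.data$replicate),
              .groups = "drop")
  tibble(position = seq_len(insert_length)) %>%
    left_join(agg, by = "position") %>%
    mutate(
      n_replicates = as.integer(dplyr::coalesce(.data$n_replicates, 0L)),
      low_support = .data$n_replicates < min_replicates_per_position
    )
}

#' Per-residue mean normalized profiles for all samples
#'
#' Full first half of the analysis: standard-channel normalization, peak to
#' residue assignment per replicate, and replicate aggregation, for every
#' (subfragment, strand, condition, concentration) sample in `peaks`.
#'
#' @param peaks Peak tibble (both channels) as from [read_peak_table()] or
#'   [simulate_experiment()].
#' @param fragments Fragment tibble (one row per subfragment), as from
#'   [read_region_fasta()].
#' @param params Caller parameters, see [caller_params()]; uses `tolerance`,
#'   `min_replicates`, `min_replicates_per_position`.
#' @param normalize Divide by the standard-channel factor (default TRUE).
#' @return Tibble with one row per residue per sample: `subfragment_id`,
#'   `strand`, `condition`, `concentration`, `position`, `region_position`,
#'   `mean_norm_height`, `n_replicates`, `low_support`.
#' @export
residue_profiles <- function(peaks, fragments, params = caller_params(),
                             normalize = TRUE) {
  validate_peaks(peaks)
  if (normalize) {
    norm <- normalize_heights(peaks)
    sig <- norm$peaks
    value <- "norm_height"
  } else {
    sig <- peaks %>% filter(.data$channel == "signal")
    value <- "height"
  }

  groups <- sig %>%
    distinct(.data$subfragment_id, .data$labeled_strand, .data$condition,
             .data$concentration)

  purrr::pmap(groups, function(subfragment_id, labeled_strand, condition,
                               concentration) {
    frag <- fragments[fragments$subfragment_id == subfragment_id, , drop = FALSE]
    if (nrow(frag) != 1L) {
      abort(paste0("no unique fragment record for subfragment '",
                   subfragment_id, "'"),
            class = "footcall_validation_error")
    }
    sample <- sig %>%
      filter(.data$subfragment_id == .env$subfragment_id,
             .data$labeled_strand == .env$labeled_strand,
             .data$condition == .env$condition,
             .data$concentration == .env$concentration)
    assigned <- assign_peaks_to_residues(sample, frag,
                                         tolerance = params$tolerance)
    prof <- aggregate_replicates(
      assigned, frag$insert_length,
      min_replicates = params$min_replicates,
      min_replicates_per_position = params$min_replicates_per_position,
      value = value)
    prof %>%
      mutate(subfragment_id = subfragment_id,
             strand = labeled_strand,
             condition = condition,
             concentration = concentration,
             region_position = as.integer(frag$region_offset + .data$position - 1L),
             .before = 1L)
  }) %>%
    purrr::list_rbind() %>%
    relocate("subfragment_id", "strand", "condition", "concentration",
             "position", "region_position")
}
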