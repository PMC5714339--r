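# End-to-end footprint calling and broom/ggplot2-style methods for the
# fitted result.

#' Call footprints from peak tables
#'
#' The full analysis: standard-channel normalization, size-to-residue
#' assignment, replicate aggregation ([residue_profiles()]), BSA/FOXO
#' protection ratios at both concentrations ([protection_track()]),
#' protected-residue clustering per strand ([cluster_footprints()]), strand
#' reconciliation ([reconcile_strands()]), and the inside/outside-footprint
#' heterogeneity test ([heterogeneity_test()]).
#'
#' @param peaks Tidy peak tibble (both channels, all samples), from
#'   [read_peak_table()] or [simulate_experiment()].
#' @param fragments Fragment tibble, from [read_region_fasta()] or the
#'   simulator.
#' @param params [caller_params()].
#' @param region_length Region length in bp; default inferred from the
#'   fragment geometry.
#' @param normalize Normalize against the size-standard channel
#'   (default TRUE).
#' @return Object of class `footprint_call` with elements `footprints`,
#'   `track`, `profiles`, `protected`, `heterogeneity`, `params`,
#'   `region_length`. Use [tidy()], [glance()], [autoplot()].
#' @export
call_footprints <- function(peaks, fragments, params = caller_params(),
                            region_length = NULL, normalize = TRUE) {
  if (is.null(region_length)) {
    region_length <- max(fragments$region_offset + fragments$insert_length - 1L)
  }
  profiles <- residue_profiles(peaks, fragments, params, normalize = normalize)
  track <- protection_track(profiles, params)

  protected <- track %>%
    filter(.data$protected) %>%
    select("strand", position = "region_position")

  intervals <- function(str) {
    cluster_footprints(protected$position[protected$strand == str], params)
  }
  footprints <- reconcile_strands(intervals("forward"), intervals("reverse"),
                                  params)
  het <- heterogeneity_test(footprints, unique(protected$position),
                            region_length)

  structure(
    list(footprints = footprints, track = track, profiles = profiles,
         protected = protected, heterogeneity = het, params = params,
         region_length = as.integer(region_length)),
    class = "footprint_call")
}

#' @export
print.footprint_call <- function(x, ...) {
  cat("Footprint call over", x$region_length, "bp:",
      nrow(x$footprints), "footprint(s),",
      sum(x$footprints$length), "bp footprinted,",
      nrow(x$protected), "protected residue calls\n")
  if (nrow(x$footprints) > 0L) print(x$footprints, n = 5)
  invisible(x)
}

#' Tidy the footprints of a footprint call
#'
#' @param x `footprint_call` object.
#' @param ... Unused.
#' @return The footprint tibble (`name`, `start`, `end`, `length`,
#'   `defining_strand`) plus TSS-relative coordinates.
#' @export
tidy.footprint_call <- function(x, ...) {
  x$footprints %>%
    mutate(tss_start = tss_relative(.data$start, x$region_length),
           tss_end = tss_relative(.data$end, x$region_length))
}

#' One-row summary of a footprint call
#'
#' @param x `footprint_call` object.
#' @param ... Unused.
#' @return Tibble with `n_footprints`, `total_footprinted_bp`,
#'   `n_protected_residues`, `chi2`, `p_heterogeneity`.
#' @export
glance.footprint_call <- function(x, ...) {
  tibble(
    n_footprints = nrow(x$footprints),
    total_footprinted_bp = sum(x$footprints$length),
    n_protected_residues = length(unique(x$protected$position)),
    chi2 = x$heterogeneity$chi2,
    p_heterogeneity = x$heterogeneity$p_value
  )
}

#' Plot the protection track and called footprints
#'
#' Step plot of the per-residue BSA/FOXO ratio (the larger of the two
#' concentrations), faceted by strand, with called footprints shaded and
#' the protection threshold drawn.
#'
#' @param object `footprint_call` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.footprint_call <- function(object, ...) {
  track <- object$track %>%
    mutate(best_ratio = pmax(.data$ratio_600, .data$ratio_1200, na.rm = TRUE))
  fp <- object$footprints
  p <- ggplot(track, aes(x = .data$region_position, y = .data$best_ratio))
  if (nrow(fp) > 0L) {
    p <- p + geom_rect(data = fp,
                       aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
                       ymin = -Inf, ymax = Inf, fill = "grey85",
                       inherit.aes = FALSE)
  }
  p +
    geom_step(na.rm = TRUE) +
    geom_hline(yintercept = object$params$ratio_threshold,
               linetype = "dashed", colour = "firebrick") +
    facet_wrap(~strand, ncol = 1) +
    labs(x = "region position (bp, distal to proximal)",
         y = "BSA/FOXO protection ratio",
         title = "Protection ratios and called footprints") +
    theme_bw()
}

#' Plot motif hits along the region
#'
#' Vertical marks at motif start positions colored by pattern class, with
#' footprint extents shaded, mirroring the usual footprint-map figure.
#'
#' @param hits Annotated hits from [assign_hits_to_footprints()].
#' @param footprints Footprint tibble.
#' @param region_length Region length in bp.
#' @return A ggplot.
#' @export
plot_motif_map <- function(hits, footprints, region_length = 1300) {
  p <- ggplot()
  if (nrow(footprints) > 0L) {
    p <- p + geom_rect(data = footprints,
                       aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
                       ymin = 0, ymax = 1, fill = "grey85")
  }
  p +
    ggplot2::geom_segment(
      data = hits,
      aes(x = .data$start, xend = .data$start, colour = .data$class),
      y = 0, yend = 1) +
    ggplot2::xlim(0, region_length + 1) +
    labs(x = "region position (bp)", y = NULL, colour = "motif class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
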