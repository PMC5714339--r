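# Protection ratios, protected-residue calls, footprint clustering, strand
# reconciliation and the heterogeneity test.
#
# Footprint criteria, applied in order:
#   i.  a residue is protected iff its BSA/FOXO ratio is >= ratio_threshold at
#       either protein concentration (a ratio of 1 means no protection);
#   ii. protected residues must be clustered (gaps of unprotected residues of
#       at most max_gap bp within a cluster);
#   iii. when footprinted sequence on one strand overlaps the complementary
#        strand, the footprint extent follows the strand with the longer
#        footprinted sequence (tie -> union);
#   iv.  when the two strands are slightly offset (separation <= max_gap), the
#        footprint limits are the 5' protected residues of each strand.

#' Footprint caller parameters
#'
#' @param ratio_threshold Protection-ratio threshold, inclusive (default 2).
#' @param max_gap Maximum run of unprotected residues inside a cluster, and
#'   maximum strand offset for criterion-iv merging (default 4 bp).
#' @param min_protected_in_cluster Minimum protected residues per cluster
#'   (default 3).
#' @param min_footprint_length Minimum footprint span in bp (default 9, the
#'   shortest footprint the method is expected to resolve).
#' @param epsilon_fraction Floor for missing FOXO peaks, as a fraction of the
#'   FOXO sample's median normalized height (default 0.05).
#' @param ratio_cap Cap applied to ratios computed against the epsilon floor
#'   (default 50).
#' @param tolerance Size-to-residue snapping tolerance in bp (default 0.5).
#' @param min_replicates Minimum replicate maps per sample (default 3).
#' @param min_replicates_per_position Low-support flag threshold (default 2).
#' @param name_prefix Prefix for footprint names (default `"F"`; use the
#'   species initial to follow the field's naming).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(ratio_threshold = 2, max_gap = 4,
                          min_protected_in_cluster = 3,
                          min_footprint_length = 9,
                          epsilon_fraction = 0.05, ratio_cap = 50,
                          tolerance = 0.5, min_replicates = 3,
                          min_replicates_per_position = 2,
                          name_prefix = "F") {
  stopifnot(ratio_threshold > 0, max_gap >= 0, min_protected_in_cluster >= 1,
            min_footprint_length >= 1, epsilon_fraction > 0, ratio_cap > 0,
            tolerance > 0)
  structure(
    list(ratio_threshold = ratio_threshold, max_gap = max_gap,
         min_protected_in_cluster = min_protected_in_cluster,
         min_footprint_length = min_footprint_length,
         epsilon_fraction = epsilon_fraction, ratio_cap = ratio_cap,
         tolerance = tolerance, min_replicates = min_replicates,
         min_replicates_per_position = min_replicates_per_position,
         name_prefix = name_prefix),
    class = "caller_params")
}

#' Per-residue BSA/FOXO protection ratios
#'
#' Pairs the BSA and FOXO residue profiles of each (subfragment, strand,
#' concentration) sample and computes ratio = BSA mean / FOXO mean per
#' residue. A residue observed in BSA but missing from every FOXO replicate
#' is the strongest protection signal; its ratio is computed against an
#' epsilon floor (`epsilon_fraction` x the FOXO sample's median normalized
#' height) and capped at `ratio_cap`, flagged `foxo_missing`. A residue
#' missing from BSA has no interpretable ratio (`bsa_missing`); a residue
#' missing from both is `unobserved`.
#'
#' @param profiles Residue profiles from [residue_profiles()], containing
#'   both conditions.
#' @param params [caller_params()].
#' @return Tibble `subfragment_id`, `strand`, `concentration`, `position`,
#'   `region_position`, `ratio`, `support`.
#' @export
protection_ratio <- function(profiles, params = caller_params()) {
  need <- c("BSA", "FOXO")
  if (!all(need %in% profiles$condition)) {
    abort("profiles must contain both BSA and FOXO conditions",
          class = "footcall_validation_error")
  }
  bsa <- profiles %>% filter(.data$condition == "BSA")
  foxo <- profiles %>% filter(.data$condition == "FOXO")

  eps <- foxo %>%
    group_by(.data$subfragment_id, .data$strand, .data$concentration) %>%
    summarise(epsilon = params$epsilon_fraction *
                median(.data$mean_norm_height, na.rm = TRUE),
              .groups = "drop")

  key <- c("subfragment_id", "strand", "concentration", "position",
           "region_position")
  full_join(
    bsa %>% select(all_of(key), bsa_height = "mean_norm_height"),
    foxo %>% select(all_of(key), foxo_height = "mean_norm_height"),
    by = key) %>%
    left_join(eps, by = c("subfragment_id", "strand", "concentration")) %>%
    mutate(
      support = case_when(
        !is.na(.data$bsa_height) & !is.na(.data$foxo_height) ~ "both_observed",
        !is.na(.data$bsa_height) & is.na(.data$foxo_height) ~ "foxo_missing",
        is.na(.data$bsa_height) & !is.na(.data$foxo_height) ~ "bsa_missing",
        TRUE ~ "unobserved"),
      ratio = case_when(
        .data$support == "both_observed" ~ .data$bsa_height / .data$foxo_height,
        .data$support == "foxo_missing" ~
          pmin(.data$bsa_height / .data$epsilon, params$ratio_cap),
        TRUE ~ NA_real_)
    ) %>%
    select(all_of(key), "ratio", "support") %>%
    arrange(.data$strand, .data$concentration, .data$region_position)
}

.support_rank <- c(both_observed = 1L, foxo_missing = 2L, bsa_missing = 3L,
                   unobserved = 4L)

#' Region-level protection track across concentrations
#'
#' Lifts per-subfragment ratios to region coordinates (averaging the defined
#' ratios of overlapping subfragments), spreads the two protein
#' concentrations into `ratio_600` / `ratio_1200`, and applies criterion i:
#' a residue is protected iff its ratio reaches the threshold at either
#' concentration (inclusive) and it is not unobserved.
#'
#' @inheritParams protection_ratio
#' @return Tibble `strand`, `region_position`, `ratio_600`, `ratio_1200`,
#'   `support_600`, `support_1200`, `protected`.
#' @export
protection_track <- function(profiles, params = caller_params()) {
  ratios <- protection_ratio(profiles, params)

  region <- ratios %>%
    group_by(.data$strand, .data$concentration, .data$region_position) %>%
    summarise(
      ratio = if (all(is.na(.data$ratio))) NA_real_ else
        mean(.data$ratio, na.rm = TRUE),
      support = names(.support_rank)[min(.support_rank[.data$support])],
      .groups = "drop")

  wide <- region %>%
    pivot_wider(names_from = "concentration",
                values_from = c("ratio", "support"))
  for (col in c("ratio_600", "ratio_1200")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  for (col in c("support_600", "support_1200")) {
    if (!col %in% names(wide)) wide[[col]] <- "unobserved"
  }
  wide %>%
    mutate(protected = call_protected(.data$ratio_600, .data$ratio_1200,
                                      params$ratio_threshold)) %>%
    arrange(.data$strand, .data$region_position)
}

#' Criterion i: protected-residue call from the two concentration ratios
#'
#' @param ratio_600,ratio_1200 Ratio vectors (NA where undefined).
#' @param ratio_threshold Inclusive threshold (default 2).
#' @return Logical vector; TRUE where max(ratio_600, ratio_1200) >= threshold.
#' @export
call_protected <- function(ratio_600, ratio_1200, ratio_threshold = 2) {
  best <- pmax(ratio_600, ratio_1200, na.rm = TRUE)
  !is.na(best) & best >= ratio_threshold
}

#' Criterion ii: cluster protected residues into footprint intervals
#'
#' Greedy left-to-right grouping: consecutive protected positions join one
#' cluster while the run of unprotected residues between them is at most
#' `max_gap`. Clusters with fewer than `min_protected_in_cluster` protected
#' residues or spanning less than `min_footprint_length` bp are discarded.
#' The interval runs from the first to the last protected residue.
#'
#' @param positions Sorted unique protected positions on one strand.
#' @param params [caller_params()].
#' @return Tibble `start`, `end`, `n_protected`, `length`.
#' @export
cluster_footprints <- function(positions, params = caller_params()) {
  empty <- tibble(start = integer(), end = integer(),
                  n_protected = integer(), length = integer())
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0L) return(empty)
  gap_break <- c(FALSE, diff(positions) - 1L > params$max_gap)
  cluster <- cumsum(gap_break)
  tibble(position = positions, cluster = cluster) %>%
    group_by(.data$cluster) %>%
    summarise(start = min(.data$position), end = max(.data$position),
              n_protected = n(), .groups = "drop") %>%
    mutate(length = .data$end - .data$start + 1L) %>%
    filter(.data$n_protected >= params$min_protected_in_cluster,
           .data$length >= params$min_footprint_length) %>%
    select("start", "end", "n_protected", "length") %>%
    arrange(.data$start)
}

# Criterion iii/iv merge of one interval pair (a starts first).
# Returns list(start, end, strand) where strand is the defining strand.
.merge_pair <- function(a_start, a_end, a_strand, b_start, b_end, b_strand) {
  overlap <- min(a_end, b_end) - max(a_start, b_start) + 1L
  pair_fr <- setequal(c(a_strand, b_strand), c("forward", "reverse"))
  if (overlap >= 1L) {
    len_a <- a_end - a_start + 1L
    len_b <- b_end - b_start + 1L
    if (pair_fr && len_a != len_b) {
      # criterion iii: the longer strand defines the extent
      if (len_a > len_b) list(a_start, a_end, a_strand)
      else list(b_start, b_end, b_strand)
    } else {
      # tie between strands, or merge involving an already-reconciled
      # interval: union
      list(min(a_start, b_start), max(a_end, b_end),
           if (a_strand == b_strand) a_strand else "both")
    }
  } else {
    # criterion iv offset pair: limits = forward 5' protected residue
    # (lowest forward coordinate) and reverse 5' protected residue (highest
    # coordinate).
    if (a_strand == "forward" && b_strand == "reverse") {
      list(a_start, b_end, "both")
    } else {
      # reverse interval 5' of the forward one: the two 5' limits would not
      # bracket all protected residues, so fall back to the union.
      list(min(a_start, b_start), max(a_end, b_end), "both")
    }
  }
}

#' Criteria iii-iv: reconcile strand-specific intervals into footprints
#'
#' Overlapping forward/reverse interval pairs keep the longer interval's
#' extent (equal lengths: union). Pairs with no overlap but separated by at
#' most `max_gap` unprotected residues are merged from the forward strand's
#' 5' protected residue to the reverse strand's 5' protected residue.
#' Merging is applied transitively until the set is disjoint; single-strand
#' intervals pass through. Footprints are sorted by start and named
#' `prefix`N..`prefix`1 from the 5' (distal) to the 3' (proximal) end of the
#' forward strand, following the field's convention of numbering from the
#' promoter outwards.
#'
#' @param forward,reverse Interval tibbles (`start`, `end`) from
#'   [cluster_footprints()], both in forward-strand coordinates.
#' @param params [caller_params()].
#' @return Footprint tibble `name`, `start`, `end`, `length`,
#'   `defining_strand`.
#' @export
reconcile_strands <- function(forward, reverse, params = caller_params()) {
  iv <- bind_rows(
    forward %>% mutate(strand = "forward"),
    reverse %>% mutate(strand = "reverse")
  ) %>%
    select("start", "end", "strand") %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))

  if (nrow(iv) > 0L) {
    repeat {
      iv <- iv %>% arrange(.data$start, .data$end)
      merged <- FALSE
      for (i in seq_len(nrow(iv) - 1L)) {
        a <- iv[i, ]; b <- iv[i + 1L, ]
        gap <- b$start - a$end - 1L
        pair_fr <- setequal(c(a$strand, b$strand), c("forward", "reverse"))
        if (gap <= 0L || (pair_fr && gap <= params$max_gap)) {
          se <- .merge_pair(a$start, a$end, a$strand, b$start, b$end, b$strand)
          both <- tibble(start = as.integer(se[[1]]), end = as.integer(se[[2]]),
                         strand = se[[3]])
          iv <- bind_rows(iv[-c(i, i + 1L), ], both)
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }

  iv <- iv %>% arrange(.data$start)
  n <- nrow(iv)
  tibble(
    name = if (n > 0L) paste0(params$name_prefix, rev(seq_len(n))) else character(),
    start = iv$start, end = iv$end,
    length = iv$end - iv$start + 1L,
    defining_strand = iv$strand
  )
}

#' Heterogeneity of protected residues inside vs outside footprints
#'
#' 2x2 chi-square test (1 df, no continuity correction) of
#' {protected, unprotected} x {inside footprints, outside}, where the inside
#' total is the summed footprint length. If any expected cell is below 1 the
#' test falls back to Fisher's exact test with a warning.
#'
#' @param footprints Footprint tibble (`start`, `end`).
#' @param protected_positions Integer positions protected on either strand.
#' @param region_length Region length in bp.
#' @return One-row tibble `chi2`, `df`, `p_value`, `method`, plus the four
#'   observed counts.
#' @export
heterogeneity_test <- function(footprints, protected_positions,
                               region_length) {
  protected_positions <- unique(as.integer(protected_positions))
  inside_total <- sum(footprints$end - footprints$start + 1L)
  outside_total <- region_length - inside_total
  if (inside_total == 0L || outside_total == 0L) {
    return(tibble(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                  method = "undefined",
                  inside_protected = NA_integer_,
                  inside_unprotected = NA_integer_,
                  outside_protected = length(protected_positions),
                  outside_unprotected = NA_integer_))
  }
  in_fp <- rep(FALSE, region_length)
  for (i in seq_len(nrow(footprints))) {
    in_fp[footprints$start[i]:footprints$end[i]] <- TRUE
  }
  inside_prot <- sum(in_fp[protected_positions])
  outside_prot <- length(protected_positions) - inside_prot

  m <- matrix(c(inside_prot, inside_total - inside_prot,
                outside_prot, outside_total - outside_prot),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("inside", "outside"),
                              c("protected", "unprotected")))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1)) {
    warn("expected cell count below 1; falling back to Fisher's exact test")
    ft <- fisher.test(m)
    return(tibble(chi2 = NA_real_, df = NA_integer_, p_value = ft$p.value,
                  method = "fisher",
                  inside_protected = inside_prot,
                  inside_unprotected = inside_total - inside_prot,
                  outside_protected = outside_prot,
                  outside_unprotected = outside_total - outside_prot))
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(chi2 = unname(ct$statistic), df = as.integer(unname(ct$parameter)),
         p_value = ct$p.value, method = "chisq",
         inside_protected = inside_prot,
         inside_unprotected = inside_total - inside_prot,
         outside_protected = outside_prot,
         outside_unprotected = outside_total - outside_prot)
}
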