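# Protection ratios, criterion i-iv footprint calling, heterogeneity test,
# and the caller's invariants.

make_profiles <- function(bsa, foxo, strand = "forward", conc = 600,
                          subfragment_id = "SF1", offset = 1L) {
  L <- length(bsa)
  bind_rows(
    tibble(subfragment_id = subfragment_id, strand = strand,
           condition = "BSA", concentration = conc, position = seq_len(L),
           region_position = offset + seq_len(L) - 1L,
           mean_norm_height = bsa,
           n_replicates = ifelse(is.na(bsa), 0L, 5L), low_support = FALSE),
    tibble(subfragment_id = subfragment_id, strand = strand,
           condition = "FOXO", concentration = conc, position = seq_len(L),
           region_position = offset + seq_len(L) - 1L,
           mean_norm_height = foxo,
           n_replicates = ifelse(is.na(foxo), 0L, 5L), low_support = FALSE))
}

test_that("protection ratios follow the BSA/FOXO rule with missing-data flags", {
  prof <- make_profiles(bsa = c(4.0, 1.5, 3.0, NA, NA),
                        foxo = c(2.0, 1.5, NA, 2.0, NA))
  tr <- protection_ratio(prof, caller_params())
  expect_equal(tr$ratio[1], 2.0)
  # a ratio of one means no protection
  expect_equal(tr$ratio[2], 1.0)
  expect_equal(tr$support[1:5],
               c("both_observed", "both_observed", "foxo_missing",
                 "bsa_missing", "unobserved"))
  # FOXO fully missing: ratio against the epsilon floor
  # (5% of the FOXO sample's median normalized height), capped
  # the FOXO median here is 2.0, so epsilon = 0.05 * 2.0 = 0.1 and the
  # missing-FOXO residue with BSA 3.0 gets ratio 3.0 / 0.1 = 30 (below cap)
  expect_equal(tr$ratio[3], 30)
  expect_true(is.na(tr$ratio[4]))
  expect_true(is.na(tr$ratio[5]))

  # the cap kicks in when BSA signal is very strong
  prof_hi <- make_profiles(bsa = c(1000, 2.0, 2.0, 2.0),
                           foxo = c(NA, 2.0, 2.0, 2.0))
  tr_hi <- protection_ratio(prof_hi, caller_params())
  expect_equal(tr_hi$ratio[1], 50)
  expect_equal(tr_hi$support[1], "foxo_missing")
})

test_that("criterion i protects at >= 2 in either concentration, inclusively", {
  expect_true(call_protected(2.0, 1.3))
  expect_false(call_protected(1.9, 1.9))
  expect_true(call_protected(1.0, 2.4))
  expect_false(call_protected(NA_real_, NA_real_))
  expect_true(call_protected(NA_real_, 2.0))
})

test_that("criterion ii clusters protected residues with gap and size rules", {
  p <- caller_params()
  # nine consecutive protected residues: one 9 bp footprint, the minimum
  cl <- cluster_footprints(100:108, p)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(100L, 108L))
  expect_equal(cl$length, 9L)

  # two isolated residues never cluster
  expect_equal(nrow(cluster_footprints(c(10, 20), p)), 0L)

  # a gap of 5 > max_gap 4 splits; 3 bp clusters survive only if the
  # minimum footprint length allows them
  pos <- c(50, 51, 52, 58, 59, 60)
  expect_equal(nrow(cluster_footprints(pos, p)), 0L)
  p3 <- caller_params(min_footprint_length = 3)
  cl3 <- cluster_footprints(pos, p3)
  expect_equal(cl3$start, c(50L, 58L))
  expect_equal(cl3$end, c(52L, 60L))

  # gap of exactly max_gap joins
  joined <- cluster_footprints(c(50, 51, 52, 57, 58, 59), p3)
  expect_equal(nrow(joined), 1L)
  expect_equal(c(joined$start, joined$end), c(50L, 59L))
})

test_that("criteria iii-iv reconcile strands and name footprints distal-first", {
  p <- caller_params()
  iv <- function(s, e) tibble(start = s, end = e)

  # overlap: the longer strand defines the extent
  fp <- reconcile_strands(iv(10, 30), iv(15, 30), p)
  expect_equal(c(fp$start, fp$end), c(10L, 30L))
  expect_equal(fp$defining_strand, "forward")

  # slight offset (2 bp): limits are the 5' protected residues of each strand
  fp <- reconcile_strands(iv(100, 110), iv(113, 118), p)
  expect_equal(c(fp$start, fp$end), c(100L, 118L))
  expect_equal(fp$defining_strand, "both")

  # single-strand footprints pass through
  fp <- reconcile_strands(iv(10, 30), iv(integer(), integer()), p)
  expect_equal(c(fp$start, fp$end), c(10L, 30L))
  expect_equal(fp$defining_strand, "forward")

  # equal-length overlap: union
  fp <- reconcile_strands(iv(10, 30), iv(12, 32), p)
  expect_equal(c(fp$start, fp$end), c(10L, 32L))

  # naming runs prefixN (distal) .. prefix1 (proximal along the forward strand)
  fp <- reconcile_strands(iv(c(10, 200), c(30, 220)),
                          iv(500, 520), caller_params(name_prefix = "M"))
  expect_equal(fp$name, c("M3", "M2", "M1"))
  expect_false(is.unsorted(fp$start))
  # disjointness
  expect_true(all(fp$start[-1] > fp$end[-nrow(fp)]))
})

test_that("heterogeneity test matches a hand-computed chi-square oracle", {
  # spec'd worked table: inside 300/444 protected, outside 50/856
  build_case <- function(inside_prot, inside_total, outside_prot,
                         outside_total) {
    region_length <- inside_total + outside_total
    fp <- tibble(name = "F1", start = 1L, end = inside_total)
    protected <- c(seq_len(inside_prot),
                   inside_total + seq_len(outside_prot))
    heterogeneity_test(fp, protected, region_length)
  }
  het <- build_case(300, 444, 50, 856)
  m <- matrix(c(300, 144, 50, 806), nrow = 2, byrow = TRUE)
  expect_equal(het$chi2, oracle_chi2(m), tolerance = 1e-10)
  expect_lt(het$p_value, 1e-10)

  # identical protected proportion inside and out: chi2 = 0, p = 1
  het0 <- build_case(100, 200, 100, 200)
  expect_equal(het0$chi2, 0, tolerance = 1e-12)
  expect_equal(het0$p_value, 1)

  # degenerate direction: all protected residues inside footprints
  het1 <- build_case(444, 444, 0, 856)
  expect_equal(het1$chi2, oracle_chi2(matrix(c(444, 0, 0, 856), 2, byrow = TRUE)),
               tolerance = 1e-10)
  expect_lt(het1$p_value, 1e-3)

  # randomized tables against the oracle
  set.seed(21)
  for (i in 1:20) {
    it <- sample(50:500, 1); ot <- sample(50:1000, 1)
    ip <- sample.int(it, 1); op <- sample.int(ot, 1)
    het <- build_case(ip, it, op, ot)
    if (het$method == "chisq") {
      expect_equal(het$chi2,
                   oracle_chi2(matrix(c(ip, it - ip, op, ot - op), 2,
                                      byrow = TRUE)),
                   tolerance = 1e-8)
    }
  }
})

test_that("raising the ratio threshold never enlarges the called set", {
  cfg <- simulation_config(seed = 13)
  ex <- simulate_experiment(cfg)
  prev_protected <- Inf; prev_bp <- Inf
  for (thr in c(1.5, 2, 3, 4.5)) {
    # at stringent thresholds the heterogeneity table can go sparse and fall
    # back to the exact test; only the monotonicity is under test here
    fc <- suppressWarnings(
      call_footprints(ex$peaks, ex$fragments,
                      caller_params(ratio_threshold = thr)))
    n_prot <- nrow(fc$protected)
    bp <- sum(fc$footprints$length)
    expect_lte(n_prot, prev_protected)
    expect_lte(bp, prev_bp)
    prev_protected <- n_prot; prev_bp <- bp
  }
})

test_that("the caller is deterministic and invariant to per-sample scaling", {
  cfg <- simulation_config(seed = 29)
  ex <- simulate_experiment(cfg)
  fc1 <- call_footprints(ex$peaks, ex$fragments)
  fc2 <- call_footprints(ex$peaks, ex$fragments)
  expect_identical(fc1$footprints, fc2$footprints)

  # multiply all heights (signal and standard) of one sample by a constant
  scaled <- ex$peaks %>%
    mutate(height = ifelse(.data$subfragment_id == "SF2" &
                             .data$condition == "FOXO" &
                             .data$concentration == 1200 &
                             .data$labeled_strand == "reverse",
                           .data$height * 137, .data$height))
  fc3 <- call_footprints(scaled, ex$fragments)
  expect_equal(fc3$footprints, fc1$footprints)
  expect_equal(fc3$track$ratio_600, fc1$track$ratio_600, tolerance = 1e-12)
  expect_equal(fc3$track$ratio_1200, fc1$track$ratio_1200, tolerance = 1e-12)
})

test_that("every surviving protected residue lies inside exactly one footprint", {
  cfg <- simulation_config(seed = 31)
  ex <- simulate_experiment(cfg)
  fc <- call_footprints(ex$peaks, ex$fragments)
  fp <- fc$footprints
  for (s in c("forward", "reverse")) {
    pos <- fc$protected$position[fc$protected$strand == s]
    surviving <- cluster_footprints(pos, fc$params)
    for (i in seq_len(nrow(surviving))) {
      covered <- vapply(seq_len(nrow(fp)), function(j) {
        surviving$start[i] >= fp$start[j] && surviving$end[i] <= fp$end[j]
      }, logical(1))
      expect_equal(sum(covered), 1L)
    }
  }
})
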