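# IUPAC scanning, footprint assignment, density statistics, consensus
# derivation.

pat1 <- function(iupac, class = "DBE_core") {
  tibble(pattern_id = iupac, iupac = iupac, class = class)
}

test_that("motif scanning handles both strands and IUPAC semantics", {
  h <- scan_motifs("AATTGTTTCC", pat1("TTGTTT"))
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(3L, 8L))
  expect_equal(h$strand, "forward")
  expect_equal(h$site, "TTGTTT")

  # reverse-strand hit reported in forward coordinates
  h <- scan_motifs("AAACAA", pat1("TTGTTT"))
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(1L, 6L))
  expect_equal(h$strand, "reverse")
  expect_equal(h$site, "TTGTTT")

  # degenerate codes: R matches G, K matches T; C is not in R
  expect_equal(nrow(scan_motifs("TGTTT", pat1("TRTTK", "FKH"))), 1L)
  expect_equal(nrow(scan_motifs("TCTTT", pat1("TRTTK", "FKH"),
                                strands = "forward")), 0L)
  # the derived consensus accepts a DBE-core instance
  expect_gte(nrow(scan_motifs("TTGTTTAC", pat1("TTDTTKNB",
                                               "derived_consensus"),
                              strands = "forward")), 1L)

  # overlapping and self-overlapping matches are all reported
  h <- scan_motifs("TTTTTTTT", pat1("TTTTTT"), strands = "forward")
  expect_equal(h$start, 1:3)

  expect_error(scan_motifs("ACGT", pat1("TTXTTT")),
               class = "footcall_iupac_error")
  expect_error(scan_motifs("ACNT", pat1("TTGTTT")),
               class = "footcall_sequence_error")
})

test_that("scanning agrees with a brute-force oracle and is revcomp-symmetric", {
  set.seed(17)
  patterns <- default_motif_patterns()
  for (i in 1:20) {
    s <- random_dna(300)
    for (j in seq_len(nrow(patterns))) {
      got <- scan_motifs(s, patterns[j, ]) %>%
        select("start", "end", "strand") %>%
        arrange(.data$start, .data$strand)
      want <- oracle_scan(s, patterns$iupac[j]) %>%
        arrange(start, strand) %>% as_tibble() %>%
        mutate(start = as.integer(start), end = as.integer(end))
      expect_equal(got, want)
    }
    # reverse-complement symmetry: strands swap, coordinates reflect
    rc <- revcomp(s)
    h_f <- scan_motifs(s, patterns)
    h_r <- scan_motifs(rc, patterns)
    reflect <- h_r %>%
      mutate(new_start = nchar(s) - .data$end + 1L,
             new_end = nchar(s) - .data$start + 1L,
             strand = dplyr::if_else(.data$strand == "forward",
                                     "reverse", "forward")) %>%
      select(start = "new_start", end = "new_end", "strand", "pattern_id") %>%
      arrange(.data$start, .data$strand, .data$pattern_id)
    expect_equal(
      reflect,
      h_f %>% select("start", "end", "strand", "pattern_id") %>%
        arrange(.data$start, .data$strand, .data$pattern_id))
  }
})

test_that("hits are assigned to footprints and FKH is subsumed by DBE spans", {
  fp <- tibble(name = c("F2", "F1"), start = c(90L, 190L), end = c(110L, 210L))
  hits <- tibble(
    pattern_id = c("TRTTK", "TTGTTT", "TRTTK", "TTGTTT"),
    class = c("FKH", "DBE_core", "FKH", "DBE_core"),
    start = c(100L, 99L, 200L, 300L),
    end = c(104L, 104L, 204L, 305L),
    strand = "forward", site = "NNNNN")
  ann <- assign_hits_to_footprints(hits, fp)
  # FKH overlapping a DBE span is reported but flagged subsumed
  expect_true(ann$subsumed[1])
  expect_false(ann$subsumed[3])
  expect_equal(ann$footprint, c("F2", "F2", "F1", NA))

  # with precedence off nothing is subsumed
  ann2 <- assign_hits_to_footprints(hits, fp, dbe_precedence = FALSE)
  expect_false(any(ann2$subsumed))
})

test_that("per-fragment densities and percentages match the printed rounding", {
  part <- region_partition()
  mk <- function(starts) {
    tibble(pattern_id = "TTGTTT", class = "DBE_core",
           start = as.integer(starts), end = as.integer(starts + 5L),
           strand = "forward", site = "TTGTTT",
           footprint = "F1", subsumed = FALSE)
  }
  # 3 hits in the 392 bp fragment -> 7.7/kb; 21 in the 650 bp -> 32.3/kb
  hits <- mk(c(300, 350, 400, seq(660, 1260, by = 30)))
  expect_equal(sum(hits$start >= 259 & hits$start <= 650), 3L)
  expect_equal(sum(hits$start >= 651), 21L)
  dens <- motif_density(hits, part)
  expect_equal(dens$density_per_kb[2], 7.7)
  expect_equal(dens$density_per_kb[3], 32.3)
  # counts recoverable from the rounded densities
  expect_equal(counts_from_densities(dens$density_per_kb, dens$length),
               dens$count)
  expect_equal(sum(dens$count), nrow(hits))

  # spans matched on both strands count once
  dup <- bind_rows(hits, hits %>% mutate(strand = "reverse"))
  expect_equal(motif_density(dup, part)$count, dens$count)

  # no hits: densities 0, percentages 0 with a warning
  expect_warning(empty <- motif_density(mk(integer()), part), "percentages")
  expect_equal(empty$density_per_kb, c(0, 0, 0))
  expect_equal(empty$percent, c(0, 0, 0))
  expect_error(motif_density(hits, part[0, ]),
               class = "footcall_validation_error")
})

test_that("published density arithmetic reproduces integer counts and percentages", {
  tab <- inr_density_table() %>% filter(.data$species == "D. melanogaster")
  counts <- counts_from_densities(tab$density_per_kb, tab$length)
  expect_equal(counts, c(8L, 3L, 21L))
  expect_equal(round(100 * counts / sum(counts)), c(25, 9, 66))
})

test_that("consensus derivation covers frequent bases with minimal codes", {
  # identical sites give themselves back
  expect_equal(derive_consensus(rep("TTGTTTGC", 3))$consensus, "TTGTTTGC")

  # worked three-site case at threshold 0.2, checked against the oracle
  sites <- c("TTGTTGGC", "TTATTTTG", "TTTTTTGT")
  cons <- derive_consensus(sites, freq_threshold = 0.2)
  expect_equal(cons$consensus, "TTDTTKKB")
  expect_equal(cons$consensus, oracle_consensus(sites, 0.2))
  expect_equal(unname(cons$frequency["G", 3]), 1 / 3)

  # randomized site sets against the column-count oracle
  set.seed(23)
  for (i in 1:15) {
    n <- sample(3:12, 1); L <- sample(4:10, 1)
    sset <- vapply(seq_len(n), function(j) random_dna(L), "")
    # the most frequent base in a column has frequency >= 0.25, so these
    # thresholds always leave at least one covered base
    thr <- sample(c(0.05, 0.1, 0.2, 0.25), 1)
    expect_equal(derive_consensus(sset, thr)$consensus,
                 oracle_consensus(sset, thr))
  }

  # threshold -> 0 yields the fully degenerate code of observed bases
  expect_equal(derive_consensus(c("AC", "GC", "TC"), 1e-9)$consensus, "DC")
  # threshold above every column frequency fails loudly
  expect_error(derive_consensus(c("AC", "GC", "TC"), 0.5),
               class = "footcall_consensus_error")
  expect_error(derive_consensus(c("ACGT", "ACG")),
               class = "footcall_validation_error")

  # tidy() exposes the frequency matrix in long form
  td <- tidy(derive_consensus(sites, freq_threshold = 0.2))
  expect_equal(nrow(td), 4L * 8L)
  expect_true(all(td$in_consensus[td$frequency >= 0.2]))
})
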