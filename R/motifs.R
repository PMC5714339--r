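# IUPAC motif scanning on both strands, footprint assignment, per-fragment
# density statistics and degenerate-consensus derivation.

#' Default binding-motif pattern set
#'
#' The FOXO-family elements searched in footprinted regions: the DBE cores
#' TTGTTT and TTATTT (shared by the mouse DBE and IRE elements), the
#' near-DBE single-mismatch variants TTGTTG and TTTTTT, the TRTTK core
#' recognized by all FORKHEAD-domain proteins, and the degenerate Drosophila
#' consensus TTDTTKNB derived from detected DBE sites. Each class can be
#' switched off by subsetting the returned tibble.
#'
#' @return Tibble `pattern_id`, `iupac`, `class`.
#' @export
default_motif_patterns <- function() {
  tibble(
    pattern_id = c("TTGTTT", "TTATTT", "TTGTTG", "TTTTTT", "TRTTK",
                   "TTDTTKNB"),
    iupac = c("TTGTTT", "TTATTT", "TTGTTG", "TTTTTT", "TRTTK", "TTDTTKNB"),
    class = c("DBE_core", "DBE_core", "near_DBE", "near_DBE", "FKH",
              "derived_consensus")
  )
}

#' Scan a sequence for IUPAC motifs on both strands
#'
#' Reports every position where a pattern matches the forward strand, plus
#' every position where it matches the reverse complement (given in forward
#' coordinates with `strand = "reverse"`). Overlapping and self-overlapping
#' matches are all reported; order is deterministic by (start, strand,
#' pattern_id). `site` carries the matched bases read 5'->3' on the matching
#' strand.
#'
#' @param sequence A/C/G/T character string.
#' @param patterns Pattern tibble (`pattern_id`, `iupac`, `class`); default
#'   [default_motif_patterns()].
#' @param strands Strands to scan (default both).
#' @return Tibble `pattern_id`, `class`, `start`, `end`, `strand`, `site`.
#' @export
#' @examples
#' scan_motifs("AATTGTTTCC", tibble::tibble(
#'   pattern_id = "TTGTTT", iupac = "TTGTTT", class = "DBE_core"))
scan_motifs <- function(sequence, patterns = default_motif_patterns(),
                        strands = c("forward", "reverse")) {
  sequence <- .validate_acgt(sequence)
  subj <- DNAString(sequence)
  strands <- match.arg(strands, c("forward", "reverse"), several.ok = TRUE)

  one <- function(pattern_id, iupac, class) {
    .validate_iupac_string(iupac)
    hits <- list()
    if ("forward" %in% strands) {
      m <- matchPattern(DNAString(iupac), subj, fixed = "subject")
      if (length(m) > 0L) {
        hits$fwd <- tibble(pattern_id = pattern_id, class = class,
                           start = start(m), end = end(m),
                           strand = "forward",
                           site = as.character(m))
      }
    }
    if ("reverse" %in% strands) {
      rc <- reverseComplement(DNAString(iupac))
      m <- matchPattern(rc, subj, fixed = "subject")
      if (length(m) > 0L) {
        hits$rev <- tibble(pattern_id = pattern_id, class = class,
                           start = start(m), end = end(m),
                           strand = "reverse",
                           site = revcomp(as.character(m)))
      }
    }
    bind_rows(hits)
  }

  res <- purrr::pmap(patterns, one) %>% purrr::list_rbind()
  if (nrow(res) == 0L) {
    return(tibble(pattern_id = character(), class = character(),
                  start = integer(), end = integer(), strand = character(),
                  site = character()))
  }
  res %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    arrange(.data$start, .data$strand, .data$pattern_id)
}

#' Assign motif hits to footprints and apply DBE precedence
#'
#' Each hit is assigned to the footprint it overlaps by at least 1 bp (the
#' footprint with the larger overlap when a hit straddles two; footprints
#' are disjoint). With `dbe_precedence` on, FKH hits whose span overlaps any
#' DBE-core or near-DBE hit span are flagged `subsumed`: they are reported
#' but excluded from FKH counts, since the FKH core is contained in every
#' DBE and only copies outside DBE motifs are counted separately.
#'
#' @param hits Tibble from [scan_motifs()].
#' @param footprints Footprint tibble (`name`, `start`, `end`).
#' @param dbe_precedence Flag FKH hits inside DBE/near-DBE spans
#'   (default TRUE).
#' @return `hits` with added `footprint` (name or NA) and `subsumed`
#'   columns.
#' @export
assign_hits_to_footprints <- function(hits, footprints,
                                      dbe_precedence = TRUE) {
  fp_of <- function(s, e) {
    if (nrow(footprints) == 0L) return(NA_character_)
    ov <- pmin(footprints$end, e) - pmax(footprints$start, s) + 1L
    if (all(ov < 1L)) NA_character_ else footprints$name[which.max(ov)]
  }
  hits <- hits %>%
    mutate(footprint = purrr::map2_chr(.data$start, .data$end, fp_of))

  subsumed <- rep(FALSE, nrow(hits))
  if (dbe_precedence && nrow(hits) > 0L) {
    dbe <- hits %>% filter(.data$class %in% c("DBE_core", "near_DBE"))
    if (nrow(dbe) > 0L) {
      is_fkh <- hits$class == "FKH"
      subsumed[is_fkh] <- vapply(which(is_fkh), function(i) {
        any(pmin(dbe$end, hits$end[i]) - pmax(dbe$start, hits$start[i]) + 1L >= 1L)
      }, logical(1))
    }
  }
  hits$subsumed <- subsumed
  hits
}

#' Per-fragment motif counts, densities and percentages
#'
#' Local density statistics over a region partition. The counting unit is
#' the distinct hit span: a span matched on both strands counts once.
#' By default only hits assigned to footprints are counted (the statistic
#' describes motifs in footprinted sequence), subsumed FKH hits are
#' excluded, and the classes counted are DBE cores, near-DBE variants and
#' FKH (the "DBE+FKH" statistic). A hit belongs to the fragment containing
#' its start. Densities are per kb rounded to 1 decimal; percentages to the
#' nearest integer.
#'
#' @param hits Annotated hits from [assign_hits_to_footprints()].
#' @param partition Region partition from [region_partition()].
#' @param count_classes Pattern classes counted (default DBE_core, near_DBE,
#'   FKH).
#' @param footprint_only Count only hits inside footprints (default TRUE).
#' @return Tibble `fragment`, `start`, `end`, `length`, `count`,
#'   `density_per_kb`, `percent`.
#' @export
motif_density <- function(hits, partition,
                          count_classes = c("DBE_core", "near_DBE", "FKH"),
                          footprint_only = TRUE) {
  if (nrow(partition) == 0L) {
    abort("empty region partition", class = "footcall_validation_error")
  }
  counted <- hits %>% filter(.data$class %in% count_classes)
  if ("subsumed" %in% names(counted)) {
    counted <- counted %>% filter(!.data$subsumed)
  }
  if (footprint_only && "footprint" %in% names(counted)) {
    counted <- counted %>% filter(!is.na(.data$footprint))
  }
  spans <- counted %>% distinct(.data$start, .data$end)

  frag_of <- function(s) {
    hit <- which(partition$start <= s & s <= partition$end)
    if (length(hit) == 0L) NA_integer_ else partition$fragment[hit[1]]
  }
  spans$fragment <- vapply(spans$start, frag_of, integer(1))
  counts <- spans %>%
    filter(!is.na(.data$fragment)) %>%
    count(.data$fragment, name = "count")

  out <- partition %>%
    select("fragment", "start", "end", "length") %>%
    left_join(counts, by = "fragment") %>%
    mutate(count = as.integer(dplyr::coalesce(.data$count, 0L)))
  total <- sum(out$count)
  if (total == 0L) {
    warn("no motif hits in any fragment; percentages reported as 0")
  }
  out %>%
    mutate(
      density_per_kb = round(.data$count / (.data$length / 1000), 1),
      percent = if (total == 0L) 0 else round(100 * .data$count / total)
    )
}

#' Integer motif counts implied by published per-kb densities
#'
#' Inverts the density statistic: count = round(density x length / 1000).
#' Useful for checking printed density tables against fragment lengths.
#'
#' @param density_per_kb Densities (motifs per kb).
#' @param length_bp Fragment lengths in bp.
#' @return Integer counts.
#' @export
#' @examples
#' counts_from_densities(c(31.0, 7.7, 32.3), c(258, 392, 650))
counts_from_densities <- function(density_per_kb, length_bp) {
  as.integer(round(density_per_kb * length_bp / 1000))
}

#' Published per-fragment DBE+FKH motif densities
#'
#' The per-kb densities of DBE+FKH motifs in footprinted sequence for the
#' three fragments (distal 258 bp, central 392 bp, proximal 650 bp) of the
#' 1.3 kb InR P2 upstream region in five Drosophila species, as established
#' by automated DNase I footprinting. Used as an input table for arithmetic
#' cross-checks (see [counts_from_densities()]).
#'
#' @return Tibble `species`, `fragment`, `length`, `density_per_kb`.
#' @export
inr_density_table <- function() {
  species <- c("D. melanogaster", "D. simulans", "D. yakuba",
               "D. pseudoobscura", "D. virilis")
  dens <- c(31.0, 7.7, 32.3,
            34.9, 10.2, 26.2,
            19.4, 10.2, 43.1,
            23.3, 35.7, 10.8,
            46.5, 15.3, 27.7)
  tibble(
    species = rep(species, each = 3L),
    fragment = rep(1:3, times = 5L),
    length = rep(c(258L, 392L, 650L), times = 5L),
    density_per_kb = dens
  )
}

#' Derive a degenerate IUPAC consensus from aligned binding sites
#'
#' Per alignment column, base counts become frequencies and the consensus
#' symbol is the minimal IUPAC code covering every base whose frequency
#' reaches `freq_threshold`. Sites must be equal length and oriented 5'->3'
#' on their matching strand.
#'
#' @param sites Character vector of equal-length A/C/G/T site sequences.
#' @param freq_threshold Minimum column frequency for a base to enter the
#'   code (default 0.10). A threshold above every column frequency is an
#'   error rather than an empty symbol.
#' @return Object of class `motif_consensus`: list with `consensus` (IUPAC
#'   string), `frequency` (4 x L matrix of column base frequencies) and
#'   `n_sites`.
#' @export
#' @examples
#' derive_consensus(c("TTGTTGGC", "TTATTTTG", "TTTTTTGT"),
#'                  freq_threshold = 0.2)
derive_consensus <- function(sites, freq_threshold = 0.10) {
  if (length(sites) == 0L) {
    abort("no sites supplied", class = "footcall_validation_error")
  }
  sites <- vapply(sites, .validate_acgt, "", USE.NAMES = FALSE)
  L <- unique(nchar(sites))
  if (length(L) != 1L) {
    abort("sites must all have the same length",
          class = "footcall_validation_error")
  }
  mat <- do.call(rbind, strsplit(sites, ""))
  bases <- c("A", "C", "G", "T")
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = bases))
    as.numeric(tab) / length(sites)
  }, numeric(4))
  rownames(freq) <- bases
  colnames(freq) <- seq_len(L)

  consensus <- vapply(seq_len(L), function(j) {
    keep <- bases[freq[, j] >= freq_threshold]
    if (length(keep) == 0L) {
      abort(paste0("no base reaches frequency ", freq_threshold,
                   " in column ", j, " (max ", round(max(freq[, j]), 3), ")"),
            class = "footcall_consensus_error")
    }
    iupac_code(keep)
  }, "")

  structure(list(consensus = paste(consensus, collapse = ""),
                 frequency = freq, n_sites = length(sites)),
            class = "motif_consensus")
}

#' @export
print.motif_consensus <- function(x, ...) {
  cat("Degenerate consensus from", x$n_sites, "sites: 5'-", x$consensus,
      "\n", sep = " ")
  invisible(x)
}

#' Tidy a derived consensus into a long frequency table
#'
#' @param x `motif_consensus` object.
#' @param ... Unused.
#' @return Tibble `position`, `base`, `frequency`, `in_consensus`.
#' @export
tidy.motif_consensus <- function(x, ...) {
  L <- ncol(x$frequency)
  cons <- strsplit(x$consensus, "")[[1]]
  expand_grid(position = seq_len(L), base = rownames(x$frequency)) %>%
    mutate(
      frequency = purrr::map2_dbl(.data$position, .data$base,
                                  ~ x$frequency[.y, .x]),
      in_consensus = purrr::map2_lgl(.data$position, .data$base,
                                     ~ .y %in% iupac_bases(cons[.x]))
    )
}
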