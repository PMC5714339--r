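# Readers/writers for peak tables, region sequences and footprint intervals.
# All coordinate conventions are fixed in this file:
#   * internal coordinates are 1-based inclusive on the region forward strand,
#     position 1 = most distal residue;
#   * TSS-relative reporting maps position p -> p - (region_length + 1), so the
#     proximal end of a 1300 bp region is -1;
#   * BED output is the only 0-based half-open surface, converted exactly once
#     here.

.size_aliases   <- c("size", "called_size", "size_bp", "called size")
.height_aliases <- c("height", "height_rfu", "peak height", "height_in_rfu")

.meta_fields <- c("subfragment_id", "condition", "concentration",
                  "replicate", "labeled_strand", "channel")

.normalize_condition <- function(x) {
  up <- toupper(as.character(x))
  out <- dplyr::case_when(
    up %in% c("BSA") ~ "BSA",
    up %in% c("FOXO", "DFOXO") ~ "FOXO",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    abort(paste0("unknown condition label(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", "),
                 " (expected BSA or FOXO/dFOXO)"),
          class = "footcall_metadata_error")
  }
  out
}

#' Read a fragment-analysis peak table
#'
#' Reads one Peak Scanner-style export (comma- or tab-delimited, with a
#' header) into a tidy tibble of peak records. Column names `Size`/`size_bp`
#' and `Height`/`height_rfu` are resolved case-insensitively. Sample metadata
#' (condition, concentration, replicate, labeled strand, channel, subfragment
#' id) can be present as columns in the file and/or supplied through
#' `metadata`; `metadata` wins on conflict.
#'
#' @param path Path to the delimited peak table.
#' @param metadata Named list with any of `subfragment_id`, `condition`
#'   (`"BSA"` or `"FOXO"`), `concentration` (600 or 1200 nM), `replicate`,
#'   `labeled_strand` (`"forward"`/`"reverse"`), `channel`
#'   (`"signal"`/`"standard"`).
#' @return A tibble with columns `subfragment_id`, `condition`,
#'   `concentration`, `replicate`, `labeled_strand`, `channel`,
#'   `called_size`, `height`.
#' @export
read_peak_table <- function(path, metadata = list()) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  names(raw) <- tolower(trimws(names(raw)))

  pick <- function(aliases, label) {
    hit <- intersect(aliases, names(raw))
    if (length(hit) == 0L) {
      abort(paste0("peak table '", path, "' is missing a '", label,
                   "' column (accepted names: ",
                   paste(aliases, collapse = ", "), ")"),
            class = "footcall_format_error")
    }
    hit[1]
  }
  size_col <- pick(.size_aliases, "size")
  height_col <- pick(.height_aliases, "height")

  out <- tibble(
    called_size = suppressWarnings(as.numeric(raw[[size_col]])),
    height = suppressWarnings(as.numeric(raw[[height_col]]))
  )
  bad <- which(is.na(out$called_size) | is.na(out$height))
  if (length(bad) > 0L) {
    warn(paste0("dropping ", length(bad), " malformed row(s) in '", path,
                "' (data line ", paste(bad, collapse = ", "), ")"))
  }

  for (f in .meta_fields) {
    if (f %in% names(raw)) out[[f]] <- raw[[f]]
    if (!is.null(metadata[[f]])) out[[f]] <- metadata[[f]]
    if (!f %in% names(out)) {
      out[[f]] <- switch(f, channel = "signal", replicate = 1L, NA)
    }
  }
  if (length(bad) > 0L) out <- out[-bad, ]

  out <- out %>%
    mutate(
      condition = .normalize_condition(.data$condition),
      concentration = as.numeric(.data$concentration),
      replicate = as.integer(.data$replicate),
      labeled_strand = tolower(as.character(.data$labeled_strand)),
      channel = tolower(as.character(.data$channel)),
      subfragment_id = as.character(.data$subfragment_id)
    ) %>%
    select("subfragment_id", "condition", "concentration", "replicate",
           "labeled_strand", "channel", "called_size", "height")

  validate_peaks(out)
}

#' Validate a tibble of peak records
#'
#' Enforces the peak-record invariants: non-negative heights, positive called
#' sizes, concentrations in {600, 1200}, known strand and channel labels.
#'
#' @param peaks Tibble as returned by [read_peak_table()].
#' @return `peaks`, invisibly unchanged, for piping.
#' @export
validate_peaks <- function(peaks) {
  if (any(peaks$height < 0, na.rm = TRUE)) {
    abort("negative peak height(s) found", class = "footcall_validation_error")
  }
  if (any(peaks$called_size <= 0, na.rm = TRUE)) {
    abort("non-positive called size(s) found", class = "footcall_validation_error")
  }
  conc <- unique(stats::na.omit(peaks$concentration))
  if (length(conc) > 0 && !all(conc %in% c(600, 1200))) {
    abort("concentration must be 600 or 1200 (nM)",
          class = "footcall_validation_error")
  }
  st <- unique(stats::na.omit(peaks$labeled_strand))
  if (length(st) > 0 && !all(st %in% c("forward", "reverse"))) {
    abort("labeled_strand must be 'forward' or 'reverse'",
          class = "footcall_validation_error")
  }
  ch <- unique(stats::na.omit(peaks$channel))
  if (length(ch) > 0 && !all(ch %in% c("signal", "standard"))) {
    abort("channel must be 'signal' or 'standard'",
          class = "footcall_validation_error")
  }
  peaks
}

#' Write a peak table
#'
#' Writes the tidy peak tibble back to delimited text (CSV) so that
#' [read_peak_table()] reproduces it field-for-field.
#'
#' @param peaks Tibble of peak records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_csv(peaks, path, progress = FALSE)
  invisible(path)
}

#' Read region or subfragment sequences from FASTA
#'
#' Sequences are upper-cased and validated to contain only A/C/G/T
#' (ambiguity codes are rejected with the offending offset). Each record
#' becomes a labeled fragment carrying the vector-context geometry used for
#' size-to-residue mapping: forward-labeled reads share `vector_prefix_len`
#' leading vector residues, reverse-labeled reads share `vector_suffix_len`
#' trailing ones.
#'
#' @param path FASTA file, one record per region/subfragment.
#' @param vector_prefix_len Shared leading vector residues (default 69 bp).
#' @param vector_suffix_len Shared trailing vector residues (default 48 bp).
#' @param region_offset 1-based start of each insert within the full region;
#'   recycled, default 1.
#' @return Tibble with columns `subfragment_id`, `sequence`, `insert_length`,
#'   `vector_prefix_len`, `vector_suffix_len`, `region_offset`.
#' @export
read_region_fasta <- function(path, vector_prefix_len = 69,
                              vector_suffix_len = 48, region_offset = 1L) {
  set <- readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    .validate_acgt(seqs[i], what = paste0("record '", names(set)[i], "'"))
  }
  tibble(
    subfragment_id = names(set),
    sequence = unname(seqs),
    insert_length = nchar(unname(seqs)),
    vector_prefix_len = vector_prefix_len,
    vector_suffix_len = vector_suffix_len,
    region_offset = as.integer(rep_len(region_offset, length(seqs)))
  )
}

#' Build a labeled fragment record
#'
#' Programmatic constructor mirroring [read_region_fasta()] for sequences
#' already in memory.
#'
#' @inheritParams read_region_fasta
#' @param sequence Insert sequence (A/C/G/T only).
#' @param subfragment_id Identifier.
#' @return One-row fragment tibble.
#' @export
labeled_fragment <- function(sequence, subfragment_id = "F1",
                             vector_prefix_len = 69, vector_suffix_len = 48,
                             region_offset = 1L) {
  sequence <- .validate_acgt(sequence)
  tibble(
    subfragment_id = subfragment_id,
    sequence = sequence,
    insert_length = nchar(sequence),
    vector_prefix_len = vector_prefix_len,
    vector_suffix_len = vector_suffix_len,
    region_offset = as.integer(region_offset)
  )
}

#' Default region partition for local motif densities
#'
#' Partitions the analyzed region into fragments used for local motif
#' density statistics. The defaults split a 1300 bp region into a 258 bp
#' distal, 392 bp central and 650 bp proximal fragment; the internal cut
#' points correspond to TSS-relative coordinates -1042 and -650 when the TSS
#' sits one position past the proximal end.
#'
#' @param region_length Total region length in bp (default 1300).
#' @param lengths Fragment lengths, 5' (distal) to 3' (proximal); must sum to
#'   `region_length`.
#' @return Tibble with columns `fragment`, `start`, `end`, `length`,
#'   `tss_start`, `tss_end`.
#' @export
#' @examples
#' region_partition()
region_partition <- function(region_length = 1300,
                             lengths = c(258, 392, 650)) {
  if (length(lengths) == 0L) {
    abort("partition must contain at least one fragment",
          class = "footcall_validation_error")
  }
  if (sum(lengths) != region_length) {
    abort(paste0("fragment lengths sum to ", sum(lengths),
                 ", expected region length ", region_length),
          class = "footcall_validation_error")
  }
  ends <- cumsum(lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  tibble(
    fragment = seq_along(lengths),
    start = as.integer(starts),
    end = as.integer(ends),
    length = as.integer(lengths),
    tss_start = as.integer(starts - region_length - 1L),
    tss_end = as.integer(ends - region_length - 1L)
  )
}

#' Convert region coordinates to TSS-relative coordinates
#'
#' @param position Region positions (1-based, 1 = distal end).
#' @param region_length Region length in bp.
#' @return Integer TSS-relative coordinates (proximal end = -1).
#' @export
tss_relative <- function(position, region_length = 1300) {
  as.integer(position - region_length - 1L)
}

.validate_footprints <- function(footprints) {
  if (nrow(footprints) == 0L) return(footprints)
  fp <- arrange(footprints, .data$start)
  if (any(fp$start > fp$end)) {
    abort("footprint with start > end", class = "footcall_validation_error")
  }
  if (nrow(fp) > 1L && any(fp$start[-1] <= fp$end[-nrow(fp)])) {
    abort("footprints overlap; a footprint set must be pairwise disjoint",
          class = "footcall_validation_error")
  }
  fp
}

#' Write footprints as BED6
#'
#' The single place where 1-based inclusive internal coordinates become
#' 0-based half-open BED coordinates. The name column carries the footprint
#' name; the strand column collapses the defining strand (`.` when both).
#'
#' @param footprints Tibble with `name`, `start`, `end` and optionally
#'   `defining_strand`.
#' @param path Output path.
#' @param region_name Value for the BED chrom column.
#' @return `path`, invisibly.
#' @export
write_footprints_bed <- function(footprints, path, region_name = "region") {
  fp <- .validate_footprints(footprints)
  strand_col <- if ("defining_strand" %in% names(fp)) {
    dplyr::recode(fp$defining_strand, forward = "+", reverse = "-", both = ".")
  } else {
    rep(".", nrow(fp))
  }
  bed <- tibble(
    chrom = region_name,
    chromStart = as.integer(fp$start - 1L),
    chromEnd = as.integer(fp$end),
    name = fp$name,
    score = 0L,
    strand = strand_col
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read footprints from BED6
#'
#' Inverse of [write_footprints_bed()]; restores 1-based inclusive
#' coordinates exactly.
#'
#' @param path BED6 file.
#' @return Tibble with `name`, `start`, `end`, `defining_strand`,
#'   `region_name`.
#' @export
read_footprints_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(tibble(name = character(), start = integer(), end = integer(),
                  defining_strand = character(), region_name = character()))
  }
  bed <- readr::read_tsv(path, col_names = c("chrom", "chromStart", "chromEnd",
                                             "name", "score", "strand"),
                         show_col_types = FALSE, progress = FALSE)
  tibble(
    name = as.character(bed$name),
    start = as.integer(bed$chromStart + 1L),
    end = as.integer(bed$chromEnd),
    defining_strand = unname(c("+" = "forward", "-" = "reverse",
                               "." = "both")[bed$strand]),
    region_name = bed$chrom
  )
}
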