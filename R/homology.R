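# Cross-species footprint projection through a supplied multiple alignment.
# The alignment itself is an input (gapped FASTA); orientation segments mark
# alignment-column intervals where a species' sequence enters the alignment
# reverse-complemented (e.g. a microinversion), so its column->sequence
# coordinate map decreases across that segment.

#' Build an alignment map from gapped sequences
#'
#' @param sequences Named character vector of equal-length gapped rows
#'   (gap character `-`), one per species.
#' @param orientation Optional tibble `species`, `col_start`, `col_end`,
#'   `orientation` listing `"inverted"` alignment-column segments per
#'   species; columns not covered are `"same"`.
#' @return Object of class `alignment_map` with per-species column-to-
#'   position maps (`col2pos`, NA at gaps), inverse maps (`pos2col`) and
#'   per-column orientation.
#' @export
alignment_map <- function(sequences, orientation = NULL) {
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) {
    abort("alignment rows must all have the same length",
          class = "footcall_validation_error")
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("sequences must be uniquely named by species",
          class = "footcall_validation_error")
  }
  ncol <- lens
  species <- names(sequences)

  col2pos <- list(); pos2col <- list(); ori <- list()
  for (sp in species) {
    row <- toupper(sequences[[sp]])
    chars <- strsplit(row, "")[[1]]
    nongap <- chars != "-"
    pos <- rep(NA_integer_, ncol)
    pos[nongap] <- seq_len(sum(nongap))
    o <- rep("same", ncol)
    if (!is.null(orientation)) {
      segs <- orientation[orientation$species == sp, , drop = FALSE]
      for (i in seq_len(nrow(segs))) {
        cols <- segs$col_start[i]:segs$col_end[i]
        if (identical(segs$orientation[i], "inverted")) {
          o[cols] <- "inverted"
          idx <- cols[nongap[cols]]
          pos[idx] <- rev(pos[idx])
        }
      }
    }
    col2pos[[sp]] <- pos
    p2c <- rep(NA_integer_, sum(nongap))
    p2c[pos[!is.na(pos)]] <- which(!is.na(pos))
    pos2col[[sp]] <- p2c
    ori[[sp]] <- o
  }

  structure(list(species = species, ncol = ncol,
                 sequences = sequences, col2pos = col2pos,
                 pos2col = pos2col, orientation = ori),
            class = "alignment_map")
}

#' Read an alignment map from gapped FASTA
#'
#' @param path Gapped FASTA (aligner output), one record per species.
#' @param orientation Optional orientation-segment tibble or path to a YAML
#'   sidecar with entries `species`, `col_start`, `col_end`, `orientation`.
#' @return An `alignment_map`.
#' @export
read_alignment_fasta <- function(path, orientation = NULL) {
  set <- readDNAStringSet(path)
  seqs <- setNames(toupper(as.character(set)), names(set))
  if (is.character(orientation) && length(orientation) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML orientation sidecar requires the yaml package")
    }
    orientation <- dplyr::bind_rows(yaml::read_yaml(orientation))
  }
  alignment_map(seqs, orientation)
}

#' @export
print.alignment_map <- function(x, ...) {
  cat("Alignment map:", length(x$species), "species x", x$ncol, "columns\n")
  invisible(x)
}

#' Project footprint intervals onto another species
#'
#' Maps each footprint's positions in species `from` to alignment columns
#' and on to coordinates in species `to`, skipping columns gapped in `to`.
#' The projected interval is the [min, max] of mapped positions;
#' `fraction_mapped` reports the mapped fraction, and footprints mapping
#' below `min_mapped_fraction` are `unalignable`. Intervals passing through
#' a segment whose orientation differs between the two species come back
#' flagged `inverted`; a footprint spanning an orientation breakpoint is
#' split into per-segment projections with a warning.
#'
#' @param footprints Tibble `name`, `start`, `end` in `from` coordinates.
#' @param aln [alignment_map()].
#' @param from,to Species identifiers present in the alignment.
#' @param min_mapped_fraction Minimum mapped fraction (default 0.5).
#' @return Tibble `name`, `start`, `end`, `fraction_mapped`, `inverted`,
#'   `status` (`projected`/`unalignable`), `segment`.
#' @export
project_intervals <- function(footprints, aln, from, to,
                              min_mapped_fraction = 0.5) {
  for (sp in c(from, to)) {
    if (!sp %in% aln$species) {
      abort(paste0("species '", sp, "' absent from alignment"),
            class = "footcall_validation_error")
    }
  }
  rows <- purrr::pmap(
    footprints %>% select("name", "start", "end"),
    function(name, start, end) {
      positions <- start:end
      cols <- aln$pos2col[[from]][positions]
      cols <- cols[!is.na(cols)]
      to_pos <- aln$col2pos[[to]][cols]
      mapped <- !is.na(to_pos)
      fraction <- sum(mapped) / length(positions)
      if (sum(mapped) == 0L || fraction < min_mapped_fraction) {
        return(tibble(name = name, start = NA_integer_, end = NA_integer_,
                      fraction_mapped = fraction, inverted = NA,
                      status = "unalignable", segment = 1L))
      }
      mcols <- cols[mapped]
      mpos <- to_pos[mapped]
      rel_inv <- aln$orientation[[from]][mcols] != aln$orientation[[to]][mcols]
      runs <- rle(rel_inv)
      if (length(runs$lengths) > 1L) {
        warn(paste0("footprint '", name,
                    "' spans an orientation breakpoint; projection split"))
      }
      seg_id <- rep(seq_along(runs$lengths), runs$lengths)
      purrr::map(unique(seg_id), function(s) {
        sel <- seg_id == s
        tibble(name = name,
               start = min(mpos[sel]), end = max(mpos[sel]),
               fraction_mapped = fraction,
               inverted = runs$values[s],
               status = "projected", segment = s)
      }) %>% purrr::list_rbind()
    }) %>% purrr::list_rbind()
  rows
}

#' Classify pairwise footprint conservation through the alignment
#'
#' Two footprints of two species are conserved homologs iff their
#' alignment-column spans share at least `min_overlap` columns. For every
#' footprint and every other species the call is `conserved` (with the
#' best-overlapping partner), `species_specific` (aligned but no partner
#' overlap), or `unalignable` (every footprint column is gapped in the other
#' species). Calls are emitted in both directions, so conservation symmetry
#' can be checked directly.
#'
#' @param footprints Tibble `species`, `name`, `start`, `end` pooling all
#'   species' footprints in their own coordinates.
#' @param aln [alignment_map()].
#' @param min_overlap Minimum shared columns (default 1).
#' @return Tibble `species_a`, `footprint_a`, `species_b`, `footprint_b`,
#'   `overlap_columns`, `status`.
#' @export
classify_conservation <- function(footprints, aln, min_overlap = 1L) {
  colsets <- purrr::pmap(
    footprints %>% select("species", "name", "start", "end"),
    function(species, name, start, end) {
      cols <- aln$pos2col[[species]][start:end]
      list(species = species, name = name, cols = cols[!is.na(cols)])
    })

  species <- unique(footprints$species)
  out <- list()
  for (a in seq_along(colsets)) {
    fa <- colsets[[a]]
    for (sp_b in setdiff(species, fa$species)) {
      aligned_b <- !is.na(aln$col2pos[[sp_b]][fa$cols])
      if (!any(aligned_b)) {
        out[[length(out) + 1L]] <- tibble(
          species_a = fa$species, footprint_a = fa$name,
          species_b = sp_b, footprint_b = NA_character_,
          overlap_columns = 0L, status = "unalignable")
        next
      }
      partners <- purrr::keep(colsets, ~ .x$species == sp_b)
      overlaps <- vapply(partners,
                         function(fb) length(intersect(fa$cols, fb$cols)),
                         integer(1))
      if (length(overlaps) > 0L && max(overlaps) >= min_overlap) {
        best <- which.max(overlaps)
        out[[length(out) + 1L]] <- tibble(
          species_a = fa$species, footprint_a = fa$name,
          species_b = sp_b, footprint_b = partners[[best]]$name,
          overlap_columns = max(overlaps), status = "conserved")
      } else {
        out[[length(out) + 1L]] <- tibble(
          species_a = fa$species, footprint_a = fa$name,
          species_b = sp_b, footprint_b = NA_character_,
          overlap_columns = 0L, status = "species_specific")
      }
    }
  }
  purrr::list_rbind(out)
}

#' Summarize conservation calls per footprint
#'
#' @param calls Tibble from [classify_conservation()].
#' @param species All species considered (defaults to those in `calls`).
#' @return Tibble per footprint: `species`, `footprint`, `n_conserved`
#'   (partner species with a conserved call) and `conserved_in_all`
#'   (conserved pairwise with every other species, i.e. clade-wide).
#' @export
conservation_summary <- function(calls,
                                 species = union(calls$species_a,
                                                 calls$species_b)) {
  n_other <- length(species) - 1L
  calls %>%
    group_by(species = .data$species_a, footprint = .data$footprint_a) %>%
    summarise(n_conserved = sum(.data$status == "conserved"),
              .groups = "drop") %>%
    mutate(conserved_in_all = .data$n_conserved == n_other)
}
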