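# IUPAC nucleotide ambiguity codes and small sequence helpers.
# Coordinates everywhere in the package are 1-based inclusive on the forward
# strand of the analyzed region; position 1 is the most distal residue.

.iupac_meaning <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set -> minimal covering IUPAC code
.iupac_code_of <- local({
  keys <- vapply(.iupac_meaning, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(.iupac_meaning), keys)
})

#' Bases matched by an IUPAC symbol
#'
#' @param symbol A single IUPAC nucleotide symbol.
#' @return Character vector of the A/C/G/T bases the symbol stands for.
#' @export
#' @examples
#' iupac_bases("D")
iupac_bases <- function(symbol) {
  symbol <- toupper(symbol)
  if (!symbol %in% names(.iupac_meaning)) {
    abort(paste0("invalid IUPAC symbol: '", symbol, "'"), class = "footcall_iupac_error")
  }
  .iupac_meaning[[symbol]]
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector drawn from A, C, G, T.
#' @return The single IUPAC symbol whose meaning is exactly that base set.
#' @export
#' @examples
#' iupac_code(c("A", "G", "T")) # "D"
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0L || !all(bases %in% c("A", "C", "G", "T"))) {
    abort("bases must be a non-empty subset of A, C, G, T",
          class = "footcall_iupac_error")
  }
  .iupac_code_of[[paste(bases, collapse = "")]]
}

.validate_iupac_string <- function(x, what = "pattern") {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(unique(chars), names(.iupac_meaning))
  if (nchar(x) == 0L) abort(paste(what, "must be non-empty"), class = "footcall_iupac_error")
  if (length(bad) > 0L) {
    abort(paste0("invalid IUPAC symbol(s) in ", what, ": ",
                 paste(bad, collapse = ", ")),
          class = "footcall_iupac_error")
  }
  invisible(toupper(x))
}

.validate_acgt <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    abort(paste0(what, " contains non-ACGT symbol '", chars[bad[1]],
                 "' at position ", bad[1]),
          class = "footcall_sequence_error")
  }
  seq
}

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' IUPAC ambiguity codes are complemented correctly.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) as.character(reverseComplement(DNAString(s))), "",
         USE.NAMES = FALSE)
}
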