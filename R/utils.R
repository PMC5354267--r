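#' Round half away from zero
#'
#' Commercial rounding used for all reported densities and percentages:
#' 0.5 always rounds away from zero (base R's \code{round} rounds half to
#' even, which disagrees with the tabulated arithmetic conventions of
#' published cross-link reports).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # small epsilon so exact halves survive binary representation (e.g.
  # 0.725 * 100 = 72.4999...)
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Normalize residue pairs so that i < j
#'
#' @param pairs two-column matrix or data.frame of residue positions.
#' @return two-column integer matrix with columns \code{i}, \code{j},
#'   \code{i < j}, self pairs dropped, duplicates retained.
#' @export
normalize_pairs <- function(pairs) {
  p <- as.matrix(pairs[, 1:2, drop = FALSE])
  storage.mode(p) <- "integer"
  swap <- p[, 1] > p[, 2]
  p[swap, ] <- p[swap, c(2, 1), drop = FALSE]
  p <- p[p[, 1] != p[, 2], , drop = FALSE]
  colnames(p) <- c("i", "j")
  p
}

#' Key string for a residue pair ("i-j", normalized)
#' @keywords internal
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "-")
}

# Residues that carry the NHS-ester end of sulfo-SDA; position 1 (protein
# N-terminus) is always linkable regardless of residue type.
SDA_ANCHORS <- c("K", "S", "T", "Y")

#' Anchor positions for SDA chemistry
#'
#' One end of a sulfo-SDA link must sit at lysine, serine, threonine,
#' tyrosine or the protein N-terminus; the diazirine end is non-specific.
#'
#' @param sequence character vector of one-letter residue codes, or a
#'   single string.
#' @return integer vector of anchor positions (always includes 1).
#' @export
sda_anchor_positions <- function(sequence) {
  aa <- as_residue_vector(sequence)
  sort(unique(c(1L, which(aa %in% SDA_ANCHORS))))
}

#' All SDA-linkable unordered residue pairs
#'
#' @param sequence residue codes (string or vector).
#' @param resolved optional logical vector; when given, both ends must be
#'   resolved.
#' @return two-column integer matrix (i < j) of linkable pairs.
#' @export
linkable_pairs <- function(sequence, resolved = NULL) {
  aa <- as_residue_vector(sequence)
  n <- length(aa)
  anchors <- sda_anchor_positions(aa)
  if (!is.null(resolved)) {
    stopifnot(length(resolved) == n)
    anchors <- anchors[resolved[anchors]]
    others <- which(resolved)
  } else {
    others <- seq_len(n)
  }
  if (length(anchors) == 0L || length(others) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  p <- cbind(i = rep(anchors, each = length(others)),
             j = rep(others, times = length(anchors)))
  p <- normalize_pairs(p)
  p[!duplicated(paste(p[, 1], p[, 2])), , drop = FALSE]
}

#' @keywords internal
as_residue_vector <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L) {
    strsplit(toupper(sequence), "")[[1]]
  } else {
    toupper(as.character(sequence))
  }
}

#' Integer percentage with half-away-from-zero rounding
#' @keywords internal
int_percent <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_away(100 * num / den, 0)
}
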