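#' Read a crystal structure into the package's residue-level model
#'
#' Parses PDB ATOM records (via bio3d), selects one chain, and extracts
#' one Calpha per residue. Alternate locations are resolved by highest
#' occupancy (ties: first record). Residues present in the supplied
#' sequence but absent from the coordinates are kept as unresolved
#' positions, matching crystallographic practice for disordered regions.
#' When \code{seq} is given, the structure's author numbering is aligned
#' to it by exact subsequence match of the resolved-residue string and
#' positions are re-expressed in sequence numbering.
#'
#' @param file path to a PDB file.
#' @param chain chain identifier; default: first chain in the file.
#' @param seq optional protein sequence for author-numbering alignment.
#' @return an \code{xl_structure}: \code{residues} data.frame (pos, aa,
#'   x, y, z, resolved, ss = NA), \code{offset_map} (author numbering ->
#'   sequence position), \code{source}.
#' @export
read_structure <- function(file, chain = NULL, seq = NULL) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", file)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain ", chain, " not found")
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes present; renumber the structure explicitly")
  }
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms in chain ", chain)
  # altLoc: keep highest occupancy, first on ties
  ca <- ca[order(ca$resno, -replace(ca$o, is.na(ca$o), 1)), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]

  aa1 <- bio3d::aa321(ca$resid)
  resolved_str <- paste(aa1, collapse = "")

  if (!is.null(seq)) {
    seq_str <- paste(as_residue_vector(seq), collapse = "")
    # exact windowed match of resolved stretches against the sequence:
    # align the first author residue, then require identity at every
    # resolved position under a constant offset
    offs <- NULL
    for (cand in seq_len(nchar(seq_str))) {
      off <- cand - ca$resno[1]
      pos <- ca$resno + off
      if (all(pos >= 1 & pos <= nchar(seq_str)) &&
          all(substring(seq_str, pos, pos) == aa1)) {
        offs <- off
        break
      }
    }
    if (is.null(offs)) stop("could not align structure residues to sequence")
    n <- nchar(seq_str)
    pos <- ca$resno + offs
    res <- data.frame(pos = seq_len(n),
                      aa = strsplit(seq_str, "")[[1]],
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      resolved = FALSE, ss = NA_character_,
                      stringsAsFactors = FALSE)
    res$x[pos] <- ca$x; res$y[pos] <- ca$y; res$z[pos] <- ca$z
    res$resolved[pos] <- TRUE
    offset_map <- stats::setNames(pos, ca$resno)
  } else {
    res <- data.frame(pos = ca$resno, aa = aa1,
                      x = ca$x, y = ca$y, z = ca$z,
                      resolved = TRUE, ss = NA_character_,
                      stringsAsFactors = FALSE)
    offset_map <- stats::setNames(ca$resno, ca$resno)
  }

  heavy <- at[at$elety %in% c("N", "CA", "C", "O") |
                grepl("^C[BGDEZH]", at$elety) |
                grepl("^[NOS][BGDEZH]", at$elety), , drop = FALSE]
  atoms <- NULL
  if (nrow(heavy) > 0L) {
    map_pos <- if (!is.null(seq)) unname(offset_map[as.character(heavy$resno)])
               else heavy$resno
    atoms <- data.frame(pos = map_pos, aa = bio3d::aa321(heavy$resid),
                        atom = heavy$elety, x = heavy$x, y = heavy$y,
                        z = heavy$z, stringsAsFactors = FALSE)
    atoms <- atoms[!is.na(atoms$pos), , drop = FALSE]
  }
  structure(list(residues = res, atoms = atoms, offset_map = offset_map,
                 source = file), class = "xl_structure")
}

#' Calpha-Calpha distance between two residues
#'
#' @param struct an \code{xl_structure}.
#' @param i,j 1-based residue positions (vectorized).
#' @return distance(s) in Angstrom; NA when either residue is unresolved.
#' @export
ca_distance <- function(struct, i, j) {
  res <- struct$residues
  idx <- function(p) {
    m <- match(p, res$pos)
    if (any(is.na(m))) stop("position out of range: ",
                            paste(p[is.na(m)], collapse = ", "))
    m
  }
  a <- idx(i); b <- idx(j)
  sqrt((res$x[a] - res$x[b])^2 + (res$y[a] - res$y[b])^2 +
         (res$z[a] - res$z[b])^2)
}

#' Classify residue pairs against a distance bound
#'
#' Each pair is \code{within} (distance <= threshold), \code{over}
#' (distance > threshold) or \code{unverifiable} (either residue
#' unresolved in the structure). The summary's over-percentage uses only
#' verifiable pairs in its denominator and is NA ("not determined") when
#' nothing is verifiable.
#'
#' @param pairs two-column matrix/data.frame of residue pairs.
#' @param struct an \code{xl_structure}.
#' @param threshold Calpha-Calpha bound in Angstrom (default 25).
#' @return list: \code{per_pair} data.frame (pos_a, pos_b, distance,
#'   class), \code{summary} list (n_within, n_over, n_unverifiable,
#'   percent_over).
#' @export
classify_links <- function(pairs, struct, threshold = 25) {
  p <- normalize_pairs(pairs)
  if (nrow(p) == 0L) {
    per <- data.frame(pos_a = integer(0), pos_b = integer(0),
                      distance = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
    return(list(per_pair = per,
                summary = list(n_within = 0L, n_over = 0L,
                               n_unverifiable = 0L,
                               percent_over = NA_real_,
                               threshold = threshold)))
  }
  d <- ca_distance(struct, p[, 1], p[, 2])
  cls <- ifelse(is.na(d), "unverifiable",
                ifelse(d <= threshold, "within", "over"))
  per <- data.frame(pos_a = p[, 1], pos_b = p[, 2], distance = d,
                    class = cls, stringsAsFactors = FALSE)
  nw <- sum(cls == "within"); no <- sum(cls == "over")
  list(per_pair = per,
       summary = list(n_within = nw, n_over = no,
                      n_unverifiable = sum(cls == "unverifiable"),
                      percent_over = int_percent(no, nw + no),
                      threshold = threshold))
}

#' Random-pair Calpha distance distribution
#'
#' Samples linkable pairs (one end K/S/T/Y/N-terminus, both resolved,
#' distinct residues) uniformly with replacement and returns their
#' Calpha-Calpha distances — the null distribution observed link
#' distances are compared against.
#'
#' @param struct an \code{xl_structure}.
#' @param sequence residue string aligned with the structure.
#' @param n_samples sample size.
#' @param seed RNG seed.
#' @return numeric vector of distances (Angstrom).
#' @export
random_distance_distribution <- function(struct, sequence,
                                         n_samples = 10000, seed = 1L) {
  lp <- linkable_pairs(sequence, resolved = struct$residues$resolved)
  if (nrow(lp) == 0L) stop("no linkable resolved pairs")
  set.seed(seed)
  k <- sample.int(nrow(lp), n_samples, replace = TRUE)
  ca_distance(struct, lp[k, 1], lp[k, 2])
}

#' Histogram counts over fixed-width distance bins
#' @keywords internal
distance_histogram <- function(observed, random, bin_width = 1) {
  hi <- ceiling(max(c(observed, random, 0), na.rm = TRUE) / bin_width)
  breaks <- seq(0, (hi + 1) * bin_width, by = bin_width)
  oc <- graphics::hist(observed[!is.na(observed)], breaks = breaks,
                       plot = FALSE)$counts
  rc <- graphics::hist(random[!is.na(random)], breaks = breaks,
                       plot = FALSE)$counts
  data.frame(bin_low = utils::head(breaks, -1),
             bin_high = breaks[-1], observed_count = oc,
             random_count = rc)
}

#' Full structural validation report for a set of accepted links
#'
#' Bundles distance classification, long-range fraction, link density
#' and the observed-versus-random distance histogram into one
#' machine-readable object.
#'
#' @param pairs two-column matrix/data.frame of accepted residue pairs.
#' @param struct an \code{xl_structure}.
#' @param sequence protein sequence.
#' @param threshold distance bound (Angstrom).
#' @param min_sep long-range separation bound (strict).
#' @param n_random random-pair sample size for the null histogram.
#' @param seed RNG seed for the random sample.
#' @return list of class \code{xl_validation_report}: \code{per_pair},
#'   \code{classification}, \code{long_range}, \code{links_per_residue},
#'   \code{histogram}, \code{threshold}, \code{n_pairs}.
#' @export
validation_report <- function(pairs, struct, sequence, threshold = 25,
                              min_sep = 11, n_random = 10000, seed = 1L) {
  p <- normalize_pairs(pairs)
  cl <- classify_links(p, struct, threshold)
  lr <- long_range_fraction(p, min_sep)
  n_res <- nrow(struct$residues)
  hist <- if (nrow(p) > 0L) {
    rnd <- random_distance_distribution(struct, sequence, n_random, seed)
    distance_histogram(cl$per_pair$distance, rnd)
  } else NULL
  structure(list(per_pair = cl$per_pair, classification = cl$summary,
                 long_range = lr,
                 links_per_residue = links_per_residue(nrow(p), n_res),
                 histogram = hist, threshold = threshold,
                 n_pairs = nrow(p)),
            class = "xl_validation_report")
}
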