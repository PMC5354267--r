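#' Fraction of residues in beta strands
#'
#' @param ss per-residue labels in \{H, E, C\}.
#' @return integer percentage of residues labelled E.
#' @export
beta_residue_fraction <- function(ss) {
  if (length(ss) == 0L) stop("empty annotation")
  int_percent(sum(ss == "E"), length(ss))
}

#' Beta-strand content of observed residue pairs
#'
#' Counts residue pairs with at least one end (default) or both ends in
#' a beta strand.
#'
#' @param pairs two-column matrix/data.frame of residue pairs.
#' @param ss per-residue labels.
#' @param mode \code{"at_least_one"} or \code{"both"}.
#' @return list: \code{count}, \code{percent} (integer), \code{total}.
#' @export
observed_pair_beta_fraction <- function(pairs, ss,
                                        mode = c("at_least_one", "both")) {
  mode <- match.arg(mode)
  p <- normalize_pairs(pairs)
  isE <- ss == "E"
  hit <- if (mode == "at_least_one") isE[p[, 1]] | isE[p[, 2]] else
    isE[p[, 1]] & isE[p[, 2]]
  list(count = sum(hit), percent = int_percent(sum(hit), nrow(p)),
       total = nrow(p))
}

#' Expected beta-strand content of unbiased residue pairs
#'
#' The combinatorial expectation if cross-linked pairs were drawn
#' without secondary-structure bias. Over all unordered distinct pairs
#' the at-least-one expectation has the closed form
#' \eqn{1 - C(n-b,2)/C(n,2)} with b beta residues of n; the both-ends
#' form is \eqn{C(b,2)/C(n,2)}. The \code{linkable_pairs} universe
#' restricts to pairs with one end at K/S/T/Y/N-terminus (requires
#' \code{sequence}) and is evaluated by exact enumeration.
#'
#' @param ss per-residue labels.
#' @param mode \code{"at_least_one"} or \code{"both"}.
#' @param universe \code{"all_pairs"} or \code{"linkable_pairs"}.
#' @param sequence residue string; needed for the linkable universe.
#' @return percentage (real-valued, not integer-rounded — callers round
#'   for presentation).
#' @export
expected_pair_beta_fraction <- function(ss,
                                        mode = c("at_least_one", "both"),
                                        universe = c("all_pairs",
                                                     "linkable_pairs"),
                                        sequence = NULL) {
  mode <- match.arg(mode)
  universe <- match.arg(universe)
  n <- length(ss)
  if (n < 2) stop("need at least two residues")
  b <- sum(ss == "E")
  if (universe == "all_pairs") {
    frac <- if (mode == "at_least_one") {
      1 - choose(n - b, 2) / choose(n, 2)
    } else {
      choose(b, 2) / choose(n, 2)
    }
  } else {
    if (is.null(sequence)) stop("sequence required for linkable universe")
    p <- linkable_pairs(sequence)
    if (nrow(p) == 0L) stop("no linkable pairs")
    isE <- ss == "E"
    hit <- if (mode == "at_least_one") isE[p[, 1]] | isE[p[, 2]] else
      isE[p[, 1]] & isE[p[, 2]]
    frac <- mean(hit)
  }
  100 * frac
}

#' Lysine/arginine content by secondary-structure class
#'
#' Tryptic anchor density overall, inside beta strands, and outside
#' them — low K/R density in strands starves strand regions of both
#' cross-linkable lysines and tryptic cleavage sites.
#'
#' @param sequence residue string or vector.
#' @param ss per-residue labels, aligned with the sequence.
#' @return list: \code{percent} (overall, within_E, outside_E integer
#'   percentages), \code{counts} (K+R counts in the same classes),
#'   \code{n} (class sizes).
#' @export
kr_content_by_class <- function(sequence, ss) {
  aa <- as_residue_vector(sequence)
  stopifnot(length(aa) == length(ss))
  kr <- aa %in% c("K", "R")
  isE <- ss == "E"
  cnt <- c(overall = sum(kr), within_E = sum(kr & isE),
           outside_E = sum(kr & !isE))
  n <- c(overall = length(aa), within_E = sum(isE),
         outside_E = sum(!isE))
  pct <- c(overall = int_percent(cnt[[1]], n[[1]]),
           within_E = int_percent(cnt[[2]], n[[2]]),
           outside_E = int_percent(cnt[[3]], n[[3]]))
  list(percent = pct, counts = cnt, n = n)
}

#' Geometric fallback secondary-structure assignment
#'
#' Labels residues from Calpha geometry alone when no external
#' annotation is available: a window i..i+3 votes helix when its
#' Calpha(i)-Calpha(i+3) distance lies in 5.0-6.5 Angstrom, extended
#' when in 9.9-11.0 Angstrom; residues take the majority vote of the
#' windows covering them, requiring at least two concordant votes
#' (ties, single votes and unvoted residues are coil). The extended
#' band starts at 9.9 rather than ~9 Angstrom because tight-turn
#' chords reach 9.2-9.8 and would otherwise be called strand. Far
#' coarser than a hydrogen-bond-based assignment — intended for toy
#' structures and smoke tests, not for real annotation work.
#'
#' @param struct an \code{xl_structure}.
#' @return per-residue labels in \{H, E, C\}; unresolved residues get
#'   \code{"C"}.
#' @export
assign_ss <- function(struct) {
  res <- struct$residues
  n <- nrow(res)
  votes <- matrix(0L, nrow = n, ncol = 2,
                  dimnames = list(NULL, c("H", "E")))
  if (n >= 4) {
    for (i in seq_len(n - 3)) {
      span <- i:(i + 3)
      if (any(!res$resolved[span])) next
      d <- sqrt((res$x[i] - res$x[i + 3])^2 + (res$y[i] - res$y[i + 3])^2 +
                  (res$z[i] - res$z[i + 3])^2)
      if (d >= 5.0 && d <= 6.5) votes[span, "H"] <- votes[span, "H"] + 1L
      if (d >= 9.9 && d <= 11.0) votes[span, "E"] <- votes[span, "E"] + 1L
    }
  }
  lab <- rep("C", n)
  lab[votes[, "H"] >= 2L & votes[, "H"] > votes[, "E"]] <- "H"
  lab[votes[, "E"] >= 2L & votes[, "E"] > votes[, "H"]] <- "E"
  lab
}

#' Theoretical maximum per-residue accessibilities
#'
#' Gly-X-Gly theoretical maxima (Angstrom^2) used to normalize absolute
#' solvent-accessible surface areas into relative accessibilities;
#' shipped as a plain-text data file so it can be audited or swapped.
#'
#' @return named numeric vector over the 20 one-letter codes.
#' @export
max_asa_table <- function() {
  f <- system.file("extdata", "max_asa_theoretical.csv",
                   package = "hdclms", mustWork = TRUE)
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  stats::setNames(d$max_asa, d$aa)
}

# Deterministic quasi-uniform sphere dots (golden spiral).
sphere_dots <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Dot-sampled solvent-accessible surface area per atom.
sasa_atoms <- function(xyz, radii, probe = 1.4, n_dots = 960) {
  n <- nrow(xyz)
  ext <- radii + probe
  dots <- sphere_dots(n_dots)
  area <- numeric(n)
  cut2 <- (outer(ext, ext, "+"))^2
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < cut2[i, ] & seq_len(n) != i)
    pts <- sweep(dots * ext[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      exposed <- rep(TRUE, n_dots)
      for (j in nb) {
        dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        exposed <- exposed & dd >= ext[j]^2
        if (!any(exposed)) break
      }
      frac <- mean(exposed)
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * ext[i]^2
  }
  area
}

ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Relative solvent accessibility profile
#'
#' Shrake-Rupley-style dot sampling (probe 1.4 Angstrom, \code{n_dots}
#' points per atom) over the structure's heavy atoms, normalized by the
#' theoretical maximum accessibility of each residue type
#' (\code{\link{max_asa_table}}). Calpha-only structures fall back to
#' one sphere per residue whose radius is chosen so an isolated residue
#' scores RSA 1 under the same normalization; this mode is flagged
#' approximate in the result.
#'
#' @param struct an \code{xl_structure}.
#' @param n_dots dots per atom (>= 960 recommended).
#' @param probe probe radius in Angstrom.
#' @return list of class \code{xl_rsa}: \code{rsa} (per-position
#'   fraction, NA for unresolved residues, capped at 1.5),
#'   \code{sasa} (absolute Angstrom^2), \code{approximate} (TRUE in
#'   Calpha-only mode).
#' @export
compute_rsa <- function(struct, n_dots = 960, probe = 1.4) {
  res <- struct$residues
  maxasa <- max_asa_table()
  if (!is.null(struct$atoms) && nrow(struct$atoms) > 0L) {
    at <- struct$atoms
    elem <- substr(at$atom, 1, 1)
    radii <- ELEMENT_RADII[elem]
    radii[is.na(radii)] <- 1.70
    area <- sasa_atoms(as.matrix(at[, c("x", "y", "z")]), radii,
                       probe, n_dots)
    per_res <- tapply(area, at$pos, sum)
    approximate <- FALSE
  } else {
    keep <- which(res$resolved)
    if (length(keep) == 0L) stop("no coordinates")
    radii <- sqrt(maxasa[res$aa[keep]] / (4 * pi)) - probe
    area <- sasa_atoms(as.matrix(res[keep, c("x", "y", "z")]), radii,
                       probe, n_dots)
    per_res <- stats::setNames(area, res$pos[keep])
    approximate <- TRUE
  }
  rsa <- rep(NA_real_, nrow(res))
  sasa <- rep(NA_real_, nrow(res))
  idx <- match(as.integer(names(per_res)), res$pos)
  sasa[idx] <- as.numeric(per_res)
  rsa[idx] <- pmin(as.numeric(per_res) / maxasa[res$aa[idx]], 1.5)
  structure(list(rsa = rsa, sasa = sasa, approximate = approximate),
            class = "xl_rsa")
}

#' Mean relative accessibility by secondary-structure class
#'
#' Mean RSA (as a percentage) for beta-strand residues versus all other
#' residues, optionally restricted to a residue subset such as the SDA
#' anchors \{K, S, T, Y\}.
#'
#' @param rsa an \code{xl_rsa} or a numeric per-position RSA vector.
#' @param ss per-residue labels.
#' @param sequence residue string (required when \code{residue_subset}
#'   is given).
#' @param residue_subset optional one-letter codes to restrict to.
#' @return list: \code{mean_percent} (within_E, outside_E; NA when a
#'   class is empty), \code{n} (residues contributing to each mean).
#' @export
rsa_summary <- function(rsa, ss, sequence = NULL, residue_subset = NULL) {
  v <- if (inherits(rsa, "xl_rsa")) rsa$rsa else rsa
  stopifnot(length(v) == length(ss))
  keep <- !is.na(v)
  if (!is.null(residue_subset)) {
    if (is.null(sequence)) stop("sequence required with residue_subset")
    aa <- as_residue_vector(sequence)
    keep <- keep & aa %in% residue_subset
  }
  isE <- ss == "E"
  cls_mean <- function(sel) {
    if (!any(sel)) return(NA_real_)
    100 * mean(v[sel])
  }
  list(mean_percent = c(within_E = cls_mean(keep & isE),
                        outside_E = cls_mean(keep & !isE)),
       n = c(within_E = sum(keep & isE), outside_E = sum(keep & !isE)))
}
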