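#' Configuration for the synthetic HD-CLMS data generator
#'
#' Bundles all knobs of the simulator: size and fold of the toy protein,
#' number of LC-MS runs, PSM counts, score-distribution parameters and the
#' fraction of residues left unresolved in the toy "crystal structure".
#' Every random choice downstream is driven by \code{seed}, so a config
#' fully determines the generated data.
#'
#' The decoy model mirrors a target-decoy search against a decoy database
#' of the same size as the target: for every false target-target match the
#' search is expected to produce two target-decoy (TD) and one decoy-decoy
#' (DD) match, hence \code{decoy_ratio = 3} and \code{decoy_td_share = 2/3}
#' by default. This 1:2:1 proportion is what makes the
#' \code{(TD - DD) / TT} estimator unbiased.
#'
#' @param n_residues protein length (>= 20).
#' @param fold_spec one of \code{"helix-bundle"}, \code{"beta-sandwich"},
#'   \code{"mixed"}.
#' @param n_runs number of simulated LC-MS runs (>= 1).
#' @param n_true_psms,n_false_psms counts of true and false target-target
#'   PSMs to simulate.
#' @param true_score_mean,true_score_sd,false_score_mean,false_score_sd
#'   location/scale of the (0-truncated) Gaussian score distributions.
#'   Decoy PSMs draw from the false distribution, the assumption that
#'   underlies target-decoy FDR.
#' @param unresolved_fraction fraction of residues without coordinates in
#'   the toy structure.
#' @param decoy_ratio expected number of decoy-flagged PSMs per false
#'   target-target PSM.
#' @param decoy_td_share share of decoy PSMs with exactly one decoy end.
#' @param link_threshold Calpha-Calpha bound (Angstrom) used to define
#'   ground-truth links.
#' @param backbone also place N, C, O, CB atoms at idealized geometry
#'   (used by solvent-accessibility tests).
#' @param seed integer RNG seed.
#' @return object of class \code{xl_config} (a validated list).
#' @export
synthetic_config <- function(n_residues = 120,
                             fold_spec = c("mixed", "helix-bundle",
                                           "beta-sandwich"),
                             n_runs = 4,
                             n_true_psms = 600,
                             n_false_psms = 200,
                             true_score_mean = 12, true_score_sd = 2,
                             false_score_mean = 6, false_score_sd = 2,
                             unresolved_fraction = 0,
                             decoy_ratio = 3,
                             decoy_td_share = 2 / 3,
                             link_threshold = 25,
                             backbone = FALSE,
                             seed = 1L) {
  fold_spec <- match.arg(fold_spec)
  stopifnot(n_residues >= 20, n_runs >= 1,
            unresolved_fraction >= 0, unresolved_fraction <= 1,
            decoy_td_share >= 0, decoy_td_share <= 1,
            decoy_ratio >= 0, link_threshold >= 0)
  if (true_score_mean < 0 || false_score_mean < 0 ||
      true_score_sd <= 0 || false_score_sd <= 0) {
    stop("score distributions must have non-negative location and positive scale")
  }
  structure(list(
    n_residues = as.integer(n_residues), fold_spec = fold_spec,
    n_runs = as.integer(n_runs),
    n_true_psms = as.integer(n_true_psms),
    n_false_psms = as.integer(n_false_psms),
    true_score_mean = true_score_mean, true_score_sd = true_score_sd,
    false_score_mean = false_score_mean, false_score_sd = false_score_sd,
    unresolved_fraction = unresolved_fraction,
    decoy_ratio = decoy_ratio, decoy_td_share = decoy_td_share,
    link_threshold = link_threshold, backbone = backbone,
    seed = as.integer(seed)
  ), class = "xl_config")
}

# Approximate vertebrate amino-acid background frequencies; keeps K/S/T/Y
# anchors at realistic density (~20% of residues).
AA_FREQS <- c(A = 8.3, R = 5.7, N = 4.4, D = 5.3, C = 1.8, E = 6.2, Q = 3.7,
              G = 7.2, H = 2.2, I = 5.3, L = 9.1, K = 5.8, M = 2.3, F = 3.9,
              P = 5.1, S = 6.9, T = 5.9, W = 1.3, Y = 3.2, V = 6.6)

# Segment layout per fold: (type, length) templates cycled until n is filled.
fold_segments <- function(fold_spec, n) {
  template <- switch(fold_spec,
    "helix-bundle"  = list(c("H", 14), c("C", 3)),
    "beta-sandwich" = list(c("E", 7), c("C", 3)),
    "mixed"         = list(c("H", 12), c("C", 3), c("E", 7), c("C", 3))
  )
  segs <- list(); total <- 0L; k <- 0L
  while (total < n) {
    t <- template[[k %% length(template) + 1L]]
    len <- min(as.integer(t[2]), n - total)
    segs[[length(segs) + 1L]] <- list(type = t[1], len = len)
    total <- total + len
    k <- k + 1L
  }
  if (sum(vapply(segs, `[[`, 1L, "len")) != n) stop("internal: bad layout")
  segs
}

# Ideal-geometry Calpha trace: helix 1.5 A rise / 100 deg twist on a 2.3 A
# radius; strand 3.3 A rise with alternating 0.95 A zigzag; loops are
# semicircular turns whose chord length equals the virtual CA-CA bond.
# After assembly every consecutive step is renormalized to exactly 3.8 A.
build_ca_trace <- function(segs) {
  step <- 3.8
  pts <- matrix(0, nrow = 0, ncol = 3)
  pos <- c(0, 0, 0); dir <- 1
  for (si in seq_along(segs)) {
    s <- segs[[si]]
    if (s$type == "C") {
      L <- s$len
      r <- step / (2 * sin(pi / (2 * (L + 1))))
      ctr <- pos + c(r, 0, 0)
      th <- pi * seq_len(L) / (L + 1)
      loop <- cbind(ctr[1] - r * cos(th), ctr[2], ctr[3] + dir * r * sin(th))
      pts <- rbind(pts, loop)
      pos <- ctr + c(r, 0, 0)   # theta = pi end point
      dir <- -dir
    } else if (s$type == "H") {
      t <- seq_len(s$len) - 1
      ang <- t * 100 * pi / 180
      axis <- pos - c(2.3, 0, 0)
      seg <- cbind(axis[1] + 2.3 * cos(ang), axis[2] + 2.3 * sin(ang),
                   axis[3] + dir * 1.5 * t)
      pts <- rbind(pts, seg)
      pos <- seg[nrow(seg), ]
    } else {                    # strand
      t <- seq_len(s$len) - 1
      # lateral offset chosen so the zigzag step is exactly 3.8 A
      seg <- cbind(pos[1] + sqrt(3.8^2 - 3.3^2) * (t %% 2),
                   pos[2], pos[3] + dir * 3.3 * t)
      pts <- rbind(pts, seg)
      pos <- seg[nrow(seg), ]
    }
  }
  # renormalize steps to the canonical virtual bond length
  out <- pts
  for (i in 2:nrow(pts)) {
    v <- pts[i, ] - pts[i - 1, ]
    out[i, ] <- out[i - 1, ] + v / sqrt(sum(v^2)) * step
  }
  out
}

# Idealized backbone/CB placement from the CA trace (approximate bond
# geometry; sufficient for surface-accessibility work on toys).
place_backbone <- function(ca) {
  n <- nrow(ca)
  unit <- function(v) v / sqrt(sum(v^2))
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - (ca[i + 1, ] - ca[i, ])
    nxt  <- if (i < n) ca[i + 1, ] else ca[i, ] + (ca[i, ] - ca[i - 1, ])
    to_prev <- unit(prev - ca[i, ]); to_next <- unit(nxt - ca[i, ])
    bis <- to_prev + to_next
    bis <- if (sqrt(sum(bis^2)) < 1e-8) c(0, 0, 1) else unit(bis)
    perp <- pracma_cross(to_next, to_prev)
    perp <- if (sqrt(sum(perp^2)) < 1e-8) c(0, 1, 0) else unit(perp)
    N  <- ca[i, ] + 1.46 * to_prev
    C  <- ca[i, ] + 1.52 * to_next
    O  <- C + 1.23 * unit(-bis + 0.5 * perp)
    CB <- ca[i, ] - 1.53 * unit(bis + 0.8 * perp)
    atoms[[i]] <- rbind(N = N, CA = ca[i, ], C = C, O = O, CB = CB)
  }
  atoms
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a toy protein: sequence, structure and secondary structure
#'
#' Builds a compact Calpha trace from ideal secondary-structure geometry
#' according to \code{fold_spec}, draws a random sequence from background
#' amino-acid frequencies, and marks
#' \code{round(unresolved_fraction * n)} randomly chosen residues as
#' unresolved (numbered but without coordinates, matching PDB semantics
#' for disordered residues).
#'
#' @param config an \code{\link{synthetic_config}} object.
#' @return list with \code{structure} (class \code{xl_structure}),
#'   \code{ss} (per-residue labels in H/E/C), and \code{sequence}
#'   (single string).
#' @export
make_structure <- function(config) {
  stopifnot(inherits(config, "xl_config"))
  set.seed(config$seed)
  n <- config$n_residues
  segs <- fold_segments(config$fold_spec, n)
  ss <- unlist(lapply(segs, function(s) rep(s$type, s$len)))
  ca <- build_ca_trace(segs)
  aa <- sample(names(AA_FREQS), n, replace = TRUE, prob = AA_FREQS)
  n_unres <- round(config$unresolved_fraction * n)
  resolved <- rep(TRUE, n)
  if (n_unres > 0) resolved[sample.int(n, n_unres)] <- FALSE

  res <- data.frame(pos = seq_len(n), aa = aa,
                    x = ca[, 1], y = ca[, 2], z = ca[, 3],
                    resolved = resolved, ss = ss,
                    stringsAsFactors = FALSE)
  res$x[!resolved] <- NA_real_
  res$y[!resolved] <- NA_real_
  res$z[!resolved] <- NA_real_

  atoms <- NULL
  if (isTRUE(config$backbone)) {
    ba <- place_backbone(ca)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (!resolved[i]) return(NULL)
      m <- ba[[i]]
      data.frame(pos = i, aa = aa[i], atom = rownames(m),
                 x = m[, 1], y = m[, 2], z = m[, 3],
                 stringsAsFactors = FALSE)
    }))
    rownames(atoms) <- NULL
  }

  st <- structure(list(residues = res, atoms = atoms,
                       source = "synthetic"), class = "xl_structure")
  list(structure = st, ss = ss, sequence = paste(aa, collapse = ""))
}

#' Ground-truth cross-links compatible with SDA chemistry and a distance bound
#'
#' Enumerates all residue pairs with one end at K/S/T/Y or the N-terminus
#' whose Calpha-Calpha distance in the structure is at most
#' \code{threshold} Angstrom. Pairs are normalized (i < j), self pairs
#' excluded, and both ends must be resolved.
#'
#' @param struct an \code{xl_structure}.
#' @param sequence residue string aligned to the structure.
#' @param threshold distance bound in Angstrom (default 25, the bound at
#'   which observed sulfo-SDA Calpha-Calpha distances merge with random).
#' @return two-column integer matrix of linkable true pairs.
#' @export
make_true_links <- function(struct, sequence, threshold = 25) {
  stopifnot(inherits(struct, "xl_structure"))
  res <- struct$residues
  cand <- linkable_pairs(sequence, resolved = res$resolved)
  if (nrow(cand) == 0L) return(cand)
  d <- sqrt((res$x[cand[, 1]] - res$x[cand[, 2]])^2 +
            (res$y[cand[, 1]] - res$y[cand[, 2]])^2 +
            (res$z[cand[, 1]] - res$z[cand[, 2]])^2)
  cand[!is.na(d) & d <= threshold, , drop = FALSE]
}

# 0-truncated Gaussian scores (rejection sampling; vectorized, seeded by
# the caller's RNG state).
rtrunc_score <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  s <- stats::rnorm(n, mean, sd)
  while (any(bad <- s < 0)) s[bad] <- stats::rnorm(sum(bad), mean, sd)
  s
}

peptide_window <- function(sequence, pos, flank = 5L) {
  aa <- as_residue_vector(sequence)
  start <- max(1L, pos - flank)
  end <- min(length(aa), pos + flank - 1L)
  list(pep = paste(aa[start:end], collapse = ""),
       link_pos = pos - start + 1L)
}

#' Simulate scored target/decoy PSM tables with known ground truth
#'
#' True PSMs sample residue pairs from \code{truth_links} with scores from
#' the true distribution; false target-target PSMs sample uniformly among
#' non-truth linkable pairs with scores from the false distribution; decoy
#' PSMs (expected \code{decoy_ratio} per false PSM, split between
#' one-decoy TD and two-decoy DD by \code{decoy_td_share}) also draw from
#' the false distribution. Each PSM is assigned to one LC-MS run uniformly
#' at random, so runs share identifications of well-supported pairs but
#' differ in their single-PSM tails.
#'
#' @param truth_links matrix of true pairs from
#'   \code{\link{make_true_links}}.
#' @param config the generating \code{\link{synthetic_config}}.
#' @param sequence the protein sequence (for peptide windows).
#' @return list with \code{psms} (data.frame in the canonical PSM-table
#'   layout) and \code{truth} (list: \code{true_links}, \code{psm_labels}
#'   named character vector over psm_id with values
#'   true/false/decoy).
#' @export
simulate_psms <- function(truth_links, config, sequence) {
  stopifnot(inherits(config, "xl_config"))
  if (config$n_true_psms > 0 && nrow(truth_links) == 0L) {
    stop("truth_links is empty but n_true_psms > 0")
  }
  set.seed(config$seed + 7919L)  # offset so structure and PSM draws differ
  all_link <- linkable_pairs(sequence)
  truth_keys <- pair_key(truth_links[, 1], truth_links[, 2])
  nontruth <- all_link[!(pair_key(all_link[, 1], all_link[, 2]) %in%
                           truth_keys), , drop = FALSE]

  n_t <- config$n_true_psms
  n_f <- config$n_false_psms
  n_d <- round(config$decoy_ratio * n_f)
  if (n_f > 0 && nrow(nontruth) == 0L) {
    stop("no non-truth linkable pairs available for false PSMs")
  }

  draw_pairs <- function(pool, k) {
    if (k == 0) return(pool[integer(0), , drop = FALSE])
    pool[sample.int(nrow(pool), k, replace = TRUE), , drop = FALSE]
  }
  tp <- draw_pairs(truth_links, n_t)
  fp <- draw_pairs(nontruth, n_f)
  dp <- draw_pairs(all_link, n_d)

  lab <- c(rep("true", n_t), rep("false", n_f), rep("decoy", n_d))
  pairs <- rbind(tp, fp, dp)
  n_all <- nrow(pairs)
  score <- c(rtrunc_score(n_t, config$true_score_mean, config$true_score_sd),
             rtrunc_score(n_f + n_d, config$false_score_mean,
                          config$false_score_sd))

  dec_a <- rep(FALSE, n_all); dec_b <- rep(FALSE, n_all)
  if (n_d > 0) {
    idx <- n_t + n_f + seq_len(n_d)
    dd <- stats::runif(n_d) >= config$decoy_td_share   # two-decoy share
    which_end <- stats::runif(n_d) < 0.5
    dec_a[idx] <- dd | which_end
    dec_b[idx] <- dd | !which_end
  }

  runs <- paste0("run", sample.int(config$n_runs, n_all, replace = TRUE))
  wins_a <- lapply(pairs[, 1], function(p) peptide_window(sequence, p))
  wins_b <- lapply(pairs[, 2], function(p) peptide_window(sequence, p))
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  pep_a <- vapply(wins_a, `[[`, "", "pep")
  pep_b <- vapply(wins_b, `[[`, "", "pep")
  pep_a[dec_a] <- vapply(pep_a[dec_a], revstr, "")
  pep_b[dec_b] <- vapply(pep_b[dec_b], revstr, "")

  ids <- sprintf("PSM%06d", seq_len(n_all))
  psms <- data.frame(
    psm_id = ids, run_id = runs,
    pep_seq_a = pep_a, pep_seq_b = pep_b,
    link_pos_a = vapply(wins_a, `[[`, 1L, "link_pos"),
    link_pos_b = vapply(wins_b, `[[`, 1L, "link_pos"),
    prot_pos_a = pairs[, 1], prot_pos_b = pairs[, 2],
    score = score, is_decoy_a = dec_a, is_decoy_b = dec_b,
    stringsAsFactors = FALSE
  )
  labels <- stats::setNames(lab, ids)
  list(psms = psms,
       truth = list(true_links = truth_links, psm_labels = labels))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: structure + ground-truth links + PSM table.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{structure}, \code{ss}, \code{sequence},
#'   \code{true_links}, \code{psms}, \code{truth}.
#' @export
simulate_dataset <- function(config) {
  sd <- make_structure(config)
  tl <- make_true_links(sd$structure, sd$sequence, config$link_threshold)
  sim <- simulate_psms(tl, config, sd$sequence)
  c(sd, list(true_links = tl, psms = sim$psms, truth = sim$truth))
}
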