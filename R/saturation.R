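#' Split accepted residue pairs by LC-MS run
#'
#' Expands the semicolon-joined \code{runs} column of an accepted
#' residue-pair table into a per-run list of pair-key sets.
#'
#' @param accepted data.frame with \code{key} and \code{runs} columns
#'   (as produced by \code{\link{group_entities}}).
#' @return named list: run id -> character vector of pair keys.
#' @export
pairs_by_run <- function(accepted) {
  if (nrow(accepted) == 0L) return(list())
  rl <- strsplit(accepted$runs, ";", fixed = TRUE)
  long <- data.frame(run = unlist(rl),
                     key = rep(accepted$key, lengths(rl)),
                     stringsAsFactors = FALSE)
  lapply(split(long$key, long$run), unique)
}

cumulative_union_sizes <- function(sets, ord) {
  seen <- character(0)
  out <- integer(length(ord))
  for (r in seq_along(ord)) {
    seen <- unique(c(seen, sets[[ord[r]]]))
    out[r] <- length(seen)
  }
  out
}

#' Saturation curve: unique residue pairs accumulated over runs
#'
#' For each permutation of the run order, counts the cumulative number
#' of unique residue pairs after each successive run; returns the
#' per-rank mean (and SD) over permutations. With at most
#' \code{exact_max} runs all orders are enumerated, giving the exact
#' expectation; otherwise \code{n_permutations} random orders are drawn
#' under \code{seed}.
#'
#' @param sets named list: run -> character vector (or any atomic
#'   vector) of identifications; see \code{\link{pairs_by_run}}.
#' @param n_permutations number of random orders when sampling.
#' @param seed RNG seed.
#' @param exact_max run count up to which exhaustive enumeration is
#'   used (default 7).
#' @return list of class \code{xl_saturation}: \code{mean_cumulative},
#'   \code{sd_cumulative}, \code{n_runs}, \code{n_permutations}
#'   (\code{factorial(n_runs)} in exact mode), \code{exact},
#'   \code{total} (order-independent final union size).
#' @export
saturation_curve <- function(sets, n_permutations = 100, seed = 1L,
                             exact_max = 7) {
  m <- length(sets)
  stopifnot(m >= 1)
  sets <- lapply(sets, unique)
  exact <- m <= exact_max
  orders <- if (exact) {
    perm_all(m)
  } else {
    set.seed(seed)
    lapply(seq_len(n_permutations), function(k) sample.int(m))
  }
  mat <- vapply(orders, function(o) cumulative_union_sizes(sets, o),
                integer(m))
  mat <- matrix(mat, nrow = m)
  structure(list(
    mean_cumulative = rowMeans(mat),
    sd_cumulative = apply(mat, 1, stats::sd),
    n_runs = m,
    n_permutations = length(orders),
    exact = exact,
    total = length(unique(unlist(sets)))
  ), class = "xl_saturation")
}

# all permutations of 1..m (m small)
perm_all <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (sub in perm_all(m - 1)) {
    for (pos in 0:(m - 1)) {
      out[[length(out) + 1L]] <- append(sub, m, after = pos)
    }
  }
  out
}

#' Marginal gains of a saturation curve
#'
#' First differences of the mean cumulative counts, plus a saturation
#' flag: saturated when the final marginal gain is below
#' \code{gain_fraction} of the total.
#'
#' @param curve an \code{xl_saturation}.
#' @param gain_fraction saturation threshold as a fraction of the total
#'   (default 0.01).
#' @return list: \code{gains} (length n_runs; first element is the rank-1
#'   mean itself), \code{saturated}.
#' @export
saturation_slope <- function(curve, gain_fraction = 0.01) {
  mc <- curve$mean_cumulative
  gains <- diff(c(0, mc))
  final_gain <- if (length(mc) > 1) gains[length(gains)] else 0
  list(gains = gains,
       saturated = final_gain < gain_fraction * curve$total)
}

#' Exact expected accumulation by inclusion-exclusion
#'
#' Analytic expectation of the cumulative union size after r of m runs
#' under a uniformly random order: each identification seen in k of the
#' m runs is covered with probability 1 - C(m-k, r)/C(m, r). Used as an
#' independent oracle for \code{\link{saturation_curve}}.
#'
#' @param sets list of per-run identification sets.
#' @return numeric vector of expected cumulative counts per rank.
#' @export
expected_accumulation <- function(sets) {
  m <- length(sets)
  items <- unique(unlist(sets))
  k <- vapply(items, function(x)
    sum(vapply(sets, function(s) x %in% s, FALSE)), 0L)
  vapply(seq_len(m), function(r)
    sum(1 - choose(m - k, r) / choose(m, r)), 0)
}
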