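#' Protease cleavage rules
#'
#' An enzyme rule names the residues it cleaves after and the residues
#' that block cleavage when they follow the site. \code{trypsin} cleaves
#' after K/R, blocked by a following proline (the classical rule; the
#' proline block can be switched off). \code{gluc} cleaves after
#' glutamate; \code{cleave_d = TRUE} adds aspartate (phosphate-buffer
#' specificity).
#'
#' @param cleave_after character vector of P1 residues.
#' @param blocked_by_next residues at P1' that suppress cleavage.
#' @param name enzyme name.
#' @return an \code{enzyme_rule} list.
#' @export
enzyme_rule <- function(cleave_after, blocked_by_next = character(0),
                        name = "custom") {
  aa20 <- names(AA_FREQS)
  stopifnot(all(cleave_after %in% aa20), all(blocked_by_next %in% aa20))
  structure(list(name = name, cleave_after = cleave_after,
                 blocked_by_next = blocked_by_next),
            class = "enzyme_rule")
}

#' @rdname enzyme_rule
#' @param proline_rule block cleavage before proline (default TRUE).
#' @export
trypsin <- function(proline_rule = TRUE) {
  enzyme_rule(c("K", "R"), if (proline_rule) "P" else character(0),
              name = "trypsin")
}

#' @rdname enzyme_rule
#' @param cleave_d also cleave after aspartate.
#' @export
gluc <- function(cleave_d = FALSE) {
  enzyme_rule(if (cleave_d) c("E", "D") else "E", name = "gluc")
}

#' Cleavage sites of an enzyme on a sequence
#'
#' A site is a position i such that residue i is in the enzyme's
#' cleave-after set and residue i+1 is not in its blocking set; the chain
#' C-terminus is never a site.
#'
#' @param sequence residue string or vector.
#' @param rule an \code{\link{enzyme_rule}}.
#' @param on_noncanonical \code{"fail"} (default) or \code{"skip"}
#'   non-standard residue codes.
#' @return increasing integer vector of cleavage positions.
#' @export
cleavage_sites <- function(sequence, rule, on_noncanonical = c("fail", "skip")) {
  on_noncanonical <- match.arg(on_noncanonical)
  aa <- as_residue_vector(sequence)
  bad <- !(aa %in% names(AA_FREQS))
  if (any(bad) && on_noncanonical == "fail") {
    stop("non-canonical residues at positions ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  n <- length(aa)
  if (n < 2) return(integer(0))
  i <- seq_len(n - 1)
  sites <- i[aa[i] %in% rule$cleave_after &
               !(aa[i + 1] %in% rule$blocked_by_next)]
  as.integer(sites)
}

#' In-silico digestion with missed cleavages
#'
#' Co-digestion with several enzymes unions their cleavage sites. A
#' peptide runs from one boundary to another and spans some number of
#' internal (missed) sites; all peptides with at most \code{max_missed}
#' missed cleavages are returned. At \code{max_missed = 0} the peptides
#' tile the sequence exactly.
#'
#' @param sequence residue string or vector.
#' @param rules a single \code{\link{enzyme_rule}} or list of rules.
#' @param max_missed maximum missed cleavages (>= 0).
#' @return data.frame: start, end (1-based inclusive), length,
#'   missed_cleavages, enzymes.
#' @export
digest <- function(sequence, rules, max_missed = 4) {
  stopifnot(max_missed >= 0)
  if (inherits(rules, "enzyme_rule")) rules <- list(rules)
  aa <- as_residue_vector(sequence)
  n <- length(aa)
  sites <- sort(unique(unlist(lapply(rules, function(r)
    cleavage_sites(aa, r)))))
  bounds <- c(0L, sites, n)          # peptide k = bounds[k]+1 .. bounds[k+1]
  nb <- length(bounds)
  out <- list()
  enz <- paste(sort(vapply(rules, `[[`, "", "name")), collapse = "+")
  for (a in seq_len(nb - 1)) {
    for (b in (a + 1):min(nb, a + 1 + max_missed)) {
      out[[length(out) + 1L]] <- c(bounds[a] + 1L, bounds[b], b - a - 1L)
    }
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], length = m[, 2] - m[, 1] + 1L,
             missed_cleavages = m[, 3], enzymes = enz,
             stringsAsFactors = FALSE)
}

#' Theoretically observable residues under a peptide-length window
#'
#' A residue is observable if it lies on at least one digest peptide
#' (within the missed-cleavage allowance) whose length falls in
#' \code{[len_min, len_max]}; the complement is the set of residues
#' theoretically inaccessible to the protease/MS combination. The window
#' default (5-45 residues) reflects what routinely survives LC-MS of
#' cross-linked samples; peptides much longer are effectively
#' unanalyzable.
#'
#' @param sequence residue string or vector.
#' @param rules enzyme rule(s).
#' @param len_min,len_max peptide length window (residues).
#' @param max_missed missed-cleavage allowance.
#' @return integer vector of observable positions.
#' @export
observable_residue_set <- function(sequence, rules, len_min = 5,
                                   len_max = 45, max_missed = 4) {
  stopifnot(len_min <= len_max)
  peps <- digest(sequence, rules, max_missed)
  peps <- peps[peps$length >= len_min & peps$length <= len_max, ,
               drop = FALSE]
  if (nrow(peps) == 0L) return(integer(0))
  sort(unique(unlist(mapply(seq.int, peps$start, peps$end,
                            SIMPLIFY = FALSE))))
}

#' Cross-link density: links per residue
#'
#' @param n_pairs number of unique residue pairs.
#' @param n_residues protein length.
#' @return density rounded (half away from zero) to 2 decimals.
#' @export
links_per_residue <- function(n_pairs, n_residues) {
  if (n_residues <= 0) stop("n_residues must be positive")
  round_half_away(n_pairs / n_residues, 2)
}

#' Cross-link density within a sequence region
#'
#' Counts pairs with at least one end inside \code{region} (default) or
#' both ends (\code{mode = "both"}), divided by the region length.
#'
#' @param pairs two-column matrix/data.frame of residue pairs.
#' @param region length-2 integer vector, inclusive interval.
#' @param mode \code{"either"} or \code{"both"} ends in region.
#' @return density rounded to 2 decimals; attribute \code{n} carries the
#'   raw pair count.
#' @export
region_link_density <- function(pairs, region, mode = c("either", "both")) {
  mode <- match.arg(mode)
  stopifnot(length(region) == 2, region[1] <= region[2])
  p <- normalize_pairs(pairs)
  inr <- function(x) x >= region[1] & x <= region[2]
  hit <- if (mode == "either") inr(p[, 1]) | inr(p[, 2]) else
    inr(p[, 1]) & inr(p[, 2])
  len <- region[2] - region[1] + 1
  structure(round_half_away(sum(hit) / len, 2), n = sum(hit))
}

#' Long-range pairs: sequence separation above a bound
#'
#' @param pairs two-column matrix/data.frame of residue pairs.
#' @param min_sep separation bound; "long range" means |i - j| strictly
#'   greater than this (default 11).
#' @return list: \code{count}, \code{percent} (integer-rounded share of
#'   all pairs), \code{total}.
#' @export
long_range_fraction <- function(pairs, min_sep = 11) {
  p <- normalize_pairs(pairs)
  cnt <- sum(abs(p[, 1] - p[, 2]) > min_sep)
  list(count = cnt, percent = int_percent(cnt, nrow(p)), total = nrow(p))
}
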