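#' Target/decoy class of a match
#'
#' TT if neither end is decoy, TD if exactly one, DD if both. Works on
#' vectors.
#'
#' @param is_decoy_a,is_decoy_b logical flags for the two link ends.
#' @return character vector in \{"TT","TD","DD"\}.
#' @export
classify_td <- function(is_decoy_a, is_decoy_b) {
  n_dec <- as.integer(is_decoy_a) + as.integer(is_decoy_b)
  c("TT", "TD", "DD")[n_dec + 1L]
}

#' Aggregate supporting PSM scores into an entity score
#'
#' The score of a unique peptide pair or residue pair is the
#' root-sum-of-squares of its supporting PSM scores:
#' \eqn{\sqrt{\sum s_i^2}}. The root keeps the aggregate on the PSM score
#' scale; it is strictly increasing in every support and never below the
#' best single PSM. \code{method = "sum_sq"} switches to the plain sum of
#' squares (rank-equivalent for a fixed support multiset).
#'
#' @param scores non-empty numeric vector of non-negative PSM scores.
#' @param method \code{"root_sum_sq"} (default) or \code{"sum_sq"}.
#' @return single aggregated score.
#' @export
aggregate_score <- function(scores, method = c("root_sum_sq", "sum_sq")) {
  method <- match.arg(method)
  if (length(scores) == 0L) stop("empty score list")
  if (any(scores < 0)) stop("negative PSM scores")
  s2 <- sum(scores^2)
  if (method == "root_sum_sq") sqrt(s2) else s2
}

# Canonical grouping key at each level.
entity_keys <- function(psms, level) {
  if (level == "residue_pair") {
    pair_key(psms$prot_pos_a, psms$prot_pos_b)
  } else {
    # order the two (peptide, link position) ends lexicographically
    a <- paste0(psms$pep_seq_a, ":", psms$link_pos_a)
    b <- paste0(psms$pep_seq_b, ":", psms$link_pos_b)
    paste(pmin(a, b), pmax(a, b), sep = "|")
  }
}

#' Group PSMs into scored unique entities
#'
#' One entity per canonical key x target/decoy class; entity score is the
#' aggregated score of its supporting PSMs. Keys are order-invariant in
#' the two link ends (residue pairs by sorted positions, peptide pairs by
#' lexicographically sorted peptide:site strings).
#'
#' @param psms PSM data.frame (canonical columns).
#' @param level \code{"residue_pair"} or \code{"peptide_pair"}.
#' @param method score aggregation method, see
#'   \code{\link{aggregate_score}}.
#' @return data.frame of entities: key, score, td_class, n_psms, support
#'   (semicolon-joined psm ids), runs, and for residue pairs pos_a/pos_b.
#' @export
group_entities <- function(psms, level = c("residue_pair", "peptide_pair"),
                           method = "root_sum_sq") {
  level <- match.arg(level)
  if (nrow(psms) == 0L) {
    return(data.frame(key = character(0), score = numeric(0),
                      td_class = character(0), n_psms = integer(0),
                      support = character(0), runs = character(0),
                      stringsAsFactors = FALSE))
  }
  td <- classify_td(psms$is_decoy_a, psms$is_decoy_b)
  key <- entity_keys(psms, level)
  grp <- paste(key, td, sep = "@")
  idx <- split(seq_len(nrow(psms)), grp)
  ent <- data.frame(
    key = vapply(idx, function(ii) key[ii[1]], ""),
    score = vapply(idx, function(ii) aggregate_score(psms$score[ii], method),
                   0),
    td_class = vapply(idx, function(ii) td[ii[1]], ""),
    n_psms = vapply(idx, length, 0L),
    support = vapply(idx, function(ii)
      paste(psms$psm_id[ii], collapse = ";"), ""),
    runs = vapply(idx, function(ii)
      paste(sort(unique(psms$run_id[ii])), collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (level == "residue_pair") {
    kp <- do.call(rbind, strsplit(ent$key, "-", fixed = TRUE))
    ent$pos_a <- as.integer(kp[, 1])
    ent$pos_b <- as.integer(kp[, 2])
  }
  ent[order(-ent$score), , drop = FALSE]
}

#' Target-decoy q-values for scored entities
#'
#' At every candidate threshold s (the distinct entity scores), the raw
#' FDR over entities scoring >= s is \eqn{\max(0, TD - DD) / TT} (0 when
#' TT = 0), capped at 1. The q-value of an entity is the minimum raw FDR
#' over all thresholds at or below its score, so q-values are
#' non-increasing in score. Entities tied on score are counted together
#' at their shared threshold, which places decoys before targets at that
#' threshold (the conservative convention).
#'
#' @param entities data.frame with \code{score} and \code{td_class}.
#' @return numeric q-values aligned with \code{entities} rows.
#' @export
estimate_fdr <- function(entities) {
  n <- nrow(entities)
  if (n == 0L) return(numeric(0))
  o <- order(-entities$score)
  sc <- entities$score[o]
  td <- entities$td_class[o]
  ctt <- cumsum(td == "TT")
  ctd <- cumsum(td == "TD")
  cdd <- cumsum(td == "DD")
  # last index of each distinct-score block = counts at that threshold
  last <- which(c(sc[-1] != sc[-n], TRUE))
  raw <- pmax(0, ctd[last] - cdd[last]) / pmax(ctt[last], 1)
  raw[ctt[last] == 0] <- 0
  raw <- pmin(raw, 1)
  # q at block b = min raw FDR over blocks >= b (lower thresholds)
  qblock <- rev(cummin(rev(raw)))
  block_of <- rep(seq_along(last), times = diff(c(0L, last)))
  q <- numeric(n)
  q[o] <- qblock[block_of]
  q
}

#' Accept entities at a nominal FDR level
#'
#' @param entities entity data.frame (see \code{\link{group_entities}}).
#' @param alpha nominal FDR in (0, 1].
#' @return list of class \code{xl_fdr_result}: \code{accepted} (TT
#'   entities with q <= alpha, with a \code{q_value} column),
#'   \code{nominal_fdr}, \code{score_cutoff} (lowest accepted score, NA
#'   if none), \code{counts} (TT/TD/DD at the cutoff), \code{q_values}
#'   for all entities.
#' @export
filter_at_fdr <- function(entities, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]")
  }
  q <- estimate_fdr(entities)
  ok <- q <= alpha
  cutoff <- if (any(ok)) min(entities$score[ok]) else NA_real_
  at_cut <- if (is.na(cutoff)) rep(FALSE, nrow(entities)) else
    entities$score >= cutoff
  acc <- entities[ok & entities$td_class == "TT", , drop = FALSE]
  acc$q_value <- q[ok & entities$td_class == "TT"]
  structure(list(
    accepted = acc[order(-acc$score), , drop = FALSE],
    nominal_fdr = alpha,
    score_cutoff = cutoff,
    counts = c(TT = sum(at_cut & entities$td_class == "TT"),
               TD = sum(at_cut & entities$td_class == "TD"),
               DD = sum(at_cut & entities$td_class == "DD")),
    q_values = q
  ), class = "xl_fdr_result")
}

# Prefilter: keep all PSMs (any class) scoring at or above the cutoff
# that a given nominal level implies for the entity list. Decoys must be
# retained for the next level's FDR estimation.
prefilter_psms <- function(psms, level, alpha, method) {
  if (alpha >= 1 || nrow(psms) == 0L) {
    return(list(psms = psms, cutoff = -Inf))
  }
  if (level == "psm") {
    ent <- data.frame(score = psms$score,
                      td_class = classify_td(psms$is_decoy_a,
                                             psms$is_decoy_b))
    q <- estimate_fdr(ent)
    ok <- q <= alpha
    cutoff <- if (any(ok)) min(psms$score[ok]) else Inf
    list(psms = psms[psms$score >= cutoff, , drop = FALSE], cutoff = cutoff)
  } else {
    ent <- group_entities(psms, level, method)
    q <- estimate_fdr(ent)
    ok <- q <= alpha
    cutoff <- if (any(ok)) min(ent$score[ok]) else Inf
    keep_keys <- ent$key[ent$score >= cutoff]
    keys <- entity_keys(psms, level)
    list(psms = psms[keys %in% keep_keys, , drop = FALSE], cutoff = cutoff)
  }
}

#' Hierarchical target-decoy FDR
#'
#' The three-level filtering scheme for cross-link identifications:
#' (1) PSM-level score cutoff at \code{psm_alpha}; (2) surviving PSMs
#' grouped to unique peptide pairs, cutoff at \code{peppair_alpha};
#' (3) surviving support grouped to unique residue pairs, accepted at
#' \code{respair_alpha}. Pre-filter levels keep decoy matches above their
#' cutoffs so the next level can still estimate its FDR. Setting both
#' pre-filter alphas to 1 reduces to single-level residue-pair FDR.
#'
#' @param psms PSM data.frame.
#' @param psm_alpha,peppair_alpha pre-filter nominal FDR levels in (0,1].
#' @param respair_alpha residue-pair nominal FDR level.
#' @param method score aggregation method.
#' @return an \code{xl_fdr_result} (see \code{\link{filter_at_fdr}}) with
#'   extra fields \code{psm_prefilter_fdr}, \code{peppair_prefilter_fdr},
#'   \code{psm_cutoff}, \code{peppair_cutoff}, \code{n_psms_in},
#'   \code{n_psms_surviving}. Empty survivor sets yield an empty accepted
#'   table, not an error.
#' @export
hierarchical_fdr <- function(psms, psm_alpha = 1, peppair_alpha = 1,
                             respair_alpha = 0.05,
                             method = "root_sum_sq") {
  stopifnot(psm_alpha > 0, psm_alpha <= 1,
            peppair_alpha > 0, peppair_alpha <= 1)
  f1 <- prefilter_psms(psms, "psm", psm_alpha, method)
  f2 <- prefilter_psms(f1$psms, "peptide_pair", peppair_alpha, method)
  ent <- group_entities(f2$psms, "residue_pair", method)
  res <- filter_at_fdr(ent, respair_alpha)
  res$psm_prefilter_fdr <- psm_alpha
  res$peppair_prefilter_fdr <- peppair_alpha
  res$psm_cutoff <- f1$cutoff
  res$peppair_cutoff <- f2$cutoff
  res$n_psms_in <- nrow(psms)
  res$n_psms_surviving <- nrow(f2$psms)
  res
}

#' Automatic pre-filter optimization
#'
#' Exhaustive grid search over PSM-level and peptide-pair-level
#' pre-filter levels, maximizing the number of accepted unique residue
#' pairs at \code{respair_alpha}. Ties are broken toward least filtering
#' (larger alphas), PSM level first.
#'
#' @param psms PSM data.frame.
#' @param respair_alpha residue-pair nominal FDR.
#' @param grid candidate pre-filter levels (used for both levels).
#' @param method score aggregation method.
#' @return list: \code{psm_alpha}, \code{peppair_alpha}, \code{result}
#'   (the winning \code{xl_fdr_result}), \code{grid_counts} (data.frame
#'   of accepted counts over the whole grid).
#' @export
optimize_prefilters <- function(psms, respair_alpha = 0.05,
                                grid = c(1, 0.5, 0.2, 0.1, 0.05, 0.01),
                                method = "root_sum_sq") {
  stopifnot(length(grid) > 0)
  combos <- expand.grid(psm_alpha = grid, peppair_alpha = grid)
  counts <- integer(nrow(combos))
  results <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    r <- hierarchical_fdr(psms, combos$psm_alpha[k],
                          combos$peppair_alpha[k], respair_alpha, method)
    results[[k]] <- r
    counts[k] <- nrow(r$accepted)
  }
  best <- order(-counts, -combos$psm_alpha, -combos$peppair_alpha)[1]
  list(psm_alpha = combos$psm_alpha[best],
       peppair_alpha = combos$peppair_alpha[best],
       result = results[[best]],
       grid_counts = cbind(combos, accepted = counts))
}

#' Counts of accepted residue pairs at several FDR levels
#'
#' Convenience summary mirroring a links-at-5/10/20\%-FDR table.
#'
#' @param psms PSM data.frame.
#' @param levels nominal FDR levels.
#' @param ... passed to \code{\link{hierarchical_fdr}}.
#' @return data.frame with fdr_level, n_accepted, score_cutoff.
#' @export
fdr_level_summary <- function(psms, levels = c(0.05, 0.10, 0.20), ...) {
  rows <- lapply(levels, function(a) {
    r <- hierarchical_fdr(psms, respair_alpha = a, ...)
    data.frame(fdr_level = a, n_accepted = nrow(r$accepted),
               score_cutoff = r$score_cutoff)
  })
  do.call(rbind, rows)
}
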