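#' Pipeline configuration
#'
#' Paths plus the analysis parameters shared across stages. Only
#' \code{psm_table} and \code{fasta} are mandatory; structural stages are
#' skipped gracefully when \code{pdb} is absent, and the geometric
#' fallback assigner is used when \code{ss_file} is absent.
#'
#' @param psm_table path to the delimited PSM table.
#' @param fasta path to the protein FASTA.
#' @param pdb optional path to a PDB structure.
#' @param ss_file optional path to a two-column SS annotation.
#' @param fdr_levels nominal FDR levels, ascending, each in (0,1].
#' @param psm_alpha,peppair_alpha pre-filter levels (1 = no pre-filter;
#'   \code{"auto"} runs \code{\link{optimize_prefilters}} at the first
#'   FDR level).
#' @param distance_threshold Calpha-Calpha bound in Angstrom.
#' @param min_seq_sep long-range separation bound (strict).
#' @param digestion_max_missed missed-cleavage allowance.
#' @param observable_len length-2 peptide-length observability window.
#' @param n_permutations saturation permutations.
#' @param seed integer seed for all stochastic stages.
#' @return validated \code{xl_pipeline_config} list.
#' @export
pipeline_config <- function(psm_table, fasta, pdb = NULL, ss_file = NULL,
                            fdr_levels = c(0.05, 0.10, 0.20),
                            psm_alpha = 1, peppair_alpha = 1,
                            distance_threshold = 25, min_seq_sep = 11,
                            digestion_max_missed = 4,
                            observable_len = c(5, 45),
                            n_permutations = 100, seed = 1L) {
  stopifnot(!is.unsorted(fdr_levels), all(fdr_levels > 0),
            all(fdr_levels <= 1), length(observable_len) == 2)
  for (f in c(psm_table, fasta)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  structure(list(psm_table = psm_table, fasta = fasta, pdb = pdb,
                 ss_file = ss_file, fdr_levels = fdr_levels,
                 psm_alpha = psm_alpha, peppair_alpha = peppair_alpha,
                 distance_threshold = distance_threshold,
                 min_seq_sep = min_seq_sep,
                 digestion_max_missed = digestion_max_missed,
                 observable_len = observable_len,
                 n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "xl_pipeline_config")
}

#' Run the full downstream analysis
#'
#' FDR filtering at each configured level, then — on the pairs accepted
#' at the first (most stringent) level — structural validation,
#' saturation analysis, digestion/observability analysis and
#' secondary-structure bias analysis. Stages whose inputs are missing
#' are recorded as skipped rather than failing the run.
#'
#' @param config an \code{\link{pipeline_config}}.
#' @return list of class \code{xl_report}: \code{fdr} (per-level
#'   results + summary table), \code{validation}, \code{saturation},
#'   \code{digestion}, \code{bias}, \code{skipped} (character vector),
#'   \code{config}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "xl_pipeline_config"))
  psms <- read_psm_table(config$psm_table)
  sequence <- read_sequence_fasta(config$fasta)
  n_res <- nchar(sequence)
  skipped <- character(0)

  # --- FDR stage -------------------------------------------------------
  if (identical(config$psm_alpha, "auto")) {
    opt <- optimize_prefilters(psms, respair_alpha = config$fdr_levels[1])
    pa <- opt$psm_alpha; ppa <- opt$peppair_alpha
  } else {
    pa <- config$psm_alpha; ppa <- config$peppair_alpha
  }
  fdr_results <- lapply(config$fdr_levels, function(a)
    hierarchical_fdr(psms, pa, ppa, a))
  names(fdr_results) <- paste0("fdr_", config$fdr_levels * 100)
  fdr_table <- do.call(rbind, lapply(seq_along(config$fdr_levels),
    function(k) {
      r <- fdr_results[[k]]
      data.frame(fdr_level = config$fdr_levels[k],
                 n_residue_pairs = nrow(r$accepted),
                 links_per_residue = links_per_residue(nrow(r$accepted),
                                                       n_res),
                 score_cutoff = r$score_cutoff)
    }))
  primary <- fdr_results[[1]]$accepted
  prim_pairs <- if (nrow(primary)) {
    cbind(primary$pos_a, primary$pos_b)
  } else matrix(integer(0), ncol = 2)

  # --- long-range / density over levels --------------------------------
  lr_table <- do.call(rbind, lapply(seq_along(config$fdr_levels),
    function(k) {
      acc <- fdr_results[[k]]$accepted
      pp <- if (nrow(acc)) cbind(acc$pos_a, acc$pos_b) else
        matrix(integer(0), ncol = 2)
      lr <- long_range_fraction(pp, config$min_seq_sep)
      data.frame(fdr_level = config$fdr_levels[k], n_long_range = lr$count,
                 percent_long_range = lr$percent)
    }))

  # --- structural validation -------------------------------------------
  validation <- NULL
  struct <- NULL
  if (!is.null(config$pdb) && file.exists(config$pdb)) {
    struct <- read_structure(config$pdb, seq = sequence)
    validation <- validation_report(prim_pairs, struct, sequence,
                                    threshold = config$distance_threshold,
                                    min_sep = config$min_seq_sep,
                                    seed = config$seed)
  } else {
    skipped <- c(skipped, "validation")
  }

  # --- saturation ------------------------------------------------------
  sets <- pairs_by_run(primary)
  saturation <- if (length(sets)) {
    saturation_curve(sets, config$n_permutations, config$seed)
  } else {
    skipped <- c(skipped, "saturation")
    NULL
  }

  # --- digestion / observability ---------------------------------------
  tryp <- trypsin()
  both <- list(trypsin(), gluc())
  obs_t <- observable_residue_set(sequence, tryp,
                                  config$observable_len[1],
                                  config$observable_len[2],
                                  config$digestion_max_missed)
  obs_tg <- observable_residue_set(sequence, both,
                                   config$observable_len[1],
                                   config$observable_len[2],
                                   config$digestion_max_missed)
  digestion <- list(
    tryptic_sites = cleavage_sites(sequence, tryp),
    observable_trypsin = obs_t,
    observable_trypsin_gluc = obs_tg,
    n_inaccessible_trypsin = n_res - length(obs_t),
    n_inaccessible_trypsin_gluc = n_res - length(obs_tg)
  )

  # --- secondary-structure / RSA bias ----------------------------------
  bias <- NULL
  if (!is.null(struct)) {
    ss <- if (!is.null(config$ss_file) && file.exists(config$ss_file)) {
      read_ss_annotation(config$ss_file)
    } else {
      assign_ss(struct)
    }
    rsa <- compute_rsa(struct)
    bias <- list(
      beta_fraction = beta_residue_fraction(ss),
      observed_beta = observed_pair_beta_fraction(prim_pairs, ss),
      expected_beta = expected_pair_beta_fraction(ss),
      kr_by_class = kr_content_by_class(sequence, ss),
      rsa_by_class = rsa_summary(rsa, ss),
      rsa_anchors_by_class = rsa_summary(rsa, ss, sequence,
                                         residue_subset = SDA_ANCHORS)
    )
  } else {
    skipped <- c(skipped, "bias")
  }

  structure(list(
    fdr = list(results = fdr_results, table = fdr_table,
               psm_alpha = pa, peppair_alpha = ppa,
               long_range = lr_table),
    validation = validation, saturation = saturation,
    digestion = digestion, bias = bias,
    skipped = skipped, config = config
  ), class = "xl_report")
}

#' Attribute accepted residue pairs to digestion protocols
#'
#' A residue pair is Glu-C-attributed when every one of its supporting
#' PSMs comes from a Glu-C-involving protocol, i.e. the pair is "added"
#' relative to trypsin-only digestion. \code{mode = "any"} switches to
#' the union-based reading (at least one Glu-C-involving PSM).
#'
#' @param accepted accepted residue-pair data.frame (with \code{support}
#'   column of semicolon-joined PSM ids).
#' @param psm_protocols named character vector: psm_id -> protocol name.
#' @param gluc_protocols protocol names that involve Glu-C.
#' @param mode \code{"exclusive"} (default) or \code{"any"}.
#' @param region optional length-2 interval; restrict to pairs with at
#'   least one end inside.
#' @return list: \code{count} (Glu-C-attributed), \code{total},
#'   \code{percent} (integer), \code{trypsin_only} (= total - count in
#'   exclusive mode).
#' @export
enzyme_attribution <- function(accepted, psm_protocols, gluc_protocols,
                               mode = c("exclusive", "any"),
                               region = NULL) {
  mode <- match.arg(mode)
  if (nrow(accepted) == 0L) {
    return(list(count = 0L, total = 0L, percent = NA_real_,
                trypsin_only = 0L))
  }
  sup <- strsplit(accepted$support, ";", fixed = TRUE)
  if (any(!unlist(sup) %in% names(psm_protocols))) {
    stop("unlabeled supporting PSMs")
  }
  keep <- rep(TRUE, nrow(accepted))
  if (!is.null(region)) {
    keep <- (accepted$pos_a >= region[1] & accepted$pos_a <= region[2]) |
      (accepted$pos_b >= region[1] & accepted$pos_b <= region[2])
  }
  gl <- vapply(sup, function(ids) {
    g <- psm_protocols[ids] %in% gluc_protocols
    if (mode == "exclusive") all(g) else any(g)
  }, FALSE)
  total <- sum(keep)
  cnt <- sum(gl & keep)
  list(count = cnt, total = total, percent = int_percent(cnt, total),
       trypsin_only = total - cnt)
}

#' @export
print.xl_report <- function(x, ...) {
  cat("HD-CLMS downstream analysis report\n")
  cat("----------------------------------\n")
  print(x$fdr$table, row.names = FALSE)
  if (!is.null(x$validation)) {
    s <- x$validation$classification
    cat(sprintf("\nDistance validation (<= %.0f A): %d within, %d over, %d unverifiable (%s%% over)\n",
                x$validation$threshold, s$n_within, s$n_over,
                s$n_unverifiable,
                ifelse(is.na(s$percent_over), "n.d.", s$percent_over)))
  }
  if (!is.null(x$saturation)) {
    cat(sprintf("Saturation: %d runs, final mean %.1f of %d unique pairs\n",
                x$saturation$n_runs,
                x$saturation$mean_cumulative[x$saturation$n_runs],
                x$saturation$total))
  }
  if (length(x$skipped)) {
    cat("Skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
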