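# Shared fixtures and independent brute-force oracles. Oracles are kept
# deliberately naive (O(n^2) loops, full enumeration) and never call the
# package implementation they check.

# Hand-built residue-level structure for distance fixtures.
make_test_structure <- function(coords, aa = NULL, resolved = NULL) {
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(resolved)) resolved <- rep(TRUE, n)
  res <- data.frame(pos = seq_len(n), aa = aa,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    resolved = resolved, ss = NA_character_,
                    stringsAsFactors = FALSE)
  res$x[!resolved] <- NA_real_
  res$y[!resolved] <- NA_real_
  res$z[!resolved] <- NA_real_
  structure(list(residues = res, atoms = NULL, source = "test"),
            class = "xl_structure")
}

# Minimal PSM table builder.
make_psms <- function(pos_a, pos_b, score, dec_a = FALSE, dec_b = FALSE,
                      run = "run1", pep_a = NULL, pep_b = NULL) {
  n <- length(score)
  rec <- function(x) rep_len(x, n)
  data.frame(
    psm_id = sprintf("P%03d", seq_len(n)), run_id = rec(run),
    pep_seq_a = if (is.null(pep_a)) rec("AAKAA") else rec(pep_a),
    pep_seq_b = if (is.null(pep_b)) rec("CCDCC") else rec(pep_b),
    link_pos_a = rec(3L), link_pos_b = rec(3L),
    prot_pos_a = rec(pos_a), prot_pos_b = rec(pos_b),
    score = score, is_decoy_a = rec(dec_a), is_decoy_b = rec(dec_b),
    stringsAsFactors = FALSE
  )
}

# --- oracle: naive threshold-enumeration q-values ----------------------
oracle_qvalues <- function(score, td_class) {
  n <- length(score)
  fdr_at <- function(s) {
    in_set <- score >= s
    tt <- sum(in_set & td_class == "TT")
    td <- sum(in_set & td_class == "TD")
    dd <- sum(in_set & td_class == "DD")
    if (tt == 0) return(0)
    min(max(0, td - dd) / tt, 1)
  }
  vapply(seq_len(n), function(i) {
    ths <- unique(score[score <= score[i]])
    min(vapply(ths, fdr_at, 0))
  }, 0)
}

# --- oracle: brute-force digestion -------------------------------------
oracle_digest <- function(seq_str, cleave_after, blocked, max_missed) {
  aa <- strsplit(seq_str, "")[[1]]
  n <- length(aa)
  is_site <- function(i) {
    i < n && aa[i] %in% cleave_after && !(aa[i + 1] %in% blocked)
  }
  sites <- Filter(is_site, seq_len(n))
  bounds <- c(0, sites, n)
  out <- NULL
  for (a in seq_along(bounds)) {
    for (b in seq_along(bounds)) {
      if (b <= a) next
      internal <- b - a - 1
      if (internal > max_missed) next
      out <- rbind(out, c(bounds[a] + 1, bounds[b], internal))
    }
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

oracle_observable <- function(seq_str, cleave_after, blocked, len_min,
                              len_max, max_missed) {
  peps <- oracle_digest(seq_str, cleave_after, blocked, max_missed)
  obs <- logical(nchar(seq_str))
  for (k in seq_len(nrow(peps))) {
    len <- peps[k, 2] - peps[k, 1] + 1
    if (len >= len_min && len <= len_max) {
      obs[peps[k, 1]:peps[k, 2]] <- TRUE
    }
  }
  which(obs)
}

# --- oracle: expected accumulation by direct permutation enumeration ---
oracle_accumulation <- function(sets) {
  m <- length(sets)
  perms <- rbind(1L)
  if (m > 1) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(m)), m)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == m), ,
                   drop = FALSE]
  }
  acc <- matrix(0, nrow(perms), m)
  for (p in seq_len(nrow(perms))) {
    seen <- character(0)
    for (r in seq_len(m)) {
      seen <- union(seen, sets[[perms[p, r]]])
      acc[p, r] <- length(seen)
    }
  }
  colMeans(acc)
}

# --- oracle: exhaustive pair enumeration for beta expectation ----------
oracle_beta_expectation <- function(ss, mode) {
  n <- length(ss)
  hits <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    cnt <- (ss[i] == "E") + (ss[j] == "E")
    if (mode == "at_least_one" && cnt >= 1) hits <- hits + 1
    if (mode == "both" && cnt == 2) hits <- hits + 1
  }
  100 * hits / tot
}

random_ss <- function(n, p_beta) {
  sample(c("E", "H", "C"), n, replace = TRUE,
         prob = c(p_beta, (1 - p_beta) / 2, (1 - p_beta) / 2))
}

# A random amino-acid string over the canonical alphabet.
random_seq <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
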