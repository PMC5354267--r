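test_that("beta residue fraction is an integer percentage", {
  expect_equal(beta_residue_fraction(rep("H", 40)), 0)
  expect_equal(beta_residue_fraction(c(rep("E", 27), rep("C", 23))), 54)
  expect_error(beta_residue_fraction(character(0)))
})

test_that("observed pair beta content counts the requested mode", {
  ss <- c("E", "E", "C", "C", "H")
  pairs <- rbind(c(1, 2), c(1, 3), c(3, 4), c(2, 5))
  one <- observed_pair_beta_fraction(pairs, ss, "at_least_one")
  expect_equal(one$count, 3L)
  expect_equal(one$percent, 75)
  both <- observed_pair_beta_fraction(pairs, ss, "both")
  expect_equal(both$count, 1L)
  expect_lte(both$count, one$count)
  # one coil end each -> zero in both mode
  expect_equal(observed_pair_beta_fraction(rbind(c(1, 3), c(2, 4)), ss,
                                           "both")$count, 0L)
})

test_that("expected pair beta fraction equals exhaustive enumeration", {
  set.seed(17)
  for (k in 1:100) {
    n <- sample(4:100, 1)
    ss <- random_ss(n, runif(1, 0, 1))
    for (mode in c("at_least_one", "both")) {
      expect_equal(expected_pair_beta_fraction(ss, mode),
                   oracle_beta_expectation(ss, mode), tolerance = 1e-12)
    }
  }
  expect_equal(expected_pair_beta_fraction(rep("E", 10)), 100)
})

test_that("a 54 percent beta protein expects about 79 percent of unbiased pairs to touch a strand", {
  ss <- c(rep("E", 216), rep("C", 184))     # b/n = 0.54, n = 400
  e <- expected_pair_beta_fraction(ss, "at_least_one")
  expect_equal(e, oracle_beta_expectation(ss, "at_least_one"))
  expect_lt(abs(e - 100 * (1 - 0.46^2)), 0.3)  # converges to 78.84
})

test_that("the linkable-pair universe restricts the expectation correctly", {
  # anchors K at 1..2; strand at the anchor-free tail
  seqv <- c("K", "K", "A", "A", "A", "A")
  ss <- c("C", "C", "E", "E", "E", "E")
  sq <- paste(seqv, collapse = "")
  got <- expected_pair_beta_fraction(ss, "at_least_one",
                                     "linkable_pairs", sequence = sq)
  # enumeration: anchored pairs are those touching positions 1 or 2
  lp <- linkable_pairs(sq)
  manual <- mean(ss[lp[, 1]] == "E" | ss[lp[, 2]] == "E")
  expect_equal(got, 100 * manual)
  expect_error(expected_pair_beta_fraction(ss, universe = "linkable_pairs"))
})

test_that("K/R content by class satisfies the length-weighted identity", {
  none <- kr_content_by_class("AAAA", c("E", "E", "C", "C"))
  expect_equal(unname(none$percent), c(0, 0, 0))
  all_e <- kr_content_by_class("KRKR", rep("E", 4))
  expect_equal(unname(all_e$percent[["within_E"]]), 100)
  set.seed(23)
  for (k in 1:20) {
    n <- 200
    sq <- random_seq(n)
    ss <- random_ss(n, runif(1, 0.2, 0.8))
    r <- kr_content_by_class(sq, ss)
    # overall count splits exactly across the two classes
    expect_equal(r$counts[["overall"]],
                 r$counts[["within_E"]] + r$counts[["outside_E"]])
    w <- (r$counts[["within_E"]] + r$counts[["outside_E"]]) / n
    expect_equal(r$percent[["overall"]],
                 as.numeric(round_half_away(100 * w)))
  }
})

test_that("the geometric assigner recovers the generator's labels to within 10 points", {
  for (fold in c("beta-sandwich", "mixed", "helix-bundle")) {
    cfg <- synthetic_config(n_residues = 120, fold_spec = fold, seed = 3)
    ds <- make_structure(cfg)
    got <- beta_residue_fraction(assign_ss(ds$structure))
    truth <- beta_residue_fraction(ds$ss)
    expect_lte(abs(got - truth), 10)
  }
})

test_that("links sampled uniformly from linkable pairs show no beta bias", {
  cfg <- synthetic_config(n_residues = 200, fold_spec = "beta-sandwich",
                          seed = 47)
  ds <- make_structure(cfg)
  lp <- linkable_pairs(ds$sequence)
  set.seed(5)
  n_links <- 800
  draw <- lp[sample.int(nrow(lp), n_links, replace = TRUE), ]
  obs <- observed_pair_beta_fraction(draw, ds$ss, "at_least_one")
  exp_pct <- expected_pair_beta_fraction(ds$ss, "at_least_one",
                                         "linkable_pairs", ds$sequence)
  se <- 100 * sqrt((exp_pct / 100) * (1 - exp_pct / 100) / n_links)
  expect_lt(abs(obs$percent - exp_pct), 3 * se + 0.5)  # 0.5 = rounding grain
})

test_that("isolated residues have full accessibility and enclosed residues none", {
  st1 <- make_test_structure(rbind(c(0, 0, 0)), aa = "A")
  r1 <- compute_rsa(st1)
  expect_true(r1$approximate)
  expect_lt(abs(r1$rsa[1] - 1), 0.15)
  # tryptophan normalizes against its own larger maximum
  stW <- make_test_structure(rbind(c(0, 0, 0)), aa = "W")
  expect_lt(abs(compute_rsa(stW)$rsa[1] - 1), 0.15)

  # residue enclosed by a dense shell of dummy residues
  set.seed(9)
  dirs <- matrix(rnorm(3 * 80), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  shell <- dirs * 4.0
  st2 <- make_test_structure(rbind(c(0, 0, 0), shell),
                             aa = rep("A", 81))
  r2 <- compute_rsa(st2)
  expect_lt(r2$rsa[1], 0.05)
})

test_that("doubling the dot density barely moves RSA values", {
  cfg <- synthetic_config(n_residues = 60, fold_spec = "mixed", seed = 51)
  ds <- make_structure(cfg)
  a <- compute_rsa(ds$structure, n_dots = 960)
  b <- compute_rsa(ds$structure, n_dots = 1920)
  expect_lt(max(abs(a$rsa - b$rsa), na.rm = TRUE), 0.02)
})

test_that("RSA profiles are bounded and track burial in compact folds", {
  cfg <- synthetic_config(n_residues = 120, fold_spec = "mixed", seed = 53)
  ds <- make_structure(cfg)
  r <- compute_rsa(ds$structure)
  v <- r$rsa[!is.na(r$rsa)]
  expect_true(all(v >= 0 & v <= 1.5))
  # residues near the centroid are more buried than peripheral ones
  res <- ds$structure$residues
  ctr <- colMeans(res[, c("x", "y", "z")])
  dc <- sqrt((res$x - ctr[1])^2 + (res$y - ctr[2])^2 + (res$z - ctr[3])^2)
  core <- r$rsa[dc <= stats::quantile(dc, 0.25)]
  surf <- r$rsa[dc >= stats::quantile(dc, 0.75)]
  expect_lt(mean(core), mean(surf))
})

test_that("unresolved residues carry no RSA value", {
  cfg <- synthetic_config(n_residues = 50, seed = 55,
                          unresolved_fraction = 0.2)
  ds <- make_structure(cfg)
  r <- compute_rsa(ds$structure)
  expect_true(all(is.na(r$rsa[!ds$structure$residues$resolved])))
  expect_true(all(!is.na(r$rsa[ds$structure$residues$resolved])))
})

test_that("class means of RSA aggregate and restrict correctly", {
  ss <- c("E", "E", "C", "C")
  flat <- rsa_summary(rep(0.3, 4), ss)
  expect_equal(unname(flat$mean_percent), c(30, 30))
  # hand-set values restricted to K residues
  rsa <- c(0.2, 0.4, 0.6, 0.8)
  sq <- "KAKA"
  r <- rsa_summary(rsa, ss, sq, residue_subset = "K")
  expect_equal(unname(r$mean_percent[["within_E"]]), 20)   # position 1 only
  expect_equal(unname(r$mean_percent[["outside_E"]]), 60)  # position 3 only
  expect_equal(unname(r$n), c(1L, 1L))
  # empty class reported absent, not zero
  r2 <- rsa_summary(rsa, rep("C", 4))
  expect_true(is.na(r2$mean_percent[["within_E"]]))
  # subset and complement class means reconstruct the overall mean
  full <- rsa_summary(rsa, ss)
  w <- full$n / sum(full$n)
  expect_equal(sum(w * full$mean_percent), 100 * mean(rsa))
})

test_that("class summaries on generated folds report both classes with counts", {
  cfg <- synthetic_config(n_residues = 150, fold_spec = "beta-sandwich",
                          seed = 57)
  ds <- make_structure(cfg)
  r <- compute_rsa(ds$structure)
  s <- rsa_summary(r, ds$ss)
  expect_false(any(is.na(s$mean_percent)))
  expect_equal(sum(s$n), 150L)
  sk <- rsa_summary(r, ds$ss, ds$sequence,
                    residue_subset = c("K", "S", "T", "Y"))
  expect_equal(sum(sk$n),
               sum(strsplit(ds$sequence, "")[[1]] %in%
                     c("K", "S", "T", "Y")))
})
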