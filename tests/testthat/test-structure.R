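test_that("synthetic PDB files round-trip to the same coordinates", {
  cfg <- synthetic_config(n_residues = 50, seed = 6,
                          unresolved_fraction = 0.1)
  ds <- make_structure(cfg)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(ds$structure, f)
  st <- read_structure(f, seq = ds$sequence)
  expect_equal(st$residues$resolved, ds$structure$residues$resolved)
  keep <- st$residues$resolved
  expect_equal(st$residues$x[keep], ds$structure$residues$x[keep],
               tolerance = 1e-3)
  expect_equal(st$residues$aa, ds$structure$residues$aa)
})

test_that("residues absent from the coordinates are unresolved", {
  cfg <- synthetic_config(n_residues = 30, seed = 2)
  ds <- make_structure(cfg)
  # drop residues 5-10 from the file
  st0 <- ds$structure
  st0$residues$resolved[5:10] <- FALSE
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st0, f)
  st <- read_structure(f, seq = ds$sequence)
  expect_false(any(st$residues$resolved[5:10]))
  expect_true(all(st$residues$resolved[-(5:10)]))
  expect_true(all(is.na(ca_distance(st, 5, 11))))
})

test_that("alternate locations resolve to the highest-occupancy CA", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  st <- read_structure(f)
  expect_equal(nrow(st$residues), 2L)
  expect_equal(st$residues$x[st$residues$pos == 1], 9.0)
})

test_that("Calpha distances are Euclidean, symmetric and NA-propagating", {
  coords <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 7))
  st <- make_test_structure(coords)
  expect_equal(ca_distance(st, 1, 1), 0)
  expect_equal(ca_distance(st, 1, 2), 5)
  expect_error(ca_distance(st, 1, 99))
  cfg <- synthetic_config(n_residues = 80, seed = 12)
  ds <- make_structure(cfg)
  set.seed(1)
  i <- sample(1:80, 1000, TRUE); j <- sample(1:80, 1000, TRUE)
  expect_equal(ca_distance(ds$structure, i, j),
               ca_distance(ds$structure, j, i))
})

test_that("link classification matches hand-placed fixtures", {
  # 20 pairs on a line: 18 verifiable (3 strictly over 25 A), 2 involve
  # unresolved residues
  coords <- cbind(seq(0, by = 6, length.out = 30), 0, 0)
  resolved <- rep(TRUE, 30); resolved[c(29, 30)] <- FALSE
  st <- make_test_structure(coords, resolved = resolved)
  pairs <- rbind(
    cbind(1, 2:16),          # 15 pairs, distances 6..90 -> 4 within? no:
    cbind(2, 4:6),           # distances 12, 18, 24
    cbind(1, 29), cbind(2, 30))
  # distances from 1: 6,12,...,90 -> over 25 A iff gap > 4 positions
  cl <- classify_links(pairs, st, threshold = 25)
  per <- cl$per_pair
  expect_equal(nrow(per), 20L)
  expect_equal(cl$summary$n_unverifiable, 2L)
  d_expected <- abs(per$pos_a - per$pos_b) * 6
  expect_equal(per$distance[!is.na(per$distance)],
               d_expected[!is.na(per$distance)])
  expect_equal(cl$summary$n_within + cl$summary$n_over +
                 cl$summary$n_unverifiable, 20L)
  # percent over excludes unverifiable pairs from the denominator
  expect_equal(cl$summary$percent_over,
               as.numeric(round_half_away(
                 100 * cl$summary$n_over /
                   (cl$summary$n_within + cl$summary$n_over))))
})

test_that("an 18-verifiable fixture with 3 over-bound links reports 17 percent", {
  coords <- cbind(c(seq(0, by = 1, length.out = 16), 40, 80, 120, 160), 0, 0)
  resolved <- c(rep(TRUE, 18), FALSE, FALSE)
  st <- make_test_structure(coords, resolved = resolved)
  pairs <- rbind(cbind(1, 2:16),        # 15 within (<= 15 A)
                 cbind(1, 17), cbind(2, 17), cbind(1, 18),  # 3 over
                 cbind(1, 19), cbind(1, 20))                # unverifiable
  cl <- classify_links(pairs, st, 25)
  expect_equal(cl$summary$n_within, 15L)
  expect_equal(cl$summary$n_over, 3L)
  expect_equal(cl$summary$n_unverifiable, 2L)
  expect_equal(cl$summary$percent_over, 17)
})

test_that("all-unresolved pairs give an undetermined over-percentage", {
  coords <- cbind(1:4, 0, 0)
  st <- make_test_structure(coords, resolved = rep(FALSE, 4))
  cl <- classify_links(rbind(c(1, 2), c(3, 4)), st, 25)
  expect_equal(cl$summary$n_unverifiable, 2L)
  expect_true(is.na(cl$summary$percent_over))
})

test_that("lowering the threshold never decreases the over count", {
  cfg <- synthetic_config(n_residues = 100, seed = 15)
  ds <- make_structure(cfg)
  pairs <- linkable_pairs(ds$sequence)[1:200, ]
  prev <- -1L
  for (th in c(40, 30, 25, 15, 5)) {
    cl <- classify_links(pairs, ds$structure, th)
    expect_gte(cl$summary$n_over, prev)
    prev <- cl$summary$n_over
  }
})

test_that("truth links built at the bound classify as zero percent over", {
  cfg <- synthetic_config(n_residues = 120, fold_spec = "mixed", seed = 19)
  ds <- make_structure(cfg)
  links <- make_true_links(ds$structure, ds$sequence, 25)
  cl <- classify_links(links, ds$structure, 25)
  expect_equal(cl$summary$n_over, 0L)
  expect_equal(cl$summary$percent_over, 0)
})

test_that("random distance sampling is seeded and converges to the exhaustive mean", {
  coords <- rbind(c(0, 0, 0), c(0, 0, 9))
  st <- make_test_structure(coords, aa = c("K", "A"))
  d <- random_distance_distribution(st, "KA", 50, seed = 3)
  expect_true(all(d == 9))

  cfg <- synthetic_config(n_residues = 100, fold_spec = "mixed", seed = 23)
  ds <- make_structure(cfg)
  s1 <- random_distance_distribution(ds$structure, ds$sequence, 10000, 5)
  s2 <- random_distance_distribution(ds$structure, ds$sequence, 10000, 5)
  expect_identical(s1, s2)
  lp <- linkable_pairs(ds$sequence, ds$structure$residues$resolved)
  all_d <- ca_distance(ds$structure, lp[, 1], lp[, 2])
  se <- stats::sd(all_d) / sqrt(10000)
  expect_lt(abs(mean(s1) - mean(all_d)), 3 * se)
})

test_that("observed truth-link distances sit below the random background", {
  cfg <- synthetic_config(n_residues = 150, fold_spec = "mixed", seed = 29)
  ds <- make_structure(cfg)
  links <- make_true_links(ds$structure, ds$sequence, 25)
  obs <- ca_distance(ds$structure, links[, 1], links[, 2])
  rnd <- random_distance_distribution(ds$structure, ds$sequence, 1000, 7)
  w <- stats::wilcox.test(obs, rnd, alternative = "less")
  expect_lt(w$p.value, 0.01)
})

test_that("validation reports are internally consistent", {
  cfg <- synthetic_config(n_residues = 90, fold_spec = "mixed", seed = 25,
                          unresolved_fraction = 0.1)
  ds <- make_structure(cfg)
  links <- make_true_links(ds$structure, ds$sequence, 25)
  rep <- validation_report(links, ds$structure, ds$sequence,
                           threshold = 25, n_random = 2000, seed = 2)
  expect_equal(rep$n_pairs, nrow(links))
  # summary re-derivable from the per-pair rows
  expect_equal(rep$classification$n_within,
               sum(rep$per_pair$class == "within"))
  expect_equal(rep$classification$n_unverifiable,
               sum(rep$per_pair$class == "unverifiable"))
  expect_equal(sum(rep$histogram$observed_count),
               sum(!is.na(rep$per_pair$distance)))
  expect_equal(sum(rep$histogram$random_count), 2000)
  expect_equal(as.numeric(rep$links_per_residue),
               as.numeric(links_per_residue(nrow(links), 90)))
  # empty input: zero counts, no exception
  empty <- validation_report(matrix(integer(0), ncol = 2), ds$structure,
                             ds$sequence)
  expect_equal(empty$n_pairs, 0L)
  expect_equal(empty$classification$n_within, 0L)
})
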