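# Build an accepted-CSM table from library peptides: n_within within-group
# pairs and n_cross cross-group pairs, all class TT.
make_accepted <- function(partition, n_within, n_cross, seed = 1) {
  set.seed(seed)
  lib <- partition$library
  gt <- enumerate_potential_crosslinks(partition)$species
  rows <- list()
  seq_of <- setNames(lib$sequence, lib$peptide_id)
  site_of <- setNames(lib$link_site, lib$peptide_id)
  pick <- sample(nrow(gt), n_within, replace = TRUE)
  for (i in seq_len(n_within)) {
    s <- gt[pick[i], ]
    rows[[i]] <- data.frame(
      scan_id = i, alpha_sequence = seq_of[[s$alpha_id]],
      alpha_pos = s$alpha_site, beta_sequence = seq_of[[s$beta_id]],
      beta_pos = s$beta_site, charge = 3L, score = runif(1, 5, 20),
      delta_score = 0, target_decoy_class = "TT", engine = "x")
  }
  k <- n_within
  while (k < n_within + n_cross) {
    i <- sample(nrow(lib), 1); j <- sample(nrow(lib), 1)
    if (lib$group_id[i] == lib$group_id[j]) next
    k <- k + 1
    rows[[k]] <- data.frame(
      scan_id = k, alpha_sequence = lib$sequence[i],
      alpha_pos = lib$link_site[i], beta_sequence = lib$sequence[j],
      beta_pos = lib$link_site[j], charge = 3L, score = runif(1, 5, 20),
      delta_score = 0, target_decoy_class = "TT", engine = "x")
  }
  do.call(rbind, rows)
}

test_that("calculated FDR counts ground-truth classes at each level", {
  part <- tiny_partition()
  all_good <- make_accepted(part, 15, 0)
  rep0 <- calculated_fdr(all_good, part)
  expect_equal(rep0$calculated_fdr, 0)
  mixed <- make_accepted(part, 19, 1)
  rep1 <- calculated_fdr(mixed, part)
  expect_equal(rep1$n_correct, 19)
  expect_equal(rep1$n_incorrect, 1)
  expect_equal(rep1$calculated_fdr, 0.05)
  # empty accepted set: zero FDR, flagged
  rep_empty <- calculated_fdr(all_good[0, ], part)
  expect_equal(rep_empty$calculated_fdr, 0)
  expect_true(rep_empty$empty)
  # decoys must not reach evaluation
  bad <- mixed; bad$target_decoy_class[1] <- "TD"
  expect_error(calculated_fdr(bad, part), "decoy")
  # unmapped sequences spill over with a warning
  stray <- mixed; stray$alpha_sequence[3] <- "WWWWWWKWW"
  expect_warning(repu <- calculated_fdr(stray, part), "mapped")
  expect_equal(nrow(repu$unmapped), 1)
  expect_equal(repu$n_correct + repu$n_incorrect, 19)
})

test_that("redundancy is the CSM-per-species ratio per class", {
  part <- tiny_partition()
  acc <- make_accepted(part, 6, 0, seed = 5)
  # force exactly two distinct species over six CSMs
  for (col in c("alpha_sequence", "alpha_pos", "beta_sequence", "beta_pos")) {
    acc[[col]][1:3] <- acc[[col]][1]
    acc[[col]][4:6] <- acc[[col]][4]
  }
  red <- csm_redundancy(acc, part)
  expect_equal(red$redundancy_correct, 3.0)
  expect_true(is.na(red$redundancy_incorrect))  # absent class, not 0
  # brute-force group-by count agreement on a mixed table
  acc2 <- make_accepted(part, 8, 4, seed = 6)
  red2 <- csm_redundancy(acc2, part)
  key <- mapply(function(as, ap, bs, bp) {
    paste(sort(c(paste(as, ap), paste(bs, bp))), collapse = "|")
  }, acc2$alpha_sequence, acc2$alpha_pos, acc2$beta_sequence, acc2$beta_pos)
  id_of <- setNames(part$library$peptide_id, part$library$sequence)
  labels <- unname(classify_crosslink(id_of[acc2$alpha_sequence],
                                      id_of[acc2$beta_sequence], part))
  expect_equal(red2$redundancy_correct,
               sum(labels == "correct") /
                 length(unique(key[labels == "correct"])))
  expect_equal(red2$redundancy_incorrect,
               sum(labels == "incorrect") /
                 length(unique(key[labels == "incorrect"])))
})

test_that("FDR propagation reproduces the redundancy mechanism", {
  # worked example with published inputs: 4.3% CSM FDR, 678 correct CSMs,
  # redundancies 2.9 vs 1.0 -> ~11.5% at unique-crosslink level
  expect_equal(propagate_fdr(0.043, 678, 2.9, 1.0), 0.1153, tolerance = 1e-3)
  # equal redundancies leave the FDR unchanged (algebraic identity)
  expect_equal(propagate_fdr(0.08, 500, 2.0, 2.0), 0.08, tolerance = 1e-12)
  expect_equal(propagate_fdr(0, 100, 2.9, 1.0), 0)
  expect_error(propagate_fdr(1, 100, 2, 1), "csm_fdr")
  # monotone amplification whenever correct redundancy dominates
  set.seed(77)
  for (k in 1:200) {
    q <- runif(1, 0, 0.5)
    rc <- runif(1, 1, 5); ri <- runif(1, 1, rc)
    expect_gte(propagate_fdr(q, 100, rc, ri), q - 1e-12)
  }
})

test_that("overlap regions partition the union of result sets", {
  # identical sets: only the intersection region
  ov <- overlap_analysis(list(A = 1:5, B = 1:5))
  expect_equal(ov$regions$region, "A&B")
  expect_equal(ov$regions$count, 5)
  # disjoint sets: singleton regions only
  ov2 <- overlap_analysis(list(A = 1:3, B = 4:6))
  expect_setequal(ov2$regions$region, c("A", "B"))
  expect_equal(ov2$n_union, 6)
  # duplicates are deduplicated with a warning
  expect_warning(ov3 <- overlap_analysis(list(A = c(1, 1, 2), B = 2:3)),
                 "dedup")
  expect_equal(ov3$n_union, 3)
  expect_error(overlap_analysis(list(A = 1:3)), "at least two")
  # three random sets vs brute-force membership tabulation
  set.seed(41)
  for (k in 1:5) {
    sets <- list(A = sample(100, 30), B = sample(100, 40), C = sample(100, 20))
    ov <- overlap_analysis(sets)
    expect_equal(sum(ov$regions$count), ov$n_union)
    universe <- sort(unique(unlist(sets)))
    brute <- table(sapply(universe, function(u) {
      paste(names(sets)[sapply(sets, function(s) u %in% s)], collapse = "&")
    }))
    expect_equal(sort(ov$regions$count), sort(as.integer(brute)))
    got <- setNames(ov$regions$count, ov$regions$region)
    expect_equal(got[names(brute)], setNames(as.integer(brute), names(brute)))
  }
})

test_that("score correlation is squared Pearson over shared scans", {
  a <- data.frame(scan_id = 1:20, score = seq(1, 20))
  b <- data.frame(scan_id = 1:20, score = 2 * seq(1, 20) + 1)
  expect_equal(score_correlation(a, b)$r_squared, 1.0)
  # constant scores: undefined, reported as NA
  const_b <- data.frame(scan_id = 1:20, score = rep(3, 20))
  expect_true(is.na(score_correlation(a, const_b)$r_squared))
  # textbook formula on a 20-point set with partial overlap
  set.seed(9)
  b2 <- data.frame(scan_id = 6:30, score = runif(25, 0, 50))
  got <- score_correlation(a, b2)
  shared <- 6:20
  x <- a$score[match(shared, a$scan_id)]
  y <- b2$score[match(shared, b2$scan_id)]
  r <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(got$r_squared, r^2, tolerance = 1e-12)
  expect_equal(got$n_shared, 15)
  expect_error(score_correlation(a[1:2, ], b[1:2, ]), "insufficient pairing")
})

test_that("spectra accounting assigns each scan exactly one category", {
  part <- tiny_partition()
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 19, n_true_spectra = 20, n_spoof_spectra = 0,
                           n_monolink_spectra = 6, n_noise_spectra = 8,
                           noise_peaks = 0)
  sim <- simulate_spectra(gt, "DSS", cfg)
  db <- build_candidates(part$library, "DSS", "shuffle_keep_sites", seed = 3)
  res <- search_spectra(sim$spectra, db, search_config())
  v <- apply_cutoff(res, "csm", 0.05)
  scans <- vapply(sim$spectra, `[[`, integer(1), "scan_id")
  acct <- spectra_accounting(scans, res, v$accepted_targets, sim$manifest)
  expect_equal(sum(acct$counts), acct$total)           # partition invariant
  expect_equal(acct$total, 34)
  # manifest-derived expectations: noise scans are never accepted CSMs
  noise_scans <- sim$manifest$scan_id[sim$manifest$truth == "noise"]
  cat_of <- setNames(acct$category$category, acct$category$scan_id)
  expect_true(all(cat_of[as.character(noise_scans)] %in%
                  c("unknown", "decoy_psm")))
  # monolink scans rank as other_species unless accepted
  mono_scans <- sim$manifest$scan_id[sim$manifest$truth == "monolink"]
  expect_true(all(cat_of[as.character(mono_scans)] %in%
                  c("other_species", "csm_accepted")))
  # no results at all -> everything unknown
  none <- spectra_accounting(scans, res[0, ], res[0, ], NULL)
  expect_equal(unname(none$counts["unknown"]), 34L)
  # accepted must be a subset of results
  expect_error(spectra_accounting(scans, res[0, ], res[1, , drop = FALSE]),
               "absent")
})
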