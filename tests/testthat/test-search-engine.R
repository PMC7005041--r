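test_that("candidate database enumerates the full n-squared pair space", {
  peps <- data.frame(peptide_id = c("P1", "P2", "P3"),
                     sequence = c("AAGKL", "GSVKL", "LLGKS"),
                     link_site = c(4L, 4L, 4L))
  db <- build_candidates(peps, "DSS", "invert")
  expect_equal(nrow(db$peptides), 6)           # 3 targets + 3 decoys
  expect_equal(nrow(db$pairs), 21)             # 6 * 7 / 2
  expect_setequal(unique(db$pairs$class), c("TT", "TD", "DD"))
  # single peptide, no decoys: one homodimer pair
  db1 <- build_candidates(peps[1, ], "DSS", "none")
  expect_equal(nrow(db1$pairs), 1)
  # pair masses agree with the chemistry oracle
  for (r in sample(nrow(db$pairs), 10)) {
    expect_equal(db$pairs$mass[r],
                 crosslinked_mass(db$peptides$sequence[db$pairs$idx_a[r]],
                                  db$peptides$sequence[db$pairs$idx_b[r]],
                                  "DSS"))
  }
  expect_false(is.unsorted(db$pairs$mass))
})

test_that("engine recovers every noiseless admissible spectrum", {
  part <- tiny_partition()
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 31, n_true_spectra = 40, noise_peaks = 0)
  sim <- simulate_spectra(gt, "DSS", cfg)
  db <- build_candidates(part$library, "DSS", "none")
  res <- search_spectra(sim$spectra, db, search_config())
  expect_equal(nrow(res), 40)
  seq_of <- setNames(part$library$sequence, part$library$peptide_id)
  for (i in seq_len(nrow(res))) {
    mf <- sim$manifest[sim$manifest$scan_id == res$scan_id[i], ]
    truth_pair <- sort(c(seq_of[[mf$alpha_id]], seq_of[[mf$beta_id]]))
    expect_equal(sort(c(res$alpha_sequence[i], res$beta_sequence[i])),
                 truth_pair)
    expect_equal(res$score[i], 2, tolerance = 1e-9)  # complete ladder
  }
})

test_that("pure-noise spectra and empty precursors return no match", {
  part <- tiny_partition()
  db <- build_candidates(part$library, "DSS", "none")
  # precursor on a real pair mass, peaks nowhere near any ladder
  const <- xl_constants()
  noise <- list(scan_id = 1L,
                precursor_mz = (db$pairs$mass[1] + 3 * const$proton) / 3,
                charge = 3L,
                mz = seq(2000, 2100, by = 10),
                intensity = rep(1, 11))
  expect_null(match_spectrum(noise, db, search_config()))
  # precursor far from every candidate
  far <- list(scan_id = 2L, precursor_mz = 9999, charge = 3L,
              mz = c(100, 200), intensity = c(1, 1))
  expect_null(match_spectrum(far, db, search_config()))
  expect_error(match_spectrum(list(scan_id = 3L, mz = numeric()), db),
               "no peaks")
})

test_that("best match equals exhaustive rescoring of every pair", {
  part <- tiny_partition(4, c(2L, 2L), seed = 6)
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 7, n_true_spectra = 5, noise_peaks = 3)
  sim <- simulate_spectra(gt, "DSS", cfg)
  db <- build_candidates(part$library, "DSS", "invert")
  scfg <- search_config(min_fragments = 1)
  const <- xl_constants()
  for (sp in sim$spectra) {
    mine <- match_spectrum(sp, db, scfg)
    # oracle: rescore every pair without a mass index, pick the best
    neutral <- sp$precursor_mz * sp$charge - sp$charge * const$proton
    best_score <- -Inf; best_pair <- NULL
    for (r in seq_len(nrow(db$pairs))) {
      if (abs(db$pairs$mass[r] - neutral) >
          scfg$precursor_tol_ppm * neutral * 1e-6) next
      ia <- db$pairs$idx_a[r]; ib <- db$pairs$idx_b[r]
      fa <- unique(fragment_mzs(db$peptides$sequence[ia],
                                db$peptides$link_site[ia],
                                db$peptides$mass[ib], db$xl)$mz)
      fb <- unique(fragment_mzs(db$peptides$sequence[ib],
                                db$peptides$link_site[ib],
                                db$peptides$mass[ia], db$xl)$mz)
      na <- sum(sapply(fa, function(m) any(abs(sp$mz - m) <= scfg$fragment_tol)))
      nb <- sum(sapply(fb, function(m) any(abs(sp$mz - m) <= scfg$fragment_tol)))
      if (na < 1 || nb < 1) next
      sc <- na / length(fa) + nb / length(fb)
      if (sc > best_score) {
        best_score <- sc
        best_pair <- sort(c(db$peptides$sequence[ia], db$peptides$sequence[ib]))
      }
    }
    if (is.null(best_pair)) {
      expect_null(mine)
    } else {
      expect_equal(mine$score, best_score, tolerance = 1e-12)
      expect_equal(sort(c(mine$alpha_sequence, mine$beta_sequence)), best_pair)
    }
  }
})

test_that("score is invariant under peptide order within a species", {
  part <- tiny_partition()
  lib <- part$library
  db <- build_candidates(lib, "DSS", "none")
  a <- lib$sequence[1]; b <- lib$sequence[2]
  dss <- default_crosslinkers()$DSS
  const <- xl_constants()
  mk_spec <- function(s1, site1, s2, site2) {
    mz <- sort(unique(c(
      fragment_mzs(s1, site1, peptide_mass(s2), dss)$mz,
      fragment_mzs(s2, site2, peptide_mass(s1), dss)$mz)))
    list(scan_id = 1L,
         precursor_mz = (crosslinked_mass(s1, s2, dss) + 3 * const$proton) / 3,
         charge = 3L, mz = mz, intensity = rep(1, length(mz)))
  }
  r1 <- match_spectrum(mk_spec(a, lib$link_site[1], b, lib$link_site[2]), db)
  r2 <- match_spectrum(mk_spec(b, lib$link_site[2], a, lib$link_site[1]), db)
  expect_equal(r1$score, r2$score)
  expect_equal(r1$alpha_sequence, r2$alpha_sequence)  # canonical order
})

test_that("doublet detection finds configured stub spacings", {
  dsso <- default_crosslinkers()$DSSO
  delta <- doublet_deltas(dsso)
  spec <- list(scan_id = 1L, precursor_mz = 500, charge = 3L,
               mz = c(300, 300 + delta), intensity = c(1, 1))
  hits <- detect_doublets(spec, dsso, tolerance = 0.01, charges = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mz_high - hits$mz_low, delta, tolerance = 1e-9)
  # charge-2 hypothesis: spacing delta/2 in m/z
  spec2 <- list(mz = c(300, 300 + delta / 2))
  hits2 <- detect_doublets(spec2, dsso, tolerance = 0.01, charges = 2)
  expect_equal(nrow(hits2), 1)
  # empty spectrum, and non-cleavable error
  expect_equal(nrow(detect_doublets(list(mz = numeric()), dsso)), 0)
  expect_error(detect_doublets(spec, default_crosslinkers()$DSS),
               "non-cleavable")
})

test_that("cleavable gating never drops a spectrum carrying its doublet", {
  part <- tiny_partition()
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 13, n_true_spectra = 25, noise_peaks = 0)
  sim <- simulate_spectra(gt, "DSSO", cfg)
  db <- build_candidates(part$library, "DSSO", "none")
  gated <- search_spectra(sim$spectra, db,
                          search_config(cleavable_mode = TRUE,
                                        min_fragments = 1))
  expect_equal(nrow(gated), 25)  # no false negatives from gating
})

test_that("fixed score cut-offs filter exactly as specified", {
  recs <- data.frame(score = c(50, 46, 44, 60, 45, 10, 45, 52, 30, 47),
                     delta_score = c(5, 3, 8, 4, 4, 9, 2, 0, 4, 4))
  # hand filter: score >= 45 and delta >= 4
  expect_equal(which(recs$score >= 45 & recs$delta_score >= 4),
               c(1, 4, 5, 10))
  got <- apply_score_cutoffs(recs, 45, 4)
  expect_equal(got$score, recs$score[c(1, 4, 5, 10)])
  # unset cutoffs are the identity
  expect_equal(apply_score_cutoffs(recs), recs)
  # everything below cutoff -> empty
  expect_equal(nrow(apply_score_cutoffs(recs, 100)), 0)
})
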