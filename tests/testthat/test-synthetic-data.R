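test_that("simulation config validates counts, rates and score model", {
  expect_error(simulation_config(n_true_spectra = -1), "non-negative")
  expect_error(simulation_config(isotope_error_rate = 1.5), "isotope_error_rate")
  expect_error(simulation_config(score_model = list(correct = c(mean = 1, sd = 1))),
               "score_model")
  expect_error(simulation_config(redundancy_correct = 0.5), "redundanc")
  cfg <- simulation_config(seed = 3)
  expect_s3_class(cfg, "simulation_config")
})

test_that("spectrum generator covers all classes with a bijective manifest", {
  part <- tiny_partition()
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 8, n_true_spectra = 10, n_spoof_spectra = 5,
                           n_monolink_spectra = 4, n_noise_spectra = 3)
  sim <- simulate_spectra(gt, "DSS", cfg)
  expect_length(sim$spectra, 22)
  expect_equal(nrow(sim$manifest), 22)
  scan_ids <- vapply(sim$spectra, `[[`, integer(1), "scan_id")
  expect_equal(sort(scan_ids), sim$manifest$scan_id)  # bijection, no reuse
  expect_equal(unname(table(sim$manifest$truth)[c("crosslink", "monolink", "noise")]),
               c(15L, 4L, 3L), ignore_attr = TRUE)
  expect_equal(sum(sim$manifest$within_group, na.rm = TRUE), 10)
  # peaks sorted, charges within range
  for (sp in sim$spectra) {
    expect_false(is.unsorted(sp$mz))
    expect_true(sp$charge %in% 3:8)
  }
  # empty config -> empty outputs
  empty <- simulate_spectra(gt, "DSS", simulation_config(
    n_true_spectra = 0, n_spoof_spectra = 0, n_monolink_spectra = 0,
    n_noise_spectra = 0))
  expect_length(empty$spectra, 0)
  expect_equal(nrow(empty$manifest), 0)
})

test_that("noiseless true spectra contain their full theoretical ladder", {
  part <- tiny_partition()
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 12, n_true_spectra = 50, noise_peaks = 0)
  sim <- simulate_spectra(gt, "DSS", cfg)
  dss <- default_crosslinkers()$DSS
  lib <- part$library
  seq_of <- setNames(lib$sequence, lib$peptide_id)
  for (i in seq_along(sim$spectra)) {
    sp <- sim$spectra[[i]]
    mf <- sim$manifest[sim$manifest$scan_id == sp$scan_id, ]
    a <- seq_of[[mf$alpha_id]]; b <- seq_of[[mf$beta_id]]
    theo <- c(
      fragment_mzs(a, mf$alpha_site, peptide_mass(b), dss)$mz,
      fragment_mzs(b, mf$beta_site, peptide_mass(a), dss)$mz)
    expect_true(all(sapply(theo, function(m) any(abs(sp$mz - m) < 1e-6))))
  }
})

test_that("spoof spectra are confined to cross-group species", {
  part <- tiny_partition()
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 5, n_true_spectra = 0, n_spoof_spectra = 20)
  sim <- simulate_spectra(gt, "DSS", cfg)
  labels <- classify_crosslink(sim$manifest$alpha_id, sim$manifest$beta_id, part)
  expect_true(all(labels == "incorrect"))
  # when the precursor tolerance is below the smallest spoof-to-admissible
  # mass gap, no spoof precursor can be confused with an admissible species
  admissible_mass <- apply(gt$species, 1, function(s) {
    crosslinked_mass(part$library$sequence[part$library$peptide_id == s["alpha_id"]],
                     part$library$sequence[part$library$peptide_id == s["beta_id"]],
                     "DSS")
  })
  const <- xl_constants()
  spoof_neutral <- vapply(sim$spectra, function(sp) {
    sp$precursor_mz * sp$charge - sp$charge * const$proton
  }, numeric(1))
  gap <- min(vapply(spoof_neutral, function(m) min(abs(admissible_mass - m)),
                    numeric(1)))
  tol_da <- 10 * 2000 * 1e-6  # 10 ppm at m ~ 2000 Da
  if (gap > tol_da) {
    expect_true(all(vapply(spoof_neutral, function(m) {
      all(abs(admissible_mass - m) > tol_da)
    }, logical(1))))
  }
})

test_that("identical seeds give byte-identical MGF output", {
  part <- tiny_partition()
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 21, n_true_spectra = 15, n_noise_spectra = 5)
  f1 <- tempfile(fileext = ".mgf"); f2 <- tempfile(fileext = ".mgf")
  write_mgf(simulate_spectra(gt, "DSS", cfg)$spectra, f1)
  write_mgf(simulate_spectra(gt, "DSS", cfg)$spectra, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("MGF round-trips and rejects malformed input", {
  part <- tiny_partition()
  gt <- enumerate_potential_crosslinks(part)
  sim <- simulate_spectra(gt, "DSS", simulation_config(seed = 2,
                                                       n_true_spectra = 10))
  path <- tempfile(fileext = ".mgf")
  write_mgf(sim$spectra, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "BEGIN IONS"), 10)
  expect_equal(sum(lines == "END IONS"), 10)
  back <- read_mgf(path)
  expect_length(back, 10)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$scan_id, sim$spectra[[i]]$scan_id)
    expect_equal(back[[i]]$charge, sim$spectra[[i]]$charge)
    expect_equal(back[[i]]$precursor_mz, sim$spectra[[i]]$precursor_mz,
                 tolerance = 1e-5)
    expect_equal(back[[i]]$mz, sim$spectra[[i]]$mz, tolerance = 1e-5)
  }
  # empty file -> no spectra
  empty <- tempfile(); writeLines(character(0), empty)
  expect_length(read_mgf(empty), 0)
  # malformed inputs carry line numbers
  bad <- tempfile(); writeLines(c("BEGIN IONS", "PEPMASS=100", "oops"), bad)
  expect_error(read_mgf(bad), "unterminated|line")
  bad2 <- tempfile(); writeLines(c("100.0 1.0"), bad2)
  expect_error(read_mgf(bad2), "line 1")
})

test_that("mock CSM tables realise the configured class structure", {
  part <- tiny_partition(95, default_group_sizes(), seed = 3)
  gt <- enumerate_potential_crosslinks(part)
  cfg <- simulation_config(seed = 17, n_correct_csms = 580,
                           n_incorrect_csms = 100, n_td_csms = 200,
                           n_dd_csms = 100)
  out <- simulate_csm_table(cfg, gt)
  expect_equal(nrow(out$csms), 980)
  expect_equal(out$csms$scan_id, out$truth$scan_id)
  expect_equal(unname(table(out$truth$class)[c("target_correct",
                                               "target_incorrect",
                                               "td_decoy", "dd_decoy")]),
               c(580L, 100L, 200L, 100L), ignore_attr = TRUE)
  expect_equal(unname(table(out$csms$target_decoy_class)[c("TT", "TD", "DD")]),
               c(680L, 200L, 100L), ignore_attr = TRUE)
  # empirical class means within 3 standard errors of configured means
  sm <- cfg$score_model
  for (pair in list(c("target_correct", "correct"),
                    c("td_decoy", "td"))) {
    scores <- out$csms$score[out$truth$class == pair[1]]
    se <- sm[[pair[2]]][["sd"]] / sqrt(length(scores))
    expect_lt(abs(mean(scores) - sm[[pair[2]]][["mean"]]), 3 * se + 0.05)
  }
  # realised redundancies within 10% of the targets
  truth_tt <- out$truth$class[out$csms$target_decoy_class == "TT"]
  tt <- out$csms[out$csms$target_decoy_class == "TT", ]
  red <- csm_redundancy(tt[truth_tt == "target_correct", ], part)
  expect_lt(abs(red$redundancy_correct - 2.9) / 2.9, 0.1)
  red_i <- csm_redundancy(tt[truth_tt == "target_incorrect", ], part)
  expect_lt(abs(red_i$redundancy_incorrect - 1.0), 0.1)
  # empty request -> valid empty table
  zero <- simulate_csm_table(simulation_config(
    n_correct_csms = 0, n_incorrect_csms = 0, n_td_csms = 0, n_dd_csms = 0), gt)
  expect_equal(nrow(zero$csms), 0)
  expect_named(zero$csms, names(out$csms))
})
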