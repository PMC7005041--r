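# Synthetic spectra and mock CSM tables with full ground-truth manifests.
#
# The generator stands in for the wet-lab and instrument stages of the
# benchmark: it emits (a) toy crosslinked MS2 peak lists for the end-to-end
# search -> validate -> evaluate path and (b) mock search-engine output
# tables whose score structure emulates what real engines report: correct
# target CSMs scoring high, cross-group false-positive targets and decoy
# matches scoring low, with configurable CSM redundancy per species.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with validated
#' defaults. Score distributions are truncated normals (at 0), one per match
#' class. Default class counts for the mock CSM tables keep the paired-decoy
#' ratio TD:DD = 2:1 with TD - DD equal to the number of false-target CSMs,
#' the structure implied by searching with a 1:1 decoy database, so that the
#' target-decoy estimator is calibrated by construction.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param n_true_spectra,n_spoof_spectra,n_monolink_spectra,n_noise_spectra
#'   Spectrum counts per class: within-group crosslinks, between-group
#'   ("spoof") crosslinks, monolinked peptides, pure-noise scans.
#' @param n_correct_csms,n_incorrect_csms,n_td_csms,n_dd_csms Mock CSM-table
#'   counts per class.
#' @param score_model Named list of `c(mean, sd)` per class
#'   (`correct`, `incorrect`, `td`, `dd`).
#' @param redundancy_correct,redundancy_incorrect Target mean CSMs per unique
#'   species for correct (default 2.9) and incorrect (default 1.0) classes.
#' @param noise_peaks Noise peaks added to every signal spectrum.
#' @param ppm_jitter Mass accuracy: peaks and precursors are jittered
#'   uniformly within +/- this many ppm.
#' @param isotope_error_rate Probability that the precursor neutral mass is
#'   offset by +/- one C13-C12 spacing (monoisotopic peak mis-picked).
#' @param charge_range Precursor charge states sampled uniformly (default
#'   3:8, the usual crosslink acquisition charge window).
#' @param fragment_charges Fragment ion charges (default 1:2).
#' @param mz_range m/z window for noise peaks and noise-scan precursors.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_true_spectra = 200L,
                              n_spoof_spectra = 0L,
                              n_monolink_spectra = 0L,
                              n_noise_spectra = 0L,
                              n_correct_csms = 600L,
                              n_incorrect_csms = 100L,
                              n_td_csms = 200L,
                              n_dd_csms = 100L,
                              score_model = list(
                                correct = c(mean = 12, sd = 3),
                                incorrect = c(mean = 4, sd = 1.5),
                                td = c(mean = 4, sd = 1.5),
                                dd = c(mean = 4, sd = 1.5)
                              ),
                              redundancy_correct = 2.9,
                              redundancy_incorrect = 1.0,
                              noise_peaks = 20L,
                              ppm_jitter = 0,
                              isotope_error_rate = 0,
                              charge_range = 3:8,
                              fragment_charges = 1:2,
                              mz_range = c(100, 1400)) {
  counts <- c(n_true_spectra, n_spoof_spectra, n_monolink_spectra,
              n_noise_spectra, n_correct_csms, n_incorrect_csms,
              n_td_csms, n_dd_csms, noise_peaks)
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (isotope_error_rate < 0 || isotope_error_rate > 1) {
    stop("isotope_error_rate must be in [0, 1]")
  }
  if (ppm_jitter < 0) stop("ppm_jitter must be non-negative")
  needed <- c("correct", "incorrect", "td", "dd")
  if (!all(needed %in% names(score_model))) {
    stop("score_model needs entries: ", paste(needed, collapse = ", "))
  }
  for (cl in needed) {
    if (score_model[[cl]][["sd"]] <= 0) stop("score sd must be > 0 for ", cl)
  }
  if (redundancy_correct < 1 || redundancy_incorrect < 1) {
    stop("redundancies are mean CSMs per species and must be >= 1")
  }
  structure(list(
    seed = as.integer(seed),
    n_true_spectra = as.integer(n_true_spectra),
    n_spoof_spectra = as.integer(n_spoof_spectra),
    n_monolink_spectra = as.integer(n_monolink_spectra),
    n_noise_spectra = as.integer(n_noise_spectra),
    n_correct_csms = as.integer(n_correct_csms),
    n_incorrect_csms = as.integer(n_incorrect_csms),
    n_td_csms = as.integer(n_td_csms),
    n_dd_csms = as.integer(n_dd_csms),
    score_model = score_model,
    redundancy_correct = redundancy_correct,
    redundancy_incorrect = redundancy_incorrect,
    noise_peaks = as.integer(noise_peaks),
    ppm_jitter = ppm_jitter,
    isotope_error_rate = isotope_error_rate,
    charge_range = as.integer(charge_range),
    fragment_charges = as.integer(fragment_charges),
    mz_range = mz_range
  ), class = "simulation_config")
}

.jitter_ppm <- function(mz, ppm) {
  if (ppm <= 0) return(mz)
  mz * (1 + stats::runif(length(mz), -ppm, ppm) * 1e-6)
}

# Sample cross-group (inadmissible) peptide pairs, canonical, unique.
.sample_cross_group_pairs <- function(partition, n) {
  lib <- partition$library
  if (length(unique(lib$group_id)) < 2) {
    stop("cross-group pairs need at least two groups")
  }
  seen <- character(0)
  out <- list()
  while (length(out) < n) {
    i <- sample.int(nrow(lib), 1)
    j <- sample.int(nrow(lib), 1)
    if (lib$group_id[i] == lib$group_id[j]) next
    if (lib$peptide_id[i] > lib$peptide_id[j]) { tmp <- i; i <- j; j <- tmp }
    key <- paste(lib$peptide_id[i], lib$peptide_id[j])
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- data.frame(
      alpha_id = lib$peptide_id[i], alpha_site = lib$link_site[i],
      beta_id = lib$peptide_id[j], beta_site = lib$link_site[j],
      group_id = NA_integer_
    )
  }
  do.call(rbind, out)
}

# Build one crosslink spectrum: full b/y ladders of both peptides (stub
# variants in cleavable mode, plus intact peptide+stub diagnostic peaks),
# noise peaks, precursor with optional isotope mis-assignment.
.crosslink_spectrum <- function(scan_id, seq_a, site_a, seq_b, site_b, xl, cfg) {
  const <- xl_constants()
  m_a <- peptide_mass(seq_a)
  m_b <- peptide_mass(seq_b)
  neutral <- m_a + m_b + xl$bridge_mass
  z <- sample1(cfg$charge_range)
  if (cfg$isotope_error_rate > 0 &&
      stats::runif(1) < cfg$isotope_error_rate) {
    neutral <- neutral + sample(c(-1, 1), 1) * const$isotope_spacing
  }
  frags_a <- fragment_mzs(seq_a, site_a, partner_mass = m_b, xl = xl,
                          charges = cfg$fragment_charges)
  frags_b <- fragment_mzs(seq_b, site_b, partner_mass = m_a, xl = xl,
                          charges = cfg$fragment_charges)
  mzs <- c(frags_a$mz, frags_b$mz)
  if (xl$cleavable) {
    # intact peptide + stub remnants: the diagnostic doublet peaks
    for (z_f in cfg$fragment_charges) {
      mzs <- c(mzs,
               (m_a + xl$stub_masses + z_f * const$proton) / z_f,
               (m_b + xl$stub_masses + z_f * const$proton) / z_f)
    }
  }
  mzs <- unique(mzs)
  mzs <- .jitter_ppm(mzs, cfg$ppm_jitter)
  if (cfg$noise_peaks > 0) {
    mzs <- c(mzs, stats::runif(cfg$noise_peaks, cfg$mz_range[1], cfg$mz_range[2]))
  }
  ord <- order(mzs)
  list(scan_id = scan_id,
       precursor_mz = .jitter_ppm((neutral + z * const$proton) / z,
                                  cfg$ppm_jitter),
       charge = as.integer(z),
       mz = mzs[ord],
       intensity = stats::runif(length(mzs), 0.1, 1)[ord])
}

.monolink_spectrum <- function(scan_id, seq, site, xl, cfg) {
  const <- xl_constants()
  neutral <- peptide_mass(seq) + xl$monolink_mass
  z <- sample1(cfg$charge_range)
  # monolink = bridge + water on the link site; fragment_mzs adds bridge +
  # partner_mass to linked fragments, so partner_mass = one water
  xl_plain <- xl
  xl_plain$stubs <- list(); xl_plain$stub_masses <- numeric(0)
  xl_plain$cleavable <- FALSE
  frags <- fragment_mzs(seq, site,
                        partner_mass = xl$monolink_mass - xl$bridge_mass,
                        xl = xl_plain, charges = cfg$fragment_charges)
  mzs <- .jitter_ppm(unique(frags$mz), cfg$ppm_jitter)
  if (cfg$noise_peaks > 0) {
    mzs <- c(mzs, stats::runif(cfg$noise_peaks, cfg$mz_range[1], cfg$mz_range[2]))
  }
  ord <- order(mzs)
  list(scan_id = scan_id,
       precursor_mz = .jitter_ppm((neutral + z * const$proton) / z,
                                  cfg$ppm_jitter),
       charge = as.integer(z),
       mz = mzs[ord],
       intensity = stats::runif(length(mzs), 0.1, 1)[ord])
}

.noise_spectrum <- function(scan_id, cfg) {
  n <- max(cfg$noise_peaks, 5L)
  mzs <- sort(stats::runif(n, cfg$mz_range[1], cfg$mz_range[2]))
  list(scan_id = scan_id,
       precursor_mz = stats::runif(1, 400, 1600),
       charge = as.integer(sample1(cfg$charge_range)),
       mz = mzs,
       intensity = stats::runif(n, 0.1, 1))
}

#' Simulate crosslinked MS2 spectra with a truth manifest
#'
#' Generates toy peak lists for four scan classes: true crosslinks (species
#' drawn from the admissible within-group space, containing their full
#' theoretical fragment ladder), spoof crosslinks (built from cross-group
#' pairs, so a correct-looking match exists only to a species that is false
#' by design), monolinked peptides, and pure-noise scans. With probability
#' `isotope_error_rate` a precursor neutral mass is offset by one isotope
#' spacing, emulating monoisotopic peak mis-assignment by the instrument. In
#' cleavable mode stub-variant fragment ladders and intact peptide+stub
#' diagnostic doublet peaks are included.
#'
#' @param ground_truth A [enumerate_potential_crosslinks()] result.
#' @param xl Crosslinker name or [crosslinker_spec()].
#' @param cfg A [simulation_config()].
#' @return List with `spectra` (list of peak lists: `scan_id`,
#'   `precursor_mz`, `charge`, `mz`, `intensity`) and `manifest` (data.frame
#'   `scan_id`, `truth` in `{crosslink, monolink, noise}`, `alpha_id`,
#'   `alpha_site`, `beta_id`, `beta_site`, `within_group`).
#' @export
simulate_spectra <- function(ground_truth, xl, cfg = simulation_config()) {
  xl <- crosslinker(xl)
  species <- ground_truth$species
  partition <- ground_truth$partition
  lib <- partition$library
  if (cfg$n_true_spectra > 0 && nrow(species) == 0) {
    stop("cannot draw true spectra from an empty ground-truth space")
  }
  with_seed(cfg$seed, {
    spectra <- list()
    manifest <- list()
    scan_id <- 0L
    seq_of <- stats::setNames(lib$sequence, lib$peptide_id)
    add_crosslink <- function(row, within) {
      scan_id <<- scan_id + 1L
      spectra[[scan_id]] <<- .crosslink_spectrum(
        scan_id, seq_of[[row$alpha_id]], row$alpha_site,
        seq_of[[row$beta_id]], row$beta_site, xl, cfg)
      manifest[[scan_id]] <<- data.frame(
        scan_id = scan_id, truth = "crosslink",
        alpha_id = row$alpha_id, alpha_site = row$alpha_site,
        beta_id = row$beta_id, beta_site = row$beta_site,
        within_group = within)
    }
    if (cfg$n_true_spectra > 0) {
      pick <- sample.int(nrow(species), cfg$n_true_spectra, replace = TRUE)
      for (i in pick) add_crosslink(species[i, ], TRUE)
    }
    if (cfg$n_spoof_spectra > 0) {
      spoof <- .sample_cross_group_pairs(partition, cfg$n_spoof_spectra)
      for (i in seq_len(nrow(spoof))) add_crosslink(spoof[i, ], FALSE)
    }
    if (cfg$n_monolink_spectra > 0) {
      monos <- enumerate_monolinks(partition)
      pick <- sample.int(nrow(monos), cfg$n_monolink_spectra, replace = TRUE)
      for (i in pick) {
        scan_id <- scan_id + 1L
        spectra[[scan_id]] <- .monolink_spectrum(
          scan_id, seq_of[[monos$peptide_id[i]]], monos$link_site[i], xl, cfg)
        manifest[[scan_id]] <- data.frame(
          scan_id = scan_id, truth = "monolink",
          alpha_id = monos$peptide_id[i], alpha_site = monos$link_site[i],
          beta_id = NA_character_, beta_site = NA_integer_,
          within_group = NA)
      }
    }
    if (cfg$n_noise_spectra > 0) {
      for (k in seq_len(cfg$n_noise_spectra)) {
        scan_id <- scan_id + 1L
        spectra[[scan_id]] <- .noise_spectrum(scan_id, cfg)
        manifest[[scan_id]] <- data.frame(
          scan_id = scan_id, truth = "noise",
          alpha_id = NA_character_, alpha_site = NA_integer_,
          beta_id = NA_character_, beta_site = NA_integer_,
          within_group = NA)
      }
    }
    manifest <- if (length(manifest) > 0) do.call(rbind, manifest) else
      data.frame(scan_id = integer(), truth = character(),
                 alpha_id = character(), alpha_site = integer(),
                 beta_id = character(), beta_site = integer(),
                 within_group = logical())
    rownames(manifest) <- NULL
    list(spectra = spectra, manifest = manifest)
  })
}

# Assign n CSMs over species rows so the realised mean CSMs per species
# approximates the target redundancy: one CSM per distinct species first,
# remainder sampled uniformly with replacement.
.assign_with_redundancy <- function(n, n_species_avail, redundancy) {
  if (n == 0) return(integer(0))
  n_distinct <- max(1L, min(n_species_avail, n, round(n / redundancy)))
  extra <- n - n_distinct
  c(seq_len(n_distinct),
    if (extra > 0) sample.int(n_distinct, extra, replace = TRUE))
}

#' Simulate a mock search-engine CSM table
#'
#' Emits crosslink-spectrum matches in four classes with scores drawn from
#' per-class truncated-normal distributions: correct targets (admissible
#' within-group species, repeated to the configured redundancy), incorrect
#' targets (cross-group species), and TD / DD decoy matches (decoy sequences
#' from an inverted database). The match class is written to a separate truth
#' table: the validation stage sees only the columns a real engine would
#' report (including the TT/TD/DD flag), never the hidden truth.
#'
#' @param cfg A [simulation_config()].
#' @param ground_truth A [enumerate_potential_crosslinks()] result.
#' @return List with `csms` (CSM data.frame: `scan_id`, `alpha_sequence`,
#'   `alpha_pos`, `beta_sequence`, `beta_pos`, `charge`, `score`,
#'   `delta_score`, `target_decoy_class`, `engine`) and `truth` (data.frame
#'   `scan_id`, `class` in
#'   `{target_correct, target_incorrect, td_decoy, dd_decoy}`).
#' @export
simulate_csm_table <- function(cfg, ground_truth) {
  species <- ground_truth$species
  partition <- ground_truth$partition
  lib <- partition$library
  n_total <- cfg$n_correct_csms + cfg$n_incorrect_csms +
    cfg$n_td_csms + cfg$n_dd_csms
  if (n_total == 0) {
    return(list(csms = empty_csm_table(),
                truth = data.frame(scan_id = integer(), class = character())))
  }
  with_seed(cfg$seed + 1L, {
    seq_of <- stats::setNames(lib$sequence, lib$peptide_id)
    site_of <- stats::setNames(lib$link_site, lib$peptide_id)
    decoys <- generate_decoys(lib, strategy = "invert")
    sm <- cfg$score_model
    blocks <- list()
    # each block: a_seq, a_pos, b_seq, b_pos, class, truth_class, score
    if (cfg$n_correct_csms > 0) {
      if (nrow(species) == 0) stop("empty ground-truth space")
      assign_idx <- .assign_with_redundancy(
        cfg$n_correct_csms, nrow(species), cfg$redundancy_correct)
      chosen <- sample.int(nrow(species), max(assign_idx))
      s <- species[chosen[assign_idx], ]
      blocks$correct <- data.frame(
        a_seq = unname(seq_of[s$alpha_id]), a_pos = s$alpha_site,
        b_seq = unname(seq_of[s$beta_id]), b_pos = s$beta_site,
        class = "TT", truth_class = "target_correct",
        score = rtruncnorm(length(assign_idx), sm$correct[["mean"]],
                           sm$correct[["sd"]]))
    }
    if (cfg$n_incorrect_csms > 0) {
      assign_idx <- .assign_with_redundancy(
        cfg$n_incorrect_csms, .Machine$integer.max, cfg$redundancy_incorrect)
      pairs <- .sample_cross_group_pairs(partition, max(assign_idx))
      s <- pairs[assign_idx, ]
      blocks$incorrect <- data.frame(
        a_seq = unname(seq_of[s$alpha_id]), a_pos = s$alpha_site,
        b_seq = unname(seq_of[s$beta_id]), b_pos = s$beta_site,
        class = "TT", truth_class = "target_incorrect",
        score = rtruncnorm(length(assign_idx), sm$incorrect[["mean"]],
                           sm$incorrect[["sd"]]))
    }
    if (cfg$n_td_csms > 0) {
      ti <- sample.int(nrow(lib), cfg$n_td_csms, replace = TRUE)
      di <- sample.int(nrow(decoys), cfg$n_td_csms, replace = TRUE)
      blocks$td <- data.frame(
        a_seq = lib$sequence[ti], a_pos = lib$link_site[ti],
        b_seq = decoys$sequence[di], b_pos = decoys$link_site[di],
        class = "TD", truth_class = "td_decoy",
        score = rtruncnorm(cfg$n_td_csms, sm$td[["mean"]], sm$td[["sd"]]))
    }
    if (cfg$n_dd_csms > 0) {
      d1 <- sample.int(nrow(decoys), cfg$n_dd_csms, replace = TRUE)
      d2 <- sample.int(nrow(decoys), cfg$n_dd_csms, replace = TRUE)
      blocks$dd <- data.frame(
        a_seq = decoys$sequence[d1], a_pos = decoys$link_site[d1],
        b_seq = decoys$sequence[d2], b_pos = decoys$link_site[d2],
        class = "DD", truth_class = "dd_decoy",
        score = rtruncnorm(cfg$n_dd_csms, sm$dd[["mean"]], sm$dd[["sd"]]))
    }
    all_rows <- do.call(rbind, blocks)
    canon <- canonical_pairs(all_rows$a_seq, all_rows$a_pos,
                             all_rows$b_seq, all_rows$b_pos)
    n <- nrow(all_rows)
    csms <- data.frame(
      scan_id = seq_len(n),
      alpha_sequence = canon$alpha_seq, alpha_pos = canon$alpha_pos,
      beta_sequence = canon$beta_seq, beta_pos = canon$beta_pos,
      charge = if (length(cfg$charge_range) == 1)
        rep(cfg$charge_range, n) else
        sample(cfg$charge_range, n, replace = TRUE),
      score = all_rows$score, delta_score = 0,
      target_decoy_class = all_rows$class, engine = "mock")
    rownames(csms) <- NULL
    list(csms = csms,
         truth = data.frame(scan_id = seq_len(n),
                            class = all_rows$truth_class))
  })
}

#' Write spectra to an MGF peak list
#'
#' Plain `BEGIN IONS`/`END IONS` dialect with `TITLE`, `PEPMASS`, `CHARGE`
#' and `SCANS` headers; m/z and intensity printed to 5 decimal places, so
#' write-then-read round-trips at that precision and identical inputs give
#' byte-identical files.
#'
#' @param spectra List of spectra (as produced by [simulate_spectra()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=scan=%d", sp$scan_id),
      sprintf("PEPMASS=%.5f", sp$precursor_mz),
      sprintf("CHARGE=%d+", sp$charge),
      sprintf("SCANS=%d", sp$scan_id),
      sprintf("%.5f %.5f", sp$mz, sp$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read an MGF peak list
#'
#' @param path MGF file path.
#' @return List of spectra (`scan_id`, `precursor_mz`, `charge`, `mz`,
#'   `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (line == "BEGIN IONS") {
      if (!is.null(cur)) stop("malformed MGF at line ", i,
                              ": nested BEGIN IONS")
      cur <- list(scan_id = NA_integer_, precursor_mz = NA_real_,
                  charge = NA_integer_, mz = numeric(), intensity = numeric())
    } else if (line == "END IONS") {
      if (is.null(cur)) stop("malformed MGF at line ", i,
                             ": END IONS without BEGIN IONS")
      spectra[[length(spectra) + 1]] <- cur
      cur <- NULL
    } else if (is.null(cur)) {
      stop("malformed MGF at line ", i, ": content outside BEGIN/END IONS")
    } else if (grepl("^TITLE=", line)) {
      m <- regmatches(line, regexpr("scan=[0-9]+", line))
      if (length(m) == 1) cur$scan_id <- as.integer(sub("scan=", "", m))
    } else if (grepl("^PEPMASS=", line)) {
      cur$precursor_mz <- as.numeric(strsplit(sub("PEPMASS=", "", line),
                                              "[ \t]")[[1]][1])
    } else if (grepl("^CHARGE=", line)) {
      cur$charge <- as.integer(sub("\\+$", "", sub("CHARGE=", "", line)))
    } else if (grepl("^SCANS=", line)) {
      cur$scan_id <- as.integer(sub("SCANS=", "", line))
    } else if (grepl("^[A-Z]+=", line)) {
      next  # unrecognised header, tolerated
    } else {
      vals <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
      if (length(vals) < 2 || anyNA(vals[1:2])) {
        stop("malformed MGF at line ", i, ": expected 'mz intensity'")
      }
      cur$mz <- c(cur$mz, vals[1])
      cur$intensity <- c(cur$intensity, vals[2])
    }
  }
  if (!is.null(cur)) stop("malformed MGF: unterminated BEGIN IONS block")
  spectra
}
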