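# A minimal, fully specified crosslink search engine.
#
# The engine exists to exercise the FDR and evaluation machinery end-to-end,
# not to rival production engines: it enumerates the full n-squared candidate
# pair space (targets plus decoys), filters candidates by precursor mass,
# scores a candidate as the sum over both peptides of the matched fraction of
# that peptide's theoretical b/y fragments (range 0-2), and optionally gates
# spectra on MS-cleavable diagnostic doublets before searching.

#' Search configuration
#'
#' @param precursor_tol_ppm Precursor mass tolerance in ppm (default 10).
#' @param fragment_tol Fragment matching tolerance in Da (default 0.02).
#' @param min_fragments Minimum matched fragments per peptide for a candidate
#'   to be reported (default 3).
#' @param cleavable_mode Search a spectrum only if at least one diagnostic
#'   doublet is detected (default FALSE).
#' @param doublet_tolerance Doublet spacing tolerance in Da (default 0.01).
#' @param score_cutoff,delta_score_cutoff Optional fixed score filters
#'   (engine-style post-filters, independent of FDR validation).
#' @param fragment_charges Fragment ion charges considered (default 1:2).
#' @return A `search_config` list.
#' @export
search_config <- function(precursor_tol_ppm = 10, fragment_tol = 0.02,
                          min_fragments = 3L, cleavable_mode = FALSE,
                          doublet_tolerance = 0.01,
                          score_cutoff = NULL, delta_score_cutoff = NULL,
                          fragment_charges = 1:2) {
  if (precursor_tol_ppm <= 0 || fragment_tol <= 0 || doublet_tolerance <= 0) {
    stop("tolerances must be positive")
  }
  structure(list(
    precursor_tol_ppm = precursor_tol_ppm,
    fragment_tol = fragment_tol,
    min_fragments = as.integer(min_fragments),
    cleavable_mode = isTRUE(cleavable_mode),
    doublet_tolerance = doublet_tolerance,
    score_cutoff = score_cutoff,
    delta_score_cutoff = delta_score_cutoff,
    fragment_charges = as.integer(fragment_charges)
  ), class = "search_config")
}

#' Build the candidate pair database
#'
#' Indexes target peptides plus (optionally) an equal number of decoys, and
#' enumerates every canonical peptide pair - the n-squared candidate space,
#' homodimers included: P peptides give P(P+1)/2 pairs. Each pair carries its
#' crosslinked precursor mass and its target-decoy class (TT/TD/DD).
#'
#' @param peptides Library data.frame (`peptide_id`, `sequence`, `link_site`),
#'   e.g. `partition$library`.
#' @param xl Crosslinker name or [crosslinker_spec()].
#' @param decoy_strategy `"shuffle_keep_sites"`, `"invert"`, or `"none"`.
#' @param seed Seed for decoy generation.
#' @return A `candidate_db`: list with `peptides` (targets + flagged decoys,
#'   with `mass`), `pairs` (data.frame `idx_a`, `idx_b`, `mass`, `class`,
#'   sorted by mass) and `xl`.
#' @export
build_candidates <- function(peptides, xl,
                             decoy_strategy = c("shuffle_keep_sites", "invert", "none"),
                             seed = 1L) {
  decoy_strategy <- match.arg(decoy_strategy)
  xl <- crosslinker(xl)
  if (nrow(peptides) == 0) stop("peptide list must be non-empty")
  targets <- data.frame(peptide_id = peptides$peptide_id,
                        sequence = peptides$sequence,
                        link_site = peptides$link_site,
                        decoy = FALSE)
  all_peps <- if (decoy_strategy == "none") targets else
    rbind(targets, generate_decoys(peptides, decoy_strategy, seed))
  all_peps$mass <- vapply(all_peps$sequence, peptide_mass, numeric(1))
  p <- nrow(all_peps)
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  pairs <- data.frame(
    idx_a = idx[, 1], idx_b = idx[, 2],
    mass = all_peps$mass[idx[, 1]] + all_peps$mass[idx[, 2]] + xl$bridge_mass,
    n_decoy = all_peps$decoy[idx[, 1]] + all_peps$decoy[idx[, 2]]
  )
  pairs$class <- c("TT", "TD", "DD")[pairs$n_decoy + 1]
  pairs$n_decoy <- NULL
  pairs <- pairs[order(pairs$mass), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(peptides = all_peps, pairs = pairs, xl = xl),
            class = "candidate_db")
}

#' @export
print.candidate_db <- function(x, ...) {
  cat(sprintf("<candidate_db: %d peptides (%d decoys), %d pairs, crosslinker %s>\n",
              nrow(x$peptides), sum(x$peptides$decoy), nrow(x$pairs),
              x$xl$name))
  invisible(x)
}

#' Detect MS-cleavable diagnostic doublets in a spectrum
#'
#' Finds all peak pairs whose m/z difference, under each charge hypothesis,
#' matches a pairwise stub mass difference of the crosslinker within the
#' tolerance.
#'
#' @param spectrum Spectrum list with an `mz` vector.
#' @param xl A cleavable crosslinker.
#' @param tolerance Mass tolerance in Da (on the neutral spacing).
#' @param charges Charge hypotheses (default 1:2).
#' @return data.frame with `mz_low`, `mz_high`, `delta` (neutral spacing),
#'   `charge`.
#' @export
detect_doublets <- function(spectrum, xl, tolerance = 0.01, charges = 1:2) {
  xl <- crosslinker(xl)
  deltas <- doublet_deltas(xl)  # errors on non-cleavable
  mz <- spectrum$mz
  out <- list()
  if (length(mz) >= 2) {
    mz <- sort(mz)
    for (delta in deltas) {
      for (z in charges) {
        gap <- outer(mz, mz, "-")
        hit <- which(abs(gap * z - delta) <= tolerance & gap > 0,
                     arr.ind = TRUE)
        if (nrow(hit) > 0) {
          out[[length(out) + 1]] <- data.frame(
            mz_low = mz[hit[, 2]], mz_high = mz[hit[, 1]],
            delta = delta, charge = as.integer(z))
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mz_low = numeric(), mz_high = numeric(),
                      delta = numeric(), charge = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Matched fragment count of one peptide against a sorted peak list.
.count_matches <- function(theo_mz, peaks_sorted, tol) {
  if (length(theo_mz) == 0 || length(peaks_sorted) == 0) return(0L)
  pos <- findInterval(theo_mz, peaks_sorted)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(peaks_sorted))
  near <- pmin(abs(theo_mz - peaks_sorted[lo]), abs(theo_mz - peaks_sorted[hi]))
  sum(near <= tol)
}

#' Match one spectrum against the candidate database
#'
#' Candidates are restricted to pairs whose crosslinked mass lies within the
#' precursor ppm tolerance of the spectrum's neutral mass (from precursor m/z
#' and charge: `m z - z * proton`). Each surviving candidate is scored as
#' `f_alpha + f_beta`, the matched fractions of the two peptides' theoretical
#' fragment ladders (range 0-2); candidates with fewer than `min_fragments`
#' matched fragments on either peptide are dropped. Ties are broken by total
#' matched peaks, then by lexicographically smallest canonical species. In
#' cleavable mode a spectrum is searched only if [detect_doublets()] fires.
#'
#' @param spectrum Spectrum list (`scan_id`, `precursor_mz`, `charge`, `mz`).
#' @param db A [build_candidates()] database.
#' @param cfg A [search_config()].
#' @return One-row CSM data.frame, or `NULL` when nothing matches. The
#'   `delta_score` column holds best minus second-best distinct species score
#'   (0 when there is no runner-up).
#' @export
match_spectrum <- function(spectrum, db, cfg = search_config()) {
  if (length(spectrum$mz) < 1) stop("spectrum has no peaks")
  if (cfg$cleavable_mode) {
    dd <- detect_doublets(spectrum, db$xl, cfg$doublet_tolerance,
                          charges = cfg$fragment_charges)
    if (nrow(dd) == 0) return(NULL)
  }
  const <- xl_constants()
  z <- spectrum$charge
  neutral <- spectrum$precursor_mz * z - z * const$proton
  tol <- cfg$precursor_tol_ppm * neutral * 1e-6
  masses <- db$pairs$mass
  lo <- findInterval(neutral - tol, masses) + 1L
  hi <- findInterval(neutral + tol, masses)
  if (hi < lo) return(NULL)
  peaks <- sort(spectrum$mz)
  peps <- db$peptides
  xl <- db$xl
  frag_cache <- new.env(parent = emptyenv())
  pep_frags <- function(i, partner_mass) {
    key <- paste0(i, "@", format(partner_mass, digits = 10))
    got <- get0(key, envir = frag_cache)
    if (!is.null(got)) return(got)
    fr <- unique(fragment_mzs(peps$sequence[i], peps$link_site[i],
                              partner_mass = partner_mass, xl = xl,
                              charges = cfg$fragment_charges)$mz)
    assign(key, fr, envir = frag_cache)
    fr
  }
  best <- NULL
  scored <- list()
  for (r in lo:hi) {
    ia <- db$pairs$idx_a[r]; ib <- db$pairs$idx_b[r]
    fa <- pep_frags(ia, peps$mass[ib])
    fb <- pep_frags(ib, peps$mass[ia])
    na <- .count_matches(fa, peaks, cfg$fragment_tol)
    nb <- .count_matches(fb, peaks, cfg$fragment_tol)
    if (na < cfg$min_fragments || nb < cfg$min_fragments) next
    score <- na / length(fa) + nb / length(fb)
    canon <- canonical_pairs(peps$sequence[ia], peps$link_site[ia],
                             peps$sequence[ib], peps$link_site[ib])
    scored[[length(scored) + 1]] <- data.frame(
      alpha_sequence = canon$alpha_seq, alpha_pos = canon$alpha_pos,
      beta_sequence = canon$beta_seq, beta_pos = canon$beta_pos,
      score = score, matched = na + nb,
      n_decoy = peps$decoy[ia] + peps$decoy[ib],
      class = db$pairs$class[r])
  }
  if (length(scored) == 0) return(NULL)
  cand <- do.call(rbind, scored)
  cand$species <- paste(cand$alpha_sequence, cand$alpha_pos,
                        cand$beta_sequence, cand$beta_pos, sep = "|")
  # ties: more matched peaks, then fewer decoy peptides (a decoy can only tie
  # a target when their fragment sets coincide exactly), then species order
  ord <- order(-cand$score, -cand$matched, cand$n_decoy, cand$species)
  cand <- cand[ord, , drop = FALSE]
  best <- cand[1, ]
  runner <- cand$score[cand$species != best$species]
  delta <- if (length(runner) > 0) best$score - max(runner) else 0
  data.frame(
    scan_id = spectrum$scan_id,
    alpha_sequence = best$alpha_sequence, alpha_pos = best$alpha_pos,
    beta_sequence = best$beta_sequence, beta_pos = best$beta_pos,
    charge = as.integer(z), score = best$score, delta_score = delta,
    target_decoy_class = best$class, engine = "xlbench"
  )
}

#' Search a list of spectra
#'
#' Applies [match_spectrum()] to every spectrum and binds the reported CSMs
#' (one best match per scan; unmatched scans are absent from the table).
#'
#' @param spectra List of spectra.
#' @param db A [build_candidates()] database.
#' @param cfg A [search_config()].
#' @return CSM data.frame (possibly empty).
#' @export
search_spectra <- function(spectra, db, cfg = search_config()) {
  rows <- lapply(spectra, match_spectrum, db = db, cfg = cfg)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_csm_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply engine-style fixed score cut-offs
#'
#' Keeps records with `score >= score_cutoff` and
#' `delta_score >= delta_score_cutoff`; either filter may be `NULL`
#' (inactive). These are the fixed post-filters some engines recommend; they
#' are independent of, and give no confidence guarantee like, FDR validation.
#'
#' @param results CSM data.frame with `score` and `delta_score` columns.
#' @param score_cutoff,delta_score_cutoff Optional numeric cut-offs.
#' @return Filtered data.frame.
#' @export
apply_score_cutoffs <- function(results, score_cutoff = NULL,
                                delta_score_cutoff = NULL) {
  keep <- rep(TRUE, nrow(results))
  if (!is.null(score_cutoff)) keep <- keep & results$score >= score_cutoff
  if (!is.null(delta_score_cutoff)) {
    keep <- keep & results$delta_score >= delta_score_cutoff
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
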