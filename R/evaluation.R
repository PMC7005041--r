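# Scoring accepted results against the library ground truth.
#
# Because the library is crosslinked in separate groups, any identified
# crosslink between peptides of different groups is false by construction.
# The calculated (actual) FDR is therefore directly computable, and can be
# compared with the decoy-based estimate the validation stage used.

#' Calculated (actual) FDR of an accepted result set
#'
#' Resolves the accepted records' peptide sequences to library peptide ids,
#' classifies each aggregated item via [classify_crosslink()] and reports the
#' true false fraction. Decoy records must already be excluded (use
#' `validation_result$accepted_targets`); records whose sequences cannot be
#' mapped to the library are collected in an `unmapped` spillover, excluded
#' from the counts, with a warning.
#'
#' @param accepted Accepted target CSM data.frame.
#' @param partition A [partition_groups()] result.
#' @param level Aggregation level at which to count (default `"csm"`).
#' @param estimated_fdr Optional decoy-based estimate to carry in the report.
#' @param exclude_homodimers Drop records where both peptides have the same
#'   sequence before counting (emulates engines that do not report
#'   homodimeric crosslinks). Default FALSE.
#' @return An `evaluation_report`: list with `level`, `n_correct`,
#'   `n_incorrect`, `calculated_fdr`, `estimated_fdr`, `unmapped`
#'   (data.frame), `empty` flag.
#' @export
calculated_fdr <- function(accepted, partition, level = c("csm", "unique_csm", "peptide_pair"),
                           estimated_fdr = NA_real_,
                           exclude_homodimers = FALSE) {
  level <- match.arg(level)
  if (!is.null(accepted$target_decoy_class) &&
      any(accepted$target_decoy_class != "TT")) {
    stop("decoy records must be excluded before ground-truth evaluation")
  }
  agg <- aggregate_csms(accepted, level)
  if (exclude_homodimers && nrow(agg) > 0) {
    agg <- agg[agg$alpha_sequence != agg$beta_sequence, , drop = FALSE]
  }
  lib <- partition$library
  id_of <- stats::setNames(lib$peptide_id, lib$sequence)
  alpha_id <- id_of[agg$alpha_sequence]
  beta_id <- id_of[agg$beta_sequence]
  mapped <- !is.na(alpha_id) & !is.na(beta_id)
  unmapped <- agg[!mapped, , drop = FALSE]
  if (nrow(unmapped) > 0) {
    warning(nrow(unmapped),
            " accepted record(s) could not be mapped to library peptides")
  }
  labels <- if (any(mapped)) {
    classify_crosslink(alpha_id[mapped], beta_id[mapped], partition)
  } else character(0)
  n_correct <- sum(labels == "correct")
  n_incorrect <- sum(labels == "incorrect")
  total <- n_correct + n_incorrect
  structure(list(
    level = level,
    n_correct = n_correct,
    n_incorrect = n_incorrect,
    calculated_fdr = if (total == 0) 0 else n_incorrect / total,
    estimated_fdr = estimated_fdr,
    unmapped = unmapped,
    empty = total == 0
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report (%s): %d correct, %d incorrect, calculated FDR %.2f%%%s>\n",
    x$level, x$n_correct, x$n_incorrect, 100 * x$calculated_fdr,
    if (is.na(x$estimated_fdr)) "" else
      sprintf(" (estimated %.2f%%)", 100 * x$estimated_fdr)))
  invisible(x)
}

#' CSM redundancy per ground-truth class
#'
#' Mean number of CSMs per unique crosslink species, computed separately for
#' correct (within-group) and incorrect (between-group) accepted CSMs. A
#' class with no species is reported as `NA` (absent), not 0.
#'
#' @param accepted Accepted target CSM data.frame (CSM level).
#' @param partition A [partition_groups()] result.
#' @return Named list `redundancy_correct`, `redundancy_incorrect`.
#' @export
csm_redundancy <- function(accepted, partition) {
  agg_species <- aggregate_csms(accepted, "csm")  # canonicalise only
  lib <- partition$library
  id_of <- stats::setNames(lib$peptide_id, lib$sequence)
  alpha_id <- id_of[agg_species$alpha_sequence]
  beta_id <- id_of[agg_species$beta_sequence]
  mapped <- !is.na(alpha_id) & !is.na(beta_id)
  agg_species <- agg_species[mapped, , drop = FALSE]
  labels <- if (any(mapped)) {
    classify_crosslink(alpha_id[mapped], beta_id[mapped], partition)
  } else character(0)
  key <- paste(agg_species$alpha_sequence, agg_species$alpha_pos,
               agg_species$beta_sequence, agg_species$beta_pos, sep = "|")
  ratio <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(sel) / length(unique(key[sel]))
  }
  list(redundancy_correct = ratio(labels == "correct"),
       redundancy_incorrect = ratio(labels == "incorrect"))
}

#' Propagate a CSM-level FDR to the unique-crosslink level
#'
#' CSM redundancy inflates the FDR when results are aggregated to unique
#' crosslinks: correct species collect many CSMs each while incorrect species
#' are mostly seen once, so collapsing shrinks the correct count more than
#' the incorrect one. From a CSM-level FDR `q` and `n` correct CSMs, the
#' implied false CSM count is `FP = n q / (1 - q)`; dividing both counts by
#' their redundancies gives the unique-level FDR
#' `(FP / r_i) / (FP / r_i + n / r_c)`.
#'
#' @param csm_fdr CSM-level calculated FDR, in `[0, 1)`.
#' @param n_correct_csms Number of correct CSMs.
#' @param redundancy_correct,redundancy_incorrect Mean CSMs per unique
#'   species for the two classes (both `>= 1`).
#' @return Unique-crosslink-level FDR fraction.
#' @export
#' @examples
#' propagate_fdr(0.043, 678, 2.9, 1.0) # ~0.115
propagate_fdr <- function(csm_fdr, n_correct_csms,
                          redundancy_correct, redundancy_incorrect) {
  if (csm_fdr < 0 || csm_fdr >= 1) stop("csm_fdr must be in [0, 1)")
  if (n_correct_csms <= 0) stop("n_correct_csms must be positive")
  if (redundancy_correct < 1 || redundancy_incorrect < 1) {
    stop("redundancies must be >= 1")
  }
  fp_csm <- n_correct_csms * csm_fdr / (1 - csm_fdr)
  fp_unique <- fp_csm / redundancy_incorrect
  tp_unique <- n_correct_csms / redundancy_correct
  fp_unique / (fp_unique + tp_unique)
}

#' Overlap (Venn region) analysis of several result sets
#'
#' Tabulates, for every non-empty subset of the input sets, the number of
#' keys found in exactly that subset. Keys are typically scan ids (CSM-level
#' agreement) or canonical species strings (crosslink-level agreement).
#' Duplicate keys within one set are deduplicated with a warning.
#'
#' @param sets Named list (>= 2) of vectors of keys.
#' @return An `overlap_report`: list with `regions` (data.frame `region`,
#'   `count`), `n_union`, `labels`.
#' @export
overlap_analysis <- function(sets) {
  if (length(sets) < 2) stop("need at least two result sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  dup <- vapply(sets, anyDuplicated, numeric(1)) > 0
  if (any(dup)) {
    warning("duplicate keys deduplicated in: ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  tab <- table(pattern)
  regions <- data.frame(region = names(tab), count = as.integer(tab))
  structure(list(regions = regions, n_union = length(universe),
                 labels = names(sets)), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report: %d keys over sets %s>\n", x$n_union,
              paste(x$labels, collapse = ", ")))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Squared Pearson correlation of scores between two engines
#'
#' Pairs the two CSM tables on shared `scan_id` and reports the squared
#' Pearson correlation of their scores plus the pairing count.
#'
#' @param results_a,results_b CSM data.frames with `scan_id` and `score`.
#' @return List with `r_squared` (`NA` when a score vector is constant),
#'   `n_shared`.
#' @export
score_correlation <- function(results_a, results_b) {
  shared <- intersect(results_a$scan_id, results_b$scan_id)
  if (length(shared) < 3) {
    stop("insufficient pairing: need at least 3 shared scans, got ",
         length(shared))
  }
  a <- results_a$score[match(shared, results_a$scan_id)]
  b <- results_b$score[match(shared, results_b$scan_id)]
  r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(a, b)^2
  list(r_squared = r2, n_shared = length(shared))
}

#' Account for every triggered MS2 scan
#'
#' Assigns each scan to exactly one category, by priority: `csm_accepted`
#' (scan in the accepted set), `other_species` (truth manifest says the scan
#' is a monolink or other non-crosslink species), `unvalidated_below_cutoff`
#' (a target CSM was reported but fell below the validation threshold),
#' `decoy_psm` (best match was a decoy), `unknown` (everything else,
#' including scans never matched).
#'
#' @param scan_ids All triggered scan ids.
#' @param results Full CSM table from the search (all reported matches).
#' @param accepted Accepted CSM data.frame (must be a subset of `results` by
#'   `scan_id`).
#' @param truth Optional truth manifest (data.frame `scan_id`, `truth`) used
#'   for the `other_species` category.
#' @return A `spectra_accounting`: list with `counts` (named integer vector
#'   over the five categories), `total`, `category` (per-scan data.frame).
#' @export
spectra_accounting <- function(scan_ids, results, accepted, truth = NULL) {
  if (!all(accepted$scan_id %in% results$scan_id)) {
    stop("accepted contains scan_ids absent from results")
  }
  category <- rep("unknown", length(scan_ids))
  res_class <- stats::setNames(results$target_decoy_class, results$scan_id)
  in_results <- scan_ids %in% results$scan_id
  cls <- res_class[as.character(scan_ids)]
  category[in_results & cls == "TT"] <- "unvalidated_below_cutoff"
  category[in_results & cls %in% c("TD", "DD")] <- "decoy_psm"
  if (!is.null(truth)) {
    other <- truth$scan_id[truth$truth %in% c("monolink", "looplink", "unmodified")]
    category[scan_ids %in% other] <- "other_species"
  }
  category[scan_ids %in% accepted$scan_id] <- "csm_accepted"
  levels <- c("csm_accepted", "other_species", "unvalidated_below_cutoff",
              "decoy_psm", "unknown")
  counts <- table(factor(category, levels = levels))
  structure(list(
    counts = stats::setNames(as.integer(counts), levels),
    total = length(scan_ids),
    category = data.frame(scan_id = scan_ids, category = category)
  ), class = "spectra_accounting")
}

#' @export
print.spectra_accounting <- function(x, ...) {
  cat(sprintf("<spectra_accounting: %d scans>\n", x$total))
  print(x$counts)
  invisible(x)
}
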