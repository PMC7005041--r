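# Target-decoy FDR estimation for crosslink search results.
#
# Estimator: FDR = max(0, #TD - #DD) / #TT, the standard crosslink
# target-decoy formulation. A match is TD when one of the two peptides is a
# decoy, DD when both are; subtracting DD corrects for the double counting of
# random matches that hit two decoys at once. Estimation can be performed at
# three aggregation levels: per CSM, per unique CSM (canonical peptide pair,
# link positions and precursor charge) or per peptide pair (sequences only).

.fdr_levels <- c("csm", "unique_csm", "peptide_pair")

#' Generate a decoy peptide database
#'
#' Two strategies, mirroring the options offered by crosslink search engines:
#' `"shuffle_keep_sites"` permutes the non-K/R residues of each peptide
#' uniformly at random (seeded) while keeping every K and R at its original
#' position (so tryptic cleavage sites and the link-site lysine are
#' preserved); `"invert"` reverses the full sequence. Decoys carry a
#' `decoy = TRUE` flag and a `link_site` recomputed at their (possibly moved)
#' single lysine.
#'
#' @param peptides data.frame with `sequence` and `peptide_id` columns (a
#'   `group_partition$library`, or any library table).
#' @param strategy `"shuffle_keep_sites"` or `"invert"`.
#' @param seed Integer seed (used by the shuffle).
#' @return data.frame with `peptide_id` (prefixed `"DEC_"`), `sequence`,
#'   `link_site`, `decoy`.
#' @export
#' @examples
#' generate_decoys(data.frame(peptide_id = "P1", sequence = "ALKGR"),
#'                 strategy = "invert")
generate_decoys <- function(peptides, strategy = c("shuffle_keep_sites", "invert"),
                            seed = 1L) {
  strategy <- match.arg(strategy)
  seqs <- peptides$sequence
  out_seqs <- if (strategy == "invert") {
    vapply(strsplit(seqs, ""), function(r) paste(rev(r), collapse = ""),
           character(1))
  } else {
    with_seed(seed, vapply(strsplit(seqs, ""), function(r) {
      movable <- which(!r %in% c("K", "R"))
      orig <- paste(r, collapse = "")
      out <- orig
      # avoid emitting a decoy identical to its source peptide (possible when
      # the permutation is the identity); degenerate peptides whose movable
      # residues are all equal cannot be changed and are kept as-is
      for (attempt in 1:25) {
        if (length(movable) > 1) r[movable] <- r[sample(movable)]
        out <- paste(r, collapse = "")
        if (out != orig || length(unique(r[movable])) <= 1) break
      }
      out
    }, character(1)))
  }
  link_site <- as.integer(regexpr("K", out_seqs, fixed = TRUE))
  if (any(link_site < 1)) {
    stop("decoy without a lysine link site; library peptides must contain K")
  }
  data.frame(
    peptide_id = paste0("DEC_", peptides$peptide_id),
    sequence = out_seqs,
    link_site = link_site,
    decoy = TRUE
  )
}

.level_key <- function(records, level) {
  switch(level,
    csm = as.character(records$scan_id),
    unique_csm = paste(records$alpha_sequence, records$alpha_pos,
                       records$beta_sequence, records$beta_pos,
                       records$charge, sep = "|"),
    peptide_pair = paste(records$alpha_sequence, records$beta_sequence,
                         sep = "|")
  )
}

#' Aggregate CSMs to an FDR level
#'
#' Keeps the best-scoring record per aggregation key: `scan_id` at the CSM
#' level (identity), canonical peptide pair + link positions + precursor
#' charge at the unique-CSM level, and canonical sequence pair at the
#' peptide-pair level. Records are canonicalised (alpha/beta ordered) first.
#'
#' @param records CSM data.frame (schema of [simulate_csm_table()] /
#'   [search_spectra()]).
#' @param level One of `"csm"`, `"unique_csm"`, `"peptide_pair"`.
#' @return data.frame of aggregated records (one per key).
#' @export
aggregate_csms <- function(records, level = c("csm", "unique_csm", "peptide_pair")) {
  level <- match.arg(level)
  if (nrow(records) == 0) return(records)
  canon <- canonical_pairs(records$alpha_sequence, records$alpha_pos,
                           records$beta_sequence, records$beta_pos)
  records$alpha_sequence <- canon$alpha_seq
  records$alpha_pos <- canon$alpha_pos
  records$beta_sequence <- canon$beta_seq
  records$beta_pos <- canon$beta_pos
  if (level == "csm") return(records)
  key <- .level_key(records, level)
  # stable best-per-key: order by descending score, keep first of each key
  ord <- order(-records$score, key)
  records <- records[ord, , drop = FALSE]
  out <- records[!duplicated(.level_key(records, level)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-decoy FDR estimate for a set of records
#'
#' `max(0, #TD - #DD) / #TT`. Defined as 0 when the set is empty or contains
#' no decoys; `Inf` when there are decoy matches but no target matches.
#'
#' @param records data.frame with a `target_decoy_class` column in
#'   `{"TT","TD","DD"}`.
#' @return Estimated FDR fraction.
#' @export
#' @examples
#' estimate_fdr(data.frame(target_decoy_class =
#'   c(rep("TT", 100), rep("TD", 5), "DD"))) # 0.04
estimate_fdr <- function(records) {
  cls <- records$target_decoy_class
  if (is.null(cls) || anyNA(cls) || !all(cls %in% c("TT", "TD", "DD"))) {
    stop("every record needs target_decoy_class in {TT, TD, DD}")
  }
  n_tt <- sum(cls == "TT")
  n_td <- sum(cls == "TD")
  n_dd <- sum(cls == "DD")
  if (n_tt == 0) {
    if (n_td == 0 && n_dd == 0) return(0)
    return(Inf)
  }
  max(0, n_td - n_dd) / n_tt
}

#' Filter results to a target estimated FDR
#'
#' Aggregates the records to the requested level, then scans candidate score
#' thresholds (the observed aggregated scores, descending) and returns the
#' largest accepted set whose estimated FDR is at or below the target.
#' Threshold semantics are closed (`score >= threshold`) so all records tied
#' at the threshold score are included. If no threshold satisfies the target
#' the accepted set is empty and the threshold is `Inf`.
#'
#' @param records CSM data.frame with `score` and `target_decoy_class`.
#' @param level Aggregation level (see [aggregate_csms()]).
#' @param target_fdr Target estimated FDR in (0, 1), default 0.05.
#' @return A `validation_result`: list with `level`, `target_fdr`,
#'   `score_threshold`, `estimated_fdr` (at the chosen threshold), `accepted`
#'   (all aggregated records above threshold, decoys included),
#'   `accepted_targets` (the TT subset) and `curve` (data.frame `threshold`,
#'   `estimated_fdr`, `n_accepted`, `n_tt`).
#' @export
apply_cutoff <- function(records, level = c("csm", "unique_csm", "peptide_pair"),
                         target_fdr = 0.05) {
  level <- match.arg(level)
  if (!(target_fdr > 0 && target_fdr < 1)) {
    stop("target_fdr must be in (0, 1)")
  }
  agg <- aggregate_csms(records, level)
  if (nrow(agg) == 0) {
    res <- list(level = level, target_fdr = target_fdr,
                score_threshold = Inf, estimated_fdr = 0,
                accepted = agg, accepted_targets = agg,
                curve = data.frame(threshold = numeric(),
                                   estimated_fdr = numeric(),
                                   n_accepted = integer(), n_tt = integer()))
    class(res) <- "validation_result"
    return(res)
  }
  cls <- agg$target_decoy_class
  if (anyNA(cls) || !all(cls %in% c("TT", "TD", "DD"))) {
    stop("every record needs target_decoy_class in {TT, TD, DD}")
  }
  ord <- order(agg$score, decreasing = TRUE)
  s <- agg$score[ord]
  cum_tt <- cumsum(cls[ord] == "TT")
  cum_td <- cumsum(cls[ord] == "TD")
  cum_dd <- cumsum(cls[ord] == "DD")
  # last index of each tied score block = counts for threshold at that score
  block_end <- which(!duplicated(s, fromLast = TRUE))
  thr <- s[block_end]
  n_tt <- cum_tt[block_end]
  n_td <- cum_td[block_end]
  n_dd <- cum_dd[block_end]
  est <- ifelse(n_tt > 0, pmax(0, n_td - n_dd) / n_tt,
                ifelse(n_td + n_dd > 0, Inf, 0))
  curve <- data.frame(threshold = thr, estimated_fdr = est,
                      n_accepted = block_end, n_tt = n_tt)
  ok <- which(est <= target_fdr)
  if (length(ok) == 0) {
    threshold <- Inf
    accepted <- agg[0, , drop = FALSE]
    est_at <- 0
  } else {
    pick <- ok[length(ok)]  # loosest passing threshold = largest accepted set
    threshold <- thr[pick]
    accepted <- agg[agg$score >= threshold, , drop = FALSE]
    est_at <- est[pick]
  }
  rownames(accepted) <- NULL
  res <- list(level = level, target_fdr = target_fdr,
              score_threshold = threshold, estimated_fdr = est_at,
              accepted = accepted,
              accepted_targets = accepted[accepted$target_decoy_class == "TT", ,
                                          drop = FALSE],
              curve = curve)
  class(res) <- "validation_result"
  res
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "<validation_result: level %s, target %.1f%%, threshold %s, est. FDR %.2f%%, %d accepted (%d targets)>\n",
    x$level, 100 * x$target_fdr,
    if (is.infinite(x$score_threshold)) "Inf" else sprintf("%.4f", x$score_threshold),
    100 * x$estimated_fdr, nrow(x$accepted), nrow(x$accepted_targets)))
  invisible(x)
}
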