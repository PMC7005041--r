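# Synthetic crosslinked peptide library: digestion, peptide selection, group
# partition, enumeration of the admissible crosslink space and the
# ground-truth classification rule.
#
# The benchmark design: single-lysine peptides are crosslinked in separate
# groups and the groups combined before measurement. A crosslink identified
# between two peptides of the same group can be correct; one between peptides
# of different groups is false by construction. That rule is what makes the
# calculated (actual) FDR computable.

#' In-silico proteolytic digestion
#'
#' Cleaves a protein sequence with a protease rule (default trypsin: after K
#' or R, not before P) and returns all peptides with up to `missed` missed
#' cleavages, each with its 1-based inclusive protein coordinates.
#'
#' @param sequence Protein sequence string.
#' @param enzyme Currently `"trypsin"` (cleave after K/R) only.
#' @param missed Maximum number of missed cleavages (default 0).
#' @param not_before_proline Suppress cleavage when the next residue is P
#'   (default TRUE).
#' @return data.frame with columns `sequence`, `start`, `end`, `missed`.
#' @export
#' @examples
#' digest("AKGR")          # "AK", "GR"
#' digest("AKPG")          # "AKPG": no cleavage before proline
digest <- function(sequence, enzyme = "trypsin", missed = 0,
                   not_before_proline = TRUE) {
  residues <- .check_sequence(sequence)
  if (!identical(enzyme, "trypsin")) {
    stop("unsupported enzyme '", enzyme, "'")
  }
  n <- length(residues)
  cut_after <- which(residues %in% c("K", "R"))
  if (not_before_proline) {
    cut_after <- cut_after[cut_after == n | residues[cut_after + 1] != "P"]
  }
  # fragment boundaries: starts after each cut, plus sequence ends
  starts <- c(1, cut_after[cut_after < n] + 1)
  ends <- c(cut_after[cut_after < n], n)
  k <- length(starts)
  out <- list()
  for (i in seq_len(k)) {
    for (m in 0:missed) {
      j <- i + m
      if (j > k) break
      out[[length(out) + 1]] <- data.frame(
        sequence = paste(residues[starts[i]:ends[j]], collapse = ""),
        start = starts[i], end = ends[j], missed = m
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select crosslinkable library peptides
#'
#' Applies the library design filters: peptide length within bounds (default
#' 5-20 residues) and exactly one lysine, the single crosslinker-reactive
#' site. Peptides ending in K are flagged `c_term_azide`: in the synthesis
#' design their C-terminal lysine is protected as epsilon-azido-lysine and
#' reduced back to an amine after digestion, so the link site is still that
#' lysine.
#'
#' @param peptides data.frame from [digest()] (needs a `sequence` column), or
#'   a character vector of sequences.
#' @param min_len,max_len Length bounds, inclusive (defaults 5 and 20).
#' @return data.frame with columns `sequence`, `link_site` (1-based index of
#'   the lysine), `c_term_azide`, plus any input coordinate columns.
#' @export
select_library_peptides <- function(peptides, min_len = 5, max_len = 20) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (is.character(peptides)) peptides <- data.frame(sequence = peptides)
  seqs <- peptides$sequence
  lens <- nchar(seqs)
  n_lys <- lengths(gregexpr("K", seqs, fixed = TRUE))
  n_lys[!grepl("K", seqs, fixed = TRUE)] <- 0L
  keep <- lens >= min_len & lens <= max_len & n_lys == 1
  out <- peptides[keep, , drop = FALSE]
  out$link_site <- as.integer(regexpr("K", out$sequence, fixed = TRUE))
  out$c_term_azide <- out$link_site == nchar(out$sequence)
  rownames(out) <- NULL
  out
}

#' Default group sizes of the benchmark partition
#'
#' Twelve crosslinking groups over 95 peptides, sizes ten groups of 8 plus one
#' of 9 and one of 6. With homodimers included this partition admits exactly
#' 426 within-group crosslink species (sum of n(n+1)/2). The actual group
#' membership used in the physical library is a bench choice; this size
#' vector is the inference consistent with 95 peptides, 12 groups and 426
#' pairs, and is fully user-overridable.
#'
#' @return Integer vector of length 12 summing to 95.
#' @export
default_group_sizes <- function() c(rep(8L, 10), 9L, 6L)

#' Partition library peptides into crosslinking groups
#'
#' Deterministically shuffles the peptides by `seed` and assigns them to
#' groups of the given sizes in order.
#'
#' @param peptides data.frame with at least `sequence` and `link_site`
#'   columns (from [select_library_peptides()]). A `peptide_id` column is
#'   created as `P001`, `P002`, ... if absent.
#' @param group_sizes Integer vector of group sizes; must sum to
#'   `nrow(peptides)`.
#' @param seed Integer seed for the shuffle.
#' @return A `group_partition` object: list with `library` (data.frame adding
#'   `peptide_id` and `group_id`), `groups` (named list group id ->
#'   peptide_ids), `sizes` and `seed`.
#' @export
partition_groups <- function(peptides, group_sizes = default_group_sizes(),
                             seed = 1L) {
  n <- nrow(peptides)
  if (sum(group_sizes) != n) {
    stop("group sizes sum to ", sum(group_sizes), " but there are ",
         n, " peptides")
  }
  if (any(group_sizes < 1)) stop("all groups must be non-empty")
  if (is.null(peptides$peptide_id)) {
    peptides$peptide_id <- sprintf("P%03d", seq_len(n))
  }
  if (anyDuplicated(peptides$peptide_id)) stop("peptide_id must be unique")
  order_idx <- with_seed(seed, sample.int(n))
  group_id <- integer(n)
  group_id[order_idx] <- rep(seq_along(group_sizes), times = group_sizes)
  peptides$group_id <- group_id
  groups <- split(peptides$peptide_id, peptides$group_id)
  names(groups) <- as.character(seq_along(group_sizes))
  structure(list(library = peptides, groups = groups,
                 sizes = as.integer(group_sizes), seed = as.integer(seed)),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("<group_partition: %d peptides in %d groups (sizes %s), seed %d>\n",
              nrow(x$library), length(x$groups),
              paste(x$sizes, collapse = ","), x$seed))
  invisible(x)
}

.partition_lookup <- function(partition) {
  stats::setNames(partition$library$group_id, partition$library$peptide_id)
}

#' Enumerate the admissible (ground-truth) crosslink space
#'
#' All canonical within-group peptide pairs, optionally including homodimers
#' (a peptide crosslinked to a second copy of itself). Species are stored
#' canonically with alpha <= beta under (peptide_id, position) lexicographic
#' order. With homodimers the count is the sum over groups of n(n+1)/2,
#' without them n(n-1)/2.
#'
#' @param partition A [partition_groups()] result.
#' @param include_homodimers Include self-pairs (default TRUE).
#' @return A `ground_truth_space` object: list with `species` (data.frame
#'   `alpha_id`, `alpha_site`, `beta_id`, `beta_site`, `group_id`),
#'   `partition` and `include_homodimers`.
#' @export
enumerate_potential_crosslinks <- function(partition, include_homodimers = TRUE) {
  lib <- partition$library
  out <- list()
  for (g in names(partition$groups)) {
    ids <- sort(partition$groups[[g]])
    sites <- lib$link_site[match(ids, lib$peptide_id)]
    ng <- length(ids)
    rows <- which(upper.tri(diag(ng), diag = include_homodimers), arr.ind = TRUE)
    if (nrow(rows) == 0) next
    out[[g]] <- data.frame(
      alpha_id = ids[rows[, 1]], alpha_site = sites[rows[, 1]],
      beta_id = ids[rows[, 2]], beta_site = sites[rows[, 2]],
      group_id = as.integer(g)
    )
  }
  species <- do.call(rbind, out)
  if (is.null(species)) {
    species <- data.frame(alpha_id = character(), alpha_site = integer(),
                          beta_id = character(), beta_site = integer(),
                          group_id = integer())
  }
  rownames(species) <- NULL
  structure(list(species = species, partition = partition,
                 include_homodimers = include_homodimers),
            class = "ground_truth_space")
}

#' @export
print.ground_truth_space <- function(x, ...) {
  cat(sprintf("<ground_truth_space: %d admissible crosslink species (%s homodimers)>\n",
              nrow(x$species),
              if (x$include_homodimers) "with" else "without"))
  invisible(x)
}

#' Classify an identified crosslink against the library design
#'
#' The ground-truth rule of the benchmark: a crosslink between two peptides
#' of the same crosslinking group can be correct; one between peptides of
#' different groups is known to be a false positive. Homodimers are always
#' within-group, hence correct.
#'
#' @param alpha_id,beta_id Peptide id vectors (recycled to common length).
#' @param partition A [partition_groups()] result.
#' @return Character vector, `"correct"` or `"incorrect"`.
#' @export
classify_crosslink <- function(alpha_id, beta_id, partition) {
  lookup <- .partition_lookup(partition)
  unknown <- setdiff(c(alpha_id, beta_id), names(lookup))
  if (length(unknown) > 0) {
    stop("unknown peptide_id(s): ", paste(unique(unknown), collapse = ", "))
  }
  ifelse(lookup[alpha_id] == lookup[beta_id], "correct", "incorrect")
}

#' Enumerate monolink species
#'
#' One monolink species (crosslinker reacted on one end, hydrolysed on the
#' other) per library peptide at its link site.
#'
#' @param partition A [partition_groups()] result.
#' @return data.frame with columns `peptide_id`, `link_site`.
#' @export
enumerate_monolinks <- function(partition) {
  lib <- partition$library
  data.frame(peptide_id = lib$peptide_id, link_site = lib$link_site)
}

#' Build a complete synthetic library from a protein sequence
#'
#' Runs the full design: tryptic digestion, single-lysine peptide selection
#' (5-20 residues by default), deterministic subsampling to the configured
#' library size when more candidates are available, and group partitioning.
#'
#' @param sequence Protein sequence string (e.g. from [read_fasta()]).
#' @param n_peptides Target library size (default 95). If fewer candidates
#'   pass the filters an error is raised; if more, a seeded subsample is
#'   taken.
#' @param group_sizes Group size vector; default [default_group_sizes()]
#'   when `n_peptides` is 95, else a near-even split into 12 groups.
#' @param seed Integer seed controlling subsampling and partition shuffle.
#' @param min_len,max_len Peptide length bounds.
#' @param missed Maximum missed cleavages for the digest (default 0).
#' @return A `group_partition` object (see [partition_groups()]).
#' @export
build_library <- function(sequence, n_peptides = 95,
                          group_sizes = NULL, seed = 1L,
                          min_len = 5, max_len = 20, missed = 0) {
  candidates <- select_library_peptides(
    digest(sequence, missed = missed), min_len = min_len, max_len = max_len)
  candidates <- candidates[!duplicated(candidates$sequence), , drop = FALSE]
  if (nrow(candidates) < n_peptides) {
    stop("only ", nrow(candidates), " candidate peptides pass the filters; ",
         n_peptides, " requested")
  }
  if (nrow(candidates) > n_peptides) {
    keep <- with_seed(seed, sort(sample.int(nrow(candidates), n_peptides)))
    candidates <- candidates[keep, , drop = FALSE]
  }
  if (is.null(group_sizes)) {
    group_sizes <- if (n_peptides == 95) default_group_sizes() else {
      base <- n_peptides %/% 12
      sizes <- rep(base, 12)
      extra <- n_peptides - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
      sizes[sizes > 0]
    }
  }
  partition_groups(candidates, group_sizes = group_sizes, seed = seed)
}
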