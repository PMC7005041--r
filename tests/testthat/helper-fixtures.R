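# Shared fixtures and independent oracles used across the test files.

# Small benchmark partition built from a seeded synthetic protein.
tiny_partition <- function(n = 12, groups = c(4L, 4L, 4L), seed = 42) {
  prot <- random_benchmark_protein(n_peptides = n, seed = seed)
  build_library(prot, n_peptides = n, group_sizes = groups, seed = seed)
}

# Independent residue masses for oracle computations (standard monoisotopic
# values, written down independently of the package's element table).
oracle_residues <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
oracle_water <- 18.01056
oracle_proton <- 1.00728

# Brute-force prefix/suffix b/y ladder for a plain linear peptide, charge 1.
oracle_linear_ladder <- function(seq) {
  r <- strsplit(seq, "")[[1]]
  n <- length(r)
  m <- oracle_residues[r]
  b <- sapply(1:(n - 1), function(i) sum(m[1:i])) + oracle_proton
  y <- sapply(1:(n - 1), function(i) sum(m[(i + 1):n])) + oracle_water +
    oracle_proton
  sort(c(b, y))
}

# Brute-force tryptic site scanner (cleave after K/R unless next is P).
oracle_digest <- function(seq) {
  r <- strsplit(seq, "")[[1]]
  n <- length(r)
  peptides <- character(0)
  start <- 1
  for (i in seq_len(n)) {
    if (r[i] %in% c("K", "R") && (i == n || r[i + 1] != "P")) {
      peptides <- c(peptides, paste(r[start:i], collapse = ""))
      start <- i + 1
    }
  }
  if (start <= n) peptides <- c(peptides, paste(r[start:n], collapse = ""))
  peptides
}

# Explicit double-loop enumeration of within-group pairs.
oracle_pair_count <- function(partition, include_homodimers = TRUE) {
  lib <- partition$library
  count <- 0
  for (i in seq_len(nrow(lib))) {
    for (j in seq_len(nrow(lib))) {
      if (j < i) next
      if (j == i && !include_homodimers) next
      if (lib$group_id[i] == lib$group_id[j]) count <- count + 1
    }
  }
  count
}

# Random CSM table with score ties, decoy classes and repeated species.
random_csm_table <- function(n, seed, n_species = 20) {
  set.seed(seed)
  seqs <- replicate(n_species, paste(
    sample(c("A", "G", "L", "S", "V", "K"), 6, replace = TRUE),
    collapse = ""))
  i <- sample.int(n_species, n, replace = TRUE)
  j <- sample.int(n_species, n, replace = TRUE)
  data.frame(
    scan_id = seq_len(n),
    alpha_sequence = seqs[i], alpha_pos = sample(1:3, n, replace = TRUE),
    beta_sequence = seqs[j], beta_pos = sample(1:3, n, replace = TRUE),
    charge = sample(3:5, n, replace = TRUE),
    score = round(runif(n, 0, 20), 1),  # one decimal: frequent ties
    delta_score = 0,
    target_decoy_class = sample(c("TT", "TD", "DD"), n, replace = TRUE,
                                prob = c(0.7, 0.2, 0.1)),
    engine = "mock"
  )
}

# Independent canonicalisation + group-by-max aggregation.
oracle_aggregate <- function(records, level) {
  swap <- records$beta_sequence < records$alpha_sequence |
    (records$beta_sequence == records$alpha_sequence &
       records$beta_pos < records$alpha_pos)
  tmp_seq <- records$alpha_sequence[swap]
  tmp_pos <- records$alpha_pos[swap]
  records$alpha_sequence[swap] <- records$beta_sequence[swap]
  records$alpha_pos[swap] <- records$beta_pos[swap]
  records$beta_sequence[swap] <- tmp_seq
  records$beta_pos[swap] <- tmp_pos
  key <- switch(level,
    csm = as.character(records$scan_id),
    unique_csm = paste(records$alpha_sequence, records$alpha_pos,
                       records$beta_sequence, records$beta_pos,
                       records$charge),
    peptide_pair = paste(records$alpha_sequence, records$beta_sequence))
  records$key <- key
  if (level == "csm") return(records)
  do.call(rbind, lapply(split(records, key), function(grp) {
    grp[which.max(grp$score), , drop = FALSE]
  }))
}

# Brute-force scan over every observed threshold at a level.
oracle_cutoff <- function(records, level, target) {
  agg <- oracle_aggregate(records, level)
  thresholds <- sort(unique(agg$score), decreasing = TRUE)
  best_thr <- Inf
  for (t in thresholds) {
    acc <- agg[agg$score >= t, , drop = FALSE]
    n_tt <- sum(acc$target_decoy_class == "TT")
    n_td <- sum(acc$target_decoy_class == "TD")
    n_dd <- sum(acc$target_decoy_class == "DD")
    est <- if (n_tt == 0) {
      if (n_td + n_dd == 0) 0 else Inf
    } else max(0, n_td - n_dd) / n_tt
    if (est <= target) best_thr <- t
  }
  accepted <- agg[agg$score >= best_thr, , drop = FALSE]
  list(threshold = best_thr, accepted = accepted)
}

# Comparable fingerprint of an accepted set: sorted key/score strings.
accepted_fingerprint <- function(records, level) {
  if (nrow(records) == 0) return(character(0))
  key <- switch(level,
    csm = as.character(records$scan_id),
    unique_csm = paste(records$alpha_sequence, records$alpha_pos,
                       records$beta_sequence, records$beta_pos,
                       records$charge),
    peptide_pair = paste(records$alpha_sequence, records$beta_sequence))
  sort(paste(key, format(records$score, digits = 12)))
}
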