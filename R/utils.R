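# Internal helpers.

# Evaluate code under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Canonicalise (sequence, position) pairs so alpha <= beta under
# lexicographic (sequence, position) order. Vectorised; returns a data.frame
# with the four canonical columns.
canonical_pairs <- function(alpha_seq, alpha_pos, beta_seq, beta_pos) {
  swap <- (beta_seq < alpha_seq) |
    (beta_seq == alpha_seq & beta_pos < alpha_pos)
  data.frame(
    alpha_seq = ifelse(swap, beta_seq, alpha_seq),
    alpha_pos = ifelse(swap, beta_pos, alpha_pos),
    beta_seq = ifelse(swap, alpha_seq, beta_seq),
    beta_pos = ifelse(swap, alpha_pos, beta_pos)
  )
}

# Draw from a normal truncated below at `lower` (simple rejection; the
# truncation point is far in the tail for all default score models).
rtruncnorm <- function(n, mean, sd, lower = 0) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower
  }
  out
}

# sample() treats a length-1 numeric as 1:x; this keeps it literal.
sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

# Empty CSM table with the canonical schema.
empty_csm_table <- function() {
  data.frame(
    scan_id = integer(), alpha_sequence = character(), alpha_pos = integer(),
    beta_sequence = character(), beta_pos = integer(), charge = integer(),
    score = numeric(), delta_score = numeric(),
    target_decoy_class = character(), engine = character()
  )
}
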