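# Synthetic benchmark protein.

#' Generate a synthetic benchmark protein sequence
#'
#' Builds a random protein whose tryptic digest is guaranteed to contain at
#' least `n_peptides` distinct single-lysine peptides within the length
#' bounds: crosslinkable peptides end in K with no internal K/R, and filler
#' peptides end in R with no lysine (so they fail the single-lysine filter).
#' Proline is excluded from the generated residues so the cleavage rule has
#' no suppressed sites. This is a synthetic stand-in used for demonstrations
#' and simulations; any real protein FASTA can be used instead via
#' [read_fasta()].
#'
#' @param n_peptides Number of crosslinkable peptides to embed (default 95).
#' @param seed Integer seed.
#' @param min_len,max_len Length bounds of the embedded peptides.
#' @param n_filler Number of interspersed lysine-free filler peptides
#'   (default 20).
#' @return A protein sequence string.
#' @export
#' @examples
#' prot <- random_benchmark_protein(n_peptides = 10, seed = 7)
#' nrow(select_library_peptides(digest(prot))) >= 10
random_benchmark_protein <- function(n_peptides = 95, seed = 1L,
                                     min_len = 5, max_len = 20,
                                     n_filler = 20) {
  alphabet <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                "Q", "S", "T", "V", "W", "Y")
  with_seed(seed, {
    seen <- character(0)
    peptides <- character(0)
    while (length(peptides) < n_peptides) {
      len <- sample(min_len:max_len, 1)
      pep <- paste0(paste(sample(alphabet, len - 1, replace = TRUE),
                          collapse = ""), "K")
      if (pep %in% seen) next
      seen <- c(seen, pep)
      peptides <- c(peptides, pep)
    }
    fillers <- vapply(seq_len(n_filler), function(i) {
      len <- sample(min_len:max_len, 1)
      paste0(paste(sample(alphabet, len - 1, replace = TRUE),
                   collapse = ""), "R")
    }, character(1))
    # interleave fillers among the crosslinkable peptides
    all_peps <- character(0)
    filler_at <- sort(sample.int(n_peptides, min(n_filler, n_peptides)))
    fi <- 1
    for (i in seq_len(n_peptides)) {
      all_peps <- c(all_peps, peptides[i])
      if (fi <= length(fillers) && i %in% filler_at) {
        all_peps <- c(all_peps, fillers[fi])
        fi <- fi + 1
      }
    }
    paste(all_peps, collapse = "")
  })
}
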