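# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Global affine-gap alignment score by exhaustive enumeration of all
# alignments (no dynamic programming). A maximal gap run of length k costs
# gap_open + k * gap_extend; end gaps are penalized.
brute_force_align_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  na <- length(ach)
  nb <- length(bch)
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > na && j > nb) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) {
      rec(i + 1L, j + 1L, score + submat[ach[i], bch[j]], 0L)
    }
    if (i <= na) {
      rec(i + 1L, j, score - (if (state == 1L) 0 else gap_open) - gap_extend, 1L)
    }
    if (j <= nb) {
      rec(i, j + 1L, score - (if (state == 2L) 0 else gap_open) - gap_extend, 2L)
    }
  }
  rec(1L, 1L, 0, 0L)
  best
}

# Naive double-loop normalized Moreau-Broto autocorrelation.
naive_moreau_broto <- function(sequence, prop_values, d) {
  ch <- strsplit(sequence, "")[[1]]
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  x <- prop_values[match(ch, aa)]
  s <- 0
  n <- 0
  for (i in seq_len(length(x) - d)) {
    s <- s + x[i] * x[i + d]
    n <- n + 1
  }
  s / n
}

random_aa_sequence <- function(len, alphabet = c(
                                 "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
                               )) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
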