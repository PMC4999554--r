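# Independent oracles used across tests.

# Exhaustive affine-gap global alignment score by plain recursion over all
# alignments (no dynamic-programming tables shared with the implementation).
# `last` is the operation immediately to the right; a gap run of length L
# costs gap_open + (L - 1) * gap_extend.
brute_force_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -2) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, last) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L, "M") + s)
    }
    if (i > 0L)
      best <- max(best, rec(i - 1L, j, "U") +
                    if (last == "U") gap_extend else gap_open)
    if (j > 0L)
      best <- max(best, rec(i, j - 1L, "L") +
                    if (last == "L") gap_extend else gap_open)
    best
  }
  rec(length(ca), length(cb), "")
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

# plant a substitution at a fixed 1-based position
substitute_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

# a small clade panel used by several tests
small_panel <- function(seed = 42, members = 5) {
  generate_clade_scheme(sim_config(seed = seed,
                                   members_per_clade = members))
}
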