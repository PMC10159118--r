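# Independent exhaustive oracle for global pairwise alignment with affine
# gaps: enumerates every monotone alignment path (no gap-gap columns) by
# recursion, scoring incrementally; a gap run of length k costs
# open + (k - 1) * extend. Completely separate from the package's dynamic
# programme.
exhaustive_align_score <- function(a, b, smat = ss_score_matrix(),
                                   open = 4, extend = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(av); lb <- length(bv)
  best <- -Inf
  # state: 0 none/match, 1 gap in b (consumed a), 2 gap in a
  rec <- function(i, j, state, acc) {
    if (i > la && j > lb) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= la && j <= lb) {
      rec(i + 1L, j + 1L, 0L, acc + smat[av[i], bv[j]])
    }
    if (i <= la) {
      rec(i + 1L, j, 1L, acc - if (state == 1L) extend else open)
    }
    if (j <= lb) {
      rec(i, j + 1L, 2L, acc - if (state == 2L) extend else open)
    }
    invisible()
  }
  rec(1L, 1L, 0L, 0)
  best
}

# Brute-force average-linkage first merge for a 3-leaf distance matrix:
# the pair with the smallest distance joins first.
first_join_pair <- function(D) {
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  pairs[which.min(D[upper.tri(D)]), ]
}
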