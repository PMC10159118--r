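# Fixture builders shared across test files. All randomness is seeded by
# the caller so every test is reproducible.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
SS3 <- c("H", "E", "C")

# A random row-stochastic 20 x 3 propensity matrix.
random_propensity <- function() {
  w <- matrix(stats::rgamma(60, shape = 2), 20, 3,
              dimnames = list(AA20, SS3))
  w / rowSums(w)
}

# A small annotated proteome with iid residues: amino acids drawn from a
# random composition, states drawn from a random propensity matrix.
random_proteome <- function(n_prot = 10, len = 150,
                            propensity = random_propensity()) {
  aa_probs <- stats::rgamma(20, shape = 2)
  aa_probs <- aa_probs / sum(aa_probs)
  seqs <- ss <- character(n_prot)
  for (i in seq_len(n_prot)) {
    aa <- sample(AA20, len, replace = TRUE, prob = aa_probs)
    st <- vapply(aa, function(a) {
      sample(SS3, 1L, prob = propensity[a, ])
    }, "")
    seqs[i] <- paste(aa, collapse = "")
    ss[i] <- paste(st, collapse = "")
  }
  names(seqs) <- names(ss) <- sprintf("p%03d", seq_len(n_prot))
  attach_ss(seqs, ss)
}

random_ss_string <- function(len) {
  paste(sample(SS3, len, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(records, ext = ".fa") {
  f <- tempfile(fileext = ext)
  writeLines(paste0(">", names(records), "\n", records), f)
  f
}
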