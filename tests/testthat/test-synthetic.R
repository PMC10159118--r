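test_that("generator hits the target GC at both mid and extreme targets", {
  for (tgt in c(0.50, 0.74)) {
    g <- generate_genome(synthetic_spec(target_gc = tgt, n_genes = 200,
                                        mean_length = 300, seed = 7))
    expect_lt(abs(g$truth$realized_gc - tgt), 0.01)
    expect_equal(g$truth$realized_gc,
                 compute_coding_gc(g$record))
  }
})

test_that("identical spec and seed give byte-identical output", {
  sp <- synthetic_spec(target_gc = 0.4, n_genes = 30, mean_length = 80,
                       persistence = 0.3, seed = 99)
  g1 <- generate_genome(sp)
  g2 <- generate_genome(sp)
  expect_identical(g1$record$genes, g2$record$genes)
  expect_identical(g1$record$proteome$seq, g2$record$proteome$seq)
  expect_identical(g1$record$proteome$ss, g2$record$proteome$ss)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(g1$record$genes, f1)
  write_fasta(g2$record$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("genes are well-formed CDS and translate to the proteins", {
  g <- generate_genome(synthetic_spec(target_gc = 0.6, n_genes = 15,
                                      mean_length = 70, seed = 3))
  genes <- g$record$genes
  prots <- g$record$proteome$seq
  expect_true(all(substr(genes, 1, 3) == "ATG"))
  stops <- substr(genes, nchar(genes) - 2, nchar(genes))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  expect_true(all(nchar(genes) %% 3 == 0))
  # independent translation oracle
  tr <- as.character(Biostrings::translate(Biostrings::DNAStringSet(genes)))
  expect_equal(unname(sub("\\*$", "", tr)), unname(prots))
  # ss strings cover every protein residue
  expect_equal(nchar(g$record$proteome$ss), nchar(prots),
               ignore_attr = TRUE)
})

test_that("gene lengths respect the 50-codon floor", {
  g <- generate_genome(synthetic_spec(target_gc = 0.3, n_genes = 120,
                                      mean_length = 50, dispersion = 2,
                                      seed = 17))
  expect_true(all(nchar(g$record$proteome$seq) >= 50))
})

test_that("closed-form CP oracle evaluates known cases", {
  # uniform conditionals: every CP is exactly 1
  unif <- matrix(1 / 3, 20, 3, dimnames = list(AA20, SS3))
  sp <- synthetic_spec(propensity = unif, seed = 1)
  f <- setNames(rep(0.05, 20), AA20)
  expect_equal(unname(expected_cp(sp, f)), matrix(1, 20, 3))

  # hand-evaluated single-cell case:
  # P(H|Ala) = 0.6, all other aa 0.3, f(Ala) = 0.05
  prop <- matrix(rep(c(0.3, 0.35, 0.35), each = 20), 20, 3,
                 dimnames = list(AA20, SS3))
  prop["A", ] <- c(0.6, 0.2, 0.2)
  sp2 <- synthetic_spec(propensity = prop, seed = 1)
  f2 <- setNames(c(0.05, rep(0.95 / 19, 19)), AA20)
  cp <- expected_cp(sp2, f2)
  expect_equal(cp["A", "H"], 0.6 / (0.05 * 0.6 + 0.95 * 0.3),
               tolerance = 1e-9)

  # algebraic identity: frequency-weighted mean CP is 1 for each state
  set.seed(53)
  for (i in 1:5) {
    pr <- random_propensity()
    fr <- rgamma(20, 2); fr <- setNames(fr / sum(fr), AA20)
    cpm <- expected_cp(synthetic_spec(propensity = pr, seed = 1), fr)
    expect_equal(unname(colSums(fr * cpm)), c(1, 1, 1), tolerance = 1e-9)
  }

  expect_error(expected_cp(synthetic_spec(persistence = 0.5, seed = 1), f),
               "persistence")
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(synthetic_spec(target_gc = 0.05), "target_gc")
  expect_error(synthetic_spec(target_gc = 0.9), "target_gc")
  expect_error(synthetic_spec(n_genes = 0), "n_genes")
  expect_error(synthetic_spec(mean_length = 10), "mean_length")
  expect_error(synthetic_spec(persistence = 1), "persistence")
  bad <- default_propensity(); bad[1, ] <- c(0.5, 0.5, 0.5)
  expect_error(synthetic_spec(propensity = bad), "sum to 1")
})

test_that("persistence produces longer state runs without changing marginals much", {
  sp0 <- synthetic_spec(target_gc = 0.5, n_genes = 60, mean_length = 200,
                        persistence = 0, seed = 8)
  sp9 <- synthetic_spec(target_gc = 0.5, n_genes = 60, mean_length = 200,
                        persistence = 0.8, seed = 8)
  runlen <- function(g) {
    mean(unlist(lapply(g$record$proteome$ss, function(s) {
      rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths
    })))
  }
  expect_gt(runlen(generate_genome(sp9)), 2 * runlen(generate_genome(sp0)))
})

test_that("GC-coupled propensities raise coil share with GC", {
  lo <- gc_coupled_propensity(0.25)
  hi <- gc_coupled_propensity(0.70)
  expect_true(all(hi[, "C"] > lo[, "C"]))
  expect_equal(unname(rowSums(hi)), rep(1, 20), tolerance = 1e-12)
})
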