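test_that("per-structure amino-acid frequencies match hand counts", {
  ap <- attach_ss(c(p = "AG"), c(p = "HC"))
  tabs <- aa_frequencies_by_ss(ap)
  expect_equal(tabs$helix$frequency[tabs$helix$aa == "A"], 1)
  expect_equal(tabs$coil$frequency[tabs$coil$aa == "G"], 1)
  expect_true(isTRUE(attr(tabs$sheet, "empty")))
  expect_true(all(is.na(tabs$sheet$frequency)))

  ap2 <- attach_ss(c(p = "AAGG"), c(p = "HHCC"))
  tabs2 <- aa_frequencies_by_ss(ap2)
  expect_equal(tabs2$helix$frequency[match(c("A", "G"), tabs2$helix$aa)],
               c(1, 0))
  expect_equal(tabs2$coil$frequency[match(c("A", "G"), tabs2$coil$aa)],
               c(0, 1))

  expect_error(aa_frequencies_by_ss(attach_ss(c(p = "AG"), NULL["x"])),
               "named")
})

test_that("conformational parameters reproduce the worked example", {
  cpars <- conformational_params(attach_ss(c(p = "AAGG"), c(p = "HHCC")))
  expect_equal(cpars$f_ss_aa["A", "H"], 1)
  expect_equal(unname(cpars$f_ss["H"]), 0.5)
  expect_equal(cpars$cp["A", "H"], 2)
  expect_equal(cpars$cp["G", "H"], 0)
  # absent amino acids are flagged missing, not zero
  expect_true("W" %in% cpars$missing_aa)
  expect_true(all(is.na(cpars$cp["W", ])))
})

test_that("a proteome with uniform state usage has every CP equal to 1", {
  seqs <- setNames(vapply(AA20, function(a) {
    paste(rep(a, 3), collapse = "")
  }, ""), paste0("p", AA20))
  ss <- setNames(rep("HEC", 20), names(seqs))
  cpars <- conformational_params(attach_ss(seqs, ss))
  expect_equal(unname(cpars$cp), matrix(1, 20, 3), tolerance = 1e-12)
})

test_that("CP identities hold on random proteomes", {
  set.seed(37)
  for (i in 1:8) {
    ap <- random_proteome(n_prot = 8, len = 120)
    cpars <- conformational_params(ap)
    freq <- aa_frequencies(ap)
    f <- setNames(freq$frequency, freq$aa)
    # frequency-weighted mean CP is exactly 1 per state
    wmean <- colSums(f[rownames(cpars$cp)] * cpars$cp, na.rm = TRUE)
    expect_equal(unname(wmean), c(1, 1, 1), tolerance = 1e-9)
    # each amino acid's residues are fully distributed over the 3 states
    present <- rowSums(cpars$counts) > 0
    expect_equal(unname(rowSums(cpars$f_ss_aa[present, , drop = FALSE])),
                 rep(1, sum(present)), tolerance = 1e-9)
    expect_equal(sum(cpars$f_ss), 1, tolerance = 1e-12)
  }
})

test_that("the two frequency formulations agree cell by cell", {
  set.seed(41)
  ap <- random_proteome(n_prot = 10, len = 100)
  cpars <- conformational_params(ap)
  by_ss <- aa_frequencies_by_ss(ap)
  fr <- aa_frequencies(ap)
  aa_g <- setNames(fr$frequency, fr$aa)
  for (k in 1:3) {
    st <- c("H", "E", "C")[k]
    tab <- by_ss[[c("helix", "sheet", "coil")[k]]]
    aa_ss <- setNames(tab$frequency, tab$aa)
    lhs <- aa_ss[AA20] * unname(cpars$f_ss[st])
    rhs <- cpars$f_ss_aa[AA20, st] * aa_g[AA20]
    cmp <- !is.na(lhs) & !is.na(rhs)
    expect_equal(unname(lhs[cmp]), unname(rhs[cmp]), tolerance = 1e-12)
  }
})

test_that("ss_composition pools, splits per protein, and length-weights", {
  expect_equal(
    as.numeric(ss_composition(c(p = "HHEC"))[1, 1:3]),
    c(0.5, 0.25, 0.25))
  per <- ss_composition(c(p = paste0(strrep("H", 4), strrep("C", 6))),
                        scope = "protein")
  expect_equal(as.numeric(per[1, c("helix", "sheet", "coil")]),
               c(0.4, 0, 0.6))
  expect_equal(as.numeric(ss_composition(c(a = "CC", b = "CCCC"))[1, 1:3]),
               c(0, 0, 1))

  set.seed(43)
  ap <- random_proteome(n_prot = 6, len = 90)
  pooled <- ss_composition(ap)
  per <- ss_composition(ap, scope = "protein")
  w <- per$length / sum(per$length)
  expect_equal(as.numeric(pooled[1, 1:3]),
               c(sum(w * per$helix), sum(w * per$sheet), sum(w * per$coil)),
               tolerance = 1e-12)
  expect_error(ss_composition(character(0)), "empty")
})

test_that("X residues are excluded from structure statistics", {
  ap <- attach_ss(c(p = "AXG"), c(p = "HEC"))
  cpars <- conformational_params(ap)
  expect_equal(cpars$n_residues, 2L)
  expect_equal(unname(cpars$f_ss), c(0.5, 0, 0.5))
})

test_that("categorize_cp maps CP to the five classical labels", {
  cpars <- conformational_params(attach_ss(c(p = "AAGG"), c(p = "HHCC")))
  th <- c(0.6, 0.9, 1.1, 1.4)
  cats <- categorize_cp(cpars, th)
  look <- function(aa, ss) cats$category[cats$aa == aa & cats$ss == ss]
  expect_equal(look("A", "H"), "strong former")   # cp = 2
  expect_equal(look("G", "H"), "strong breaker")  # cp = 0
  expect_equal(look("A", "C"), "strong breaker")
  # interior bin
  fake <- cpars; fake$cp["A", "H"] <- 1.0
  expect_equal(categorize_cp(fake, th)$category[
    cats$aa == "A" & cats$ss == "H"], "indifferent")
  expect_error(categorize_cp(cpars, c(1, 0.5, 2, 3)), "increasing")
})
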