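mk_group <- function(lengths, dom_start = NULL, dom_end = NULL,
                     id = "COGX") {
  n <- length(lengths)
  # default: a common domain span so only the length criterion can fire
  cog_group(id, data.frame(
    protein_id = paste0("p", seq_len(n)),
    length = lengths,
    domain_start = if (is.null(dom_start)) rep(1L, n) else dom_start,
    domain_end = if (is.null(dom_end)) rep(min(lengths), n) else dom_end,
    stringsAsFactors = FALSE))
}

test_that("length filter retains members within one sample SD of the mean", {
  # identical lengths: SD 0, boundary inclusive, all retained
  g0 <- select_representatives(mk_group(c(100, 100, 100)))
  expect_equal(nrow(g0$members), 3L)

  # worked example: mean 150, sample SD ~100.33, 300 dropped
  g1 <- mk_group(c(90, 100, 110, 300))
  expect_equal(g1$length_mean, 150)
  expect_equal(g1$length_sd, sqrt(30200 / 3), tolerance = 1e-12)
  f1 <- select_representatives(g1)
  expect_setequal(f1$members$protein_id, c("p1", "p2", "p3"))
  audit <- attr(f1, "audit")
  expect_equal(audit$protein_id, "p4")
  expect_match(audit$reason, "1 SD")

  # exact 1-SD boundary is retained
  g2 <- mk_group(c(98, 100, 102))   # SD = 2, deviations 2, 0, 2
  expect_equal(nrow(select_representatives(g2)$members), 3L)
})

test_that("domain filter drops members covering under 80% of mean domain length", {
  # domains 200, 200, 120: mean 173.33, cut 138.67 -> third member dropped
  g <- mk_group(c(210, 210, 210),
                dom_start = c(1L, 1L, 1L),
                dom_end = c(200L, 200L, 120L))
  f <- select_representatives(g)
  expect_setequal(f$members$protein_id, c("p1", "p2"))
  expect_match(attr(f, "audit")$reason, "coverage")

  # worked example: mean domain 200, a 150-residue span is 75% -> dropped
  g75 <- mk_group(c(260, 260, 260),
                  dom_end = c(250L, 200L, 150L))
  expect_false("p3" %in%
                 select_representatives(g75)$members$protein_id)

  # exactly 80% is retained: domains 240 and 160, mean 200
  g80 <- mk_group(c(250, 250), dom_end = c(240L, 160L))
  expect_equal(nrow(select_representatives(g80)$members), 2L)
})

test_that("the representative filter is a pure, idempotent subset", {
  set.seed(79)
  g <- mk_group(pmax(50, round(rnorm(40, 300, 60))))
  frozen <- g[c("length_mean", "length_sd", "domain_length_mean")]
  f1 <- select_representatives(g, stats = frozen)
  expect_true(all(f1$members$protein_id %in% g$members$protein_id))
  f2 <- select_representatives(f1, stats = frozen)
  expect_identical(f1$members, f2$members)
  expect_error(select_representatives(mk_group(100)), "singleton")
})

test_that("cog_gc_table pairs member gene GC with composition", {
  g <- cog_group("COGY", data.frame(
    protein_id = "p1", length = 10L, ss = "HHHHCCCCCC",
    gene_gc = 0.6, domain_start = 1L, domain_end = 10L,
    stringsAsFactors = FALSE))
  tab <- cog_gc_table(g)
  expect_equal(tab$gene_gc, 0.6)
  expect_equal(as.numeric(tab[1, c("helix", "sheet", "coil")]),
               c(0.4, 0, 0.6))
  expect_error(cog_gc_table(mk_group(c(100, 100))), "annotation")
})

test_that("synthetic COG bookkeeping matches recomputation from the strings", {
  cogs <- generate_cog_set(n_cogs = 3, members = 15, seed = 5)
  for (g in cogs) {
    tab <- cog_gc_table(g)
    redo <- ss_composition(setNames(g$members$ss, g$members$protein_id),
                           scope = "protein")
    expect_equal(tab$helix, redo$helix, tolerance = 1e-12)
    expect_equal(tab$sheet, redo$sheet, tolerance = 1e-12)
    expect_equal(tab$coil, redo$coil, tolerance = 1e-12)
  }
})

test_that("GC-coupled synthetic COGs are called biased; null COGs are not", {
  biased <- generate_cog_set(n_cogs = 2, members = 100, coil_slope = 0.2,
                             noise = 0.01, seed = 7)
  for (g in biased) {
    call <- call_cog_bias(g)
    expect_true(call$biased)
    expect_gt(call$slopes[["coil"]], 0)
  }
})

test_that("pairwise SS alignment matches fixed worked cases", {
  r <- align_pair_ss("HHEC", "HHEC")
  expect_equal(r$score, 8)
  expect_equal(r$alignment, c("HHEC", "HHEC"))
  expect_equal(align_pair_ss("HHH", "HH")$score, 0)  # 2 matches - 1 gap open
})

test_that("pairwise scores equal the exhaustive-search oracle", {
  set.seed(83)
  for (i in 1:12) {
    a <- random_ss_string(sample(2:5, 1))
    b <- random_ss_string(sample(2:5, 1))
    expect_equal(align_pair_ss(a, b)$score,
                 exhaustive_align_score(a, b),
                 info = paste(a, b))
  }
  # a couple of longer cases
  expect_equal(align_pair_ss("HHEECCH", "HECCH")$score,
               exhaustive_align_score("HHEECCH", "HECCH"))
  expect_equal(align_pair_ss("CCHHEE", "HHEECC")$score,
               exhaustive_align_score("CCHHEE", "HHEECC"))
})

test_that("progressive alignment joins the closest pair first and round-trips", {
  # two identical strings merge first under average linkage
  aln <- align_ss(c(a = "HHEECC", b = "CCCHHH", c = "HHEECC"))
  expect_identical(aln$rows[["a"]], aln$rows[["c"]])
  expect_false(grepl("-", aln$rows[["a"]]))

  set.seed(89)
  for (i in 1:30) {
    n <- sample(3:5, 1)
    strs <- setNames(vapply(seq_len(n), function(k) {
      random_ss_string(sample(10:25, 1))
    }, ""), paste0("m", seq_len(n)))
    aln <- align_ss(strs)
    expect_equal(length(unique(nchar(aln$rows))), 1L)
    expect_equal(gsub("-", "", aln$rows)[names(strs)], strs)
    expect_true(all(aln$consensus >= 0 & aln$consensus <= 1, na.rm = TRUE))
  }
  expect_error(align_ss(c(a = "HEC")), "at least 2")
})

test_that("aligned FASTA import/export round-trips", {
  aln <- align_ss(c(x = "HHEEECC", y = "HHECC", z = "HEEECC"))
  f <- tempfile(fileext = ".afa")
  write_ss_alignment(aln, f)
  back <- read_ss_alignment(f)
  expect_equal(back$rows, aln$rows)
  expect_equal(back$width, aln$width)
  expect_equal(back$consensus, aln$consensus, tolerance = 1e-12)
})
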