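# Sense and stop codons of the standard code (identical codon->aa mapping
# is shared by bacterial translation table 11).
codon_sets <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  list(sense = names(sense), sense_aa = unname(sense),
       stops = names(gc)[gc == "*"],
       gc_count = vapply(names(gc), function(cd) {
         sum(count_chars(cd, c("G", "C")))
       }, 0))
}

#' Default helix/sheet/coil propensity matrix
#'
#' A 20 x 3 matrix of `P(state | amino acid)` used by [generate_genome()].
#' Rows sum to 1. The values follow the classical Chou-Fasman tendencies:
#' helix formers (Ala, Glu, Leu, Met) get elevated helix probability,
#' sheet formers (Val, Ile, Tyr, Phe, Trp) elevated sheet probability, and
#' Gly/Pro strong coil preference, around a 0.35/0.25/0.40 baseline.
#'
#' @return Numeric matrix, rows `AA20`, columns `H`, `E`, `C`.
#' @export
default_propensity <- function() {
  # Chou-Fasman-style helix (P_alpha) and sheet (P_beta) tendencies
  p_alpha <- c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57,
               H = 1.00, I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67,
               P = 0.57, Q = 1.11, R = 0.98, S = 0.77, T = 0.83, V = 1.06,
               W = 1.08, Y = 0.69)
  p_beta  <- c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75,
               H = 0.87, I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89,
               P = 0.55, Q = 1.10, R = 0.93, S = 0.75, T = 1.19, V = 1.70,
               W = 1.37, Y = 1.47)
  w <- cbind(H = 0.35 * p_alpha[AA20], E = 0.25 * p_beta[AA20], C = 0.40)
  rownames(w) <- AA20
  w / rowSums(w)
}

#' GC-coupled propensity matrix
#'
#' Tilts the coil column of a base propensity matrix by the genome's GC
#' value: the coil odds are multiplied by `exp(coupling * (gc - centre))`
#' and rows renormalised. With positive `coupling`, genomes generated at
#' higher GC have proteomes richer in coil and poorer in helix and sheet -
#' the qualitative pattern this package's regression stage is designed to
#' detect.
#'
#' @param gc GC fraction of the genome being generated.
#' @param coupling Log-odds change in coil per unit GC (default 2).
#' @param base Base propensity matrix (default [default_propensity()]).
#' @param centre GC value at which the base matrix is returned unchanged.
#' @return A 20 x 3 propensity matrix with rows summing to 1.
#' @export
gc_coupled_propensity <- function(gc, coupling = 2, base = default_propensity(),
                                  centre = 0.475) {
  w <- base
  w[, "C"] <- w[, "C"] * exp(coupling * (gc - centre))
  w / rowSums(w)
}

#' Specify a synthetic coding genome
#'
#' Bundles and validates the parameters of [generate_genome()]: the target
#' coding GC, the number of genes, the gene-length distribution
#' (negative binomial in codons, floored at 50), the per-amino-acid
#' secondary-structure propensities, the state persistence, and the seed.
#'
#' @param target_gc Target coding GC fraction, in `[0.15, 0.80]`.
#' @param n_genes Number of genes (>= 1).
#' @param mean_length Mean gene length in codons (including the initial
#'   Met, excluding the stop codon); minimum 50.
#' @param dispersion Negative-binomial size parameter of the length
#'   distribution (larger = less dispersed).
#' @param propensity 20 x 3 matrix of `P(state | aa)`; rows must sum to 1.
#' @param persistence Probability in `[0, 1)` that a residue copies the
#'   previous residue's state instead of drawing from `propensity`,
#'   creating realistic helix/sheet runs.
#' @param seed Integer seed; identical specs generate identical genomes.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(target_gc = 0.5, n_genes = 200L,
                           mean_length = 300, dispersion = 10,
                           propensity = default_propensity(),
                           persistence = 0, seed = 1L) {
  if (!is.numeric(target_gc) || target_gc < 0.15 || target_gc > 0.80) {
    stop("target_gc must lie in [0.15, 0.80]")
  }
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (mean_length < 50) stop("mean_length must be >= 50 codons")
  if (!is.matrix(propensity) || !identical(dim(propensity), c(20L, 3L)) ||
      !setequal(rownames(propensity), AA20) ||
      !identical(colnames(propensity), SS3)) {
    stop("propensity must be a 20 x 3 matrix with rows AA20, columns H,E,C")
  }
  propensity <- propensity[AA20, ]
  if (any(abs(rowSums(propensity) - 1) > 1e-8) || any(propensity < 0)) {
    stop("propensity rows must be non-negative and sum to 1")
  }
  if (persistence < 0 || persistence >= 1) {
    stop("persistence must lie in [0, 1)")
  }
  structure(list(target_gc = target_gc, n_genes = as.integer(n_genes),
                 mean_length = mean_length, dispersion = dispersion,
                 propensity = propensity, persistence = persistence,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic genome spec: %d genes, target GC %.3f, mean length %g codons,\n  persistence %.2f, seed %d\n",
    x$n_genes, x$target_gc, x$mean_length, x$persistence, x$seed))
  invisible(x)
}

# Solve the exponential codon tilt so that the expected GC of a whole gene
# (fixed ATG start + tilted body codons + tilted stop) matches the target.
# w(c) is proportional to exp(lambda * gc(c)) over the 61 sense codons.
solve_codon_tilt <- function(target_gc, mean_length, tol = 1e-4,
                             max_iter = 200L) {
  cs <- codon_sets()
  gcb <- cs$gc_count[cs$sense]
  gcs <- cs$gc_count[cs$stops]
  expected_gc <- function(lambda) {
    wb <- exp(lambda * gcb); wb <- wb / sum(wb)
    ws <- exp(lambda * gcs); ws <- ws / sum(ws)
    (1 + (mean_length - 1) * sum(wb * gcb) + sum(ws * gcs)) /
      (3 * (mean_length + 1))
  }
  lo <- -60; hi <- 60
  if (target_gc < expected_gc(lo) || target_gc > expected_gc(hi)) {
    stop("target_gc ", target_gc, " outside the achievable coding range")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- expected_gc(mid)
    if (abs(val - target_gc) <= tol) {
      return(list(lambda = mid,
                  body_w = {w <- exp(mid * gcb); w / sum(w)},
                  stop_w = {w <- exp(mid * gcs); w / sum(w)}))
    }
    if (val < target_gc) lo <- mid else hi <- mid
  }
  stop("codon-tilt bisection did not converge in ", max_iter, " iterations")
}

# Run code with a private, restorable RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic coding genome with known structure propensities
#'
#' Draws gene lengths from a negative-binomial count distribution (floored
#' at 50 codons), assembles each gene as a fixed `ATG` start plus body
#' codons sampled from the 61 sense codons with weight proportional to
#' `exp(lambda * gc(codon))` plus a tilted stop codon, where `lambda` is
#' found by bisection so that the expected gene GC equals `target_gc`.
#' Proteins are the translations; per-residue H/E/C states are drawn from
#' `P(state | aa)` (the spec's propensity matrix), with probability
#' `persistence` of copying the previous residue's state instead.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements:
#'   * `record` - a [genome_record()] with genes, proteins and annotations;
#'   * `truth` - class `"synthetic_truth"`: `realized_gc`, `aa_freq`
#'     (realised [aa_frequencies()] table), `expected_cp` (closed-form CP
#'     matrix via [expected_cp()], only when `persistence = 0`), and
#'     `per_protein` (the generator's own per-protein composition
#'     bookkeeping).
#' @examples
#' g <- generate_genome(synthetic_spec(target_gc = 0.5, n_genes = 20,
#'                                     mean_length = 60, seed = 7))
#' g$truth$realized_gc
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cs <- codon_sets()
  tilt <- solve_codon_tilt(spec$target_gc, spec$mean_length)
  with_seed(spec$seed, {
    n <- spec$n_genes
    lens <- pmax(50L, stats::rnbinom(n, mu = spec$mean_length,
                                     size = spec$dispersion))
    gene_of <- rep.int(seq_len(n), lens - 1L)
    body <- sample(cs$sense, sum(lens - 1L), replace = TRUE,
                   prob = tilt$body_w)
    stops <- sample(cs$stops, n, replace = TRUE, prob = tilt$stop_w)

    body_by_gene <- split(body, gene_of)
    genes <- vapply(seq_len(n), function(i) {
      paste0("ATG", paste(body_by_gene[[i]], collapse = ""), stops[i])
    }, "")

    aa_body <- stats::setNames(cs$sense_aa, cs$sense)[body]
    proteins <- vapply(seq_len(n), function(i) {
      paste0("M", paste(aa_body[gene_of == i], collapse = ""))
    }, "")

    # per-residue states, vectorised: fresh draws everywhere, then each
    # residue keeps the most recent non-copied draw in its gene
    aa_all <- unlist(strsplit(proteins, "", fixed = TRUE), use.names = FALSE)
    n_res <- length(aa_all)
    row <- match(aa_all, AA20)
    cum <- t(apply(spec$propensity, 1L, cumsum))
    u <- stats::runif(n_res)
    fresh <- 1L + (u > cum[row, 1L]) + (u > cum[row, 2L])
    first_of_gene <- c(TRUE, diff(rep.int(seq_len(n), lens)) != 0L)
    copy <- stats::runif(n_res) < spec$persistence & !first_of_gene
    src <- which(!copy)[cumsum(!copy)]
    states <- SS3[fresh[src]]

    res_gene <- rep.int(seq_len(n), lens)
    ss <- vapply(split(states, res_gene), paste, "", collapse = "")

    ids <- sprintf("g%05d", seq_len(n))
    names(genes) <- names(proteins) <- names(ss) <- ids

    rec <- genome_record(
      organism_id = sprintf("synth_gc%02d_s%d",
                            round(100 * spec$target_gc), spec$seed),
      genes = genes, proteins = proteins, ss = ss)

    st_counts <- table(factor(res_gene, levels = seq_len(n)),
                       factor(states, levels = SS3))
    per_protein <- data.frame(
      protein_id = ids,
      helix = as.integer(st_counts[, "H"]) / lens,
      sheet = as.integer(st_counts[, "E"]) / lens,
      coil = as.integer(st_counts[, "C"]) / lens,
      length = lens, row.names = NULL, stringsAsFactors = FALSE)

    freq <- aa_frequencies(proteins)
    truth <- structure(list(
      realized_gc = compute_coding_gc(genes),
      aa_freq = freq,
      expected_cp = if (spec$persistence == 0) expected_cp(spec, freq),
      per_protein = per_protein), class = "synthetic_truth")

    list(record = rec, truth = truth)
  })
}

#' Closed-form conformational parameters implied by a propensity matrix
#'
#' Under the independent-residue model (`persistence = 0`), the expected
#' conformational parameter is
#' `CP(aa, ss) = P(ss | aa) / sum_aa' f(aa') P(ss | aa')`,
#' where `f` is the amino-acid frequency vector. Serves as the exact oracle
#' for parameter-recovery checks against [conformational_params()].
#'
#' @param spec A [synthetic_spec()] with `persistence = 0`.
#' @param aa_freq An `aa_freq_table` (e.g. from the generated proteome) or
#'   named frequency vector over the 20 amino acids.
#' @return 20 x 3 matrix of expected CP values.
#' @export
expected_cp <- function(spec, aa_freq) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$persistence != 0) {
    stop("closed-form CP requires persistence = 0")
  }
  f <- aa_freq_vector(aa_freq)
  p_ss <- colSums(spec$propensity * f)   # P(ss) = sum_aa f(aa) P(ss|aa)
  sweep(spec$propensity, 2L, p_ss, "/")
}
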