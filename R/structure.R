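# Pool residues of the annotated subset of a proteome into parallel
# amino-acid and state vectors. X residues (and their structure positions)
# are dropped so that helix + sheet + coil fractions stay exact.
pooled_states <- function(x) {
  x <- as_annotated(x)
  ids <- names(x$ss)
  if (length(ids) == 0L) stop("no proteins carry an H/E/C annotation")
  aa <- strsplit(paste(x$seq[ids], collapse = ""), "", fixed = TRUE)[[1]]
  ss <- strsplit(paste(x$ss[ids], collapse = ""), "", fixed = TRUE)[[1]]
  keep <- aa != "X"
  list(aa = aa[keep], ss = ss[keep])
}

#' Amino-acid frequencies within each secondary-structure state
#'
#' For each state (helix, sheet, coil), the pooled count of an amino acid
#' at residues annotated with that state divided by the total number of
#' residues in that state.
#'
#' @param x An `annotated_proteome` (see [attach_ss()]), `genome_record`,
#'   or list with `seq` and `ss`.
#' @return Named list (`helix`, `sheet`, `coil`) of `aa_freq_table` data
#'   frames. A state with zero residues yields a table with zero counts,
#'   `NA` frequencies and attribute `empty = TRUE`.
#' @export
aa_frequencies_by_ss <- function(x) {
  p <- pooled_states(x)
  out <- lapply(SS3, function(st) {
    in_st <- p$aa[p$ss == st]
    ctx <- unname(SS_LONG[st])
    if (length(in_st) == 0L) {
      tab <- data.frame(aa = AA20, count = 0L, frequency = NA_real_,
                        context = ctx, stringsAsFactors = FALSE)
      class(tab) <- c("aa_freq_table", "data.frame")
      attr(tab, "empty") <- TRUE
      return(tab)
    }
    counts <- tabulate(factor(in_st, levels = AA20), nbins = 20L)
    tab <- data.frame(aa = AA20, count = counts,
                      frequency = counts / sum(counts),
                      context = ctx, stringsAsFactors = FALSE)
    class(tab) <- c("aa_freq_table", "data.frame")
    tab
  })
  names(out) <- unname(SS_LONG)
  out
}

#' Chou-Fasman conformational parameters of an annotated proteome
#'
#' Computes, for every amino acid `aa` and structure state `ss` in
#' \{helix, sheet, coil\}:
#' * `f_ss_aa` - the share of that amino acid's residues lying in `ss`;
#' * `f_ss` - the share of all residues lying in `ss`;
#' * `cp = f_ss_aa / f_ss` - the conformational parameter. `cp > 1` marks a
#'   former of the state, `cp < 1` a breaker.
#'
#' Amino acids absent from the proteome get `NA` rows (with zero counts)
#' and are listed in `missing_aa`; they are never propagated as zeros.
#'
#' @param x An `annotated_proteome`, `genome_record`, or list with
#'   `seq`/`ss`.
#' @return Object of class `"conformational_params"`: list with `counts`
#'   (20 x 3 matrix), `f_ss_aa` (20 x 3), `f_ss` (length 3), `cp` (20 x 3),
#'   `n_residues`, `missing_aa`.
#' @examples
#' ap <- attach_ss(c(p = "AAGG"), c(p = "HHCC"))
#' cpars <- conformational_params(ap)
#' cpars$cp["A", "H"]  # 2: Ala found only in helix, helix holds half of all
#' @export
conformational_params <- function(x) {
  p <- pooled_states(x)
  if (length(p$aa) == 0L) stop("empty proteome")
  counts <- table(factor(p$aa, levels = AA20),
                  factor(p$ss, levels = SS3))
  counts <- matrix(as.integer(counts), nrow = 20L,
                   dimnames = list(AA20, SS3))
  n_aa <- rowSums(counts)
  n_ss <- colSums(counts)
  n <- sum(counts)
  f_ss_aa <- counts / n_aa
  f_ss_aa[n_aa == 0L, ] <- NA_real_   # absent, not zero
  f_ss <- n_ss / n
  cp <- sweep(f_ss_aa, 2L, f_ss, "/")
  cp[, f_ss == 0] <- NA_real_
  structure(list(counts = counts, f_ss_aa = f_ss_aa, f_ss = f_ss, cp = cp,
                 n_residues = n, missing_aa = AA20[n_aa == 0L]),
            class = "conformational_params")
}

#' @export
print.conformational_params <- function(x, digits = 3L, ...) {
  cat("Conformational parameters over", x$n_residues, "annotated residues\n")
  cat("State shares (f_ss): ",
      paste(sprintf("%s=%.*f", names(x$f_ss), digits, x$f_ss),
            collapse = ", "), "\n")
  print(round(x$cp, digits))
  if (length(x$missing_aa)) {
    cat("Absent amino acids (CP undefined):",
        paste(x$missing_aa, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Secondary-structure composition
#'
#' Fractions of residues lying in helix, sheet and coil, either pooled over
#' a whole proteome or per protein.
#'
#' @param x An `annotated_proteome`, `genome_record`, list with `seq`/`ss`,
#'   or a named character vector of bare H/E/C strings.
#' @param scope `"proteome"` (pool residues across proteins) or
#'   `"protein"` (one row per protein).
#' @return For `"proteome"`, a one-row data frame of class
#'   `"ss_composition"` with `helix`, `sheet`, `coil`, `n_residues`; for
#'   `"protein"`, a data frame with one row per protein (`protein_id`,
#'   `helix`, `sheet`, `coil`, `length`).
#' @export
ss_composition <- function(x, scope = c("proteome", "protein")) {
  scope <- match.arg(scope)
  if (is.character(x)) {
    if (length(x) == 0L) stop("empty input")
    if (any(grepl("[^HEC]", x))) {
      stop("bare input must be H/E/C strings; see read_fasta(alphabet='ss')")
    }
    ids <- if (is.null(names(x))) paste0("p", seq_along(x)) else names(x)
    ssv <- stats::setNames(as.character(x), ids)
    per <- t(vapply(ssv, function(s) {
      count_chars(s, SS3) / nchar(s)
    }, numeric(3L)))
    lens <- nchar(ssv)
  } else {
    ap <- as_annotated(x)
    ids <- names(ap$ss)
    if (length(ids) == 0L) stop("no annotated proteins")
    # drop X positions per protein
    comp_one <- function(id) {
      aa <- strsplit(ap$seq[[id]], "", fixed = TRUE)[[1]]
      st <- strsplit(ap$ss[[id]], "", fixed = TRUE)[[1]][aa != "X"]
      if (length(st) == 0L) return(c(NA_real_, NA_real_, NA_real_, 0))
      c(count_chars(paste(st, collapse = ""), SS3) / length(st), length(st))
    }
    m <- t(vapply(ids, comp_one, numeric(4L)))
    per <- m[, 1:3, drop = FALSE]
    lens <- m[, 4L]
  }
  colnames(per) <- unname(SS_LONG)
  if (scope == "protein") {
    out <- data.frame(protein_id = ids, per, length = as.integer(lens),
                      row.names = NULL, stringsAsFactors = FALSE)
    return(out)
  }
  total <- sum(lens)
  if (total == 0L) stop("no residues to pool")
  pooled <- colSums(per * lens, na.rm = TRUE) / total
  out <- data.frame(helix = pooled[["helix"]], sheet = pooled[["sheet"]],
                    coil = pooled[["coil"]], n_residues = as.integer(total))
  class(out) <- c("ss_composition", "data.frame")
  out
}

#' Categorise conformational parameters into former/breaker classes
#'
#' Maps each CP value to one of five classical labels by a monotone vector
#' of four cut points: below the first cut `strong breaker`, then
#' `breaker`, `indifferent`, `former`, and `strong former` at or above the
#' last cut. Bins are closed on the left. The default cut points are this
#' package's convention and are fully configurable.
#'
#' @param params A `"conformational_params"` object.
#' @param thresholds Strictly increasing numeric vector of length 4.
#' @return Data frame of class `"cp_categories"`: `aa`, `ss`, `cp`,
#'   `category`; the thresholds used are stored as an attribute.
#' @export
categorize_cp <- function(params, thresholds = c(0.6, 0.9, 1.1, 1.4)) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 4 strictly increasing cut points")
  }
  labs <- c("strong breaker", "breaker", "indifferent", "former",
            "strong former")
  cp <- params$cp
  out <- data.frame(
    aa = rep(rownames(cp), times = ncol(cp)),
    ss = rep(colnames(cp), each = nrow(cp)),
    cp = as.vector(cp),
    category = as.character(cut(as.vector(cp),
                                breaks = c(-Inf, thresholds, Inf),
                                labels = labs, right = FALSE)),
    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("cp_categories", "data.frame")
  out
}
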