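#' Significance codes for p-values
#'
#' Maps p-values to the conventional star codes used in regression
#' reports: `p <= 0.001` gives `'***'`, `(0.001, 0.01]` gives `'**'`,
#' `(0.01, 0.05]` gives `'*'`, `(0.05, 0.1]` gives `'.'` and anything
#' larger a blank. Intervals are right-closed, matching the legend printed
#' by R's own coefficient tables.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of codes.
#' @examples
#' signif_code(c(5e-4, 0.03, 0.5))
#' @export
signif_code <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
                   labels = c("***", "**", "*", ".", " "), right = TRUE))
}

#' Fit a GC trend to a per-organism or per-protein quantity
#'
#' Ordinary least-squares regression of a response (an amino-acid
#' frequency, a conformational parameter, a structure fraction, ...) on GC
#' content, of degree 1 or 2. The reported p-value is the two-sided t-test
#' on the slope (degree 1) or on the quadratic coefficient (degree 2).
#' With `degree = "auto"` the quadratic model is kept only when it beats
#' the linear one in an F-test at 0.05.
#'
#' A response with zero variance is flagged (`constant_response = TRUE`)
#' and reported as slope 0 with p-value 1 rather than as a failed fit.
#'
#' @param gc Numeric vector of GC fractions (0-1).
#' @param y Numeric response, same length as `gc`.
#' @param degree 1, 2 or `"auto"`.
#' @return Object of class `"gc_trend"` with fields `slope` (highest-order
#'   coefficient), `intercept`, `p_value`, `r_squared`, `n`, `signif_code`,
#'   `degree`, `constant_response` and the underlying `lm` fit. Standard
#'   methods (`print`, `summary`, `coef`, `predict`, `residuals`, `plot`)
#'   apply.
#' @examples
#' fit_gc_trend(c(0.2, 0.4, 0.6), c(1.4, 1.8, 2.2))
#' @export
fit_gc_trend <- function(gc, y, degree = 1) {
  if (length(gc) != length(y)) stop("gc and y must have equal length")
  keep <- !is.na(gc) & !is.na(y)
  gc <- gc[keep]; y <- y[keep]
  auto <- identical(degree, "auto")
  deg <- if (auto) 1L else as.integer(degree)
  if (!auto && !deg %in% 1:2) stop("degree must be 1, 2 or 'auto'")
  n <- length(gc)
  if (n < deg + 2L) stop("need at least degree + 2 points, got ", n)
  if (stats::sd(gc) == 0) stop("GC values are all identical")

  dat <- data.frame(gc = gc, y = y)
  fit1 <- stats::lm(y ~ gc, data = dat)
  fit <- fit1
  if ((auto && n >= 4L) || (!auto && deg == 2L)) {
    fit2 <- stats::lm(y ~ gc + I(gc^2), data = dat)
    if (!auto) {
      fit <- fit2; deg <- 2L
    } else if (stats::sd(y) > 0 && n >= 5L) {
      ftest <- stats::anova(fit1, fit2)
      pq <- ftest[["Pr(>F)"]][2L]
      if (!is.na(pq) && pq < 0.05) {
        fit <- fit2; deg <- 2L
      }
    }
  }

  cf <- stats::coef(fit)
  constant <- stats::sd(y) == 0
  if (constant) {
    slope <- 0; p <- 1; r2 <- 0
  } else {
    sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
    slope <- unname(cf[length(cf)])
    p <- sm$coefficients[nrow(sm$coefficients), 4L]
    # a perfect fit has zero residual variance and an undefined t statistic;
    # report it as p = 0 rather than NaN
    if (is.nan(p)) p <- 0
    r2 <- sm$r.squared
  }
  structure(list(fit = fit, degree = deg, n = n,
                 slope = slope, intercept = unname(cf[1L]),
                 p_value = unname(p), r_squared = r2,
                 signif_code = signif_code(p),
                 constant_response = constant),
            class = "gc_trend")
}

#' @export
print.gc_trend <- function(x, digits = 4L, ...) {
  cat(sprintf("GC trend (degree %d, n = %d)\n", x$degree, x$n))
  cat(sprintf("  slope%s = %.*g, intercept = %.*g\n",
              if (x$degree == 2L) " (quadratic term)" else "",
              digits, x$slope, digits, x$intercept))
  cat(sprintf("  p = %.*g %s  R^2 = %.*g\n", digits, x$p_value,
              sQuote(x$signif_code), digits, x$r_squared))
  if (x$constant_response) cat("  (constant response; no trend fitted)\n")
  invisible(x)
}

#' @export
summary.gc_trend <- function(object, ...) summary(object$fit, ...)

#' @export
coef.gc_trend <- function(object, ...) stats::coef(object$fit)

#' @export
predict.gc_trend <- function(object, newdata = NULL, ...) {
  if (is.numeric(newdata)) newdata <- data.frame(gc = newdata)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.gc_trend <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
plot.gc_trend <- function(x, xlab = "GC fraction", ylab = "response", ...) {
  d <- x$fit$model
  plot(d$gc, d$y, xlab = xlab, ylab = ylab, ...)
  o <- order(d$gc)
  graphics::lines(d$gc[o], stats::fitted(x$fit)[o], col = 2L)
  invisible(x)
}

#' Call GC bias for one COG from member compositions
#'
#' Fits three degree-1 GC trends - helix, sheet and coil fraction against
#' the member's gene GC - and calls the COG biased when at least two of
#' the three slope p-values fall below `p_threshold`.
#'
#' @param x A data frame with columns `gene_gc` (or `gc`), `helix`,
#'   `sheet`, `coil` (one row per member protein), or a `cog_group` whose
#'   members carry annotations and gene GC (converted via
#'   [cog_gc_table()]).
#' @param cog_id Optional identifier (taken from a `cog_group` input).
#' @param p_threshold Slope p-value threshold (default 0.001).
#' @param min_members Minimum member count (default 10).
#' @return Object of class `"cog_bias_call"`: `cog_id`, `n`, per-state
#'   `slopes`, `p_values`, `signif_codes`, `fits`, and logical `biased`.
#' @export
call_cog_bias <- function(x, cog_id = NULL, p_threshold = 0.001,
                          min_members = 10L) {
  if (inherits(x, "cog_group")) {
    if (is.null(cog_id)) cog_id <- x$cog_id
    x <- cog_gc_table(x)
  }
  gc_col <- intersect(c("gene_gc", "gc"), names(x))[1L]
  if (is.na(gc_col) || !all(c("helix", "sheet", "coil") %in% names(x))) {
    stop("need columns gene_gc (or gc), helix, sheet, coil")
  }
  if (nrow(x) < min_members) {
    stop("COG has ", nrow(x), " members; floor is ", min_members)
  }
  fits <- lapply(c("helix", "sheet", "coil"), function(st) {
    fit_gc_trend(x[[gc_col]], x[[st]], degree = 1)
  })
  names(fits) <- c("helix", "sheet", "coil")
  p <- vapply(fits, function(f) f$p_value, 0)
  structure(list(cog_id = cog_id, n = nrow(x),
                 slopes = vapply(fits, function(f) f$slope, 0),
                 p_values = p,
                 signif_codes = vapply(fits, function(f) f$signif_code, ""),
                 fits = fits,
                 biased = sum(p < p_threshold) >= 2L),
            class = "cog_bias_call")
}

#' @export
print.cog_bias_call <- function(x, ...) {
  cat("COG", if (!is.null(x$cog_id)) sQuote(x$cog_id) else "",
      "-", x$n, "members -", if (x$biased) "BIASED" else "unbiased", "\n")
  tab <- data.frame(slope = x$slopes, p_value = x$p_values,
                    code = x$signif_codes)
  print(tab, ...)
  invisible(x)
}
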