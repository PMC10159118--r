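# -- Secondary-structure string alignment over {H, E, C} -------------------
#
# Global (Needleman-Wunsch) alignment with affine gaps (Gotoh), generalised
# to profiles so the same dynamic programme drives both the pairwise and
# the progressive (profile-to-profile) stages. A gap run of length k costs
# gap_open + (k - 1) * gap_extend.

#' Substitution scores for the three-state alphabet
#'
#' @param match Score for identical states (default +2).
#' @param mismatch_he Score for an H/E confusion - the severe error
#'   (default -2).
#' @param mismatch_c Score for any mismatch involving C (default -1).
#' @return Symmetric 3 x 3 matrix over H, E, C.
#' @export
ss_score_matrix <- function(match = 2, mismatch_he = -2, mismatch_c = -1) {
  m <- matrix(mismatch_c, 3L, 3L, dimnames = list(SS3, SS3))
  m["H", "E"] <- m["E", "H"] <- mismatch_he
  diag(m) <- match
  m
}

# A profile: list(rows = named character vector of equal-length gapped
# strings, freq = 3 x L matrix of H/E/C column proportions over all rows).
profile_from_string <- function(s, id) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  freq <- vapply(ch, function(c0) as.numeric(SS3 == c0), numeric(3L))
  rownames(freq) <- SS3
  list(rows = stats::setNames(s, id), freq = freq)
}

profile_freq <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  freq <- apply(mat, 2L, function(col) {
    as.numeric(vapply(SS3, function(s) sum(col == s), 0L)) / length(col)
  })
  rownames(freq) <- SS3
  freq
}

# Gotoh DP over two profiles. Column-pair score is the expected
# substitution score over the two column state distributions (gap
# proportions contribute 0); new gaps pay the plain affine penalties.
# Traceback tie-break: match/mismatch, then gap in the second profile,
# then gap in the first.
profile_align <- function(p1, p2, smat = ss_score_matrix(),
                          gap_open = 4, gap_extend = 1,
                          score_only = FALSE) {
  L1 <- ncol(p1$freq); L2 <- ncol(p2$freq)
  S <- t(p1$freq) %*% smat %*% p2$freq      # L1 x L2 column-pair scores
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, L1 + 1L, L2 + 1L)
  M[1L, 1L] <- 0
  if (L1 > 0L) X[2:(L1 + 1L), 1L] <- -gap_open - (0:(L1 - 1L)) * gap_extend
  if (L2 > 0L) Y[1L, 2:(L2 + 1L)] <- -gap_open - (0:(L2 - 1L)) * gap_extend
  for (i in seq_len(L1)) {
    ii <- i + 1L
    for (j in seq_len(L2)) {
      jj <- j + 1L
      M[ii, jj] <- max(M[i, j], X[i, j], Y[i, j]) + S[i, j]
      X[ii, jj] <- max(M[i, jj] - gap_open, X[i, jj] - gap_extend,
                       Y[i, jj] - gap_open)
      Y[ii, jj] <- max(M[ii, j] - gap_open, Y[ii, j] - gap_extend,
                       X[ii, j] - gap_open)
    }
  }
  end <- c(M[L1 + 1L, L2 + 1L], X[L1 + 1L, L2 + 1L], Y[L1 + 1L, L2 + 1L])
  best <- which.max(end)
  score <- end[best]
  if (score_only) return(list(score = score))

  # traceback: ops is a vector over merged columns, one of "B" (both),
  # "1" (consume profile 1 only), "2" (consume profile 2 only)
  ops <- character(0L)
  i <- L1; j <- L2
  state <- c("M", "X", "Y")[best]
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == "M") {
      ops <- c("B", ops)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      target <- M[i + 1L, j + 1L] - S[i, j]
      state <- c("M", "X", "Y")[which(abs(prev - target) < eps)[1L]]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      ops <- c("1", ops)
      cur <- X[i + 1L, j + 1L]
      state <- if (i == 1L && j == 0L) {
        "M"
      } else if (abs(M[i, j + 1L] - gap_open - cur) < eps) {
        "M"
      } else if (abs(X[i, j + 1L] - gap_extend - cur) < eps) {
        "X"
      } else {
        "Y"
      }
      i <- i - 1L
    } else {
      ops <- c("2", ops)
      cur <- Y[i + 1L, j + 1L]
      state <- if (j == 1L && i == 0L) {
        "M"
      } else if (abs(M[i + 1L, j] - gap_open - cur) < eps) {
        "M"
      } else if (abs(Y[i + 1L, j] - gap_extend - cur) < eps) {
        "Y"
      } else {
        "X"
      }
      j <- j - 1L
    }
  }

  K <- length(ops)
  pos1 <- which(ops != "2")
  pos2 <- which(ops != "1")
  expand <- function(rows, pos) {
    vapply(rows, function(r) {
      out <- rep("-", K)
      out[pos] <- strsplit(r, "", fixed = TRUE)[[1]]
      paste(out, collapse = "")
    }, "", USE.NAMES = TRUE)
  }
  rows <- c(expand(p1$rows, pos1), expand(p2$rows, pos2))
  list(score = score, rows = rows,
       profile = list(rows = rows, freq = profile_freq(rows)))
}

#' Align two H/E/C strings
#'
#' Global alignment with affine gap penalties over the three-state
#' secondary-structure alphabet.
#'
#' @param a,b H/E/C strings.
#' @param smat Substitution matrix (see [ss_score_matrix()]).
#' @param gap_open Cost of the first position of a gap run (default 4).
#' @param gap_extend Cost of each further gap position (default 1).
#' @return List with `score` and `alignment` (two gapped strings).
#' @examples
#' align_pair_ss("HHH", "HH")$score  # 2 matches - one 1-column gap = 0
#' @export
align_pair_ss <- function(a, b, smat = ss_score_matrix(),
                          gap_open = 4, gap_extend = 1) {
  res <- profile_align(profile_from_string(a, "a"),
                       profile_from_string(b, "b"),
                       smat, gap_open, gap_extend)
  list(score = res$score, alignment = unname(res$rows))
}

#' Progressive multiple alignment of secondary-structure strings
#'
#' Aligns the H/E/C annotation strings of a COG's members: all pairwise
#' global alignment scores are turned into distances
#' `d = (self_a + self_b) / 2 - score`, an average-linkage guide tree is
#' built on them, and profiles are merged bottom-up with the same affine
#' dynamic programme. Deterministic given the input order; equal-distance
#' joins follow the lowest row index first.
#'
#' @param x A filtered `cog_group` whose members carry `ss`, or a named
#'   character vector of at least 2 H/E/C strings.
#' @param smat,gap_open,gap_extend Scoring scheme (see
#'   [ss_score_matrix()]).
#' @return Object of class `"ss_alignment"`: `cog_id`, `rows` (gapped
#'   strings in input order), `width`, and `consensus` (per-column modal
#'   state fraction over non-gap rows). Removing gaps from any row
#'   reproduces the corresponding input exactly.
#' @export
align_ss <- function(x, smat = ss_score_matrix(), gap_open = 4,
                     gap_extend = 1) {
  cog_id <- NULL
  if (inherits(x, "cog_group")) {
    cog_id <- x$cog_id
    if (!"ss" %in% names(x$members)) stop("members carry no ss annotation")
    x <- stats::setNames(x$members$ss, x$members$protein_id)
  }
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 annotated members to align")
  if (any(grepl("[^HEC]", x))) stop("inputs must be H/E/C strings")
  ids <- if (is.null(names(x))) paste0("s", seq_along(x)) else names(x)
  n <- length(x)
  profs <- lapply(seq_len(n), function(i) profile_from_string(x[[i]], ids[i]))

  if (n == 2L) {
    merged <- profile_align(profs[[1L]], profs[[2L]], smat, gap_open,
                            gap_extend)$profile
  } else {
    selfsc <- vapply(seq_len(n), function(i) {
      sum(diag(smat)[match(strsplit(x[[i]], "", fixed = TRUE)[[1]], SS3)])
    }, 0)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sc <- profile_align(profs[[i]], profs[[j]], smat, gap_open,
                            gap_extend, score_only = TRUE)$score
        D[i, j] <- D[j, i] <- max(0, (selfsc[i] + selfsc[j]) / 2 - sc)
      }
    }
    dimnames(D) <- list(ids, ids)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", n - 1L)
    node_of <- function(k) {
      if (k < 0L) profs[[-k]] else nodes[[k]]
    }
    for (m in seq_len(n - 1L)) {
      a <- node_of(hc$merge[m, 1L])
      b <- node_of(hc$merge[m, 2L])
      nodes[[m]] <- profile_align(a, b, smat, gap_open, gap_extend)$profile
    }
    merged <- nodes[[n - 1L]]
  }
  rows <- merged$rows[ids]
  cons <- apply(merged$freq[, , drop = FALSE], 2L, function(col) {
    tot <- sum(col)
    if (tot == 0) NA_real_ else max(col) / tot
  })
  structure(list(cog_id = cog_id, rows = rows,
                 width = nchar(rows[[1L]]), consensus = unname(cons)),
            class = "ss_alignment")
}

#' @export
print.ss_alignment <- function(x, n = 8L, ...) {
  cat("Secondary-structure alignment",
      if (!is.null(x$cog_id)) paste0("(", x$cog_id, ")"), "-",
      length(x$rows), "rows x", x$width, "columns\n")
  shown <- utils::head(x$rows, n)
  for (i in seq_along(shown)) {
    cat(sprintf("  %-12s %s\n", names(shown)[i],
                if (x$width > 60L) {
                  paste0(substr(shown[i], 1L, 57L), "...")
                } else {
                  shown[i]
                }))
  }
  if (length(x$rows) > n) cat("  ...", length(x$rows) - n, "more rows\n")
  cat(sprintf("  mean column consensus %.2f\n",
              mean(x$consensus, na.rm = TRUE)))
  invisible(x)
}

#' Import an externally produced secondary-structure alignment
#'
#' Reads a gapped FASTA over `{H, E, C, -}` (e.g. produced by an external
#' multiple aligner) into the same `ss_alignment` container [align_ss()]
#' returns, so downstream consumers are agnostic to the aligner used.
#'
#' @param path Path to an aligned FASTA file.
#' @param cog_id Optional identifier.
#' @return An `"ss_alignment"` object.
#' @export
read_ss_alignment <- function(path, cog_id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("alignment needs at least 2 rows")
  rows <- toupper(as.character(set))
  names(rows) <- sub("\\s.*$", "", names(set))
  if (any(grepl("[^HEC-]", rows))) {
    stop("alignment rows must be over {H, E, C, -}")
  }
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows differ in length")
  }
  freq <- profile_freq(rows)
  cons <- apply(freq, 2L, function(col) {
    tot <- sum(col)
    if (tot == 0) NA_real_ else max(col) / tot
  })
  structure(list(cog_id = cog_id, rows = rows,
                 width = nchar(rows[[1L]]), consensus = unname(cons)),
            class = "ss_alignment")
}

#' Write an `ss_alignment` as gapped FASTA
#'
#' @param x An `ss_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss_alignment <- function(x, path) {
  write_fasta(x$rows, path)
}
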