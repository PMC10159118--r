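#' Construct a COG group
#'
#' Bundles the member proteins of one cluster of orthologous genes (COG)
#' with their gene GC values and conserved-domain spans, and computes the
#' member-length statistics the representative filter relies on.
#'
#' @param cog_id COG identifier.
#' @param members Data frame with columns `protein_id`, `domain_start`,
#'   `domain_end` (1-based inclusive) and any of: `sequence` (protein),
#'   `ss` (H/E/C string), `gene_gc`, `length` (required when `sequence`
#'   is absent).
#' @return Object of class `"cog_group"`: the member table plus
#'   `length_mean`, `length_sd` (sample SD) and `domain_length_mean`.
#' @export
cog_group <- function(cog_id, members) {
  stopifnot(is.data.frame(members), nrow(members) >= 1L)
  need <- c("protein_id", "domain_start", "domain_end")
  if (!all(need %in% names(members))) {
    stop("members must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(members$protein_id)) stop("duplicate member protein IDs")
  if (!"length" %in% names(members)) {
    if (!"sequence" %in% names(members)) {
      stop("members need either a length or a sequence column")
    }
    members$length <- nchar(members$sequence)
  }
  if ("ss" %in% names(members)) {
    bad <- !is.na(members$ss) & nchar(members$ss) != members$length
    if (any(bad)) {
      stop("ss length differs from protein length for: ",
           paste(members$protein_id[bad], collapse = ", "))
    }
  }
  with(members, {
    if (any(domain_start < 1L | domain_end < domain_start |
            domain_end > length)) {
      stop("domain span outside [1, protein length] for some member(s)")
    }
  })
  g <- list(cog_id = cog_id, members = members)
  class(g) <- "cog_group"
  recompute_stats(g)
}

recompute_stats <- function(g) {
  m <- g$members
  g$length_mean <- mean(m$length)
  g$length_sd <- if (nrow(m) >= 2L) stats::sd(m$length) else NA_real_
  g$domain_length_mean <- mean(m$domain_end - m$domain_start + 1L)
  g
}

#' @export
print.cog_group <- function(x, ...) {
  cat(sprintf(
    "COG group %s: %d members, length %.1f +/- %.1f, mean domain %.1f\n",
    sQuote(x$cog_id), nrow(x$members), x$length_mean,
    x$length_sd, x$domain_length_mean))
  invisible(x)
}

#' Select representative members of a COG
#'
#' Applies the two single-pass inclusion criteria for representative
#' orthologs: (1) the protein length lies no more than one sample standard
#' deviation from the group's mean length, excluding multidomain proteins
#' with large extra regions; (2) the conserved-domain span covers at least
#' 80% of the group's mean domain length, excluding partial domains. Both
#' boundaries are inclusive, and both statistics come from the unfiltered
#' group (or from `stats`, allowing the filter to be re-applied with
#' frozen statistics).
#'
#' @param group A [cog_group()] with at least 2 members.
#' @param coverage Minimum domain coverage fraction (default 0.8).
#' @param stats Optional list with `length_mean`, `length_sd`,
#'   `domain_length_mean` overriding the group's own statistics.
#' @return The filtered `cog_group` (statistics recomputed on the retained
#'   members); dropped members and their reasons are in the `"audit"`
#'   attribute.
#' @export
select_representatives <- function(group, coverage = 0.8, stats = NULL) {
  stopifnot(inherits(group, "cog_group"))
  m <- group$members
  if (nrow(m) < 2L) {
    stop("singleton COG group: sample SD undefined")
  }
  st <- if (is.null(stats)) {
    group[c("length_mean", "length_sd", "domain_length_mean")]
  } else {
    stats
  }
  dom_len <- m$domain_end - m$domain_start + 1L
  ok_len <- abs(m$length - st$length_mean) <= st$length_sd
  ok_cov <- dom_len >= coverage * st$domain_length_mean
  reason <- character(nrow(m))
  reason[!ok_len] <- "length outside 1 SD of mean"
  reason[!ok_cov] <- sprintf("domain coverage below %d%% of mean",
                             round(100 * coverage))
  reason[!ok_len & !ok_cov] <- "length outside 1 SD; partial domain"
  keep <- ok_len & ok_cov
  if (!any(keep)) stop("no members pass the representative filters")
  out <- group
  out$members <- m[keep, , drop = FALSE]
  rownames(out$members) <- NULL
  out <- recompute_stats(out)
  attr(out, "audit") <- data.frame(protein_id = m$protein_id[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE)
  out
}

#' Per-member GC and secondary-structure composition of a COG
#'
#' For every member protein, the fraction of residues in helix, sheet and
#' coil together with the GC of the member's gene - the table
#' [call_cog_bias()] consumes.
#'
#' @param group A `cog_group` whose members carry `ss` and `gene_gc`.
#' @return Data frame: `protein_id`, `gene_gc`, `helix`, `sheet`, `coil`,
#'   `length`.
#' @export
cog_gc_table <- function(group) {
  stopifnot(inherits(group, "cog_group"))
  m <- group$members
  if (nrow(m) == 0L) stop("empty COG group")
  if (!"ss" %in% names(m) || any(is.na(m$ss))) {
    stop("all members need an H/E/C annotation")
  }
  if (!"gene_gc" %in% names(m) || any(is.na(m$gene_gc))) {
    stop("all members need a gene GC value")
  }
  comp <- ss_composition(stats::setNames(m$ss, m$protein_id),
                         scope = "protein")
  data.frame(protein_id = m$protein_id, gene_gc = m$gene_gc,
             comp[, c("helix", "sheet", "coil")],
             length = m$length, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Build COG groups from loaded genomes and a membership table
#'
#' Joins a [read_cog_table()] membership table against a list of
#' [genome_record()]s, attaching each member's protein sequence, H/E/C
#' annotation and gene GC.
#'
#' @param memberships A `cog_membership` data frame.
#' @param genomes List of `genome_record` objects.
#' @return Named list of `cog_group` objects.
#' @export
build_cog_groups <- function(memberships, genomes) {
  idx <- do.call(rbind, lapply(genomes, function(g) {
    ap <- as_annotated(g)
    data.frame(organism_id = g$organism_id, protein_id = names(ap$seq),
               sequence = unname(ap$seq),
               ss = unname(ap$ss[names(ap$seq)]),
               gene_gc = unname(gene_gc(g)[names(ap$seq)]),
               stringsAsFactors = FALSE)
  }))
  merged <- merge(memberships, idx, by = c("organism_id", "protein_id"))
  if (nrow(merged) == 0L) {
    stop("no membership rows match the loaded genomes")
  }
  lapply(split(merged, merged$cog_id), function(d) {
    cog_group(d$cog_id[1L],
              d[, c("protein_id", "sequence", "ss", "gene_gc",
                    "domain_start", "domain_end")])
  })
}

#' Generate synthetic COG groups with controllable GC coupling
#'
#' Builds COG-like groups of annotation strings whose per-member coil
#' fraction follows `coil0 + coil_slope * gene_gc` plus Gaussian noise
#' (helix and sheet share the remainder 55/45), with member gene GC drawn
#' uniformly over `gc_range`. With `coil_slope = 0` the groups are null
#' cases for the type-I behaviour of [call_cog_bias()]; with a positive
#' slope they emulate structurally GC-biased orthologous families.
#'
#' @param n_cogs Number of groups.
#' @param members Members per group.
#' @param gc_range Range of member gene GC.
#' @param coil_slope Change in coil fraction per unit GC.
#' @param coil0 Baseline coil fraction at GC 0.
#' @param noise SD of the per-member composition noise.
#' @param mean_length,sd_length Member length distribution (floored at 50).
#' @param seed Integer seed.
#' @return Named list of `cog_group` objects (members carry `ss`,
#'   `gene_gc` and full-length domain spans).
#' @export
generate_cog_set <- function(n_cogs = 10L, members = 50L,
                             gc_range = c(0.20, 0.75), coil_slope = 0,
                             coil0 = 0.40, noise = 0.02,
                             mean_length = 300, sd_length = 30,
                             seed = 1L) {
  with_seed(seed, {
    out <- lapply(seq_len(n_cogs), function(k) {
      gc <- stats::runif(members, gc_range[1L], gc_range[2L])
      pc <- pmin(0.95, pmax(0.05,
                            coil0 + coil_slope * gc +
                              stats::rnorm(members, 0, noise)))
      lens <- pmax(50L, round(stats::rnorm(members, mean_length, sd_length)))
      ss <- vapply(seq_len(members), function(i) {
        paste(sample(SS3, lens[i], replace = TRUE,
                     prob = c(0.55 * (1 - pc[i]), 0.45 * (1 - pc[i]),
                              pc[i])), collapse = "")
      }, "")
      cog_group(sprintf("SYNCOG%04d", k), data.frame(
        protein_id = sprintf("SYNCOG%04d_p%03d", k, seq_len(members)),
        ss = ss, gene_gc = gc, length = lens,
        domain_start = 1L, domain_end = lens,
        stringsAsFactors = FALSE))
    })
    names(out) <- vapply(out, function(g) g$cog_id, "")
    out
  })
}
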