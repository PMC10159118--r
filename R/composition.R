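# Byte-level counting helpers: fast on multi-megabase concatenated strings.
count_chars <- function(s, chars) {
  r <- charToRaw(s)
  vapply(chars, function(ch) sum(r == charToRaw(ch)), 0L)
}

#' Coding-region GC content of a gene set
#'
#' GC content of a genome restricted to its protein-coding genes: the total
#' number of G or C nucleotides over all genes divided by the total gene
#' length. `N` bases are excluded from both numerator and denominator. The
#' result is invariant to gene order and to concatenating the genes.
#'
#' @param genes Named character vector of CDS nucleotide sequences, or a
#'   `genome_record`.
#' @return GC fraction in `[0, 1]`.
#' @examples
#' compute_coding_gc(c(g1 = "ATGGCA", g2 = "TTTT"))  # 3/10
#' @export
compute_coding_gc <- function(genes) {
  if (inherits(genes, "genome_record")) genes <- genes$genes
  genes <- as.character(unlist(genes, use.names = FALSE))
  if (length(genes) == 0L) stop("empty gene set")
  n <- count_chars(paste(genes, collapse = ""), c("A", "C", "G", "T"))
  denom <- sum(n)
  if (denom == 0L) stop("no unambiguous (A/C/G/T) nucleotides in gene set")
  (n[["G"]] + n[["C"]]) / denom
}

#' Per-gene GC content
#'
#' @param genes Named character vector of CDS sequences or a
#'   `genome_record`.
#' @return Named numeric vector: GC fraction of each gene (`N` excluded).
#' @export
gene_gc <- function(genes) {
  if (inherits(genes, "genome_record")) genes <- genes$genes
  vapply(genes, compute_coding_gc, 0)
}

#' Classify amino acids by the GC content of their codons
#'
#' For each of the 20 standard amino acids, computes the unweighted mean
#' over its synonymous codons of (G+C count)/3 and classifies the amino
#' acid as `high` (mean > 1/2), `neutral` (exactly 1/2) or `low`
#' (mean < 1/2). Stop codons belong to no amino acid and are excluded.
#' Under the standard genetic code this yields groups of 5 (A, G, P, R, W),
#' 8 (V, H, D, T, Q, C, E, S) and 7 (L, M, F, Y, K, N, I) amino acids.
#'
#' @param codon_table Named character vector mapping codons to one-letter
#'   amino-acid codes (default [Biostrings::GENETIC_CODE]).
#' @return Data frame of class `"codon_class_table"` with one row per amino
#'   acid: `aa`, `codons` (comma-separated), `n_codons`, `mean_codon_gc`,
#'   `gc_class`.
#' @export
classify_amino_acids <- function(codon_table = Biostrings::GENETIC_CODE) {
  codon_table <- codon_table[codon_table != "*"]
  gc_per_codon <- vapply(names(codon_table), function(cd) {
    sum(count_chars(cd, c("G", "C"))) / nchar(cd)
  }, 0)
  aas <- sort(unique(codon_table))
  mean_gc <- vapply(aas, function(a) {
    mean(gc_per_codon[codon_table == a])
  }, 0)
  tol <- 1e-9
  cls <- ifelse(mean_gc > 0.5 + tol, "high",
                ifelse(mean_gc < 0.5 - tol, "low", "neutral"))
  out <- data.frame(
    aa = aas,
    codons = vapply(aas, function(a) {
      paste(names(codon_table)[codon_table == a], collapse = ",")
    }, ""),
    n_codons = vapply(aas, function(a) sum(codon_table == a), 0L),
    mean_codon_gc = mean_gc,
    gc_class = factor(cls, levels = c("high", "neutral", "low")),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("codon_class_table", "data.frame")
  out
}

#' Amino-acid frequencies of a proteome
#'
#' Pooled relative frequency of each of the 20 standard amino acids over
#' all proteins: count of the amino acid across the proteome divided by the
#' total number of standard residues. `X` residues are excluded from both
#' numerator and denominator.
#'
#' @param proteins Named character vector of protein sequences, an
#'   `annotated_proteome`, or a `genome_record`.
#' @param context Label stored with the table (`"proteome"`, `"helix"`,
#'   `"sheet"` or `"coil"`).
#' @return Data frame of class `"aa_freq_table"` with one row per amino
#'   acid: `aa`, `count`, `frequency`, `context`. Frequencies sum to 1.
#' @export
aa_frequencies <- function(proteins, context = "proteome") {
  if (inherits(proteins, "genome_record")) proteins <- proteins$proteome
  if (inherits(proteins, "annotated_proteome")) proteins <- proteins$seq
  if (length(proteins) == 0L) stop("empty proteome")
  counts <- count_chars(paste(proteins, collapse = ""), AA20)
  total <- sum(counts)
  if (total == 0L) stop("proteome contains no standard amino-acid residues")
  out <- data.frame(aa = AA20, count = unname(counts),
                    frequency = unname(counts) / total,
                    context = context,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("aa_freq_table", "data.frame")
  out
}

# Named frequency vector from an aa_freq_table (or pass-through).
aa_freq_vector <- function(x) {
  if (inherits(x, "aa_freq_table")) {
    return(stats::setNames(x$frequency, x$aa)[AA20])
  }
  if (is.numeric(x) && !is.null(names(x))) {
    v <- x[AA20]
    if (any(is.na(v))) stop("frequency vector must cover the 20 amino acids")
    return(v)
  }
  stop("expected an aa_freq_table or named numeric vector")
}
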