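#' Read a FASTA file of nucleotide, protein or secondary-structure records
#'
#' Parses a FASTA file and validates every sequence against the requested
#' alphabet. Case is normalised to upper. Nucleotide records may contain
#' `N` and protein records `X` as ambiguity codes; any other out-of-alphabet
#' character is an error. For `alphabet = "ss"` the file is a FASTA-like
#' per-residue annotation over the three-state code `{H, E, C}`; any other
#' character (e.g. extra states emitted by a secondary-structure predictor)
#' is remapped to `C`, and the number of remapped characters is recorded in
#' the `"remapped"` attribute.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"nucleotide"`, `"protein"`, `"ss"`.
#' @return A named character vector of upper-case sequences (names are the
#'   record IDs, i.e. the header up to the first whitespace), with class
#'   `"fasta_records"` and attributes `alphabet` and, for `"ss"`, `remapped`.
#' @seealso [write_fasta()], [attach_ss()]
#' @examples
#' f <- tempfile(fileext = ".fna")
#' writeLines(c(">g1", "atggca", ">g2", "TTTT"), f)
#' read_fasta(f, "nucleotide")
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein", "ss")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }

  remapped <- 0L
  if (alphabet == "ss") {
    remapped <- sum(nchar(seqs)) - sum(nchar(gsub("[^HEC]", "", seqs)))
    if (remapped > 0L) {
      # three-state convention: anything a predictor emits besides H/E is coil
      seqs <- stats::setNames(gsub("[^HE]", "C", seqs), ids)
      message("read_fasta: remapped ", remapped,
              " non-H/E character(s) to C")
    }
  } else {
    legal <- switch(alphabet,
                    nucleotide = "[^ACGTN]",
                    protein    = sprintf("[^%sX]", paste(AA20, collapse = "")))
    bad <- grepl(legal, seqs)
    if (any(bad)) {
      offending <- regmatches(seqs[bad], regexpr(legal, seqs[bad]))
      stop("illegal ", alphabet, " character(s) ",
           paste(sQuote(unique(offending)), collapse = ", "),
           " in record(s): ", paste(ids[bad], collapse = ", "))
    }
  }

  structure(seqs, class = c("fasta_records", "character"),
            alphabet = alphabet, remapped = remapped)
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences (e.g. from [read_fasta()]).
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::BStringSet(as.character(x))
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Attach secondary-structure annotations to protein sequences
#'
#' Pairs each H/E/C annotation string with the protein record of the same
#' ID, producing an annotated proteome. Every annotation must match a
#' protein and have the same length. Proteins without an annotation are kept
#' in the proteome but flagged as unannotated and excluded from all
#' structure statistics.
#'
#' @param proteins Named character vector of protein sequences, or an
#'   existing `annotated_proteome` (re-attaching identical annotations is a
#'   no-op).
#' @param ss Named character vector of H/E/C strings.
#' @return An object of class `"annotated_proteome"`: a list with elements
#'   `seq` (all proteins), `ss` (annotations for the annotated subset) and
#'   `unannotated` (IDs without annotation).
#' @examples
#' attach_ss(c(p1 = "AG", p2 = "MKL"), c(p1 = "HC"))
#' @export
attach_ss <- function(proteins, ss) {
  if (inherits(proteins, "annotated_proteome")) {
    proteins <- proteins$seq
  }
  if (is.null(names(proteins)) || is.null(names(ss))) {
    stop("proteins and ss must be named")
  }
  unknown <- setdiff(names(ss), names(proteins))
  if (length(unknown)) {
    stop("ss record(s) with no matching protein: ",
         paste(unknown, collapse = ", "))
  }
  mism <- names(ss)[nchar(ss) != nchar(proteins[names(ss)])]
  if (length(mism)) {
    stop("ss length does not match protein length for: ",
         paste(mism, collapse = ", "))
  }
  structure(
    list(seq = stats::setNames(as.character(proteins), names(proteins)),
         ss = stats::setNames(as.character(ss), names(ss)),
         unannotated = setdiff(names(proteins), names(ss))),
    class = "annotated_proteome")
}

#' @export
print.annotated_proteome <- function(x, ...) {
  cat("Annotated proteome:", length(x$seq), "proteins,",
      length(x$ss), "with H/E/C annotation")
  if (length(x$unannotated)) {
    cat(" (", length(x$unannotated), " unannotated)", sep = "")
  }
  cat("\n")
  invisible(x)
}

# Coerce the various proteome representations to annotated_proteome.
as_annotated <- function(x) {
  if (inherits(x, "annotated_proteome")) return(x)
  if (inherits(x, "genome_record")) return(x$proteome)
  if (is.list(x) && !is.null(x$seq) && !is.null(x$ss)) {
    return(attach_ss(x$seq, x$ss))
  }
  stop("cannot interpret input as an annotated proteome")
}

#' Bundle one organism's genes, proteins and annotations
#'
#' @param organism_id Identifier for the organism.
#' @param genes Named character vector of coding (CDS) nucleotide sequences.
#' @param proteins Optional named character vector of protein sequences.
#' @param ss Optional named character vector of H/E/C annotations.
#' @param taxon_label Optional free-text taxon (phylum/class).
#' @return Object of class `"genome_record"` with elements `organism_id`,
#'   `taxon_label`, `genes` and `proteome` (an `annotated_proteome`, or
#'   plain proteins when `ss` is absent).
#' @details When a gene and a protein share an ID, the translated gene
#'   length (codons minus the stop) is checked against the protein length;
#'   a mismatch raises a warning naming the offending IDs.
#' @export
genome_record <- function(organism_id, genes, proteins = NULL, ss = NULL,
                          taxon_label = NA_character_) {
  if (anyDuplicated(names(genes))) stop("duplicate gene IDs")
  if (!is.null(proteins) && anyDuplicated(names(proteins))) {
    stop("duplicate protein IDs")
  }
  if (!is.null(proteins)) {
    shared <- intersect(names(genes), names(proteins))
    if (length(shared)) {
      exp_len <- nchar(genes[shared]) %/% 3L - 1L
      bad <- shared[exp_len != nchar(proteins[shared])]
      if (length(bad)) {
        warning("translated gene length disagrees with protein length for ",
                length(bad), " record(s): ",
                paste(utils::head(bad, 5L), collapse = ", "))
      }
    }
  }
  proteome <- if (!is.null(proteins) && !is.null(ss)) {
    attach_ss(proteins, ss)
  } else {
    proteins
  }
  structure(list(organism_id = organism_id, taxon_label = taxon_label,
                 genes = stats::setNames(as.character(genes), names(genes)),
                 proteome = proteome),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  np <- if (inherits(x$proteome, "annotated_proteome")) {
    length(x$proteome$seq)
  } else {
    length(x$proteome)
  }
  cat("Genome record", sQuote(x$organism_id), "-", length(x$genes),
      "coding genes,", np, "proteins\n")
  invisible(x)
}

#' Read a COG membership table
#'
#' Reads a tab-separated table assigning proteins to clusters of orthologous
#' genes (COGs), with the conserved-domain span located in each protein by
#' upstream HMM scanning. Required columns: `protein_id`, `cog_id`,
#' `domain_start`, `domain_end`, `organism_id`. Coordinates are 1-based
#' inclusive residue indices.
#'
#' @param path Path to the TSV file.
#' @param proteins Optional named character vector (or `annotated_proteome`)
#'   used to verify that domain coordinates fall within protein lengths.
#' @return A data frame of memberships with class `"cog_membership"`.
#' @export
read_cog_table <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("COG table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "cog_id", "domain_start", "domain_end",
            "organism_id")
  if (!all(need %in% names(tab))) {
    stop("COG table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  if (nrow(tab)) {
    if (any(is.na(tab$domain_start)) || any(is.na(tab$domain_end))) {
      stop("malformed domain coordinates (NA) in COG table")
    }
    bad <- tab$domain_start < 1L | tab$domain_end < tab$domain_start
    if (any(bad)) {
      stop("invalid domain span for protein(s): ",
           paste(tab$protein_id[bad], collapse = ", "))
    }
    if (!is.null(proteins)) {
      if (inherits(proteins, "annotated_proteome")) proteins <- proteins$seq
      known <- tab$protein_id %in% names(proteins)
      over <- known & tab$domain_end > nchar(proteins[tab$protein_id])
      if (any(over)) {
        stop("domain_end exceeds protein length for: ",
             paste(tab$protein_id[over], collapse = ", "))
      }
    }
  }
  class(tab) <- c("cog_membership", "data.frame")
  tab
}
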