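#' Gene model container
#'
#' A `gene_model` holds the transcript-ordered exon and CDS structure of one
#' gene on one locus sequence. All coordinates are 0-based half-open on the
#' forward strand of the locus; exon and CDS tables are ordered 5'->3' in
#' transcript orientation (for minus-strand genes that is decreasing genomic
#' position).
#'
#' @param gene_id gene identifier.
#' @param seq_id identifier of the locus sequence the coordinates refer to.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end`
#'   (0-based half-open genomic coordinates).
#' @param cds data.frame like `exons`; every CDS segment must be contained in
#'   exactly one exon.
#' @param sequence optional locus nucleotide sequence (forward strand,
#'   character scalar).
#' @param complete logical; `TRUE` when the CDS is believed complete
#'   (length a multiple of 3, starts at the initiator codon).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, cds,
                       sequence = NULL, complete = NA) {
  if (!strand %in% c("+", "-")) {
    stop("unknown strand symbol '", strand, "' for gene ", gene_id)
  }
  exons <- normalize_intervals(exons, strand, gene_id, "exon")
  cds <- normalize_intervals(cds, strand, gene_id, "CDS")
  check_exon_layout(exons, gene_id)
  check_cds_containment(exons, cds, gene_id)
  cds_len <- sum(cds$end - cds$start)
  if (is.na(complete)) complete <- cds_len > 0 && cds_len %% 3L == 0L
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nrow(exons) && max(exons$end) > nchar(sequence)) {
      stop("gene ", gene_id, ": exon coordinates exceed sequence length")
    }
  }
  structure(
    list(gene_id = gene_id, seq_id = seq_id, strand = strand,
         exons = exons, cds = cds, sequence = sequence,
         complete = complete),
    class = "gene_model"
  )
}

# Sort intervals into transcript orientation and validate basic invariants.
normalize_intervals <- function(x, strand, gene_id, what) {
  if (is.null(x) || nrow(x) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  x <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  if (any(x$start < 0) || any(x$end <= x$start)) {
    stop("gene ", gene_id, ": invalid ", what,
         " interval (need 0 <= start < end)")
  }
  ord <- order(x$start)
  if (strand == "-") ord <- rev(ord)
  x[ord, , drop = FALSE]
}

check_exon_layout <- function(exons, gene_id) {
  if (nrow(exons) < 2) return(invisible(TRUE))
  g <- exons[order(exons$start), , drop = FALSE]
  if (any(g$start[-1] < g$end[-nrow(g)])) {
    stop("gene ", gene_id, ": overlapping or abutting-unmerged exons")
  }
  if (any(g$start[-1] == g$end[-nrow(g)])) {
    stop("gene ", gene_id, ": zero-length intron between abutting exons")
  }
  invisible(TRUE)
}

check_cds_containment <- function(exons, cds, gene_id) {
  if (nrow(cds) == 0) return(invisible(TRUE))
  for (i in seq_len(nrow(cds))) {
    host <- which(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    if (length(host) != 1) {
      stop("gene ", gene_id, ": CDS segment [", cds$start[i], ",",
           cds$end[i], ") is not contained in exactly one exon")
    }
  }
  invisible(TRUE)
}

#' @export
print.gene_model <- function(x, ...) {
  cds_len <- sum(x$cds$end - x$cds$start)
  cat("<gene_model> ", x$gene_id, " (", x$seq_id, x$strand, ")\n", sep = "")
  cat("  exons: ", nrow(x$exons), "  CDS segments: ", nrow(x$cds),
      "  CDS length: ", cds_len, " nt",
      if (isTRUE(x$complete)) "" else "  [incomplete]", "\n", sep = "")
  invisible(x)
}

#' Number of introns of a gene model
#' @param model a [gene_model()].
#' @return integer, `nrow(exons) - 1`.
#' @export
n_introns <- function(model) max(0L, nrow(model$exons) - 1L)

#' Precursor region annotation
#'
#' Partition of a translated precursor into signal peptide, propeptide and
#' mature peptide segments. Residue coordinates are 0-based half-open over
#' `[0, precursor_len)`; the precursor length excludes the stop codon.
#' Region order along the precursor is unconstrained (e.g. signal - mature -
#' propeptide precursors are valid).
#'
#' @param gene_id gene identifier.
#' @param signal_len signal peptide length in residues (>= 1).
#' @param precursor_len total precursor length in residues.
#' @param propeptide_spans,mature_spans data.frames with columns
#'   `start`, `end` (residue coordinates), or `NULL`. When both are `NULL`
#'   and `precursor_len` is known, a single mature span
#'   `[signal_len, precursor_len)` is inferred.
#' @return an object of class `precursor_annotation`.
#' @export
precursor_annotation <- function(gene_id, signal_len, precursor_len = NA,
                                 propeptide_spans = NULL,
                                 mature_spans = NULL) {
  signal_len <- as.integer(signal_len)
  if (is.na(signal_len) || signal_len <= 0) {
    stop("gene ", gene_id, ": signal_len must be >= 1")
  }
  precursor_len <- as.integer(precursor_len)
  norm_spans <- function(s) {
    if (is.null(s) || (is.data.frame(s) && nrow(s) == 0)) {
      return(data.frame(start = integer(0), end = integer(0)))
    }
    s <- data.frame(start = as.integer(s$start), end = as.integer(s$end))
    s[order(s$start), , drop = FALSE]
  }
  pp <- norm_spans(propeptide_spans)
  mp <- norm_spans(mature_spans)
  if (nrow(pp) + nrow(mp) == 0 && !is.na(precursor_len)) {
    if (precursor_len > signal_len) {
      mp <- data.frame(start = signal_len, end = precursor_len)
    }
  }
  all_spans <- rbind(
    data.frame(start = 0L, end = signal_len),
    pp, mp
  )
  all_spans <- all_spans[order(all_spans$start), , drop = FALSE]
  if (any(all_spans$end <= all_spans$start)) {
    stop("gene ", gene_id, ": empty precursor span")
  }
  if (nrow(all_spans) > 1 &&
      any(all_spans$start[-1] < all_spans$end[-nrow(all_spans)])) {
    stop("gene ", gene_id, ": overlapping precursor spans")
  }
  if (!is.na(precursor_len) && any(all_spans$end > precursor_len)) {
    stop("gene ", gene_id, ": span exceeds precursor length")
  }
  complete <- !is.na(precursor_len) &&
    sum(all_spans$end - all_spans$start) == precursor_len
  structure(
    list(gene_id = gene_id, signal_len = signal_len,
         precursor_len = precursor_len,
         propeptide_spans = pp, mature_spans = mp, complete = complete),
    class = "precursor_annotation"
  )
}

#' @export
print.precursor_annotation <- function(x, ...) {
  fmt <- function(s) {
    if (nrow(s) == 0) "-" else
      paste(sprintf("[%d,%d)", s$start, s$end), collapse = " ")
  }
  cat("<precursor_annotation> ", x$gene_id,
      ": SP 1..", x$signal_len,
      "  PP ", fmt(x$propeptide_spans),
      "  MP ", fmt(x$mature_spans),
      "  len ", x$precursor_len, " aa\n", sep = "")
  invisible(x)
}

# Region label (SIGNAL/PROPEPTIDE/MATURE) of a residue index, or NA when the
# index falls in an annotation gap.
region_of_residue <- function(annot, idx) {
  out <- rep(NA_character_, length(idx))
  out[idx >= 0 & idx < annot$signal_len] <- "SIGNAL"
  pp <- annot$propeptide_spans
  for (i in seq_len(nrow(pp))) {
    out[idx >= pp$start[i] & idx < pp$end[i]] <- "PROPEPTIDE"
  }
  mp <- annot$mature_spans
  for (i in seq_len(nrow(mp))) {
    out[idx >= mp$start[i] & idx < mp$end[i]] <- "MATURE"
  }
  out
}
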