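#' Classify every intron of a gene model by phase
#'
#' An intron's phase is its position relative to the reading frame: phase 0
#' between codons, phase 1 between the first and second nucleotide of a
#' codon, phase 2 between the second and third. The phase is
#' `L mod 3`, where `L` is the number of coding nucleotides strictly 5' of
#' the intron; introns entirely 5' of the first CDS nucleotide are labelled
#' `UTR5` and those entirely 3' of the last `UTR3`, with phase `NA`.
#'
#' For phase-1/2 introns `interrupted_codon_index` (0-based) is the codon the
#' intron splits; for phase-0 introns it is the codon immediately 3' of the
#' intron — in both cases `floor(L / 3)`, which keeps cleavage-site offsets
#' comparable across phases.
#'
#' @param model a [gene_model()].
#' @return data.frame, one row per intron in transcript order, with columns
#'   `gene_id`, `ordinal`, `donor`, `acceptor`, `length`, `region`
#'   (`UTR5`/`CODING`/`UTR3`), `upstream_coding_nt`, `phase`,
#'   `interrupted_codon_index`.
#' @export
compute_intron_phases <- function(model) {
  check_exon_layout(model$exons, model$gene_id)
  iv <- intron_intervals(model)
  n <- nrow(iv)
  ex <- model$exons
  cds_len_per_exon <- vapply(seq_len(nrow(ex)), function(i) {
    inside <- model$cds$start >= ex$start[i] & model$cds$end <= ex$end[i]
    sum(model$cds$end[inside] - model$cds$start[inside])
  }, 0L)
  cds_total <- sum(cds_len_per_exon)
  if (n == 0) {
    return(data.frame(gene_id = character(0), ordinal = integer(0),
                      donor = integer(0), acceptor = integer(0),
                      length = integer(0), region = character(0),
                      upstream_coding_nt = integer(0), phase = integer(0),
                      interrupted_codon_index = integer(0)))
  }
  # intron i lies between transcript exons i and i+1
  L <- cumsum(cds_len_per_exon)[seq_len(n)]
  region <- ifelse(L == 0L, "UTR5", ifelse(L == cds_total, "UTR3", "CODING"))
  coding <- region == "CODING"
  phase <- ifelse(coding, L %% 3L, NA_integer_)
  codon <- ifelse(coding, L %/% 3L, NA_integer_)
  if (model$strand == "+") {
    donor <- iv$start; acceptor <- iv$end
  } else {
    donor <- iv$end; acceptor <- iv$start
  }
  data.frame(
    gene_id = model$gene_id,
    ordinal = seq_len(n),
    donor = donor,
    acceptor = acceptor,
    length = abs(iv$end - iv$start),
    region = region,
    upstream_coding_nt = as.integer(L),
    phase = as.integer(phase),
    interrupted_codon_index = as.integer(codon)
  )
}

#' Map intron records onto precursor protein regions
#'
#' Locates each coding intron's interrupted codon within the annotated
#' signal peptide / propeptide / mature peptide partition of the precursor
#' and reports the signed residue offset from the signal-peptide cleavage
#' site (`interrupted_codon_index - signal_len`; negative values lie inside
#' the signal peptide).
#'
#' @param introns data.frame from [compute_intron_phases()].
#' @param annot the gene's [precursor_annotation()].
#' @return `introns` with columns `precursor_region`
#'   (`SIGNAL`/`PROPEPTIDE`/`MATURE`/`UTR5`/`UTR3`) and
#'   `offset_from_cleavage` appended.
#' @export
map_to_precursor <- function(introns, annot) {
  if (nrow(introns) && any(introns$gene_id != annot$gene_id)) {
    stop("gene_id mismatch: introns are for ", introns$gene_id[1],
         ", annotation for ", annot$gene_id)
  }
  coding <- introns$region == "CODING"
  idx <- introns$interrupted_codon_index
  if (!is.na(annot$precursor_len) &&
      any(coding & idx >= annot$precursor_len, na.rm = TRUE)) {
    stop("gene ", annot$gene_id, ": interrupted codon index beyond the ",
         "precursor - annotation and CDS disagree")
  }
  region <- introns$region
  region[coding] <- region_of_residue(annot, idx[coding])
  introns$precursor_region <- region
  introns$offset_from_cleavage <-
    ifelse(coding, idx - annot$signal_len, NA_integer_)
  introns
}

#' Call the exon-shuffling boundary signature for one gene
#'
#' The signature is a phase-1 intron whose interrupted codon lies within
#' `window` residues of the signal-peptide cleavage site. When several
#' introns qualify the one with the smallest absolute offset is named
#' (ties broken toward the smaller ordinal).
#'
#' @param introns data.frame from [map_to_precursor()].
#' @param annot the gene's [precursor_annotation()].
#' @param window residue half-width of the boundary window (default 3).
#' @return one-row data.frame: `gene_id`, `has_boundary_phase1`,
#'   `signature_intron_ordinal`, `offset_from_cleavage`, `window`.
#' @export
call_boundary_signature <- function(introns, annot, window = 3L) {
  if (length(window) != 1 || is.na(window) || window < 0) {
    stop("window must be a non-negative residue count")
  }
  cand <- which(!is.na(introns$phase) & introns$phase == 1L &
                  abs(introns$offset_from_cleavage) <= window)
  if (length(cand)) {
    cand <- cand[order(abs(introns$offset_from_cleavage[cand]),
                       introns$ordinal[cand])]
    hit <- cand[1]
    data.frame(gene_id = annot$gene_id, has_boundary_phase1 = TRUE,
               signature_intron_ordinal = introns$ordinal[hit],
               offset_from_cleavage = introns$offset_from_cleavage[hit],
               window = as.integer(window))
  } else {
    data.frame(gene_id = annot$gene_id, has_boundary_phase1 = FALSE,
               signature_intron_ordinal = NA_integer_,
               offset_from_cleavage = NA_integer_,
               window = as.integer(window))
  }
}

#' Summarise boundary-signature calls over a gene set
#'
#' @param calls data.frame of row-bound [call_boundary_signature()] results.
#' @return object of class `boundary_summary`: counts, fraction with the
#'   signature, and the ids of the exceptions.
#' @export
summarize_gene_set <- function(calls) {
  if (nrow(calls) == 0) stop("no boundary calls to summarise")
  n <- nrow(calls)
  k <- sum(calls$has_boundary_phase1)
  structure(
    list(n_genes = n, n_signature = k, n_without = n - k,
         fraction = k / n,
         exceptions = calls$gene_id[!calls$has_boundary_phase1]),
    class = "boundary_summary"
  )
}

#' @export
print.boundary_summary <- function(x, ...) {
  cat("Boundary phase-1 signature: ", x$n_signature, "/", x$n_genes,
      " genes (fraction ", format(x$fraction, digits = 4), ")\n", sep = "")
  if (length(x$exceptions)) {
    cat("  without signature: ", paste(x$exceptions, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Annotate a set of gene models end-to-end
#'
#' Convenience wrapper composing [compute_intron_phases()],
#' [map_to_precursor()] and [call_boundary_signature()] over matched models
#' and precursor annotations.
#'
#' @param models list of [gene_model()].
#' @param annots named list of [precursor_annotation()] (by gene_id).
#' @param window boundary window in residues.
#' @return list with `introns` (one data.frame, all genes) and `calls`
#'   (one row per gene).
#' @export
annotate_gene_set <- function(models, annots, window = 3L) {
  introns <- list(); calls <- list()
  for (m in models) {
    a <- annots[[m$gene_id]]
    if (is.null(a)) stop("no precursor annotation for gene ", m$gene_id)
    rec <- map_to_precursor(compute_intron_phases(m), a)
    introns[[length(introns) + 1]] <- rec
    calls[[length(calls) + 1]] <- call_boundary_signature(rec, a, window)
  }
  list(introns = do.call(rbind, introns), calls = do.call(rbind, calls))
}
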