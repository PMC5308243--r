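#' Render a gene-structure diagram
#'
#' Draws the precursor as labelled region boxes (5'UTR, SP, PP, MP) with
#' intron connectors labelled by phase, in the style of classic exon-intron
#' architecture figures. The text mode emits a one-line schematic such as
#' `[5'UTR]--i(NA)--[SP]--i(1)--[MP][PP]`; the SVG mode a standalone
#' SVG 1.1 document with deterministic layout.
#'
#' @param model a [gene_model()] (used for UTR intron placement).
#' @param introns the gene's [map_to_precursor()] records.
#' @param annot its [precursor_annotation()].
#' @param format `"text"` or `"svg"`.
#' @return character scalar: the schematic line or the SVG document.
#' @export
render_structure <- function(model, introns, annot,
                             format = c("text", "svg")) {
  format <- match.arg(format)
  seg <- precursor_segments(annot)
  cuts <- sort(unique(c(seg$start, seg$end,
                        introns$interrupted_codon_index[
                          introns$region == "CODING"])))
  cuts <- cuts[cuts > 0 & cuts < annot$precursor_len]
  bounds <- c(0L, cuts, annot$precursor_len)
  boxes <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  boxes$label <- region_code(region_of_residue(annot, boxes$start))
  conn <- function(at) {
    sel <- introns$region == "CODING" &
      introns$interrupted_codon_index == at
    if (!any(sel)) return("")
    paste0(sprintf("--i(%d)--", introns$phase[sel]), collapse = "")
  }
  utr5_introns <- sum(introns$region == "UTR5")
  utr3_introns <- sum(introns$region == "UTR3")

  if (format == "text") {
    out <- if (utr5_introns) {
      paste0("[5'UTR]", strrep("--i(NA)--", utr5_introns))
    } else ""
    for (i in seq_len(nrow(boxes))) {
      out <- paste0(out, conn(boxes$start[i]), "[", boxes$label[i], "]")
    }
    out <- paste0(out, conn(annot$precursor_len))
    if (utr3_introns) {
      out <- paste0(out, strrep("--i(NA)--", utr3_introns), "[3'UTR]")
    }
    return(out)
  }
  render_structure_svg(boxes, introns, annot, utr5_introns, utr3_introns)
}

precursor_segments <- function(annot) {
  seg <- rbind(
    data.frame(start = 0L, end = annot$signal_len),
    annot$propeptide_spans, annot$mature_spans
  )
  seg[order(seg$start), , drop = FALSE]
}

region_code <- function(region) {
  code <- c(SIGNAL = "SP", PROPEPTIDE = "PP", MATURE = "MP")
  out <- unname(code[region])
  out[is.na(out)] <- "?"
  out
}

REGION_FILL <- c(SP = "#d9a441", PP = "#9ecae1", MP = "#74c476",
                 "5'UTR" = "#d9d9d9", "3'UTR" = "#d9d9d9", "?" = "#ffffff")

render_structure_svg <- function(boxes, introns, annot, utr5_introns,
                                 utr3_introns) {
  px <- 4                                  # pixels per residue
  x0 <- 10; y0 <- 30; h <- 24
  elems <- character(0)
  x <- x0
  add_box <- function(x, w, label) {
    c(sprintf(
        '<rect x="%.1f" y="%d" width="%.1f" height="%d" fill="%s" stroke="black"/>',
        x, y0, w, h, REGION_FILL[[label]]),
      sprintf('<text x="%.1f" y="%d" font-size="10" text-anchor="middle">%s</text>',
              x + w / 2, y0 + h / 2 + 4, label))
  }
  add_intron <- function(x, label) {
    c(sprintf('<path d="M %.1f %d L %.1f %d L %.1f %d" fill="none" stroke="black"/>',
              x - 8, y0, x, y0 - 14, x + 8, y0),
      sprintf('<text x="%.1f" y="%d" font-size="9" text-anchor="middle">i(%s)</text>',
              x, y0 - 17, label))
  }
  if (utr5_introns) {
    w <- 15 * px
    elems <- c(elems, add_box(x, w, "5'UTR"))
    x <- x + w
    for (k in seq_len(utr5_introns)) elems <- c(elems, add_intron(x, "NA"))
    x <- x + 6
  }
  for (i in seq_len(nrow(boxes))) {
    sel <- introns$region == "CODING" &
      introns$interrupted_codon_index == boxes$start[i]
    for (p in introns$phase[sel]) {
      elems <- c(elems, add_intron(x, p)); x <- x + 6
    }
    w <- (boxes$end[i] - boxes$start[i]) * px
    elems <- c(elems, add_box(x, w, boxes$label[i]))
    x <- x + w
  }
  sel <- introns$region == "CODING" &
    introns$interrupted_codon_index == annot$precursor_len
  for (p in introns$phase[sel]) {
    elems <- c(elems, add_intron(x, p)); x <- x + 6
  }
  if (utr3_introns) {
    for (k in seq_len(utr3_introns)) elems <- c(elems, add_intron(x, "NA"))
    x <- x + 6
    elems <- c(elems, add_box(x, 15 * px, "3'UTR"))
    x <- x + 15 * px
  }
  elems <- c(elems, sprintf(
    '<text x="%d" y="%d" font-size="11">%s</text>', x0, y0 + h + 16,
    annot$gene_id))
  paste(c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%.0f" height="90">',
    x + 20), elems, "</svg>"), collapse = "\n")
}

#' Annotate a gene set from files and write result tables
#'
#' Composes [load_gene_models()], [load_precursor_annotations()],
#' [compute_intron_phases()], [map_to_precursor()] and
#' [call_boundary_signature()]; writes `introns.tsv` (one intron per row)
#' and `boundary.tsv` (one gene per row) under `out_dir`.
#'
#' @param annotation_path GFF3 or GenBank file.
#' @param annotations_path precursor-annotation TSV/JSON.
#' @param fasta_path optional locus FASTA.
#' @param window boundary window in residues (default 3).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with `introns`, `calls`, `summary`
#'   (a [summarize_gene_set()] object).
#' @export
run_annotate <- function(annotation_path, annotations_path,
                         fasta_path = NULL, window = 3L, out_dir = NULL) {
  models <- load_gene_models(annotation_path, fasta_path)
  if (length(models) == 0) stop("no genes found in '", annotation_path, "'")
  annots <- load_precursor_annotations(annotations_path)
  res <- annotate_gene_set(models, annots, window = window)
  res$summary <- summarize_gene_set(res$calls)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_tsv(res$introns, file.path(out_dir, "introns.tsv"))
    write_table_tsv(res$calls, file.path(out_dir, "boundary.tsv"))
  }
  res$models <- models
  res$annots <- annots
  invisible(res)
}

#' Run the full analysis and write a combined JSON report
#'
#' Runs annotation, phase-distribution statistics, the enrichment test
#' against reference proportions, the boundary permutation test, scaffold
#' motif annotation of the translated precursors, text diagrams, and
#' (when promoter inputs are given) the promoter module scan. Each section
#' of the JSON report carries its inputs; the header records seed, window
#' and package version.
#'
#' @inheritParams run_annotate
#' @param n_perm permutations for the boundary test (default 10000).
#' @param seed integer seed (required).
#' @param reference a [reference_proportions()] object or label.
#' @param promoter_fasta,motif_tsv optional promoter inputs; when missing
#'   the promoter section is marked `"skipped"`.
#' @param out_dir directory for `report.json` (and `diagrams.svg` in SVG
#'   format), or `NULL`.
#' @param format diagram format, `"text"` or `"svg"`.
#' @return the report as a list, invisibly.
#' @export
run_full_report <- function(annotation_path, annotations_path,
                            fasta_path = NULL, window = 3L,
                            n_perm = 10000L, seed,
                            reference = "nonsecretory_human",
                            promoter_fasta = NULL, motif_tsv = NULL,
                            out_dir = NULL, format = c("text", "svg")) {
  if (missing(seed)) stop("seed is required")
  format <- match.arg(format)
  if (is.character(reference)) reference <- reference_proportions(reference)
  ann <- run_annotate(annotation_path, annotations_path, fasta_path,
                      window = window, out_dir = out_dir)
  dist <- phase_distribution(ann$introns)
  enr <- phase_enrichment_test(dist, reference)
  genes <- lapply(ann$models, function(m) {
    list(introns = ann$introns[ann$introns$gene_id == m$gene_id, ,
                               drop = FALSE],
         annot = ann$annots[[m$gene_id]])
  })
  has_coding <- vapply(genes, function(g) any(g$introns$region == "CODING"),
                       TRUE)
  perm <- boundary_permutation_test(genes[has_coding], window = window,
                                    n_perm = n_perm, seed = seed)
  motifs_sec <- if (!is.null(fasta_path)) {
    prot <- vapply(ann$models, function(m) translate_cds(spliced_cds(m)), "")
    hits <- lapply(seq_along(prot), function(i) {
      h <- match_ick_consensus(prot[i])
      if (nrow(h)) cbind(protein_id = ann$models[[i]]$gene_id, h)
    })
    hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
    list(status = "done",
         ick_matches = if (is.null(hits)) list() else hits,
         cysteines = lapply(seq_along(prot), function(i)
           c(list(protein_id = ann$models[[i]]$gene_id),
             count_cysteines(prot[i]))))
  } else list(status = "skipped", reason = "no locus FASTA supplied")
  promoter_sec <- if (!is.null(promoter_fasta) && !is.null(motif_tsv)) {
    sc <- scan_promoter_fasta(promoter_fasta, load_motifs(motif_tsv))
    mm <- module_matrix(sc$hits, sc$promoter_ids)
    list(status = "done", hits = sc$hits,
         presence = mm$presence, jaccard = mm$jaccard,
         mean_sharing = as.list(mean_sharing(mm)))
  } else list(status = "skipped", reason = "no promoter inputs supplied")
  diagrams <- vapply(seq_along(ann$models), function(i) {
    m <- ann$models[[i]]
    render_structure(m, ann$introns[ann$introns$gene_id == m$gene_id, ,
                                    drop = FALSE],
                     ann$annots[[m$gene_id]], format = format)
  }, "")
  names(diagrams) <- vapply(ann$models, function(m) m$gene_id, "")
  report <- list(
    provenance = list(
      package = "intronsig",
      version = as.character(utils::packageVersion("intronsig")),
      inputs = list(annotation = annotation_path,
                    precursors = annotations_path,
                    fasta = fasta_path, promoters = promoter_fasta,
                    motifs = motif_tsv),
      window = as.integer(window), n_perm = as.integer(n_perm),
      seed = as.integer(seed), reference = reference$label,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    boundary = list(calls = ann$calls,
                    summary = unclass(ann$summary)),
    phase_distribution = unclass(dist),
    enrichment = list(method = enr$method, statistic = enr$statistic,
                      p_value = enr$p_value, df = enr$df,
                      reference = as.list(enr$reference$p)),
    permutation = list(observed = perm$observed, null_mean = perm$null_mean,
                       p_value = perm$p_value, n_perm = perm$n_perm,
                       seed = perm$seed, window = perm$window),
    motifs = motifs_sec,
    promoters = promoter_sec,
    diagrams = as.list(diagrams)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE, force = TRUE)
    if (format == "svg") {
      writeLines(paste(diagrams, collapse = "\n"),
                 file.path(out_dir, "diagrams.svg"))
    }
  }
  invisible(report)
}
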