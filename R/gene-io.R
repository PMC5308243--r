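#' Load gene models from a GFF3 or GenBank annotation
#'
#' Reads gene/mRNA/exon/CDS features and assembles one [gene_model()] per
#' selected transcript. GFF3 coordinates (1-based inclusive) and GenBank
#' locations are converted to the package's internal 0-based half-open
#' convention at this boundary; minus-strand exon lists are reversed into
#' transcript (5'->3') orientation. Models whose CDS length is not a multiple
#' of 3 are flagged incomplete but kept.
#'
#' @param annotation_path path to a GFF3 file (`.gff`, `.gff3`) or GenBank
#'   flat file (`.gb`, `.gbk`, `.genbank`).
#' @param fasta_path optional FASTA with the locus sequences; sequences are
#'   attached to models by `seq_id`.
#' @param transcripts `"longest"` (default) keeps, per gene, the transcript
#'   with the longest CDS; `"all"` keeps every transcript.
#' @return list of [gene_model()] objects.
#' @export
load_gene_models <- function(annotation_path, fasta_path = NULL,
                             transcripts = c("longest", "all")) {
  transcripts <- match.arg(transcripts)
  ext <- tolower(tools::file_ext(annotation_path))
  models <- if (ext %in% c("gb", "gbk", "genbank")) {
    load_genbank_models(annotation_path)
  } else {
    load_gff3_models(annotation_path)
  }
  if (transcripts == "longest") {
    by_gene <- split(models, vapply(models, function(m) m$gene_id, ""))
    models <- lapply(by_gene, function(ms) {
      lens <- vapply(ms, function(m) sum(m$cds$end - m$cds$start), 0)
      ms[[which.max(lens)]]
    })
    models <- unname(models[order(names(by_gene))])
  }
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*", "", names(seqs))
    models <- lapply(models, function(m) {
      if (m$seq_id %in% names(seqs)) {
        m$sequence <- as.character(seqs[[m$seq_id]])
      }
      m
    })
  }
  for (m in models) warn_noncanonical_splice(m)
  models
}

load_gff3_models <- function(path) {
  feats <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("cannot parse GFF3 file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(feats) == 0) return(list())
  type <- as.character(feats$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(feats))) feats$ID else
    rep(NA_character_, length(feats))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(feats))) {
    vapply(as.list(feats$Parent),
           function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else rep(NA_character_, length(feats))

  tx_idx <- which(type %in% c("mRNA", "transcript"))
  cds_idx <- which(type == "CDS")
  if (any(is.na(parents[cds_idx]))) {
    stop("CDS feature without a Parent transcript in '", path, "'")
  }
  # transcripts may be implicit: CDS/exon parented directly by a gene
  tx_ids <- unique(c(ids[tx_idx], setdiff(parents[cds_idx], ids[tx_idx])))
  tx_ids <- tx_ids[!is.na(tx_ids)]

  models <- list()
  for (tx in tx_ids) {
    sel_exon <- which(type == "exon" & parents == tx)
    sel_cds <- which(type == "CDS" & parents == tx)
    if (length(sel_cds) == 0 && length(sel_exon) == 0) next
    i0 <- c(sel_exon, sel_cds)[1]
    strand <- as.character(BiocGenerics::strand(feats[i0]))
    if (!strand %in% c("+", "-")) {
      stop("unknown strand symbol '", strand, "' for transcript ", tx)
    }
    seq_id <- as.character(GenomicRanges::seqnames(feats[i0]))
    iv <- function(sel) data.frame(
      start = BiocGenerics::start(feats[sel]) - 1L,
      end = BiocGenerics::end(feats[sel])
    )
    exons <- if (length(sel_exon)) iv(sel_exon) else iv(sel_cds)
    # gene id: parent gene of the transcript if present, else the tx id
    tx_row <- which(ids == tx & type %in% c("mRNA", "transcript"))
    gid <- if (length(tx_row) && !is.na(parents[tx_row[1]])) {
      parents[tx_row[1]]
    } else tx
    models[[length(models) + 1]] <- gene_model(
      gene_id = gid, seq_id = seq_id, strand = strand,
      exons = exons, cds = iv(sel_cds)
    )
  }
  models
}

# Minimal GenBank flat-file reader: LOCUS name, exon/CDS FEATURES with
# join()/complement() locations, ORIGIN sequence. Covers single-record files
# with locations on the record itself (no remote accessions).
load_genbank_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  recs <- recs[names(recs) != "0"]
  if (length(recs) == 0) stop("no LOCUS record found in '", path, "'")
  out <- list()
  for (rec in recs) {
    seq_id <- strsplit(trimws(sub("^LOCUS", "", rec[1])), "\\s+")[[1]][1]
    fstart <- grep("^FEATURES", rec)
    ostart <- grep("^ORIGIN", rec)
    if (!length(fstart)) stop("GenBank record ", seq_id, " has no FEATURES")
    fend <- if (length(ostart)) ostart[1] - 1 else length(rec)
    flines <- rec[(fstart[1] + 1):fend]
    sequence <- NULL
    if (length(ostart)) {
      seq_lines <- rec[(ostart[1] + 1):length(rec)]
      seq_lines <- seq_lines[!grepl("^//", seq_lines)]
      sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    }
    feats <- parse_genbank_features(flines, seq_id)
    cds <- feats[vapply(feats, function(f) f$key == "CDS", TRUE)]
    exons <- feats[vapply(feats, function(f) f$key == "exon", TRUE)]
    for (f in cds) {
      gid <- f$qualifiers[["gene"]] %||% f$qualifiers[["locus_tag"]] %||% seq_id
      ex <- exons[vapply(exons, function(e)
        identical(e$qualifiers[["gene"]] %||% e$qualifiers[["locus_tag"]] %||%
                    seq_id, gid), TRUE)]
      exon_iv <- if (length(ex)) {
        do.call(rbind, lapply(ex, function(e) e$intervals))
      } else f$intervals
      out[[length(out) + 1]] <- gene_model(
        gene_id = gid, seq_id = seq_id, strand = f$strand,
        exons = exon_iv, cds = f$intervals, sequence = sequence
      )
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_genbank_features <- function(flines, seq_id) {
  key_re <- "^ {5}(\\S+) +(.*)$"
  feats <- list()
  cur <- NULL
  for (ln in flines) {
    if (grepl(key_re, ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
      cur <- list(key = sub(key_re, "\\1", ln),
                  loc = sub(key_re, "\\2", ln), quals = character(0))
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (length(cur$quals) == 0) cur$loc <- paste0(cur$loc, txt)
      else cur$quals[length(cur$quals)] <- paste0(cur$quals[length(cur$quals)], txt)
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
  lapply(feats, function(f) {
    loc <- gsub("\\s", "", f$loc)
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    inner <- gsub("^complement\\(|^join\\(|\\)+$", "", gsub("join\\(", "", loc))
    parts <- strsplit(inner, ",")[[1]]
    m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$|^(\\d+)$", parts))
    iv <- do.call(rbind, lapply(m, function(g) {
      if (length(g) == 0 || g[1] == "") {
        stop("unsupported GenBank location '", loc, "' in record ", seq_id)
      }
      if (g[4] != "") c(as.integer(g[4]) - 1L, as.integer(g[4]))
      else c(as.integer(g[2]) - 1L, as.integer(g[3]))
    }))
    quals <- list()
    qm <- regmatches(f$quals, regexec("^/([A-Za-z_]+)=\"?([^\"]*)\"?$", f$quals))
    for (g in qm) if (length(g) == 3) quals[[g[2]]] <- g[3]
    list(key = f$key, strand = strand,
         intervals = data.frame(start = iv[, 1], end = iv[, 2]),
         qualifiers = quals)
  })
}

warn_noncanonical_splice <- function(model) {
  if (is.null(model$sequence) || nrow(model$exons) < 2) return(invisible())
  introns <- intron_intervals(model)
  for (i in seq_len(nrow(introns))) {
    s <- intron_donor_acceptor_dinucs(model$sequence, introns$start[i],
                                      introns$end[i], model$strand)
    if (!(s[1] == "GT" && s[2] == "AG")) {
      warning("gene ", model$gene_id, ": non-canonical splice sites ",
              s[1], "..", s[2], " at intron ", i, call. = FALSE)
    }
  }
  invisible()
}

intron_donor_acceptor_dinucs <- function(sequence, start, end, strand) {
  seg <- substr(sequence, start + 1, end)
  if (strand == "-") seg <- revcomp(seg)
  c(substr(seg, 1, 2), substr(seg, nchar(seg) - 1, nchar(seg)))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Genomic half-open intervals of the introns, in transcript order.
intron_intervals <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  if (model$strand == "+") {
    data.frame(start = ex$end[-n], end = ex$start[-1])
  } else {
    data.frame(start = ex$end[-1], end = ex$start[-n])
  }
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates the CDS segments in transcript orientation,
#' reverse-complementing minus-strand genes.
#'
#' @param model a [gene_model()] carrying its locus `sequence`.
#' @return coding nucleotide string.
#' @export
spliced_cds <- function(model) {
  if (is.null(model$sequence)) {
    stop("gene ", model$gene_id, ": no sequence attached")
  }
  if (nrow(model$cds) == 0) return("")
  if (max(model$cds$end) > nchar(model$sequence)) {
    stop("gene ", model$gene_id, ": CDS segment outside sequence bounds")
  }
  segs <- substring(model$sequence, model$cds$start + 1, model$cds$end)
  if (model$strand == "-") segs <- vapply(segs, revcomp, "")
  paste(segs, collapse = "")
}

#' Translate a coding sequence
#'
#' Standard genetic code; the trailing stop codon (if any) is removed and an
#' internal stop raises an error naming the offending codon.
#'
#' @param cds coding nucleotide string, length a multiple of 3.
#' @return protein string, one residue per codon.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  }
  if (nchar(cds) == 0) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  n <- nchar(aa)
  stops <- which(strsplit(aa, "")[[1]] == "*")
  internal <- stops[stops < n]
  if (length(internal)) {
    stop("internal stop codon at codon index ", internal[1] - 1L)
  }
  if (length(stops) && stops[length(stops)] == n) aa <- substr(aa, 1, n - 1)
  aa
}

#' Load precursor annotations from TSV or JSON
#'
#' The TSV needs columns `gene_id` and `signal_len`; optional columns
#' `precursor_len`, `propeptide_spans` and `mature_spans` (span lists are
#' written `start-end` in 0-based half-open residue coordinates, multiple
#' spans separated by `;`). A `.json` file holds an array of objects with
#' the same fields, spans as arrays of `[start, end]` pairs.
#'
#' @param path input file.
#' @return named list of [precursor_annotation()] objects (by gene_id).
#' @export
load_precursor_annotations <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    rows <- jsonlite::read_json(path, simplifyVector = FALSE)
    anns <- lapply(rows, function(r) {
      precursor_annotation(
        gene_id = r$gene_id, signal_len = r$signal_len,
        precursor_len = r$precursor_len %||% NA,
        propeptide_spans = spans_from_list(r$propeptide_spans),
        mature_spans = spans_from_list(r$mature_spans)
      )
    })
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("gene_id", "signal_len") %in% names(tab))) {
      stop("annotation table '", path,
           "' must have gene_id and signal_len columns")
    }
    anns <- lapply(seq_len(nrow(tab)), function(i) {
      precursor_annotation(
        gene_id = tab$gene_id[i],
        signal_len = as.integer(tab$signal_len[i]),
        precursor_len = if ("precursor_len" %in% names(tab))
          suppressWarnings(as.integer(tab$precursor_len[i])) else NA,
        propeptide_spans = parse_spans(tab$propeptide_spans[i]),
        mature_spans = parse_spans(tab$mature_spans[i])
      )
    })
  }
  names(anns) <- vapply(anns, function(a) a$gene_id, "")
  anns
}

parse_spans <- function(txt) {
  if (is.null(txt) || length(txt) == 0 || is.na(txt) || !nzchar(txt)) {
    return(NULL)
  }
  parts <- strsplit(strsplit(txt, ";")[[1]], "-")
  data.frame(start = vapply(parts, function(p) as.integer(p[1]), 0L),
             end = vapply(parts, function(p) as.integer(p[2]), 0L))
}

format_spans <- function(s) {
  if (is.null(s) || nrow(s) == 0) return("")
  paste(sprintf("%d-%d", s$start, s$end), collapse = ";")
}

spans_from_list <- function(l) {
  if (is.null(l) || length(l) == 0) return(NULL)
  data.frame(start = vapply(l, function(p) as.integer(p[[1]]), 0L),
             end = vapply(l, function(p) as.integer(p[[2]]), 0L))
}

#' Write precursor annotations as TSV
#' @param annots list of [precursor_annotation()].
#' @param path output path.
#' @export
write_precursor_annotations <- function(annots, path) {
  tab <- data.frame(
    gene_id = vapply(annots, function(a) a$gene_id, ""),
    signal_len = vapply(annots, function(a) a$signal_len, 0L),
    precursor_len = vapply(annots, function(a) a$precursor_len, 0L),
    propeptide_spans = vapply(annots, function(a) format_spans(a$propeptide_spans), ""),
    mature_spans = vapply(annots, function(a) format_spans(a$mature_spans), "")
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based inclusive coordinates)
#' that [load_gene_models()] reads back into an identical model set.
#'
#' @param models list of [gene_model()].
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  grs <- lapply(models, function(m) {
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    cds <- m$cds[order(m$cds$start), , drop = FALSE]
    gid <- m$gene_id
    tid <- paste0(gid, ".t1")
    span <- c(min(ex$start), max(ex$end))
    mk <- function(type, start, end, id = NA, parent = NA, phase = NA) {
      GenomicRanges::GRanges(
        seqnames = m$seq_id,
        ranges = IRanges::IRanges(start = start + 1L, end = end),
        strand = m$strand, type = type,
        ID = id, Parent = ifelse(is.na(parent), NA, parent),
        phase = phase
      )
    }
    # GFF3 CDS phase: bases to skip to reach the next codon start,
    # accumulated in transcript order
    tx <- m$cds
    before <- cumsum(c(0L, tx$end - tx$start))[seq_len(nrow(tx))]
    tx_phase <- (3L - before %% 3L) %% 3L
    cds_phase <- tx_phase[match(paste(cds$start, cds$end),
                                paste(tx$start, tx$end))]
    c(mk("gene", span[1], span[2], id = gid),
      mk("mRNA", span[1], span[2], id = tid, parent = gid),
      mk("exon", ex$start, ex$end, parent = tid),
      mk("CDS", cds$start, cds$end, parent = tid, phase = cds_phase))
  })
  gr <- suppressWarnings(do.call(c, grs))
  p <- gr$Parent
  gr$Parent <- S4Vectors::unname(S4Vectors::splitAsList(
    p[!is.na(p)], factor(which(!is.na(p)), levels = seq_along(gr))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write locus sequences of gene models as FASTA
#' @param models list of [gene_model()] with sequences.
#' @param path output path.
#' @export
write_locus_fasta <- function(models, path) {
  seqs <- vapply(models, function(m) {
    if (is.null(m$sequence)) stop("gene ", m$gene_id, ": no sequence")
    m$sequence
  }, "")
  ids <- vapply(models, function(m) m$seq_id, "")
  keep <- !duplicated(ids)
  x <- Biostrings::DNAStringSet(seqs[keep])
  names(x) <- ids[keep]
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read a tab-separated results table
#'
#' Shared helpers for all tabular outputs; every table the package writes is
#' re-readable with [read_table_tsv()].
#' @param x data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
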