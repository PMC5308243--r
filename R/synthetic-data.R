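SENSE_CODONS <- {
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Specification of one synthetic secretory gene
#'
#' Describes a multi-exon secretory-peptide gene in precursor-residue
#' coordinates: each coding intron is placed at the nucleotide junction
#' `3 * codon + phase` of the CDS, so its phase and interrupted codon are
#' known by construction.
#'
#' @param gene_id gene identifier.
#' @param signal_len signal peptide length (residues).
#' @param precursor_len precursor length (residues, excluding stop).
#' @param introns data.frame with columns `codon` (0-based target codon
#'   index), `phase` (0/1/2) and `length` (nt, >= 8); may have zero rows.
#' @param propeptide_spans,mature_spans optional residue spans (see
#'   [precursor_annotation()]).
#' @param utr5_intron optional `c(offset, length)`: an intron after
#'   `offset` nt of the 5' UTR.
#' @param utr5_len,utr3_len UTR lengths (nt).
#' @param strand `"+"` or `"-"`.
#' @param flank_len genomic flank on each side (nt).
#' @return object of class `synthetic_gene_spec`.
#' @export
synthetic_gene_spec <- function(gene_id, signal_len, precursor_len,
                                introns = data.frame(codon = integer(0),
                                                     phase = integer(0),
                                                     length = integer(0)),
                                propeptide_spans = NULL, mature_spans = NULL,
                                utr5_intron = NULL,
                                utr5_len = 60L, utr3_len = 60L,
                                strand = "+", flank_len = 50L) {
  cds_len <- 3L * (precursor_len + 1L)        # includes the stop codon
  if (nrow(introns)) {
    j <- 3L * introns$codon + introns$phase
    if (any(j <= 0L | j >= cds_len)) {
      stop("gene ", gene_id, ": intron placement outside the CDS")
    }
    if (any(duplicated(j)) || is.unsorted(j, strictly = TRUE)) {
      stop("gene ", gene_id,
           ": intron junctions must be strictly increasing")
    }
    if (any(introns$length < 8L)) {
      stop("gene ", gene_id, ": intron length must be >= 8 nt")
    }
  }
  if (!is.null(utr5_intron) &&
      (utr5_intron[1] <= 0 || utr5_intron[1] >= utr5_len)) {
    stop("gene ", gene_id, ": 5'UTR intron offset outside the UTR")
  }
  structure(
    list(gene_id = gene_id, signal_len = as.integer(signal_len),
         precursor_len = as.integer(precursor_len), introns = introns,
         propeptide_spans = propeptide_spans, mature_spans = mature_spans,
         utr5_intron = utr5_intron, utr5_len = as.integer(utr5_len),
         utr3_len = as.integer(utr3_len), strand = strand,
         flank_len = as.integer(flank_len)),
    class = "synthetic_gene_spec"
  )
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_intron_seq <- function(len) {
  paste0("GT", random_nt(len - 4L), "AG")
}

#' Generate one synthetic gene with full ground truth
#'
#' Samples a random coding sequence (uniform over sense codons, stop TAA),
#' inserts introns with canonical GT..AG termini at the junctions the spec
#' prescribes, adds UTRs and flanks, and (for minus-strand specs)
#' reverse-complements the locus with flipped coordinates. The returned
#' ground truth is what the analysis pipeline must recover.
#'
#' @param spec a [synthetic_gene_spec()].
#' @param seed optional integer; when given the gene is generated from a
#'   private RNG stream and is byte-reproducible.
#' @param window residue half-width used for the truth signature flag
#'   (default 3).
#' @return list with `model` ([gene_model()], sequence attached),
#'   `annotation` ([precursor_annotation()]), `truth` (data.frame: ordinal,
#'   region, phase, interrupted_codon_index, precursor_region,
#'   offset_from_cleavage), `protein`, `signature` (logical).
#' @export
generate_gene <- function(spec, seed = NULL, window = 3L) {
  if (!is.null(seed)) {
    old <- local_rng(as.integer(seed))
    on.exit(restore_rng(old))
  }
  plen <- spec$precursor_len
  codons <- sample(SENSE_CODONS, plen, replace = TRUE)
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  protein <- translate_cds(cds)
  utr5 <- random_nt(spec$utr5_len)
  utr3 <- random_nt(spec$utr3_len)
  transcript <- paste0(utr5, cds, utr3)

  # transcript-coordinate insertion points, ascending
  cuts <- integer(0); ilens <- integer(0); truth_rows <- list()
  if (!is.null(spec$utr5_intron)) {
    cuts <- spec$utr5_intron[1]
    ilens <- spec$utr5_intron[2]
  }
  if (nrow(spec$introns)) {
    j <- 3L * spec$introns$codon + spec$introns$phase
    cuts <- c(cuts, spec$utr5_len + j)
    ilens <- c(ilens, spec$introns$length)
  }
  ord <- order(cuts)
  cuts <- cuts[ord]; ilens <- ilens[ord]

  pieces <- character(0)
  exon_bounds <- list()    # transcript-coordinate [start,end) of each exon
  prev <- 0L
  for (i in seq_along(cuts)) {
    exon_bounds[[i]] <- c(prev, cuts[i])
    prev <- cuts[i]
  }
  exon_bounds[[length(cuts) + 1L]] <- c(prev, nchar(transcript))

  # assemble plus-strand locus and genomic exon coordinates
  flank5 <- random_nt(spec$flank_len)
  locus <- flank5
  exons <- data.frame(start = integer(0), end = integer(0))
  gpos <- nchar(flank5)
  for (i in seq_along(exon_bounds)) {
    b <- exon_bounds[[i]]
    exons <- rbind(exons,
                   data.frame(start = gpos, end = gpos + (b[2] - b[1])))
    locus <- paste0(locus, substr(transcript, b[1] + 1, b[2]))
    gpos <- gpos + (b[2] - b[1])
    if (i <= length(cuts)) {
      locus <- paste0(locus, random_intron_seq(ilens[i]))
      gpos <- gpos + ilens[i]
    }
  }
  locus <- paste0(locus, random_nt(spec$flank_len))

  # CDS occupies transcript [utr5_len, utr5_len + cds_len)
  cds_lo <- spec$utr5_len
  cds_hi <- spec$utr5_len + nchar(cds)
  cdsseg <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_along(exon_bounds)) {
    b <- exon_bounds[[i]]
    lo <- max(b[1], cds_lo); hi <- min(b[2], cds_hi)
    if (lo < hi) {
      off <- exons$start[i] - b[1]
      cdsseg <- rbind(cdsseg, data.frame(start = lo + off, end = hi + off))
    }
  }

  strand <- spec$strand
  if (strand == "-") {
    L <- nchar(locus)
    locus <- revcomp(locus)
    flip <- function(d) data.frame(start = L - d$end, end = L - d$start)
    exons <- flip(exons)
    cdsseg <- flip(cdsseg)
  }
  seq_id <- paste0(spec$gene_id, "_locus")
  model <- gene_model(spec$gene_id, seq_id, strand, exons, cdsseg,
                      sequence = locus, complete = TRUE)
  annot <- precursor_annotation(spec$gene_id, spec$signal_len,
                                precursor_len = plen,
                                propeptide_spans = spec$propeptide_spans,
                                mature_spans = spec$mature_spans)

  truth <- truth_from_spec(spec, annot)
  list(model = model, annotation = annot, truth = truth, protein = protein,
       signature = any(truth$phase == 1L &
                         abs(truth$offset_from_cleavage) <= window,
                       na.rm = TRUE))
}

truth_from_spec <- function(spec, annot) {
  rows <- list()
  if (!is.null(spec$utr5_intron)) {
    rows[[1]] <- data.frame(region = "UTR5", phase = NA_integer_,
                            interrupted_codon_index = NA_integer_,
                            junction = -1L)
  }
  if (nrow(spec$introns)) {
    for (i in seq_len(nrow(spec$introns))) {
      cds_coding_len <- 3L * spec$precursor_len
      j <- 3L * spec$introns$codon[i] + spec$introns$phase[i]
      region <- if (j >= cds_coding_len + 3L) "UTR3" else "CODING"
      rows[[length(rows) + 1]] <- data.frame(
        region = region,
        phase = if (region == "CODING") spec$introns$phase[i] else NA_integer_,
        interrupted_codon_index = if (region == "CODING")
          spec$introns$codon[i] else NA_integer_,
        junction = j)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), ordinal = integer(0),
                      region = character(0), phase = integer(0),
                      interrupted_codon_index = integer(0),
                      precursor_region = character(0),
                      offset_from_cleavage = integer(0)))
  }
  tr <- do.call(rbind, rows)
  tr <- tr[order(tr$junction), , drop = FALSE]    # UTR5 intron sorts first
  coding <- tr$region == "CODING"
  preg <- tr$region
  preg[coding] <- region_of_residue(annot, tr$interrupted_codon_index[coding])
  data.frame(
    gene_id = spec$gene_id,
    ordinal = seq_len(nrow(tr)),
    region = tr$region,
    phase = tr$phase,
    interrupted_codon_index = tr$interrupted_codon_index,
    precursor_region = preg,
    offset_from_cleavage = ifelse(coding,
                                  tr$interrupted_codon_index - annot$signal_len,
                                  NA_integer_)
  )
}

#' Generate a cohort of synthetic secretory genes
#'
#' Builds `n` genes with a known per-gene boundary-signature status. With
#' probability `signature_prob` a gene receives a phase-1 intron whose
#' interrupted codon lies within `window` residues of the cleavage site;
#' its remaining introns (and all introns of non-signature genes) are
#' placed uniformly over the coding junctions with phases drawn from
#' `phase_props` — for non-signature genes the phase-1 junctions inside the
#' window are excluded so the truth flag is exact. With
#' `signature_prob = NA` the cohort is a pure positional null: every
#' intron's junction is drawn uniformly over all `3 * precursor_len - 1`
#' intra-CDS junctions and the phase is whatever the junction induces
#' (`phase_props` is ignored).
#'
#' @param n number of genes.
#' @param signature_prob probability of planting the boundary signature,
#'   or `NA` for the uniform positional null.
#' @param phase_props length-3 phase-0/1/2 probabilities for non-boundary
#'   introns.
#' @param seed integer seed (required; the cohort is reproducible).
#' @param introns_per_gene intron count per gene (recycled).
#' @param precursor_len,signal_len precursor geometry (residues).
#' @param intron_length_range nt range introns are drawn from.
#' @param utr5_prob probability a gene also carries a 5'UTR intron.
#' @param minus_prob probability a gene is on the minus strand.
#' @param window residue half-width defining the boundary (default 3).
#' @param sequences generate full sequences (`TRUE`, default) or only
#'   models-without-sequence plus ground truth (`FALSE`, much faster, for
#'   statistical calibration).
#' @return list of class `synthetic_cohort`: `genes` (per-gene lists as in
#'   [generate_gene()]; with `sequences = FALSE` each entry has `introns`
#'   records instead of a sequence-bearing model), `truth` (row-bound
#'   data.frame), `signature` (logical vector), `seed`.
#' @export
generate_cohort <- function(n, signature_prob = 1, phase_props = c(0.5, 0.3, 0.2),
                            seed, introns_per_gene = 2L,
                            precursor_len = 85L, signal_len = 22L,
                            intron_length_range = c(60L, 2000L),
                            utr5_prob = 0, minus_prob = 0.5,
                            window = 3L, sequences = TRUE) {
  if (missing(seed) || is.na(seed)) stop("seed is required")
  if (n < 1) stop("n must be >= 1")
  old <- local_rng(as.integer(seed))
  on.exit(restore_rng(old))
  phase_props <- phase_props / sum(phase_props)
  k_gene <- rep_len(as.integer(introns_per_gene), n)
  genes <- vector("list", n)
  for (g in seq_len(n)) {
    gid <- sprintf("G%04d", g)
    plen <- precursor_len; slen <- signal_len
    n_junc <- 3L * plen - 1L
    in_window_phase1 <- 3L * (max(0L, slen - window):min(plen - 1L, slen + window)) + 1L
    in_window_phase1 <- in_window_phase1[in_window_phase1 >= 1L &
                                           in_window_phase1 <= n_junc]
    k <- k_gene[g]
    if (is.na(signature_prob)) {
      juncs <- sample.int(n_junc, k)
      planted_sig <- NA
    } else {
      planted_sig <- stats::runif(1) < signature_prob
      juncs <- integer(0)
      if (planted_sig) {
        juncs <- sample(in_window_phase1, 1)
      }
      pool_by_phase <- lapply(0:2, function(p) {
        cand <- seq_len(n_junc)[seq_len(n_junc) %% 3L == p]
        if (!isTRUE(planted_sig)) cand <- setdiff(cand, in_window_phase1)
        cand
      })
      while (length(juncs) < k) {
        p <- sample.int(3L, 1, prob = phase_props) - 1L
        cand <- setdiff(pool_by_phase[[p + 1]], juncs)
        if (length(cand) == 0) next
        juncs <- c(juncs, if (length(cand) == 1) cand else sample(cand, 1))
      }
    }
    juncs <- sort(juncs)
    spec <- synthetic_gene_spec(
      gene_id = gid, signal_len = slen, precursor_len = plen,
      introns = data.frame(
        codon = juncs %/% 3L, phase = juncs %% 3L,
        length = sample(seq(intron_length_range[1], intron_length_range[2]),
                        length(juncs), replace = TRUE)),
      utr5_intron = if (stats::runif(1) < utr5_prob)
        c(sample(10:40, 1), sample(seq(intron_length_range[1],
                                       intron_length_range[2]), 1)),
      strand = if (stats::runif(1) < minus_prob) "-" else "+"
    )
    if (sequences) {
      genes[[g]] <- generate_gene(spec, window = window)
      genes[[g]]$spec <- spec
    } else {
      annot <- precursor_annotation(gid, slen, precursor_len = plen)
      truth <- truth_from_spec(spec, annot)
      genes[[g]] <- list(
        spec = spec, annotation = annot, truth = truth,
        introns = truth_as_records(truth),
        signature = any(truth$phase == 1L &
                          abs(truth$offset_from_cleavage) <= window,
                        na.rm = TRUE))
    }
  }
  truth <- do.call(rbind, lapply(genes, function(g) g$truth))
  structure(
    list(genes = genes, truth = truth,
         signature = vapply(genes, function(g) g$signature, TRUE),
         seed = as.integer(seed), window = as.integer(window)),
    class = "synthetic_cohort"
  )
}

# Minimal intron-record data.frame (as compute_intron_phases would emit)
# from a ground-truth table; used by the fast, sequence-free cohort path.
truth_as_records <- function(truth) {
  data.frame(
    gene_id = truth$gene_id, ordinal = truth$ordinal,
    donor = NA_integer_, acceptor = NA_integer_, length = NA_integer_,
    region = truth$region,
    upstream_coding_nt = ifelse(truth$region == "CODING",
                                3L * truth$interrupted_codon_index +
                                  truth$phase, NA_integer_),
    phase = truth$phase,
    interrupted_codon_index = truth$interrupted_codon_index
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$genes), " genes, ",
      sum(x$signature), " with boundary signature (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic cohort to standard files
#'
#' Emits `loci.fa` (locus FASTA), `genes.gff3`, `precursors.tsv` and
#' `truth.json` into a directory; the first three are read back by
#' [load_gene_models()] and [load_precursor_annotations()].
#'
#' @param cohort a [generate_cohort()] result (with sequences), or any list
#'   of [generate_gene()] results in `cohort$genes`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- lapply(cohort$genes, function(g) g$model)
  write_locus_fasta(models, file.path(dir, "loci.fa"))
  write_gff3(models, file.path(dir, "genes.gff3"))
  write_precursor_annotations(lapply(cohort$genes, function(g) g$annotation),
                              file.path(dir, "precursors.tsv"))
  truth <- lapply(cohort$genes, function(g) {
    list(gene_id = g$annotation$gene_id, protein = g$protein,
         signature = g$signature, introns = g$truth)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Generate synthetic promoters with a planted regulatory module
#'
#' Embeds a module of IUPAC motifs (one concrete site per motif, random
#' position and strand, non-overlapping) into `n - outlier_count`
#' promoters; the remaining outliers — stand-ins for housekeeping promoters
#' — receive the module minus its key motif(s).
#'
#' @param n number of promoters (>= 2).
#' @param module data.frame with `motif_id`, `pattern`; defaults to
#'   [example_module()].
#' @param outlier_count number of promoters lacking the key motif(s).
#' @param key_motifs motif_ids withheld from outliers (default: the first).
#' @param length promoter length (nt).
#' @param seed integer seed (required).
#' @return list of class `synthetic_promoters`: `sequences` (named
#'   character), `planted` (data.frame promoter_id, motif_id, start,
#'   strand, site), `outliers` (promoter ids).
#' @export
generate_promoters <- function(n, module = example_module(),
                               outlier_count = 1L,
                               key_motifs = module$motif_id[1],
                               length = 600L, seed) {
  if (missing(seed) || is.na(seed)) stop("seed is required")
  if (n < 2) stop("n must be >= 2")
  if (outlier_count >= n) stop("outlier_count must be < n")
  old <- local_rng(as.integer(seed))
  on.exit(restore_rng(old))
  ids <- sprintf("P%02d", seq_len(n))
  outliers <- if (outlier_count > 0) ids[seq_len(outlier_count)] else character(0)
  seqs <- character(0); planted <- list()
  for (id in ids) {
    seqc <- strsplit(random_nt(length), "")[[1]]
    motifs <- module
    if (id %in% outliers) {
      motifs <- motifs[!motifs$motif_id %in% key_motifs, , drop = FALSE]
    }
    used <- logical(length)
    for (i in seq_len(nrow(motifs))) {
      site <- instantiate_iupac(motifs$pattern[i])
      strand <- sample(c("+", "-"), 1)
      emb <- if (strand == "+") site else revcomp(site)
      w <- nchar(emb)
      repeat {
        s <- sample.int(length - w + 1L, 1)
        if (!any(used[s:(s + w - 1)])) break
      }
      seqc[s:(s + w - 1)] <- strsplit(emb, "")[[1]]
      used[s:(s + w - 1)] <- TRUE
      planted[[length(planted) + 1]] <- data.frame(
        promoter_id = id, motif_id = motifs$motif_id[i],
        start = s - 1L, strand = strand, site = site)
    }
    seqs[id] <- paste(seqc, collapse = "")
  }
  structure(
    list(sequences = seqs, planted = do.call(rbind, planted),
         outliers = outliers, seed = as.integer(seed)),
    class = "synthetic_promoters"
  )
}

# One concrete realisation of an IUPAC pattern.
instantiate_iupac <- function(pattern) {
  pattern <- validate_iupac(pattern)
  paste(vapply(strsplit(pattern, "")[[1]], function(l) {
    opts <- setdiff(IUPAC_SETS[[l]], "N")
    if (length(opts) == 1) opts else sample(opts, 1)
  }, ""), collapse = "")
}

#' Illustrative promoter module
#'
#' A small example module used by [generate_promoters()] and the package
#' examples: a C/EBP-family-like core site plus two generic venom-gland
#' module motifs. Illustrative only — not a curated transcription-factor
#' motif set.
#'
#' @return data.frame with `motif_id`, `pattern`.
#' @export
example_module <- function() {
  data.frame(
    motif_id = c("CEBP_like", "VG_module_A", "VG_module_B"),
    pattern = c("ATTGCGCAAT", "TGASTCAGCA", "CWTATAAAAG")
  )
}

#' Write promoter sequences as FASTA
#' @param promoters a [generate_promoters()] result or named character
#'   vector of sequences.
#' @param path output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- if (inherits(promoters, "synthetic_promoters")) {
    promoters$sequences
  } else promoters
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
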