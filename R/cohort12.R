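#' Specifications of the packaged 12-gene demonstration cohort
#'
#' Twelve synthetic secretory-peptide genes whose exon-intron topologies
#' emulate the documented gene families of scorpion venom components:
#' five CSab-fold toxin genes (including one with a second phase-1 intron in
#' the mature region and two with an additional 5'UTR intron), three ICK
#' genes (short phase-1 intron inside the propeptide adjacent to the signal
#' peptide plus a phase-2 intron at the mature N-terminus), one alpha-helical
#' antimicrobial peptide gene with signal-mature-propeptide precursor order,
#' two chymotrypsin-like protease genes with multiple phase-0/1/2 introns in
#' the mature region, and one Kunitz-type protease-inhibitor gene. Every
#' gene carries a phase-1 intron within 3 residues of the signal-peptide
#' cleavage site. Sequences are synthetic; only the topologies are modelled
#' on the real families.
#'
#' @return named list of [synthetic_gene_spec()] objects.
#' @export
venom_cohort_specs <- function() {
  iv <- function(codon, phase, length) data.frame(codon = codon,
                                                  phase = phase,
                                                  length = length)
  sp <- function(start, end) data.frame(start = start, end = end)
  specs <- list(
    # CSab fold: sodium / potassium / chloride channel toxins, defensin
    synthetic_gene_spec("CSAB_NaTx1", signal_len = 19, precursor_len = 85,
                        introns = iv(19, 1, 90)),
    synthetic_gene_spec("CSAB_KTx1", signal_len = 22, precursor_len = 60,
                        introns = iv(22, 1, 75), strand = "-"),
    synthetic_gene_spec("CSAB_KTxB", signal_len = 21, precursor_len = 90,
                        introns = iv(c(21, 60), c(1, 1), c(80, 110))),
    synthetic_gene_spec("CSAB_KTx_UTR", signal_len = 28, precursor_len = 56,
                        introns = iv(28, 1, 85), utr5_intron = c(25, 70)),
    synthetic_gene_spec("CSAB_DFN_UTR", signal_len = 23, precursor_len = 80,
                        introns = iv(23, 1, 100), utr5_intron = c(20, 95),
                        strand = "-"),
    # ICK fold: propeptide-internal phase-1 intron + mature phase-2 intron
    synthetic_gene_spec("ICK_KTx1", signal_len = 24, precursor_len = 96,
                        propeptide_spans = sp(24, 30),
                        mature_spans = sp(30, 96),
                        introns = iv(c(26, 34), c(1, 2), c(65, 140))),
    synthetic_gene_spec("ICK_CAL1", signal_len = 22, precursor_len = 92,
                        propeptide_spans = sp(22, 28),
                        mature_spans = sp(28, 92),
                        introns = iv(c(24, 31), c(1, 2), c(70, 120)),
                        strand = "-"),
    synthetic_gene_spec("ICK_CAL2", signal_len = 23, precursor_len = 95,
                        propeptide_spans = sp(23, 29),
                        mature_spans = sp(29, 95),
                        introns = iv(c(25, 33), c(1, 2), c(60, 150))),
    # alpha-helical AMP: signal - mature - C-terminal propeptide
    synthetic_gene_spec("AMP_Kn1", signal_len = 23, precursor_len = 58,
                        mature_spans = sp(23, 36),
                        propeptide_spans = sp(36, 58),
                        introns = iv(23, 1, 72)),
    # chymotrypsin-like proteases: multi-intron mature regions
    synthetic_gene_spec("PROT_ChTP1", signal_len = 18, precursor_len = 150,
                        introns = iv(c(18, 50, 80, 110), c(1, 0, 1, 2),
                                     c(88, 120, 95, 70))),
    synthetic_gene_spec("PROT_ChTP2", signal_len = 20, precursor_len = 150,
                        introns = iv(c(19, 60, 95), c(1, 0, 2),
                                     c(90, 100, 110)), strand = "-"),
    # Kunitz-type protease inhibitor
    synthetic_gene_spec("KUNITZ_PI1", signal_len = 21, precursor_len = 81,
                        introns = iv(c(20, 50), c(1, 1), c(78, 92)))
  )
  names(specs) <- vapply(specs, function(s) s$gene_id, "")
  specs
}

#' Generate the packaged demonstration cohort in memory
#'
#' @param seed integer seed (default 20161226, the seed used to build the
#'   files shipped under `inst/extdata/cohort12/`).
#' @return a `synthetic_cohort`-like list (see [generate_cohort()]).
#' @export
venom_cohort <- function(seed = 20161226L) {
  old <- local_rng(as.integer(seed))
  on.exit(restore_rng(old))
  genes <- lapply(venom_cohort_specs(), function(s) {
    g <- generate_gene(s)
    g$spec <- s
    g
  })
  structure(
    list(genes = unname(genes),
         truth = do.call(rbind, lapply(genes, function(g) g$truth)),
         signature = vapply(genes, function(g) g$signature, TRUE),
         seed = as.integer(seed), window = 3L),
    class = "synthetic_cohort"
  )
}

#' Path to the packaged demonstration cohort files
#' @return directory containing `loci.fa`, `genes.gff3`, `precursors.tsv`,
#'   `truth.json`.
#' @export
cohort12_path <- function() {
  system.file("extdata", "cohort12", package = "intronsig", mustWork = TRUE)
}
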