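# intronsig

Intron phase architecture and exon-shuffling signatures in secretory
peptide genes.

## The problem

Secreted peptides — scorpion venom neurotoxins, antimicrobial peptides,
venom proteases and protease inhibitors are the motivating examples — are
made as precursors: a signal peptide (SP), optionally a propeptide (PP),
and the mature peptide (MP). Introns interrupt the reading frame in one of
three ways: a **phase-0** intron falls between codons, a **phase-1** intron
between the first and second nucleotide of a codon, and a **phase-2**
intron between the second and third (phase = *L* mod 3, where *L* is the
number of coding nucleotides 5′ of the intron). Genes assembled by exon
shuffling from a signal-bearing donor exon are expected to keep a
**phase-1 intron near the signal-peptide cleavage site**, because only
phase-compatible junctions preserve frame. `intronsig` turns that
observation into a tested pipeline for anyone analysing the gene
architecture of secretory protein families:

* assemble gene models from GFF3/GenBank + FASTA, splice and translate;
* classify every intron by phase and map it onto precursor residue
  coordinates (SP/PP/MP), reporting the signed offset from the cleavage
  site;
* call the **boundary signature** per gene: a phase-1 intron with
  |offset| ≤ *w* residues (default *w* = 3);
* test phase-frequency bias against literature reference proportions
  (non-secretory human ≈ 50/30/20, secretory human 49.9/31.36/18.8 for
  phases 0/1/2) with an exact multinomial test (chi-square for large
  counts), and test boundary clustering with a permutation test whose null
  redraws each intron's insertion junction uniformly over the
  3·*L*<sub>precursor</sub> − 1 intra-CDS junctions;
* annotate peptide scaffolds: the inhibitor cystine knot (ICK) consensus
  `C X6 C X4 D C C X{2-4} [KR] C X3 G X{4-6} C [KR]` with knot
  connectivity C1–C4, C2–C5, C3–C6 and macrocycle ring size
  (pos C2 − pos C1 + 1) + (pos C5 − pos C4 + 1) ∈ {13, 14, 15}, and the
  CSαβ-fold CX₃C/CXC motif pair;
* scan promoters for shared IUPAC-consensus regulatory modules and score
  pairwise module sharing (Jaccard);
* generate fully ground-truthed synthetic gene cohorts, so every stage is
  testable without downloads, and render text/SVG gene-structure diagrams.

## Worked example

The package ships a 12-gene synthetic cohort whose topologies emulate the
documented venom gene families (five CSαβ toxins, three ICK toxins, one
α-helical AMP, two proteases, one Kunitz inhibitor):

```r
library(intronsig)
d <- cohort12_path()
res <- run_annotate(file.path(d, "genes.gff3"),
                    file.path(d, "precursors.tsv"),
                    file.path(d, "loci.fa"), window = 3)
print(res$summary)
#> Boundary phase-1 signature: 12/12 genes (fraction 1)

head(res$introns[, c("gene_id", "region", "phase", "precursor_region",
                     "offset_from_cleavage")], 3)
#>        gene_id region phase precursor_region offset_from_cleavage
#> 1      AMP_Kn1 CODING     1           MATURE                    0
#> 2 CSAB_DFN_UTR   UTR5    NA             UTR5                   NA
#> 3 CSAB_DFN_UTR CODING     1           MATURE                    0

dist <- phase_distribution(res$introns)
print(dist)
#> Intron phases: phase-0 2, phase-1 15, phase-2 5 (2 UTR)
#>   proportions: 0.091 / 0.682 / 0.227
```

Phase-1 introns dominate (15 of 22 coding introns), and every gene has one
at the cleavage boundary. Is that compatible with genes that are *not*
secretory? The exact multinomial test against the non-secretory reference
says no, and the permutation test shows the boundary clustering is far
beyond what uniform intron placement produces (null mean 0.54 of 12 genes):

```r
print(phase_enrichment_test(dist, reference_proportions("nonsecretory_human")))
#> Phase enrichment vs nonsecretory_human (0.500/0.300/0.200)
#>   counts 2/15/5, method exact_multinomial, p = 4.646e-05

genes <- lapply(res$models, function(m)
  list(introns = res$introns[res$introns$gene_id == m$gene_id, ],
       annot = res$annots[[m$gene_id]]))
print(boundary_permutation_test(genes, window = 3, n_perm = 10000, seed = 42))
#> Boundary-signature permutation test (window 3, 10000 permutations, seed 42)
#>   observed 12/12 genes; null mean 0.5357; p = 9.999e-05

cat(render_structure(res$models[[1]],
                     res$introns[res$introns$gene_id == "AMP_Kn1", ],
                     res$annots[["AMP_Kn1"]]))
#> [SP]--i(1)--[MP][PP]
```

Scaffold annotation on a consensus-conforming ICK peptide:

```r
match_ick_consensus("GSCAGKRSACQLSSDCCSHEKCYGTGAKDESCRIF")[,
  c("start", "c1", "c4", "c5", "ring_size", "connectivity")]
#>   start c1 c4 c5 ring_size connectivity
#> 1     2  2 16 21        14  1-4,2-5,3-6
```

A thin CLI wraps the same functions
(`inst/cli/intronsig annotate|enrich|permtest|motif|promoter|simulate|diagram|report`).

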