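---
title: "Intron phase architecture of secretory peptide genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron phase architecture of secretory peptide genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronsig)
```

## The model

A eukaryotic gene is a sequence of exons separated by introns. Relative to
the reading frame an intron is **phase 0** (between codons), **phase 1**
(between the first and second nucleotide of a codon) or **phase 2**
(between the second and third). Writing $L$ for the number of coding
nucleotides strictly 5′ of an intron, the phase is $L \bmod 3$ and the
codon the intron interrupts has 0-based index $\lfloor L/3 \rfloor$ (for a
phase-0 intron this is the codon immediately 3′, which keeps positional
offsets comparable across phases). Introns with $L = 0$ lie entirely in the
5′ UTR, those with $L$ equal to the full CDS length in the 3′ UTR; both get
phase `NA` and are excluded from phase statistics but kept in records and
diagrams.

Secretory proteins are translated as precursors: signal peptide (SP, length
$s$ residues), optional propeptide (PP) and mature peptide (MP) segments.
Mapping an intron's interrupted codon index $c$ onto this partition gives
its precursor region and its signed offset from the signal-peptide cleavage
site, $c - s$ (negative inside the signal peptide). The **boundary
signature** of a gene is a phase-1 intron with $|c - s| \le w$. Exon
shuffling predicts this signature: a donor exon carrying promoter and
signal sequence can only be joined in frame to an unrelated mature-peptide
exon through phase-compatible (here phase-1/phase-1) junctions, so genes
recruited this way retain a phase-1 intron at the SP boundary however
different their mature peptides are.

### Assumptions

* Annotations (exon/CDS structure, SP/PP/MP partition) are inputs; the
  package performs no gene prediction and no signal-peptide prediction.
* Standard nuclear genetic code; one analysed transcript per gene (by
  default the one with the longest CDS).
* Internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
  GenBank locations are converted at the I/O boundary only, which confines
  off-by-one risk to two code paths that the round-trip tests cover.
* An intron split across a codon is attributed to that one codon; there are
  no fractional positions.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window` ($w$) | 3 | residues | The documented venom gene families place the signature intron at the signal end or a couple of residues inside the adjacent propeptide; $w=3$ covers both while staying local. No canonical value exists, so every intron's offset is always reported and any other window can be applied post hoc. Widening $w$ can only turn calls from false to true (tested monotonicity). |
| `exact_max` | 30 | introns | Below this total the exact multinomial test enumerates all $\binom{n+2}{2}$ outcome triples; at paper-scale gene counts (tens of introns) exactness is cheap and preferable to the asymptotic chi-square. |
| `n_perm` | 10000 | permutations | Add-one estimator $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$ avoids $p = 0$; 10000 resolves $p \approx 10^{-4}$. |
| reference proportions | non-secretory human (0.50/0.30/0.20) | — | Literature phase-0/1/2 frequencies for human proteins without a signal peptide; `secretory_human` (0.499/0.3136/0.188, renormalised to sum 1) is the secretory counterpart. Both are literature values used as nulls, never recomputed from proteome data. |
| intron length | 60–2000 | nt | Generator default; spans the size variety typical of these compact venom loci without asserting real values. |

## Statistical procedures

**Exact multinomial test.** The p-value is the total probability of all
outcome triples whose probability does not exceed the observed one
(two-sided by outcome ordering; direction is read off the reported counts).
Floating-point ties are admitted with a relative tolerance of $10^{-7}$ so
that outcomes with mathematically equal probability land on the same side
regardless of summation order. The tests verify agreement with independent
enumeration oracles to $10^{-12}$ for every outcome with $n \le 12$. The
chi-square path (df = 2) takes over above `exact_max`; its agreement with
the exact path is asymptotic — about 0.1 absolute at $n = 30$ and within
0.02 by $n = 300$ on draws from the reference — which is why the switch
point keeps the exact path for small samples rather than relying on the
approximation.

**Permutation test for boundary clustering.** The null hypothesis is that
introns fall uniformly over the $3L_{prec} - 1$ intra-CDS nucleotide
junctions, with phase induced by the junction; each gene keeps its intron
count. This randomises position and phase jointly, because the hypothesis
under test — phase-1 excess *at the boundary* — is a joint property. The
statistic is the number of genes whose signature call is true. To make the
p-value independent of input order, each gene's null junctions come from an
RNG stream seeded deterministically by (global seed, hash of gene id); the
global seed is a required, logged argument.

**Calibration design.** The suite checks the test's size on 500
independent uniform-null cohorts at $\alpha = 0.05$. Because the count
statistic is discrete, an exact permutation test is conservative, and the
cohort geometry controls how close the attainable size gets to the nominal
level. The shipped calibration uses 80 genes per cohort, 40-residue
precursors with a 20-residue signal peptide, 4 introns per gene and 199
permutations: a binomial model of the null count, smoothed over the
finite-permutation p estimate, puts the expected rejection rate at 0.044
under these conditions, within the acceptance band while staying at gene
sizes a compact secretory peptide could plausibly have. These sizes were
fixed from that design calculation, not adjusted afterwards.

## Scaffold motifs

The ICK matcher implements the consensus
`C X6 C X4 D C C X{2-4} [KR] C X3 G X{4-6} C [KR]` strictly: `X` is any
residue, the aspartate before C3 and the basic residues are required
exactly (a consensus, not a profile). Matching is non-overlapping and
leftmost-first (venom ICK peptides are short and single-domain); a flag
enables overlapped scanning. Where a matched substring admits several
spacer decompositions, the greedy leftmost parse names the cysteines — the
alternative decompositions exist only when spacers happen to contain
C/G/K/R, and the matched span itself is identical. **Ring size** is read as
the two backbone segments C1..C2 and C4..C5 (cysteines included) closed by
the C1–C4 and C2–C5 disulfides:
$(pos_{C2} - pos_{C1} + 1) + (pos_{C5} - pos_{C4} + 1)$. This is the unique
reading under which the consensus yields exactly 13–15 residues — the
published range — as the tests re-derive by enumerating all nine
spacer-length combinations. Only the C4–C5 spacer varies the ring; the
C5–C6 spacer is outside the macrocycle (the C3–C6 bridge threads it). The
CSαβ report lists all (overlapping) CX₃C and CXC occurrences and flags the
fold-order pair: a CX₃C ending strictly before a CXC starts, since the two
motifs use distinct cysteines.

## Promoter module scanning

Motifs are IUPAC consensi scanned on both strands with degeneracy on the
motif side only: an `N` in the promoter is an undetermined base that
matches nothing except a motif `N`. This is deliberately asymmetric —
treating promoter `N` as a wildcard would fabricate shared sites from
missing data. Module sharing is binary presence per (promoter, motif)
summarised by the Jaccard index; hit counts are ignored because the
comparison at stake is the presence or absence of key sites, not site
multiplicity. The shipped motif file is an illustrative example, not a
curated transcription-factor set: which site definitions produced the
original promoter-module observation is not public, so the scanner takes
user-supplied consensi.

## The synthetic-data generator

The generator is the package's substitute for gene sets that exist only as
published figures: it emits loci (FASTA), annotations (GFF3), precursor
partitions (TSV) and a ground-truth JSON that the pipeline must reproduce
exactly. What it models: multi-exon secretory genes with prescribed intron
junctions $3c + \text{phase}$, canonical `GT..AG` termini, UTR introns,
both strands (minus-strand loci are reverse-complemented with flipped
coordinates), cohorts with a planted signature probability, phase
proportions for non-boundary introns, and a pure positional null
(`signature_prob = NA`) for calibration. In signature cohorts the
non-signature genes exclude in-window phase-1 junctions so the planted flag
is exact rather than approximate. What it does not model: codon usage and
base composition (codons are uniform over the 61 sense codons), realistic
hydrophobic signal peptides (no pipeline stage reads residue chemistry),
splice-site strength beyond the GT..AG dinucleotides, and evolutionary
history (duplication or shuffling events are not simulated). Passing tests
therefore demonstrate coordinate, phase and statistical correctness — not
that the package's calls are robust to annotation errors in real genomes,
which remain the user's responsibility.

The packaged `cohort12` fixture (regenerable via `scripts/make_fixtures.R`,
seed 20161226) instantiates the documented family topologies: five
CSαβ-type genes — signature intron at the signal end, one gene with a
second phase-1 intron deep in the mature region, two with an extra 5′UTR
intron — three ICK-type genes with a short phase-1 intron inside the
propeptide adjacent to the signal peptide plus a phase-2 intron at the
mature N-terminus, one α-helical AMP gene with SP–MP–PP precursor order,
two protease genes with phase-0/1/2 introns across the mature region, and
one Kunitz-type inhibitor gene.

## Numerical and degenerate-input choices

* Boundary-call ties (several qualifying introns) resolve to the smallest
  |offset|, then the smallest ordinal — deterministic and 5′-biased.
* Zero-probability reference class with a positive count: exact $p = 0$
  with a warning rather than an error.
* Genes whose CDS length is not a multiple of 3 are flagged incomplete but
  kept; non-canonical splice dinucleotides warn and never error, so
  imperfect annotations stay loadable.
* Jaccard of two motif-free promoters is `NA` (0/0), not 0.
* Abutting exons (zero-length introns) and overlapping exons/spans are
  validation errors at model construction.
* All randomised results (generator, permutation test, report) require an
  explicit seed, which is recorded in the output.

## Problem sizes used by the test suite

Unit and property tests run at small fuzz scales (tens of genes); the
deeper checks use 1000 random genes for phase-oracle equivalence, every
outcome triple with $n \le 12$ for exact-test enumeration, and 500 cohorts
of 80 genes for permutation calibration. These sizes give the oracles and
binomial bounds comfortable resolution while keeping the default test run
to a few minutes.

## Known limitations

* One transcript per gene; trans-splicing, seleno-proteins and non-standard
  codes are out of scope.
* The GenBank reader covers single-record flat files with
  `join`/`complement` locations — the common export shape for these loci —
  not the full location grammar.
* The exact multinomial test enumerates three categories only (the three
  phases); it is not a general multinomial machine.
* The ICK matcher is strict; natural members that deviate from the
  consensus at the D or basic positions will not match unless the user
  supplies a relaxed pattern.
* Reference phase proportions are literature values; the package makes no
  attempt to recompute them from proteome data.
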