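---
title: "Orphan-gene discovery and characterization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orphan-gene discovery and characterization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Orphan genes (OGs) are protein-coding genes with no detectable homolog
outside their own species or lineage. Identifying them is a *negative*
inference: a gene is an orphan because an ordered series of homology
searches against progressively broader reference databases all come back
empty. `orphanforge` implements that inference as a reproducible pipeline —
a homology-filter cascade, structural characterization of the resulting
OG/NOG partition, classification of the evolutionary mechanism that created
each orphan, and expression-based function inference — together with a
synthetic-data generator that plants known orphans, duplicates, TE-derived,
overlap and de novo cases so every stage can be validated against ground
truth without any external database.

## The homology engine

All homology rules reduce to local alignment with an E-value. The engine is
a seed-and-extend search: exact word matches (3-mers for protein, 11-mers
for nucleotide) are binned by alignment diagonal, and a record is extended
only when two non-overlapping words fall on one diagonal within 40 query
positions — the classic two-hit heuristic. Extension runs a full
Smith–Waterman/Gotoh affine-gap DP (BLOSUM62 with gap open/extend 11/1 for
protein; +1/−2 with 5/2 for nucleotide) on a subject window spanning the
seeded diagonals, so chromosome-length subjects stay cheap. Significance
uses the Karlin–Altschul formula

$$E = K \, m \, n \, e^{-\lambda S}$$

with the standard gapped parameter sets (λ = 0.267, K = 0.041 for BLOSUM62;
λ = 1.28, K = 0.46 for +1/−2). Edge-effect and length-adjustment
corrections are deliberately omitted: at the scale this package targets,
cascade decisions are threshold decisions on planted strong-versus-absent
homology, and the uncorrected formula separates those regimes by many
orders of magnitude. The aligner itself is held to a brute-force DP oracle
in the test suite; translated (six-frame) searches report hits in frame
coordinates. The engine is pluggable: `read_tabular_hits()` ingests
12-column tabular output so a production search tool can stand in at real
scale.

A sensitivity floor matters more than BLAST bit-compatibility here: any
pair with ungapped identity ≥ 70% over ≥ 50 columns must be found, because
the cascade's correctness on synthetic panels is defined against planted
homologs at ≥ 70% identity. The two-hit rule retains that floor (at 70%
identity the expected number of non-overlapping on-diagonal 3-mer pairs
within 40 positions is far above one) while rejecting almost all random
pairs.

## The cascade

`run_cascade()` searches each protein against an ordered panel of
databases and eliminates it at the first stage with a hit at E ≤ 1e-5
(inclusive at equality; the boundary choice is documented because the
original rule is stated as a strict inequality on significance, not on the
boundary). Survivors of all stages are OGs. Two properties follow from the
"hit anywhere" semantics and are tested: permuting database order never
changes the OG set, and adding a database can only shrink it. Records from
the query species itself can be excluded by id pattern so a panel built
from whole proteome files never eliminates a gene through its own entry.

## Structural characterization

Per gene: protein length (stop excluded), exon count, mean exon length
(mean of genomic exon lengths per gene; the pooled-exon alternative is a
defensible reading and is noted in the output metadata), GC content of the
CDS (gene-body GC is the other candidate; CDS was chosen because the
OG/NOG contrast, not the absolute value, is the object of interest), and
isoelectric point. The pI solves net charge = 0 by bisection on [0, 14]
with the EMBOSS pK set (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5,
D 3.9, E 4.1, C 8.5, Y 10.1). Group contrasts use the Wilcoxon rank-sum
test: exact by enumeration when the pooled sample has at most 10 untied
values, otherwise the tie-corrected normal approximation with continuity
correction. The exact path exists because the normal approximation is
demonstrably off by up to ~0.04 at extreme splits of 10 values; at the
sizes where the approximation engages (n ≥ 20 in practice) it tracks
enumeration within 0.02.

Chromosome distribution summaries count genes and OGs in fixed windows;
"near the telomere" is defined as the outer 10% of each chromosome arm —
the source analyses report the qualitative enrichment without defining the
region, so the fraction is a parameter.

## Origin classification

Each orphan receives exactly one mechanism, tested in the precedence order
**duplication > overlap > TE > de novo > unclassified**. The order follows
the narrative order in which the mechanisms are usually tested; it matters
because a TE-derived duplicate would otherwise be double-counted, and the
sources do not state how multi-mechanism genes are labelled.

* **Duplication** — reciprocal within-genome protein hits at E ≤ 1e-8; each
  gene keeps its best-scoring partner. Modes, in their own precedence:
  WGD (the pair anchors a collinear block: a DP chain of anchor pairs with
  strictly increasing ranks on both axes — or decreasing on one for
  inverted blocks — rank gaps ≤ 25, at least 5 anchors), tandem (adjacent
  gene ranks), proximal (rank distance 2–10), transposed (exactly one
  member inside the focal span of a focal-versus-outgroup collinear block;
  evaluated only when an outgroup genome is supplied, otherwise such pairs
  fall through to dispersed and the limitation is reported), dispersed
  (remainder).
* **Gene overlap** — union coverage of the orphan CDS by nucleotide hits
  (E ≤ 1e-5) against other-species CDS reaches 50%. Coverage unions query
  spans across hits, so two partial alignments accumulate.
* **TE exaptation** — any nucleotide hit at E ≤ 1e-5 against the TE
  library.
* **De novo** — a translated hit in another genome with identity ≥ 60%,
  query coverage ≥ 80% and E ≤ 1e-6, whose hit-frame open reading frame
  (from the hit start to the first stop) is shorter than 50% of the orphan
  protein: an alignable but non-coding orthologous region.

### Ks dating

Duplicate pairs are dated by Nei–Gojobori (1986) synonymous divergence.
Codon alignments come from a global protein alignment (BLOSUM62, affine
gaps) back-threaded onto the nucleotide sequences, with gap columns
dropped pairwise and ambiguous or stop codons skipped. Site counts S and N
are per-codon fractions of synonymous single-nucleotide changes (changes
into stop codons count as nonsynonymous), averaged between the two
sequences. Difference counts for multi-substitution codons average with
equal weight over all minimal mutation pathways, excluding pathways through
stop codons (all pathways are kept when every one is blocked, so the codon
still contributes). Proportions are Jukes–Cantor corrected,
$K_s = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_S)$, with $p_S \ge 0.75$
flagged saturated rather than extrapolated. Ages follow the strict clock
$T = K_s / (2\mu)$ with the universal plant rate $\mu = 6.5\times10^{-9}$
per site per year: Ks 0.20 ↦ 15.38 MYA, Ks 0.40 ↦ 30.77 MYA. The Ks→time
mapping is exposed directly; selecting density peaks to summarize a Ks
distribution is left to the user (`ks_density()` provides the Silverman
kernel density).

## Expression inference

FPKM is counts · 10⁹ / (length · library size). A gene is "expressed" at
FPKM > 0.02 in *any* sample (the aggregation rule is not fixed by the
convention the threshold comes from; a mean rule is available by flag).
Tissue specificity is the SPM cosine: for per-tissue means $x$,
$\mathrm{SPM}_i = x_i / \lVert x \rVert_2$, with max SPM ≥ 0.9 calling a
tissue-specific gene.

The differential-expression screen is a deliberately lightweight
negative-binomial Wald test: median-of-ratios size factors, log2 fold
change of normalized means with pseudocount 1, a pooled method-of-moments
dispersion (per-gene moment estimates are far too noisy at 2–3 replicates;
pooling trades per-gene adaptivity for calibration), delta-method standard
errors, and Benjamini–Hochberg adjustment, with calls at FDR < 0.05 and
|log2FC| > 1. It is not a reimplementation of any published DE method's
shrinkage machinery; its contract — empirical FDR within tolerance of
nominal and high power at |log2FC| = 3 — is what the acceptance suite
verifies, and an adapter can ingest externally produced DE tables.

Trend clustering is fuzzy c-means (Bezdek alternating optimization,
fuzzifier m = 2, per-gene z-standardization, tolerance 1e-6 on
memberships); the objective is asserted non-increasing at every iteration,
and genes with membership > 0.6 form each cluster's screened set.
Co-expression modules use a weighted network: adjacency |cor|^β with β the
smallest power in 1..20 whose connectivity distribution fits a scale-free
law at R² ≥ 0.8 (fallback β = 6), topological-overlap similarity,
average-linkage clustering on 1 − TOM with a fixed-height cut (0.8 by
default — on 1 − TOM the planted-block separation is wide, so the exact
height is uncritical; it is a config parameter), minimum module size 30,
small clusters merged into the best-correlated module or left unassigned.
Module eigengenes are the first principal component of the module's
standardized expression, sign-oriented to the module mean; hub genes
satisfy MM > 0.95 and GS > 0.85. Enrichment is the upper-tail
hypergeometric probability per term with BH adjustment across terms,
significant at p < 0.05.

## The synthetic-data generator

`simulate_package()` is first-class, tested code, and its defaults are the
study conditions: 1,000 genes on 4 chromosomes, 50 orphans (3 tandem, 3
proximal and 3 dispersed duplicate pairs, one collinear block of 6 WGD
anchor pairs, 2 transposed pairs with a generated outgroup, 4 TE-derived, 4
overlap, 4 de novo, 4 unclassified), non-orphan proteins ~300 aa with
Poisson(3)+1 exons versus orphan proteins ~100 aa with Poisson(0.5)+1 —
the threefold length contrast mirrors the magnitude reported for real
orphan complements. Reference homologs are planted at 80% protein identity
at a uniformly chosen first stage (and later stages with probability 0.3);
decoy proteins give the engine true negatives. Intergenic background is
i.i.d. uniform nucleotides — compositional realism is out of scope, and the
consequence (slightly elevated chance word matches relative to uniform
amino-acid usage) is handled by the two-hit seeding rule.

Duplicate pairs are created by mutating a parent CDS to a target Ks using
only third positions of fourfold-degenerate codons — each change is
strictly synonymous, so the planted synonymous-difference count is exact
and the Jukes–Cantor inversion lands the NG86 estimate on the target —
plus single-nucleotide strictly nonsynonymous changes at ~5% of codons so
protein identity is realistic without touching Ks. TE genes embed a
library fragment covering ≥ 60% of the CDS (in-frame stops in the fragment
are repaired, keeping nucleotide identity near 99%). De novo cases plant an
orthologous region in a partner genome at ~88% amino-acid identity with a
premature stop at 40% of the protein. Overlap cases plant a 60% fragment
of the orphan CDS inside an other-species CDS record.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: realistic repeat landscapes and gene families
(every planted relationship is pairwise and unambiguous), base composition
and codon-usage bias, alternative splicing, alignment-scale noise in
E-values near the cutoff, and count overdispersion that varies by gene.
Recovery being exact under these conditions validates the *logic* of the
pipeline, not the field behaviour of any particular search tool.

## Numerical and design choices

* Coordinates are 1-based inclusive (GFF3 native) everywhere; the one
  place half-open arithmetic appears (window binning in
  `chromosome_density()`) is localized.
* Multi-mRNA genes collapse to the longest-CDS representative for
  structure statistics; the choice is recorded in the docs because the
  convention is not fixed by the sources.
* Hit ties sort by (E-value, subject id, query start) for determinism; all
  stochastic operations take explicit seeds, and `run_all()` is bytewise
  deterministic given its config.
* The engine returns one best HSP per database record; union-coverage
  rules operate across records. A subject carrying two separated fragments
  of a query therefore contributes one span — at desk scale fragments are
  planted as separate records, and the adapter path exists for real-scale
  runs.
* Saturated Ks (pS ≥ 3/4), all-zero SPM profiles, constant genes in the
  network, constant traits, and empty TE libraries are all explicit
  degenerate cases with defined, tested behaviour rather than errors.

## Problem sizes used by the tests

The unit suite runs on 60–300-gene packages; planted-truth recovery runs
once at the full 1,000-gene / 50-orphan condition; the DE calibration uses
20 simulations of 2,000 genes × 6 samples; SPM and trend-clustering checks
use 10 seeded replicates each; determinism runs the whole pipeline twice at
200 genes. These sizes are the package's own validation conditions and are
stated here so they can be scaled up deliberately rather than rediscovered.

## Known limitations

* E-values are approximations (no edge-effect or composition corrections);
  do not compare them numerically with BLAST output.
* Transposed-mode calls need an outgroup; without one, those pairs are
  reported dispersed and flagged.
* One HSP per subject record; highly fragmented homology within a single
  record under-reports coverage.
* The DE stand-in pools dispersion; genes with strongly atypical
  dispersion are mis-calibrated — use the external-table adapter when a
  full shrinkage estimator is required.
* The WGD detector chains anchors within one genome only; it does not
  attempt ancestral-polyploidy reconstruction.
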