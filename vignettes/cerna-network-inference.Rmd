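---
title: "Inferring lncRNA–miRNA–mRNA ceRNA networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA–miRNA–mRNA ceRNA networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaforge)
```

## The problem

Competing endogenous RNAs (ceRNAs) are transcripts that share miRNA
response elements (MREs): a long noncoding RNA carrying a binding site for
a miRNA can sponge that miRNA away from its mRNA targets, de-repressing
them. Evidence for a ceRNA triad (lncRNA, miRNA, mRNA) in a bulk
transcriptome experiment combines four independent signals:

1. the lncRNA really is noncoding (the identification cascade),
2. all three members respond to the biological condition (differential
   expression), with the miRNA moving opposite to the two sponges,
3. both the lncRNA and the mRNA 3′ UTR carry a predicted MRE for the
   shared miRNA (sequence-level target prediction), and
4. the resulting negative-pair network assembles into lncRNA–miRNA–mRNA
   triads.

`cernaforge` implements this chain end to end for a four-group design —
luteal/follicular phase crossed with high/low fecundity (groups LH, LL,
FH, FL; four biological replicates each; contrasts LH vs LL and FH vs
FL) — together with the surrounding analyses such a study reports:
genomic-feature summaries, cis-neighbour correlation analysis, trans
targets by expression correlation, and hypergeometric term enrichment.
Because the real studies' headline numbers depend on raw sequencing data,
genome build and tool versions, the package is validated on a synthetic
generator that plants ground-truth triads; every stage is checked against
that truth or an independent brute-force oracle.

## lncRNA identification

A transcript is called lncRNA iff **all** of the following hold:

* spliced length strictly greater than 200 nt;
* at least 2 exons;
* declared biotype not in {protein_coding, miRNA, tRNA, snoRNA, rRNA,
  pseudogene};
* a unanimous *noncoding* verdict from the coding-potential scorers.

Published pipelines run several external coding-potential tools and
combine their verdicts; the combination rule is rarely stated. We adopt
the conservative intersection reading — a transcript flagged coding by
*any* scorer is discarded — because false-positive "lncRNAs" that are
actually coding poison every downstream stage, whereas a lost borderline
lncRNA only costs sensitivity. Two internal scorers stand in for the
external tools:

* **ORF scorer** (CPC/CPAT-like): coding iff the longest ATG→stop ORF
  across the three forward frames is ≥ `orf_min` (default 300 nt, the
  conventional 100-codon bound) *and* covers ≥ `cov_min` (default 0.35)
  of the transcript. The search uses forward frames only because the
  spliced transcript is already stranded.
* **Hexamer scorer** (CNCI/CPAT-like): coding iff the mean in-frame
  hexamer log-ratio is positive. The table is trained on the run's own
  declared coding set — log of in-frame hexamer frequency in coding
  sequences over the same statistic for shuffled copies, pseudocount 1 on
  all 4096 hexamers. Training on the run's own annotation avoids
  shipping a species-specific table and adapts to the data at hand.

A domain (Pfam-style) search is out of scope; the declared-biotype
exclusion plus the ORF scorer covers that role.

lncRNAs are classified **antisense** iff at least one exonic base
overlaps an exon of a coding transcript on the opposite strand, else
**intergenic**. Exonic (not span) overlap is used so that a lncRNA lying
entirely inside a long intron of an opposite-strand gene does not count
as antisense.

## Expression and differential calling

FPKM is computed from a supplied count matrix as
`count × 10⁹ / (length × sample_total)`, with effective length equal to
transcript length (no fragment-length correction — at the whole-transcript
granularity used here the correction is a near-constant offset).

Differential expression uses the dual threshold **p < 0.05 and
|log2FC| ≥ 1** (fold-change bound inclusive), with

* log2FC = `log2((mean_H + 1) / (mean_L + 1))`, high group over low;
* p from a Welch two-sample t-test on `log2(FPKM + 1)`;
* no multiple-testing correction on DE calls (the studies this mirrors
  threshold raw p-values; enrichment, where multiplicity bites hardest,
  *is* corrected).

The pseudocount of 1 keeps fold changes finite at zero counts and damps
low-abundance noise; it is configurable. With n = 4 per group the Welch
test on log-transformed negative-binomial data is mildly conservative —
on null simulations (2,000 features) the empirical positive rate at
nominal 0.05 lands around 0.03–0.05 depending on the seed. We prefer this
transparent, dependency-free test to a shrinkage-based caller because the
planted effects the pipeline must detect (|log2FC| = 2) are large; power
on such effects exceeds 0.95 in the packaged experiments. For small
effects a moderated test would be the better tool.

When both groups have zero variance the t statistic is undefined; we
return p = 1 for equal means and p = 0 otherwise, which keeps constant
features out of the significant set without special-casing callers.

## Cis neighbours and correlation nulls

Neighbouring gene pairs (lncRNA:coding and coding:coding) are genes on
one chromosome whose **gene-span gap is strictly below 10 kb** (0 when
spans overlap); gene span is the union of the gene's transcript spans.
Span gap, not TSS distance, is used because the biological question —
shared regulatory neighbourhood — concerns the whole locus.

Orientation is classified from 5′ ends: ordering the two genes by 5′
position, a pair is **divergent** when the 5′-earlier gene transcribes
leftward and the later rightward (promoters facing each other across the
gap), **convergent** for the reverse, **tandem** on a shared strand. The
same rule applies to overlapping opposite-strand genes, where span order
is ambiguous but 5′ order is not.

Each pair gets a Pearson correlation across all samples (both phases
pooled by default; the per-phase restriction is a caller choice). The
null is built from uniformly sampled distinct random coding pairs under a
seed. Neighbour-vs-null location shift is tested with a two-sided
Mann–Whitney U test — the distributions are bounded, skewed and of very
different sizes, so a rank test is the safe default.

Trans targets are all lncRNA–gene pairs with **|Pearson r| > 0.95**
(strict), zero-variance features skipped and counted.

## MRE prediction

The seed is miRNA positions 2–8. Candidate sites are exact Watson–Crick
reverse-complement matches (no G:U inside the seed), classified 8mer
(seed match plus target A opposite position 1), 7mer-m8 (seed match, no
A), or 7mer-A1 (match to positions 2–7 plus A, position 8 unpaired).
lncRNAs are searched over their whole length; mRNAs over the annotated
3′ UTR when present, else the whole transcript.

Each candidate is scored by ungapped complementarity of the *full* mature
miRNA against the implied target window: +5 per Watson–Crick pair, +2 per
G:U wobble outside the seed, −3 per mismatch, total floored at 0; the
pseudo-energy is −(2·GC + 1·AU + 0.5·GU) over paired positions. Emitted
sites must reach `score_min` (default 80) and stay below `energy_max`
(default −7). These weights are declared stand-ins with the structure of
an alignment-plus-energy target predictor, not a reimplementation of any
published scoring matrix: the defaults are set so that a perfect-duplex
site always passes (a 20-nt all-AU duplex scores 100 and −20) while
random-background seed matches with non-complementary flanks (≈ 35 from
the seed alone) essentially never do. Thermodynamic folding and
conservation filtering are out of scope.

## Network assembly

"Negative interaction" is implemented as **opposite DE direction within a
contrast**: a miRNA–mRNA (or lncRNA–miRNA) edge requires both endpoints
significant in the contrast, opposite directions, and at least one
predicted site of the miRNA on the partner. Sample-level expression
anticorrelation is deliberately *not* required by default — with n = 4
per group it is noisy, and the direction pattern already encodes the
negativity being asked for. Triads are all (lncRNA, miRNA, mRNA)
combinations in which the two edge types share the miRNA; by construction
the lncRNA and mRNA then share a direction opposite to the miRNA and both
carry an MRE for it. Networks are built independently per contrast and
exported as SIF plus node attributes for Cytoscape-style tools.

## The synthetic generator

The generator emulates the study conditions, not real genome composition:

* **Design**: 4 groups × 4 replicates (16 samples), two high-vs-low
  contrasts.
* **Annotation**: one synthetic chromosome; coding genes with 1–4 exons
  and an ORF of ≥ 300 nt (biased codon usage so the hexamer scorer has a
  learnable signal, ORF coverage ≥ 0.35); lncRNAs with 2–4 exons,
  400–2,500 nt, uniform random background at GC 0.5. A configurable
  fraction (default 0.26, matching the antisense share such surveys
  report) is placed antisense over a coding exon; the rest are
  intergenic. Intergenic gaps mix short (< 10 kb, some divergent) and
  long distances so the cis-pair stage has material.
* **Exact recoverability by construction**: lncRNA sequences are
  rejection-sampled until the longest ORF is < 300 nt *and* the hexamer
  score against the run's coding set is ≤ 0, so the filter cascade
  recovers the planted set with sensitivity = specificity = 1. This is a
  property of the generator, not evidence that the cascade separates
  real borderline transcripts.
* **MRE hygiene**: miRNA seeds are unique, mature sequences start with U
  (so perfect duplexes present the canonical A1), no miRNA's full
  reverse complement contains another's seed site, and seed reverse
  complements are excluded from all non-target transcripts (rejection at
  generation plus a constraint-preserving scrub of junction artefacts).
  Planted sites are full-length perfect-complement duplexes — an 8mer
  seed alone would not clear the default alignment score, and perfect
  complementarity is what the planted-truth recovery guarantees are
  stated over.
* **Counts**: negative binomial with common dispersion (default 0.05)
  around log-normal baseline means (meanlog log 100, sdlog 1, floored at
  10 before library scaling), scaled to an expected library size of
  5 × 10⁵. Planted features have their mean multiplied by `2^log2fc`
  (default effect 2, i.e. 4-fold — comfortably above the calling
  threshold, as planted "true" DE in such designs should be) in the high
  group of their contrast; triad miRNAs shift opposite to their partners.
  The NB-with-group-mean-shift model is the simplest overdispersed
  model matching RNA-seq marginals; it has no mechanistic titration, no
  per-feature dispersion trend, no batch structure, and no
  length/GC bias, so passing tests demonstrate the *logic* of the chain,
  not robustness to those real-data features.
* All randomness flows from one integer seed through locally scoped
  RNG streams; identical configs give byte-identical output files.

No genome FASTA is emitted: antisense lncRNA sequences are drawn
independently of their host gene, which a genome-consistent model would
forbid (the overlap would force reverse-complement identity). Transcript
sequences are authoritative throughout.

## Enrichment

Term over-representation uses the hypergeometric upper tail
P(X ≥ k) for k query hits among n query genes, K term genes and N
background genes, with Benjamini–Hochberg correction across all tested
terms and significance at adjusted p < 0.05. BH is the standard reading
of "corrected p"; Bonferroni is available. The background defaults to the
supplied annotation universe; terms with no background gene are dropped,
terms with no query hit are reported at p = 1 so the output enumerates
the whole map.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally, 1-based inclusive at the
  GTF boundary.
* "More than one exon" is exon count ≥ 2; "longer than 200 bp" is strict.
* Sequences shorter than 6 nt get hexamer score 0 (noncoding verdict);
  transcripts without any complete ORF score ORF length 0.
* Zero-count generator configs produce empty catalogs, not errors;
  infeasible triad requests and non-positive dispersions are errors.
* Correlation stages require ≥ 3 samples and drop (with a count)
  zero-variance features rather than propagating NaN.
* The 2^−ΔΔCt helper implements the relative-quantification arithmetic
  only; it makes no efficiency correction.

## Problem sizes used in the packaged experiments

The shipped tests and the acceptance script size their experiments as:
catalogs of 520 transcripts (300 coding + 220 lncRNA) for the recovery
experiment; 2,000 null features and 200 planted effects (n = 4 vs 4) for
DE calibration; a 150-coding/60-lncRNA/12-miRNA run with 10 planted
triads for the end-to-end recovery; and 2,000 random pairs over 200
independent features for the correlation null. These sizes give stable
seeded outcomes (binomial standard errors well inside the asserted bands)
while keeping a full run in tens of seconds on one core.

## Known limitations

* The coding-potential scorers are trained per run; on a catalog with
  few or atypical coding transcripts the hexamer verdict degrades.
* The DE test is unmoderated; for effects near the fold-change threshold
  a shrinkage caller would be more powerful and the type-I behaviour
  less conservative.
* MRE scoring is ungapped and non-thermodynamic; bulged sites and
  G:U-rich seeds are invisible by design.
* Triad evidence is directional + sequence-based; the package does not
  test titration dynamics, and a triad passing all filters is a
  *candidate*, exactly as in the studies this pipeline mirrors.
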