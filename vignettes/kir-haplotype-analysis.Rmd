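---
title: "KIR gene-content haplotypes and their HLA ligands: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KIR gene-content haplotypes and their HLA ligands: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirhap)
```

## The biology in brief

Natural killer (NK) cell cytotoxicity is tuned by killer-cell
immunoglobulin-like receptors (KIR, chromosome 19) engaging HLA class I
ligands (chromosome 6). Activating KIR genes (2DS1, 2DS2, 2DS3/5, 2DS4,
3DS1) push NK cells toward killing; inhibitory genes (2DL1, 2DL2, 2DL3,
2DL4, 2DL5, 3DL1, 3DL2, 3DL3) restrain it. On the ligand side, every
peptide-binding HLA-C allele belongs to one of two groups set by residue 80
of the heavy chain — C1 (asparagine; ligand of 2DL2/2DL3 and 2DS2) or C2
(lysine; ligand of 2DL1 and 2DS1) — and every HLA-B allele carries either
the Bw4 epitope (ligand of 3DL1/3DS1) or Bw6 (no KIR binding).

KIR haplotypes differ in *gene content*, not merely in alleles. They
decompose into a centromeric and a telomeric motif; this package works
with the common motifs cA01, cB01, cB02, cB03 (centromeric) and tA01, tB01
(telomeric), anchored by the framework genes 3DL3 (centromeric side) and
2DL4/3DL2 (telomeric side), with the pseudogenes 2DP1/3DP1 along for the
ride. A complete haplotype is one centromeric plus one telomeric motif on
the same chromosome.

The analysis this package implements, end to end, is the family-cohort
design used to study these haplotypes in autism: diploid gene copy numbers
(GCN) are deconvolved into motif pairs and phased into complete haplotypes,
HLA types are reduced to ligand groups, activating/inhibitory engagements
are scored, and association is assessed three ways — case versus external
control haplotype frequencies (exact 2x2 statistics), transmission
disequilibrium within trios, and inherited versus non-transmitted parental
alleles (AFBAC) as an internal control.

## Haplotype deconvolution from copy numbers

Presence/absence genotyping cannot distinguish one copy from two; the GCN
(an integer 0-3 per gene) can. For each region the deconvolver enumerates
all unordered pairs of reference motifs — 10 centromeric, 3 telomeric —
and keeps every pair whose element-wise content sum equals the observed
copy vector exactly. The reference set is tiny, so exhaustive enumeration
is both trivial and fully reproducible; there is no scoring heuristic to
tune. A subject is `unique` (one pair), `ambiguous` (several), or
`unresolved` (none).

A count of 3 at a locus is interpreted as the common single-gene
duplication (observed for 3DP1 and 2DL4 in roughly 4.5% of Caucasian
haplotypes): matching is retried after peeling one copy off each such
gene, and the subject is flagged `duplication` but retained in downstream
counts. The flag supports sensitivity re-analysis.

Phasing the centromeric pair against the telomeric pair is forced whenever
at least one region is homozygous. Doubly heterozygous subjects are phased
only if the parents' candidate complete haplotypes are compatible with
exactly one of the two phasings; otherwise the subject is `undetermined`
and contributes no complete haplotypes. On cohorts simulated at the
default frequencies about 95% of probands phase, matching the determined
fraction the study design anticipates (170 of 178 haplotypes). The
deconvolution fidelity test verifies that sum-then-deconvolve recovers the
simulated truth exactly for all non-duplicated subjects.

The motif gene contents are stored as editable reference data rather than
hard-coded logic. The cB03 content ships as defined in the haplotyping
framework the copy-number method derives from, but no cB03 observation
exists in the packaged count tables, so that definition is unverifiable
here — it is retained for completeness and can be corrected through the
YAML reference config without touching code. User configs may add motif
definitions; gene classes (activating/inhibitory/pseudogene) are immutable
because the downstream pooled-count contrasts depend on them.

## Ligand classification and the AFBAC control

HLA-C classification operates at two-digit family resolution (C*01, 03,
07, 08, 12, 14, 16 are C1; C*02, 04, 05, 06, 15, 17, 18 are C2);
higher-resolution labels are truncated, and serological dialects (`Cw7`)
are normalised. Rare intra-family exceptions to the residue-80 rule are
out of scope. Bw4 is assessed on HLA-B by default; A23/A24/A32 also carry
Bw4 and can be counted via `bw4_on_a = TRUE`, but the default follows the
B-locus-only convention of the interaction rule table.

For each trio, the two parental alleles *not* transmitted to the proband
form a control pseudo-subject. Transmission is resolved by enumerating
the (father, mother) allele assignments consistent with the trio; if more
than one distinct assignment exists (shared homozygosity), the trio is
excluded from the AFBAC pool with a logged reason rather than fractionally
weighted — the simpler convention, and the one the informativeness
arithmetic of the study implies. Mendelian inconsistency is an error that
excludes the trio and is reported in the run manifest.

## Interaction scoring

The rule matrix is exactly the engagement table of the study: C1 inhibits
2DL3 (on cA01) and 2DL2 (cB01/cB02) and activates 2DS2 (cB01/cB02); C2
inhibits 2DL1 (cA01/cB01) and activates 2DS1 (tB01); Bw4 inhibits 3DL1
(tA01) and activates 3DS1 (tB01). Bw4 never engages a centromeric
receptor, C1 never a telomeric one. A rule fires when the subject carries
the ligand group and *any* of its motifs carries the receptor gene — so a
motif sharing a rule gene (cB03 carries 2DL3) is covered without a
dedicated rule row.

Each (ligand group, gene) rule fires at most once per subject: interaction
*types* are counted, not gene-dose products. A `dose_weighted` option
multiplies each firing by the ligand copy number for sensitivity analyses.
The "potential inhibitory" count depends only on C-group zygosity:
heterozygotes can engage two distinct inhibitory receptors, homozygotes
one.

Cohort-pooled activating/inhibitory copy means are reported per subject
and per haplotype (the published comparison mixes the two denominators, so
both are exposed). The published cohort means themselves are not
reproducible because four genes' copy-number distributions were never
printed; the operation is therefore validated on synthetic cohorts only.

## Statistical conventions

* **Odds ratios** are plain cross-products a·d/(b·c) on haploid
  (per-chromosome) denominators: 178 chromosomes for 89 subjects, 9,024
  for the control panel. A zero cell yields an infinite OR with a flag;
  the Haldane-Anscombe +0.5 correction is available but off by default.
* **Fisher's exact test** uses the point-probability two-sided rule (sum
  of all margin-preserving tables whose probability does not exceed the
  observed one), with a 1e-7 relative tolerance for floating-point ties —
  the convention of `stats::fisher.test`, which serves as an independent
  cross-check in the tests alongside a from-scratch enumeration oracle.
  The source tables do not state a convention; this is the dominant one.
* **Woolf intervals**: exp(log OR ± z·sqrt(1/a+1/b+1/c+1/d)); requires
  positive cells unless the correction is enabled; level 0 degenerates to
  the point estimate.
* **TDT**: transmissions of the target from heterozygous informative
  parents are Binomial(n, 1/2) under the null; the two-tailed p doubles
  the smaller exact tail and caps at 1. Tail-doubling is a convention
  choice (the sources specify "binomial, two-tailed" but not the doubling
  rule). Transmission is resolved at allele level, which leaves ~46-48% of
  parents informative for C-group transmission at the default frequencies
  — consistent with the ~49% informativeness the study reports. Because
  the exact binomial is discrete, the attained level at α = 0.05 sits
  slightly below the nominal level at these sample sizes; the calibration
  driver and acceptance script recompute the empirical rejection rate
  (about 0.04 over 2,000 null replicates of 89 trios) rather than assuming
  nominal behaviour.
* **Multiple testing**: none is applied, matching the source analysis; a
  Bonferroni option exists but is off by default.
* The motif-level published ORs/p-values came from an unspecified
  multivariable logistic model and are *not* recoverable from the printed
  counts; `motif_associations()` computes the 2x2 statistics and attaches
  a note saying they are not expected to match. Only the complete-haplotype
  and AFBAC tables, whose printed values do equal the cross-products, are
  treated as reproducible.

## The synthetic cohort generator

The generator defines the study conditions the validation runs under:

* **Complete-haplotype frequencies** are the control panel tallies
  normalised over the six named combinations (they cover 8,997 of the
  9,024 panel chromosomes; the remainder involves motifs, like cB03, that
  never appear in a printed complete haplotype). Simulating complete
  haplotypes — not independent centromeric and telomeric draws — preserves
  the centromere-telomere linkage; independence is available as a
  degenerate configuration.
* **HLA-C family frequencies** are set so the aggregate C1-group frequency
  is 0.59, the value implied by the non-inherited parental allele pool
  (46 C1-group alleles of 78), with per-family weights at roughly common
  European proportions. **HLA-B** uses a compact serological panel with
  aggregate Bw4 frequency 0.35. HLA and KIR segregate independently by
  default, as genes on chromosomes 6 and 19 do in the general population.
* **Transmission distortion** (`transmission_tau`) biases which
  haplotype/allele a heterozygous parent gives the child; 0.5 is the null.
* **Case enrichment** uses a logistic affection model with log-odds offset
  ln(OR) per risk-haplotype copy over a base prevalence of 0.02, and
  probands are ascertained (only affected children retained). In this
  rare-baseline regime the haplotype-level case-control odds ratio equals
  the per-copy target to within about 2%, comfortably inside the
  sampling-noise band at the validation sizes. With OR = 1 no trios are
  rejected, so null simulations are cheap.
* **Duplications** occur per subject at rate 0.045 (the published
  population rate), adding one 3DP1 and one 2DL4 copy.

What the generator deliberately does not emulate: KIR allele-level
diversity, population stratification, genotyping error, HLA-KIR linkage
(available only as an optional association for power studies), and
realistic HLA haplotype structure across loci. Passing tests therefore
demonstrate the correctness and calibration of the *pipeline*, not the
robustness of the study design to those real-data complications.

## Validation problem sizes

The test suite and acceptance script use 2,000 null replicates of 89
trios for TDT calibration, 2,000 ascertained families for odds-ratio
recovery, an exhaustive sweep of all 2x2 tables with total at most 40 for
the exact-test oracle, and the full 13-pair deconvolution round-trip.
These sizes put Monte-Carlo noise well below the tolerance bands while
keeping the whole validation under a minute on one core.

## Known limitations

* Haplotype discovery is closed-world: copy vectors outside the configured
  motif set come back `unresolved` rather than suggesting novel motifs.
* cB03's gene content is unverified against any packaged observation (see
  above).
* The multivariable model behind the published motif-level statistics is
  unspecified and therefore out of scope; no attempt is made to recover
  its covariates.
* Two printed TDT p-values (C1 group and 2DL2/2DS2) lack the underlying
  transmission counts and cannot be checked; the TDT machinery is
  validated by calibration instead.
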