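---
title: "Detecting NMD-escape frameshift indels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting NMD-escape frameshift indels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdescape)
```

## The biological model

Frameshift insertions and deletions (fs-indels) shift the reading frame and
introduce a premature termination codon (PTC) downstream of the mutation.
Transcripts carrying a PTC are normally degraded by nonsense-mediated decay
(NMD), so most fs-indels never produce protein. Under the exon junction
complex (EJC) model, NMD is triggered when an EJC remains downstream of the
terminating ribosome; decay efficiency therefore drops when the PTC falls in

* the **last exon** (no downstream EJC),
* the **penultimate exon within 50 nt** of the final exon junction (the
  terminating ribosome displaces the last EJC), or
* the **first exon within the first 200 nt** of coding sequence
  (translation-reinitiation effects).

An fs-indel whose mutant allele is nonetheless detectable in RNA is an
*NMD-escape* mutation. Because the shifted frame is translated until the
new stop, escape mutations produce a *neoORF* — a stretch of entirely novel
amino acids that is a rich source of tumor-specific neoantigens. The
package implements the full chain from variant tables to cohort-level
statistics: post-caller QC, allele-specific DNA/RNA intersection, PTC
computation on the dominant isoform, five-way exon-position classification,
neoORF/peptide derivation, per-sample burden metrics, and the association
analyses linking NMD-escape burden to immunotherapy benefit.

## The PTC computation

All effect logic runs in spliced, strand-corrected mRNA space; projection
between genomic and transcript coordinates is the only strand-aware step.
For an fs-indel the edit is applied to the spliced sequence, and
translation proceeds in the shifted frame from the codon containing the
first shifted nucleotide, through the 3' UTR if necessary, until the first
stop codon. `neoorf_len` counts the shifted-frame codons before that stop —
including residues coincidentally identical to wildtype, which matches the
neoORF-length semantics used for frameshift neoantigens. Variants with no
stop before the transcript end are flagged `readthrough`, carry no category
and are excluded from burden counts. Stop-gain SNVs are handled by the same
classification with the mutated codon as the PTC and `neoorf_len = 0`,
which keeps the two classes comparable in the selection analysis.

Conventions that were genuinely open and the choices made:

* **Distance to the final junction** is measured from the PTC's *first*
  nucleotide to the last nucleotide of the penultimate exon; the boundary
  is inclusive (`<= 50` nt).
* **First-exon PTCs** always classify as `FIRST`; the 200-nt qualifier is
  applied only inside the escape rule, so both the plain five-way
  classification and the rule-based escape call are available.
* **Single-exon transcripts** classify as `LAST` (no junction exists), and
  in a two-exon transcript the first exon is treated as penultimate.
* **Indel coordinates** follow the VCF anchor-base convention; shared
  ref/alt bases are trimmed (suffix first, then prefix) while keeping the
  anchor. For classification, a PTC inside inserted sequence projects to
  the insertion locus on the reference transcript.
* **Dominant isoform**: annotation uses the isoform with the highest
  abundance for the gene in that sample; ties break to the
  lexicographically smaller isoform id for determinism.
* **Peptide windows**: mutant 9/10/11-mers are all windows over the
  wildtype prefix plus neoORF that contain at least one shifted residue and
  do not extend past the stop. With `L` novel residues and at least `k - 1`
  upstream residues this yields exactly `L` windows of length `k`; the
  `L + k - 1` candidate starts lose `k - 1` to the stop-side clip.

## Expression intersection thresholds

A DNA indel is *expressed* when an RNA indel call of the same type
(insertion vs deletion) lies within ±10 nt (allowing minor alignment
mismatches), with ≥ 5 alternative reads and RNA VAF ≥ 0.05. SNVs intersect
at the identical position and allele with the same read thresholds and no
padding. Matching attaches the nearest qualifying RNA call, ties break to
the smaller position, and each RNA call supports at most one DNA call
(greedy, in DNA position order). Requiring the same indel type prevents
cross-matching insertions to deletions inside the padding window. Whether
the original intersection demanded identical alleles within the pad is not
determinable; same-type-any-allele is implemented and flagged here.

DNA-side QC keeps an SNV called by both callers at VAF > 2% with primary
somatic p ≤ 0.01, or by the primary caller alone at VAF ≥ 5%; indels
require the high-confidence flag and somatic p < 5e-4. Caller roles are
generic ("primary" = the caller supplying somatic p-values, "secondary" =
the consensus caller) so the rule is testable without the named tools. The
"> 2%" is read strictly and the "5%" inclusively, following the wording of
the respective rules.

## Statistical machinery

* **2×2 tables**: Fisher's exact test for count data — two-sided p by the
  probabilities-at-most-observed rule, odds ratio by conditional maximum
  likelihood on the noncentral hypergeometric, exact 95% CI by test
  inversion (`stats::fisher.test`); the sample cross-product OR is reported
  alongside. The test suite checks the p-value against full hypergeometric
  enumeration on every table with margins ≤ 15 (1e-10 agreement).
* **Two-group comparisons**: two-sided Mann-Whitney U, exact when
  `n_x * n_y <= 400` with no ties, otherwise tie-corrected normal
  approximation with continuity correction; fully tied data reports p = 1.
* **Multi-group**: tie-corrected Kruskal-Wallis with chi-square df = g − 1;
  with two groups it degenerates to the two-group rank test.
* **Meta-analysis**: Fisher's combined probability,
  χ² = −2 Σ log p on 2k df. Per-cohort two-sided p-values are combined
  directly (not direction-aware one-sided p-values); this reading is
  flagged as an interpretation.
* **Proportions**: Wilson score intervals (the interval family is not
  dictated by the analyses being reproduced; Wilson is the documented
  choice for its coverage at small n).
* **Joint model**: logistic regression (IRLS) of benefit on nsSNV count,
  NMD-escape count and cohort indicators, Wald p per term; separation and
  rank-deficiency are flagged (`converged = FALSE`), never silently
  returned.
* **Multiple testing**: none is applied (α = 0.05 throughout), matching
  the analyses being reproduced; this is deliberate and stated.

The low-TMB split uses the pooled median nsSNV count by default (a fixed
override such as 217 is available), with `<=` as the subset rule and the
strict `<` variant behind a flag.

## What the synthetic cohort emulates

The generator produces transcript models with ATG-initiated, internally
stop-free CDSs, spliced FASTA sequences, per-sample isoform abundances,
DNA variant tables with QC fields, RNA evidence, protein abundances, HLA
binding tables and clinical outcomes. Its defaults encode the study
conditions the analyses assume:

* cohort sizes 33/21/25/24 (four CPI cohorts);
* negative-binomial burdens (size 1.3) with means chosen so the *medians*
  match the published per-tumor medians: fs-indel μ = 5.5 (median 4),
  nsSNV μ = 286 (median 217, ≈ 10 mutations/Mb), stop-gain μ = 26;
* fs-indel category placement (4.5/62/9/4.5/20% across
  first/middle/penult>50/penult≤50/last) with expression probabilities
  (16.9/13.5/16.9/27.2/25.1%) solved numerically so the implied
  enrichment odds ratios are 1.00/0.54/1.00/1.90/1.92 at an overall
  expression rate of 2267/13420 — the published point estimates. These are
  *calibrated*, not measured: per-category expression probabilities are
  not observable from the published enrichment ORs alone;
* RNA VAF per category Beta-distributed with medians
  0.26/0.19/0.27/0.31/0.32 and concentration 10 (only medians are
  published; the Beta family and concentration are modelling choices);
* RNA depth Poisson with mean 50× (unstated; typical exome-matched
  RNA-seq coverage);
* benefit probabilities 0.12 (zero NMD-escape mutations) vs 0.56 (≥ 1);
* protein abundance standard-normal baseline plus a 0.8 SD shift for
  expressed fs-indels (mirrors normalised protein array values; the shift
  is calibrated to give ~80% power at group sizes 40 vs 96);
* selection placement proportions solved so fs-indel vs stop-gain odds
  ratios are 1.00/1.57/0.58/0.65 (first/middle/penultimate/last);
* one binder probability (0.007 per peptide-allele pair) for the HLA
  table; breadth differences between classes emerge from neoORF length
  (an fs-indel emits `neoORF + k − 1` windows per length, an nsSNV `k`).

Category-targeted placement uses proposal regions around each target plus
rejection on the realised PTC, relaxing (and counting) after repeated
failure; expressed variants redraw their RNA read counts until detectable,
so truth flags and recomputed expression flags agree exactly on noise-free
data.

What the generator does **not** emulate: raw reads or alignment artefacts,
splice-disrupting variants, positional mutation hotspots, copy-number or
dosage-compensation effects on NMD, correlated burdens between mutation
classes beyond shared sampling, and any coupling between TMB and escape
count (their true correlation is weak, r ≈ 0.2). Passing tests therefore
demonstrate that the pipeline recovers the structure it models — not that
real tumors obey that structure.

## Problem sizes and numerical choices

The test suite checks the PTC engine against a brute-force oracle that
rebuilds the mutant mRNA by genomic string surgery and translates from the
start codon (1,000 random fs-indels and 1,000 stop-gains across
mixed-strand transcripts). Parameter-recovery experiments use the
category-level fast path of the generator: 100 replicates of 12,000
fs-indels for enrichment CI coverage (≥ 90%), 200 replicates at cohort
sizes 33/21/25/24 for meta-analysis power (≥ 70% at rates 0.56 vs 0.12),
and 100 replicates of 1,500 vs 9,000 placements for the selection ORs with
a germline (identical-placement) null. Null calibration draws 10,000
replicates per test at sizes where exact-test discreteness is negligible
(2 × 300 binomials for Fisher, 30 vs 30 for Mann-Whitney, 3 × 20 for
Kruskal-Wallis, n = 200 for the logistic Wald test); each observed size
must fall in [0.035, 0.065] at α = 0.05. Degenerate inputs are handled
explicitly: zero-cell tables yield 0/∞ OR estimates with one-sided exact
bounds, fully tied rank tests report p = 1, and readthrough variants are
excluded from burdens rather than forced into a category.

## Limitations

The package consumes variant calls, HLA binding ranks and NMD-efficiency
scores as inputs; it does not align reads, call variants, type HLA or
predict binding affinities. The escape designation is observational
(mutant allele detected in RNA), not a functional demonstration of decay
escape, and middle-exon escapes — which the EJC model does not predict but
which occur in real data — arise here only through the calibrated
middle-exon expression probability. Clinical-benefit labels are consumed
exactly as provided by each cohort's original definition.
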