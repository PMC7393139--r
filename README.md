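# nmdescape

Tools for detecting frameshift-indel mutations that escape
nonsense-mediated decay (NMD) and for testing whether the burden of such
mutations predicts benefit from cancer immunotherapy.

## The problem

Frameshift insertions/deletions (fs-indels) create premature termination
codons (PTCs) and are normally silenced by NMD, but decay is inefficient
when the PTC lands in the last exon, in the penultimate exon within 50 nt
of the final exon junction, or in the first 200 nt of coding sequence. An
fs-indel whose mutant allele is still detectable in RNA — an *NMD-escape*
mutation — is translated into a novel open reading frame (neoORF) and is a
disproportionately immunogenic source of neoantigens. For tumor
immunogenomics analysts, the package implements, as tested reusable
components:

* **Variant handling** — VCF / MAF-like TSV readers, post-caller consensus
  filters (SNVs: VAF > 2% called by both callers at somatic p ≤ 0.01, or
  VAF ≥ 5% by the primary caller alone; indels: high-confidence with
  somatic p < 5 × 10⁻⁴), and codon-level effect classification.
* **Allele-specific expression** — DNA/RNA indel intersection with ±10 nt
  padding, ≥ 5 alternative reads and RNA VAF ≥ 0.05; exact-position allele
  counts for SNVs.
* **The NMD model** — dominant-isoform selection, PTC computation in
  spliced mRNA space, five-way exon-position classification
  (`FIRST`, `MIDDLE`, `PENULT_GT50`, `PENULT_LE50`, `LAST`), the positional
  escape rule, the external-score rule (efficiency < 0.25), neoORF lengths,
  SNORF flags (neoORF ≥ 50 aa) and mutant peptide libraries.
* **Statistics** — exact 2×2 inference with conditional-MLE odds ratios
  (OR with exact CI), two-sided Mann-Whitney U, tie-corrected
  Kruskal-Wallis, Fisher's combined probability (χ² = −2 Σ log p on 2k df),
  Pearson correlation, Wilson proportion intervals, and logistic
  regression with Wald tests and separation flags.
* **Cohort analyses** — the four burden metrics (TMB nsSNVs, expressed
  nsSNVs, fs-indels, NMD-escape count), per-cohort benefit tests with
  meta-analysis, low-TMB stratification at the pooled median, a joint
  benefit ~ TMB + escape + cohort model, positional-enrichment and
  selection odds ratios, HLA binding breadth, and neoORF reactivity
  comparisons.
* **A calibrated synthetic-cohort generator** so every stage is testable
  offline, with defaults encoding the study conditions (see the methods
  vignette).

## Worked example

```r
library(nmdescape)
cfg <- sim_config(n_samples = 24, cohort_sizes = c(12, 12), n_genes = 30,
                  burden_means = c(nsSNV = 12, stop_gain = 4, fs_indel = 5),
                  seed = 7)
res <- run_all(run_config(simulate = TRUE, sim = cfg, seed = 7,
                          outdir = file.path(tempdir(), "demo")), quiet = TRUE)
head(res$summaries)
#>   sample  cohort nsSNV expressed_nsSNV fs_indel nmd_escape benefit
#> 1   S001 cohort1     1               0        2          0   FALSE
#> 2   S002 cohort1     3               3        4          1    TRUE
#> 3   S003 cohort1     4               4        4          0   FALSE
#> 4   S004 cohort1    10               5        5          0    TRUE
#> 5   S005 cohort1     4               3       13          2    TRUE
#> 6   S006 cohort1    21              13       20          2   FALSE

res$associations$nmd_escape$meta
#> Fisher combined: chi2 = 12.504 on 4 df, p_meta = 0.01397 (k = 2)
```

Each row of `summaries` is one tumor with its four burden metrics and
outcome label. The meta line combines the per-cohort two-sided
Mann-Whitney p-values for the NMD-escape metric across the two simulated
cohorts: here escape count separates benefit from no-benefit patients at
p ≈ 0.014. Per-stratum benefit rates with Wilson 95% intervals:

```r
res$associations$nmd_escape$rates
#>        stratum benefit total      rate      lower     upper
#> 1 escape_1plus       5     7 0.7142857 0.35893445 0.9177811
#> 2     escape_0       1     5 0.2000000 0.03622411 0.6244654
#> 3 escape_1plus       2     3 0.6666667 0.20765960 0.9385081
#> 4     escape_0       0     9 0.0000000 0.00000000 0.2991450
```

Patients with at least one NMD-escape mutation benefit at 67-71% versus
0-20% for patients with none — the pattern the burden metric is designed
to expose. Lower-level entry points (`compute_ptc`,
`classify_ptc_exon_position`, `match_indels_dna_rna`, `neoorf_peptides`,
`fisher_exact_2x2`, ...) are documented individually, and
`inst/scripts/nmdescape-cli.R` wraps `simulate` and `run-all` for shell
use.

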