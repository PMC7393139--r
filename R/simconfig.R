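#' Exon-position categories for premature termination codons
#'
#' Five-way classification of a PTC's exon position, in order: first exon,
#' middle exon, penultimate exon more than 50 nt from the final exon
#' junction, penultimate exon within 50 nt of the final junction, last exon.
#' @export
EXON_CATEGORIES <- c("FIRST", "MIDDLE", "PENULT_GT50", "PENULT_LE50", "LAST")

# Calibrated defaults. Expression probabilities were solved numerically so
# that, at the default category proportions, the implied expressed-vs-not
# enrichment odds ratios are 1.00 (first), 0.54 (middle), 1.00 (penult >50),
# 1.90 (penult <=50) and 1.92 (last), with an overall expression rate of
# 2267/13420. Selection placement proportions were solved so the implied
# fs-indel vs stop-gain odds ratios are 1.00/1.57/0.58/0.65
# (first/middle/penultimate/last). See implied_enrichment_or() and
# implied_selection_or().
.default_category_props <- c(FIRST = 0.045, MIDDLE = 0.62,
                             PENULT_GT50 = 0.09, PENULT_LE50 = 0.045,
                             LAST = 0.20)
.default_expression_prob <- c(FIRST = 0.1689, MIDDLE = 0.1350,
                              PENULT_GT50 = 0.1689, PENULT_LE50 = 0.2717,
                              LAST = 0.2508)
.default_vaf_median <- c(FIRST = 0.26, MIDDLE = 0.19, PENULT_GT50 = 0.27,
                         PENULT_LE50 = 0.31, LAST = 0.32)
.default_sel_fs <- c(FIRST = 0.0560, MIDDLE = 0.7760, PENULT_GT50 = 0.0391,
                     PENULT_LE50 = 0.0196, LAST = 0.1093)
.default_sel_sg <- c(FIRST = 0.0560, MIDDLE = 0.6881, PENULT_GT50 = 0.0647,
                     PENULT_LE50 = 0.0324, LAST = 0.1588)

#' Simulation configuration
#'
#' Holds every knob of the synthetic-cohort generator. Defaults encode the
#' study conditions the analyses assume: four melanoma checkpoint-inhibitor
#' cohorts of sizes 33/21/25/24, a median of ~4 fs-indels per tumor,
#' category-dependent expression probabilities calibrated to last-exon
#' enrichment OR 1.92 and middle-exon OR 0.54, RNA VAF medians of
#' 0.26/0.19/0.27/0.31/0.32 across the five exon categories, clinical-benefit
#' probabilities of 0.12 (zero NMD-escape mutations) versus 0.56 (one or
#' more), and a protein-abundance shift of 0.8 SD for expressed fs-indels.
#'
#' @param n_samples Number of tumors; defaults to `sum(cohort_sizes)`.
#' @param cohort_sizes Integer vector of per-cohort sample counts.
#' @param n_genes Number of simulated genes.
#' @param exon_count_range Integer interval for exons per transcript.
#' @param exon_length_range Nucleotide interval for exon lengths.
#' @param isoforms_range Integer interval for isoforms per gene.
#' @param utr3_length_range Nucleotide interval for the 3' UTR.
#' @param burden_means Named numeric: expected per-sample counts for
#'   `nsSNV`, `stop_gain`, `fs_indel` (negative-binomial means).
#' @param burden_size Negative-binomial size (overdispersion) parameter.
#' @param category_props Probability of each exon category for fs-indel PTC
#'   placement (named over [EXON_CATEGORIES]).
#' @param stopgain_category_props Same for stop-gain SNV placement.
#' @param category_expression_prob Probability that a variant with PTC in
#'   each category is expressed (detected in RNA).
#' @param category_vaf_median Median RNA VAF per category for expressed
#'   variants.
#' @param vaf_concentration Beta concentration (a+b) for VAF draws.
#' @param rna_depth_mean Mean Poisson RNA read depth at a variant site.
#' @param snv_expression_prob Probability an nsSNV is expressed.
#' @param benefit_prob_by_escape Length-2 numeric: clinical-benefit
#'   probability for samples with zero vs >=1 (expressed fs-indel)
#'   NMD-escape mutations.
#' @param protein_shift Standardised shift added to protein abundance when
#'   the gene's fs-indel is expressed.
#' @param binder_prob Per peptide-allele probability of an HLA binder
#'   (rank < 0.5) in the simulated binding table.
#' @param n_hla_alleles Class I HLA genotype size.
#' @param peptide_lengths Peptide window lengths.
#' @param binding_max_nssnv Cap on nsSNV mutations included in the binding
#'   table (fs-indels are always all included).
#' @param allow_abundance_ties Permit tied isoform abundances within a gene
#'   (off by default; on only for tie-break testing).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = NULL,
                       cohort_sizes = c(33L, 21L, 25L, 24L),
                       n_genes = 60,
                       exon_count_range = c(3L, 9L),
                       exon_length_range = c(120L, 300L),
                       isoforms_range = c(1L, 3L),
                       utr3_length_range = c(100L, 250L),
                       burden_means = c(nsSNV = 286, stop_gain = 26,
                                        fs_indel = 5.5),
                       burden_size = 1.3,
                       category_props = .default_category_props,
                       stopgain_category_props = .default_sel_sg,
                       category_expression_prob = .default_expression_prob,
                       category_vaf_median = .default_vaf_median,
                       vaf_concentration = 10,
                       rna_depth_mean = 50,
                       snv_expression_prob = 0.5,
                       benefit_prob_by_escape = c(0.12, 0.56),
                       protein_shift = 0.8,
                       binder_prob = 0.007,
                       n_hla_alleles = 6L,
                       peptide_lengths = c(9L, 10L, 11L),
                       binding_max_nssnv = 300L,
                       allow_abundance_ties = FALSE,
                       seed = 1L) {
  if (is.null(n_samples)) n_samples <- sum(cohort_sizes)
  cfg <- list(n_samples = as.integer(n_samples),
              cohort_sizes = as.integer(cohort_sizes),
              n_genes = as.integer(n_genes),
              exon_count_range = as.integer(exon_count_range),
              exon_length_range = as.integer(exon_length_range),
              isoforms_range = as.integer(isoforms_range),
              utr3_length_range = as.integer(utr3_length_range),
              burden_means = burden_means, burden_size = burden_size,
              category_props = category_props,
              stopgain_category_props = stopgain_category_props,
              category_expression_prob = category_expression_prob,
              category_vaf_median = category_vaf_median,
              vaf_concentration = vaf_concentration,
              rna_depth_mean = rna_depth_mean,
              snv_expression_prob = snv_expression_prob,
              benefit_prob_by_escape = benefit_prob_by_escape,
              protein_shift = protein_shift,
              binder_prob = binder_prob,
              n_hla_alleles = as.integer(n_hla_alleles),
              peptide_lengths = as.integer(peptide_lengths),
              binding_max_nssnv = as.integer(binding_max_nssnv),
              allow_abundance_ties = isTRUE(allow_abundance_ties),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$category_props, cfg$stopgain_category_props,
             cfg$category_expression_prob, cfg$snv_expression_prob,
             cfg$benefit_prob_by_escape, cfg$binder_prob,
             cfg$category_vaf_median)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  for (nm in c("category_props", "stopgain_category_props",
               "category_expression_prob", "category_vaf_median")) {
    if (!identical(names(cfg[[nm]]), EXON_CATEGORIES)) {
      stop(nm, " must be named over the five exon categories")
    }
  }
  for (nm in c("category_props", "stopgain_category_props")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-6) stop(nm, " must sum to 1")
  }
  if (any(cfg$burden_means < 0)) stop("burden means must be >= 0")
  if (cfg$exon_count_range[1] < 1) stop("exon counts must be >= 1")
  if (length(cfg$benefit_prob_by_escape) != 2) {
    stop("benefit_prob_by_escape must give probabilities for 0 and >=1")
  }
  if (cfg$n_samples < 1 || cfg$n_genes < 1) stop("need >= 1 sample and gene")
  invisible(cfg)
}

#' Enrichment and selection odds ratios implied by a configuration
#'
#' Closed-form population odds ratios implied by the generator's category
#' proportions and expression probabilities. `implied_enrichment_or` gives,
#' per exon category, the odds of being expressed for variants in that
#' category versus all others. `implied_selection_or` gives the odds of an
#' fs-indel (vs stop-gain) falling in each category versus all others,
#' with the two penultimate bins collapsed as in the selection analysis.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector of odds ratios.
#' @export
implied_enrichment_or <- function(config) {
  p <- config$category_props
  e <- config$category_expression_prob
  a <- p * e
  b <- p * (1 - e)
  vapply(seq_along(p), function(i) {
    (a[i] * sum(b[-i])) / (b[i] * sum(a[-i]))
  }, numeric(1)) |> setNames(EXON_CATEGORIES)
}

#' @rdname implied_enrichment_or
#' @param fs_props Optional fs-indel placement proportions (defaults to the
#'   configuration's `category_props`).
#' @export
implied_selection_or <- function(config, fs_props = NULL) {
  collapse <- function(p) c(FIRST = unname(p["FIRST"]),
                            MIDDLE = unname(p["MIDDLE"]),
                            PENULT = unname(p["PENULT_GT50"] + p["PENULT_LE50"]),
                            LAST = unname(p["LAST"]))
  pf <- collapse(fs_props %||% config$category_props)
  ps <- collapse(config$stopgain_category_props)
  vapply(seq_along(pf), function(i) {
    (pf[i] / (1 - pf[i])) / (ps[i] / (1 - ps[i]))
  }, numeric(1)) |> setNames(names(pf))
}
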