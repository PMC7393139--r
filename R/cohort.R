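#' Per-sample mutation burden metrics
#'
#' Assembles the four burden metrics: (i) TMB, the count of non-synonymous
#' SNVs; (ii) expressed nsSNVs; (iii) fs-indels; and (iv) NMD-escape
#' mutations, the expressed fs-indels. Readthrough fs-indels (no PTC) are
#' excluded from the fs-indel and escape counts. Samples absent from the
#' clinical table receive an `NA` benefit label.
#'
#' @param variants data.frame with one row per filtered, annotated variant:
#'   `sample`, `class`, `expressed` (logical), optional `readthrough`.
#' @param clinical Optional data.frame `sample`, `cohort`, `benefit`.
#' @param samples Optional character vector of all sample ids (so samples
#'   with zero variants appear with zero counts).
#' @return data.frame with `sample`, `cohort`, `nsSNV`, `expressed_nsSNV`,
#'   `fs_indel`, `nmd_escape`, `benefit`.
#' @export
compute_burden_metrics <- function(variants, clinical = NULL,
                                   samples = NULL) {
  if (is.null(samples)) {
    samples <- unique(c(variants$sample,
                        if (!is.null(clinical)) clinical$sample))
  }
  rt <- if (!is.null(variants$readthrough)) {
    !is.na(variants$readthrough) & variants$readthrough
  } else rep(FALSE, nrow(variants))
  out <- do.call(rbind, lapply(samples, function(s) {
    v <- variants[variants$sample == s, , drop = FALSE]
    r <- rt[variants$sample == s]
    ns <- v$class == "nsSNV"
    fs <- v$class == "fs_indel" & !r
    data.frame(sample = s,
               nsSNV = sum(ns),
               expressed_nsSNV = sum(ns & v$expressed),
               fs_indel = sum(fs),
               nmd_escape = sum(fs & v$expressed))
  }))
  out$cohort <- NA_character_
  out$benefit <- NA
  if (!is.null(clinical)) {
    i <- match(out$sample, clinical$sample)
    out$cohort <- clinical$cohort[i]
    out$benefit <- clinical$benefit[i]
  }
  out[, c("sample", "cohort", "nsSNV", "expressed_nsSNV", "fs_indel",
          "nmd_escape", "benefit")]
}

category_table_2x2 <- function(cat, in_group, category) {
  a <- sum(in_group & cat == category)
  b <- sum(in_group & cat != category)
  c_ <- sum(!in_group & cat == category)
  d <- sum(!in_group & cat != category)
  rbind(c(a, b), c(c_, d))
}

#' Positional enrichment of expressed fs-indels
#'
#' For each exon category, builds the 2x2 table of (in-category vs not) x
#' (expressed vs not) over all fs-indels and runs the exact test, each
#' category compared against all others. An odds ratio above 1 means
#' expressed fs-indels are enriched in that category.
#'
#' @param expressed_categories Character vector of exon categories of
#'   expressed fs-indels.
#' @param nonexpressed_categories Same for non-expressed fs-indels.
#' @param categories Categories to evaluate.
#' @return data.frame `category`, `n_expressed`, `n_nonexpressed`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
positional_enrichment <- function(expressed_categories,
                                  nonexpressed_categories,
                                  categories = EXON_CATEGORIES) {
  if (length(expressed_categories) == 0 ||
      length(nonexpressed_categories) == 0) {
    stop("both expressed and non-expressed groups must be non-empty")
  }
  cat <- c(expressed_categories, nonexpressed_categories)
  expr <- rep(c(TRUE, FALSE), c(length(expressed_categories),
                                length(nonexpressed_categories)))
  do.call(rbind, lapply(categories, function(cc) {
    r <- fisher_exact_2x2(category_table_2x2(cat, expr, cc))
    data.frame(category = cc,
               n_expressed = sum(expr & cat == cc),
               n_nonexpressed = sum(!expr & cat == cc),
               odds_ratio = r$odds_ratio, ci_low = r$ci_low,
               ci_high = r$ci_high, p_value = r$p_value)
  }))
}

#' RNA VAF of expressed fs-indels by exon category
#'
#' @param category Character vector of exon categories (expressed fs-indels).
#' @param rna_vaf Matching numeric vector of RNA variant allele frequencies.
#' @return List with `medians` (named, per non-empty category) and `test`
#'   (tie-corrected Kruskal-Wallis over the non-empty categories).
#' @export
vaf_by_category <- function(category, rna_vaf) {
  keep <- !is.na(rna_vaf) & !is.na(category)
  groups <- split(rna_vaf[keep], factor(category[keep],
                                        levels = EXON_CATEGORIES))
  groups <- groups[lengths(groups) > 0]
  if (length(groups) == 0) stop("all categories empty")
  list(medians = vapply(groups, median, numeric(1)),
       test = if (length(groups) >= 2) kruskal_wallis(groups) else NULL)
}

#' Protein abundance of expressed versus non-expressed fs-indels
#'
#' @param abundance Numeric protein abundances (one per fs-indel gene).
#' @param expressed Matching logical expression flags.
#' @return A `rank_test_result` (two-sided Mann-Whitney U).
#' @export
protein_comparison <- function(abundance, expressed) {
  if (!any(expressed) || all(expressed)) {
    stop("need both expressed and non-expressed fs-indels")
  }
  mann_whitney_u(abundance[expressed], abundance[!expressed])
}

#' Association between a burden metric and clinical benefit
#'
#' Runs, per cohort, the two-sided Mann-Whitney U test of the metric between
#' benefit and no-benefit patients; combines the per-cohort p-values with
#' Fisher's method; and summarises the >=1-vs-0 split of the metric as a 2x2
#' exact test with per-stratum benefit rates and Wilson intervals. Cohorts
#' with a single outcome class are excluded with a warning.
#'
#' @param summaries Output of [compute_burden_metrics()] (needs `cohort`,
#'   `benefit` and the metric column).
#' @param metric Column name of the burden metric (default `"nmd_escape"`).
#' @param pool Treat all samples as a single cohort.
#' @return An `association_result` list: `metric`, `per_cohort` (data.frame),
#'   `meta` (`meta_result`), `contingency` (`contingency_result`), `rates`
#'   (per-stratum benefit rates with 95\% intervals).
#' @export
benefit_association <- function(summaries, metric = "nmd_escape",
                                pool = FALSE) {
  s <- summaries[!is.na(summaries$benefit), , drop = FALSE]
  if (nrow(s) == 0) stop("no samples with outcome labels")
  s$cohort <- if (pool) "pooled" else as.character(s$cohort)
  per <- lapply(split(s, s$cohort), function(d) {
    if (length(unique(d$benefit)) < 2) {
      warning("cohort ", d$cohort[1],
              " has a single outcome class; excluded from meta-analysis")
      return(NULL)
    }
    mw <- mann_whitney_u(d[[metric]][d$benefit], d[[metric]][!d$benefit])
    data.frame(cohort = d$cohort[1], n = nrow(d),
               statistic = mw$statistic, p_value = mw$p_value)
  })
  per <- do.call(rbind, per)
  if (is.null(per)) stop("no cohort with both outcome classes")
  meta <- fisher_combine(per$p_value)
  # >=1 vs 0 of the metric, pooled across cohorts
  pos <- s[[metric]] >= 1
  tab <- rbind(c(sum(pos & s$benefit), sum(pos & !s$benefit)),
               c(sum(!pos & s$benefit), sum(!pos & !s$benefit)))
  ct <- fisher_exact_2x2(tab)
  rates <- do.call(rbind, lapply(split(s, s$cohort), function(d) {
    dp <- d[d[[metric]] >= 1, ]; dz <- d[d[[metric]] < 1, ]
    mk <- function(dd, stratum) {
      if (nrow(dd) == 0) return(NULL)
      ci <- proportion_ci(sum(dd$benefit), nrow(dd))
      data.frame(cohort = dd$cohort[1], stratum = stratum,
                 benefit = sum(dd$benefit), total = nrow(dd),
                 rate = ci["estimate"], lower = ci["lower"],
                 upper = ci["upper"], row.names = NULL)
    }
    rbind(mk(dp, "escape_1plus"), mk(dz, "escape_0"))
  }))
  rownames(rates) <- NULL
  structure(list(metric = metric, per_cohort = per, meta = meta,
                 contingency = ct, rates = rates),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("metric:", x$metric, "\n")
  print(x$per_cohort)
  cat(sprintf("meta p = %.4g; >=1 vs 0: ", x$meta$p_meta))
  print(x$contingency)
  invisible(x)
}

#' Benefit association restricted to low-TMB samples
#'
#' Splits the pooled cohorts at the median nsSNV count (or a fixed override,
#' e.g. 217) and reruns the benefit association for the NMD-escape metric in
#' the low-TMB subset, alongside the nsSNV metric for comparison. The subset
#' is `nsSNV <= threshold` by default; the strict `<` variant used in some
#' displays is available via `inclusive = FALSE`.
#'
#' @param summaries Output of [compute_burden_metrics()].
#' @param threshold Optional fixed nsSNV threshold; defaults to the pooled
#'   median.
#' @param inclusive Include samples at the threshold.
#' @return List: `threshold`, `n`, `escape` (pooled `association_result` for
#'   `nmd_escape`), `tmb_p` (pooled Mann-Whitney p for nsSNV), or
#'   `degenerate = TRUE` when the subset has a single outcome class.
#' @export
low_tmb_analysis <- function(summaries, threshold = NULL, inclusive = TRUE) {
  s <- summaries[!is.na(summaries$benefit), , drop = FALSE]
  thr <- threshold %||% median(s$nsSNV)
  sub <- if (inclusive) s[s$nsSNV <= thr, ] else s[s$nsSNV < thr, ]
  if (length(unique(sub$benefit)) < 2) {
    return(list(threshold = thr, n = nrow(sub), degenerate = TRUE))
  }
  esc <- benefit_association(sub, "nmd_escape", pool = TRUE)
  tmb <- mann_whitney_u(sub$nsSNV[sub$benefit], sub$nsSNV[!sub$benefit])
  list(threshold = thr, n = nrow(sub), escape = esc, tmb_p = tmb$p_value,
       degenerate = FALSE)
}

#' Joint logistic model of benefit on TMB and NMD-escape count
#'
#' Fits benefit ~ nsSNV + NMD-escape + cohort indicators by maximum
#' likelihood and reports per-term Wald p-values, together with the Pearson
#' correlation between the two burden metrics.
#'
#' @param summaries Output of [compute_burden_metrics()] spanning >= 2
#'   cohorts.
#' @return List: `fit` (a `logistic_fit`), `r` (Pearson correlation of nsSNV
#'   and NMD-escape counts).
#' @export
multivariable_model <- function(summaries) {
  s <- summaries[!is.na(summaries$benefit), , drop = FALSE]
  if (length(unique(s$cohort)) < 2) stop("need >= 2 cohorts")
  design <- data.frame(nsSNV = s$nsSNV, nmd_escape = s$nmd_escape)
  mm <- stats::model.matrix(~ cohort, data = s)[, -1, drop = FALSE]
  colnames(mm) <- make.names(colnames(mm))
  design <- cbind(design, as.data.frame(mm))
  list(fit = logistic_fit(s$benefit, design),
       r = pearson_r(s$nsSNV, s$nmd_escape))
}

#' Positional selection of fs-indels against stop-gain SNVs
#'
#' For each exon category, builds the 2x2 table of (fs-indel vs stop-gain) x
#' (in-category vs not). Stop-gain SNVs act as the benchmark comparator:
#' equivalent loss-of-function effect and identical treatment by NMD, but no
#' neoantigens. An odds ratio below 1 means fs-indels are depleted in that
#' category. The two penultimate bins are collapsed by default, matching the
#' four-way selection comparison; a germline variant pair can be run
#' identically as a negative control.
#'
#' @param fs_categories Exon categories of somatic fs-indels.
#' @param stopgain_categories Exon categories of somatic stop-gain SNVs.
#' @param collapse_penultimate Merge `PENULT_GT50`/`PENULT_LE50` into
#'   `PENULT`.
#' @return data.frame `category`, `n_fs`, `n_stopgain`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
selection_position_or <- function(fs_categories, stopgain_categories,
                                  collapse_penultimate = TRUE) {
  if (length(fs_categories) == 0 || length(stopgain_categories) == 0) {
    stop("both variant classes must be non-empty")
  }
  squash <- function(x) if (collapse_penultimate) {
    ifelse(x %in% c("PENULT_GT50", "PENULT_LE50"), "PENULT", x)
  } else x
  fs <- squash(fs_categories); sg <- squash(stopgain_categories)
  cats <- if (collapse_penultimate) c("FIRST", "MIDDLE", "PENULT", "LAST")
          else EXON_CATEGORIES
  cat <- c(fs, sg)
  is_fs <- rep(c(TRUE, FALSE), c(length(fs), length(sg)))
  do.call(rbind, lapply(cats, function(cc) {
    r <- fisher_exact_2x2(category_table_2x2(cat, is_fs, cc))
    data.frame(category = cc, n_fs = sum(is_fs & cat == cc),
               n_stopgain = sum(!is_fs & cat == cc),
               odds_ratio = r$odds_ratio, ci_low = r$ci_low,
               ci_high = r$ci_high, p_value = r$p_value)
  }))
}

#' HLA binding breadth per mutation
#'
#' A peptide-allele pair is a binder when its rank score is strictly below
#' `rank_cutoff`. Breadth is the number of distinct HLA alleles with at
#' least one binder peptide per mutation. Class-level proportions of
#' mutations binding 1, 2, 3 or >= 4 alleles are computed over mutations
#' with breadth >= 1 (binders only), with Wilson intervals.
#'
#' @param binding data.frame `variant_id`, `class`, `peptide`, `allele`,
#'   `rank`.
#' @param genotype Optional character vector of genotype alleles; alleles in
#'   the table but absent from the genotype raise an error.
#' @param rank_cutoff Binder threshold on the rank score (strict `<`).
#' @return List: `breadth` (data.frame `variant_id`, `class`, `breadth`),
#'   `proportions` (per class and bin, over breadth >= 1 mutations).
#' @export
hla_binding_breadth <- function(binding, genotype = NULL, rank_cutoff = 0.5) {
  if (!is.null(genotype)) {
    extra <- setdiff(unique(binding$allele), genotype)
    if (length(extra)) stop("allele(s) absent from genotype: ",
                            paste(extra, collapse = ", "))
  }
  b <- binding[binding$rank < rank_cutoff, , drop = FALSE]
  ids <- unique(binding[, c("variant_id", "class")])
  breadth <- vapply(ids$variant_id, function(v) {
    length(unique(b$allele[b$variant_id == v]))
  }, integer(1))
  br <- data.frame(variant_id = ids$variant_id, class = ids$class,
                   breadth = breadth, row.names = NULL)
  pos <- br[br$breadth >= 1, , drop = FALSE]
  props <- do.call(rbind, lapply(split(pos, pos$class), function(d) {
    bins <- c(`1` = sum(d$breadth == 1), `2` = sum(d$breadth == 2),
              `3` = sum(d$breadth == 3), `4+` = sum(d$breadth >= 4))
    do.call(rbind, lapply(names(bins), function(bn) {
      ci <- proportion_ci(bins[[bn]], nrow(d))
      data.frame(class = d$class[1], bin = bn, count = bins[[bn]],
                 total = nrow(d), rate = ci["estimate"],
                 lower = ci["lower"], upper = ci["upper"], row.names = NULL)
    }))
  }))
  rownames(props) <- NULL
  list(breadth = br, proportions = props)
}

#' Compare neoORF lengths of immunogenic and non-immunogenic fs-indels
#'
#' Two-sided Mann-Whitney U test on neoORF lengths between T cell reactive
#' and screened-but-non-reactive fs-indel mutations, with per-group medians
#' and counts of super-neoORF (SNORF, >= 50 amino acids) events.
#'
#' @param reactive_lengths neoORF lengths (aa) of reactive mutations.
#' @param nonreactive_lengths Same for non-reactive mutations.
#' @return List: `test` (`rank_test_result`), `median_reactive`,
#'   `median_nonreactive`, `snorf_reactive`, `snorf_nonreactive`.
#' @export
neoorf_reactivity_compare <- function(reactive_lengths,
                                      nonreactive_lengths) {
  if (length(reactive_lengths) == 0 || length(nonreactive_lengths) == 0) {
    stop("both groups must be non-empty")
  }
  list(test = mann_whitney_u(reactive_lengths, nonreactive_lengths),
       median_reactive = median(reactive_lengths),
       median_nonreactive = median(nonreactive_lengths),
       snorf_reactive = sum(reactive_lengths >= 50),
       snorf_nonreactive = sum(nonreactive_lengths >= 50))
}
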