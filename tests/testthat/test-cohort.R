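mk_summaries <- function(escape, benefit, cohort = "c1", nsSNV = NULL) {
  n <- length(escape)
  data.frame(sample = sprintf("S%04d", seq_len(n)), cohort = cohort,
             nsSNV = nsSNV %||% rpois(n, 200), expressed_nsSNV = 0,
             fs_indel = escape, nmd_escape = escape, benefit = benefit)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("burden metrics count the four classes with the hierarchy intact", {
  v <- data.frame(sample = c("A", "A", "A", "A", "A", "B"),
                  class = c("fs_indel", "fs_indel", "fs_indel", "nsSNV",
                            "nsSNV", "nsSNV"),
                  expressed = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                  readthrough = FALSE)
  s <- compute_burden_metrics(v, samples = c("A", "B", "C"))
  expect_identical(s$fs_indel, c(3L, 0L, 0L))
  expect_identical(s$nmd_escape, c(1L, 0L, 0L))
  expect_identical(s$nsSNV, c(2L, 1L, 0L))
  expect_identical(s$expressed_nsSNV, c(1L, 0L, 0L))
  expect_true(all(s$expressed_nsSNV <= s$nsSNV))
  expect_true(all(s$nmd_escape <= s$fs_indel))
  # readthrough fs-indels are excluded from both fs-indel counts
  v$readthrough[2] <- TRUE
  s2 <- compute_burden_metrics(v, samples = "A")
  expect_identical(s2$fs_indel, 2L)
  # sample missing from the clinical table gets an NA benefit
  cl <- data.frame(sample = "A", cohort = "c1", benefit = TRUE)
  s3 <- compute_burden_metrics(v, clinical = cl, samples = c("A", "B"))
  expect_true(is.na(s3$benefit[2]))
})

test_that("burden metrics recompute truth exactly on a noise-free cohort", {
  cfg <- sim_config(n_samples = 12, cohort_sizes = c(6, 6), n_genes = 25,
                    burden_means = c(nsSNV = 8, stop_gain = 2, fs_indel = 4),
                    seed = 31)
  co <- simulate_cohort(cfg)
  res <- run_all(run_config(simulate = TRUE, sim = cfg, seed = 31,
                            outdir = tempfile()), quiet = TRUE)
  truth <- co$truth
  for (s in unique(res$summaries$sample)) {
    t_s <- truth[truth$sample == s, ]
    r <- res$summaries[res$summaries$sample == s, ]
    expect_identical(r$nsSNV, sum(t_s$class == "nsSNV"))
    expect_identical(r$fs_indel, sum(t_s$class == "fs_indel"))
    expect_identical(r$nmd_escape,
                     sum(t_s$class == "fs_indel" & t_s$expressed))
    expect_identical(r$expressed_nsSNV,
                     sum(t_s$class == "nsSNV" & t_s$expressed))
  }
})

test_that("positional enrichment is null when categories are exchangeable", {
  set.seed(32)
  cats <- sample(EXON_CATEGORIES, 3000, replace = TRUE,
                 prob = c(0.1, 0.5, 0.1, 0.1, 0.2))
  e <- positional_enrichment(cats[1:600], cats[601:3000])
  expect_true(all(e$ci_low < 1 & 1 < e$ci_high))
  expect_error(positional_enrichment(character(), cats), "non-empty")
})

test_that("VAF-by-category reports per-category medians and a global test", {
  set.seed(33)
  cat <- rep(c("LAST", "MIDDLE", "FIRST"), each = 200)
  vaf <- c(rbeta(200, 8, 17) + 0.12, rbeta(200, 8, 17), rbeta(200, 8, 17) + 0.07)
  r <- vaf_by_category(cat, vaf)
  expect_gt(r$medians[["LAST"]], r$medians[["MIDDLE"]])
  expect_lt(r$test$p_value, 0.01)
  expect_error(vaf_by_category(character(), numeric()), "empty")
  # two categories degenerate to a two-group rank test
  r2 <- vaf_by_category(cat[1:400], vaf[1:400])
  expect_equal(unname(r2$test$df), 1)
})

test_that("protein comparison is powered at the study's group sizes", {
  set.seed(34)
  hits <- replicate(100, {
    ab <- c(rnorm(40, 0.8), rnorm(96))
    protein_comparison(ab, rep(c(TRUE, FALSE), c(40, 96)))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
  expect_equal(protein_comparison(rep(1, 10),
                                  rep(c(TRUE, FALSE), 5))$p_value, 1)
  expect_error(protein_comparison(rnorm(5), rep(TRUE, 5)), "both")
})

test_that("benefit association combines cohorts and summarises the 1-vs-0 split", {
  set.seed(35)
  esc <- rbinom(103, 2, 0.2)
  ben <- runif(103) < ifelse(esc >= 1, 0.56, 0.12)
  s <- mk_summaries(esc, ben,
                    cohort = rep(paste0("c", 1:4), c(33, 21, 25, 24)))
  a <- benefit_association(s, "nmd_escape")
  expect_identical(nrow(a$per_cohort), 4L)
  expect_identical(length(a$meta$pvalues), 4L)
  expect_true(all(c("escape_1plus", "escape_0") %in% a$rates$stratum))
  # a single cohort's meta p equals its own p
  one <- benefit_association(s[s$cohort == "c1", ], "nmd_escape")
  expect_equal(one$meta$p_meta, one$per_cohort$p_value[1], tolerance = 1e-12)
  # a cohort with one outcome class is excluded with a warning
  s2 <- s; s2$benefit[s2$cohort == "c2"] <- TRUE
  expect_warning(benefit_association(s2, "nmd_escape"), "single outcome")
})

test_that("null meta p-values are uniform over replicates", {
  set.seed(36)
  ps <- replicate(200, {
    esc <- rbinom(60, 2, 0.3)
    ben <- runif(60) < 0.35           # independent of escape
    s <- mk_summaries(esc, ben, cohort = rep(c("c1", "c2"), 30))
    suppressWarnings(benefit_association(s, "nmd_escape")$meta$p_meta)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the low-TMB split uses the pooled median and rescues the escape signal", {
  set.seed(37)
  nsSNV <- c(rpois(52, 100), rpois(51, 400))
  esc <- rbinom(103, 2, 0.25)
  ben <- runif(103) < ifelse(esc >= 1, 0.53, 0.15)
  s <- mk_summaries(esc, ben, cohort = rep(paste0("c", 1:4), c(33, 21, 25, 24)),
                    nsSNV = nsSNV)
  r <- low_tmb_analysis(s)
  expect_identical(r$threshold, median(nsSNV))
  expect_identical(r$n, sum(nsSNV <= median(nsSNV)))
  expect_false(r$degenerate)
  # fixed override reproduces the <= 217 subset rule
  r217 <- low_tmb_analysis(s, threshold = 217)
  expect_identical(r217$n, sum(nsSNV <= 217))
  r_strict <- low_tmb_analysis(s, threshold = 217, inclusive = FALSE)
  expect_identical(r_strict$n, sum(nsSNV < 217))
  # all counts equal: the subset is the whole cohort
  s_eq <- s; s_eq$nsSNV <- 100
  expect_identical(low_tmb_analysis(s_eq)$n, 103L)
})

test_that("the joint model separates an escape effect from a null TMB effect", {
  set.seed(38)
  wins_esc <- 0; wins_tmb <- 0
  for (i in 1:60) {
    esc <- rbinom(104, 3, 0.2)
    tmb <- rpois(104, 200)
    ben <- runif(104) < plogis(-1.5 + 1.2 * pmin(esc, 2))
    s <- mk_summaries(esc, ben, cohort = rep(paste0("c", 1:4), each = 26),
                      nsSNV = tmb)
    f <- multivariable_model(s)
    cf <- f$fit$coefficients
    p_esc <- cf$p_value[cf$term == "nmd_escape"]
    p_tmb <- cf$p_value[cf$term == "nsSNV"]
    wins_esc <- wins_esc + (p_esc < 0.05)
    wins_tmb <- wins_tmb + (p_tmb < 0.05)
  }
  expect_gt(wins_esc, wins_tmb)
  # independent counts correlate near zero
  set.seed(39)
  s0 <- mk_summaries(rbinom(200, 3, 0.2), runif(200) < 0.3,
                     cohort = rep(c("a", "b"), 100))
  expect_lt(abs(multivariable_model(s0)$r), 0.2)
  expect_error(multivariable_model(mk_summaries(1:4, c(TRUE, FALSE, TRUE,
                                                       FALSE))), ">= 2")
})

test_that("selection odds ratios are exactly 1 on identical inputs", {
  cats <- rep(EXON_CATEGORIES, c(5, 50, 10, 5, 20))
  r <- selection_position_or(cats, cats)
  expect_equal(r$odds_ratio, rep(1, 4), tolerance = 1e-6)
  expect_identical(r$category, c("FIRST", "MIDDLE", "PENULT", "LAST"))
  r5 <- selection_position_or(cats, cats, collapse_penultimate = FALSE)
  expect_identical(r5$category, EXON_CATEGORIES)
  expect_error(selection_position_or(character(), cats), "non-empty")
})

test_that("binding breadth counts distinct alleles under the strict 0.5 cutoff", {
  b <- data.frame(variant_id = c("m1", "m1", "m1", "m2", "m3"),
                  class = c("fs_indel", "fs_indel", "fs_indel", "nsSNV",
                            "nsSNV"),
                  peptide = c("p1", "p2", "p3", "p4", "p5"),
                  allele = c("A", "A", "B", "C", "D"),
                  rank = c(0.2, 0.2, 0.2, 0.5, 0.49))
  r <- hla_binding_breadth(b)
  expect_identical(r$breadth$breadth[r$breadth$variant_id == "m1"], 2L)
  expect_identical(r$breadth$breadth[r$breadth$variant_id == "m2"], 0L)
  expect_identical(r$breadth$breadth[r$breadth$variant_id == "m3"], 1L)
  # zero-breadth mutations are excluded from the binder-only proportions
  expect_identical(sum(r$proportions$count[r$proportions$class == "nsSNV"]),
                   1L)
  expect_true(all(r$proportions$total[r$proportions$class == "nsSNV"] == 1))
  expect_error(hla_binding_breadth(b, genotype = c("A", "B", "C")),
               "absent from genotype")
})

test_that("neoORF reactivity comparison reports medians and SNORF counts", {
  set.seed(40)
  reactive <- c(27, 27, 30, 12, 80, 55, 60, 51, 27, 20, 5, 70, 26, 28, 27)
  nonreactive <- c(5, 4, 6, 5)
  r <- neoorf_reactivity_compare(reactive, nonreactive)
  expect_identical(r$median_reactive, 27)
  expect_identical(r$median_nonreactive, 5)
  expect_identical(r$snorf_reactive, 5L)
  expect_identical(r$snorf_nonreactive, 0L)
  expect_lt(r$test$p_value, 0.05)
  expect_identical(neoorf_reactivity_compare(c(50, 51, 49),
                                             c(1, 2))$snorf_reactive, 2L)
  same <- neoorf_reactivity_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$test$p_value, 1)
  expect_error(neoorf_reactivity_compare(numeric(), 1:3), "non-empty")
})
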