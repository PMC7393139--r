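test_that("a minimal single-exon config yields a valid in-frame CDS", {
  cfg <- sim_config(n_samples = 1, cohort_sizes = 1, n_genes = 1,
                    exon_count_range = c(1, 1),
                    exon_length_range = c(60, 60),
                    isoforms_range = c(1, 1), seed = 3)
  tx <- simulate_transcriptome(cfg)[[1]]
  cds_len <- tx$cds_end - tx$cds_start + 1
  expect_equal(cds_len %% 3, 0)
  cds <- substr(tx$seq, tx$cds_start, tx$cds_end)
  expect_identical(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, cds_len - 2, cds_len) %in% c("TAA", "TAG", "TGA"))
  # no internal in-frame stop
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  expect_identical(regexpr("*", prot, fixed = TRUE)[1],
                   nchar(prot))
})

test_that("exon lengths too short to host a CDS raise a gene-named error", {
  cfg <- sim_config(n_samples = 1, cohort_sizes = 1, n_genes = 1,
                    exon_count_range = c(1, 1),
                    exon_length_range = c(20, 20),
                    isoforms_range = c(1, 1), seed = 3)
  expect_error(simulate_transcriptome(cfg), "GENE0001")
})

test_that("identical config and seed reproduce byte-identical outputs", {
  cfg <- sim_config(n_samples = 6, cohort_sizes = c(3, 3), n_genes = 12,
                    burden_means = c(nsSNV = 5, stop_gain = 2, fs_indel = 3),
                    seed = 99)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
})

test_that("exon count range is passed through exactly", {
  cfg <- sim_config(n_samples = 1, cohort_sizes = 1, n_genes = 40,
                    exon_count_range = c(3, 3), isoforms_range = c(1, 1),
                    seed = 5)
  txs <- simulate_transcriptome(cfg)
  expect_true(all(vapply(txs, function(t) nrow(t$exons), numeric(1)) == 3))
})

test_that("fs-indel burdens follow the configured count distribution", {
  cfg <- sim_config(n_samples = 500, cohort_sizes = c(250, 250),
                    n_genes = 30,
                    burden_means = c(nsSNV = 0, stop_gain = 0, fs_indel = 4),
                    seed = 21)
  tx <- simulate_transcriptome(cfg)
  ab <- simulate_isoform_abundance(tx, cfg)
  sv <- simulate_somatic_variants(tx, ab, cfg)
  per_sample <- table(factor(sv$truth$sample,
                             levels = sprintf("S%03d", 1:500)))
  mu <- 4; size <- cfg$burden_size
  se <- sqrt((mu + mu^2 / size) / 500)
  expect_lt(abs(mean(per_sample) - mu), 3 * se)
  # fs-indels never have a length change divisible by 3
  dl <- abs(nchar(sv$variants$alt) - nchar(sv$variants$ref))
  expect_true(all(dl %% 3 != 0))
  # truth covers every simulated variant
  expect_setequal(sv$truth$variant_id, sv$variants$variant_id)
})

test_that("forcing all fs-indels into the last exon yields all-LAST truth", {
  props <- c(FIRST = 0, MIDDLE = 0, PENULT_GT50 = 0, PENULT_LE50 = 0,
             LAST = 1)
  cfg <- sim_config(n_samples = 10, cohort_sizes = c(5, 5), n_genes = 15,
                    burden_means = c(nsSNV = 0, stop_gain = 0, fs_indel = 3),
                    category_props = props, seed = 22)
  tx <- simulate_transcriptome(cfg)
  ab <- simulate_isoform_abundance(tx, cfg)
  sv <- simulate_somatic_variants(tx, ab, cfg)
  expect_true(all(sv$truth$category == "LAST"))
})

test_that("RNA evidence exists iff truth marks the variant expressed", {
  cfg <- sim_config(n_samples = 15, cohort_sizes = c(8, 7), n_genes = 25,
                    burden_means = c(nsSNV = 5, stop_gain = 2, fs_indel = 4),
                    seed = 23)
  co <- simulate_cohort(cfg)
  fs <- co$truth[co$truth$class == "fs_indel", ]
  expect_identical(nrow(co$rna_indels), sum(fs$expressed))
  sn <- co$truth[co$truth$class != "fs_indel", ]
  expect_identical(nrow(co$rna_snv_counts), sum(sn$expressed))
  # zero expression probability emits no RNA rows at all
  zero <- sim_config(n_samples = 10, cohort_sizes = c(5, 5), n_genes = 15,
                     burden_means = c(nsSNV = 3, stop_gain = 1,
                                      fs_indel = 3),
                     category_expression_prob = setNames(rep(0, 5),
                                                         EXON_CATEGORIES),
                     snv_expression_prob = 0, seed = 24)
  co0 <- simulate_cohort(zero)
  expect_identical(nrow(co0$rna_indels), 0L)
  expect_identical(nrow(co0$rna_snv_counts), 0L)
  expect_false(any(co0$truth$expressed))
})

test_that("expressed last-exon VAFs reproduce the configured 0.32 median", {
  cfg <- sim_config(seed = 25)
  props <- c(FIRST = 0, MIDDLE = 0, PENULT_GT50 = 0, PENULT_LE50 = 0,
             LAST = 1)
  tab <- simulate_category_table(9000, cfg, props = props, seed = 25)
  v <- tab$rna_vaf[tab$expressed]
  expect_gt(length(v), 1500)
  expect_gte(median(v), 0.29)
  expect_lte(median(v), 0.35)
})

test_that("clinical benefit rates match the configured 0.12/0.56 split", {
  n <- 4000
  truth <- data.frame(sample = sprintf("S%03d", rep(1:n, each = 1)),
                      class = "fs_indel",
                      expressed = rep(c(TRUE, FALSE), length.out = n))
  cfg <- sim_config(n_samples = n, cohort_sizes = rep(1000, 4), seed = 26)
  cl <- simulate_clinical_outcomes(truth, cfg)
  esc <- cl$true_escape_count >= 1
  r1 <- mean(cl$benefit[esc]); r0 <- mean(cl$benefit[!esc])
  se1 <- sqrt(0.56 * 0.44 / sum(esc)); se0 <- sqrt(0.12 * 0.88 / sum(!esc))
  expect_lt(abs(r1 - 0.56), 3 * se1)
  expect_lt(abs(r0 - 0.12), 3 * se0)
  # determinism of labels
  cl2 <- simulate_clinical_outcomes(truth, cfg)
  expect_identical(cl$benefit, cl2$benefit)
  # cohorts assigned by the configured sizes
  expect_identical(as.integer(table(cl$cohort)), rep(1000L, 4))
})

test_that("binding breadth follows the closed-form complement rule", {
  # binder probability 0: breadth 0 everywhere
  truth <- data.frame(variant_id = sprintf("v%03d", 1:50), sample = "S1",
                      gene = "G", isoform = "G.T1", class = "nsSNV",
                      category = NA, neoorf_len = NA, expressed = FALSE)
  cfg0 <- sim_config(binder_prob = 0, binding_max_nssnv = 50, seed = 27)
  b0 <- simulate_hla_binding(truth, cfg0)
  expect_identical(nrow(hla_binding_breadth(b0)$breadth[
    hla_binding_breadth(b0)$breadth$breadth > 0, ]), 0L)
  # E[breadth] = 6 * (1 - (1-p)^L) with L = 30 peptide windows per nsSNV
  cfg <- sim_config(binder_prob = 0.05, binding_max_nssnv = 400, seed = 28)
  truth2 <- data.frame(variant_id = sprintf("v%03d", 1:400), sample = "S1",
                       gene = "G", isoform = "G.T1", class = "nsSNV",
                       category = NA, neoorf_len = NA, expressed = FALSE)
  b <- simulate_hla_binding(truth2, cfg)
  br <- hla_binding_breadth(b)$breadth
  q <- 1 - (1 - 0.05)^30
  expected <- 6 * q
  se <- sqrt(6 * q * (1 - q) / 400)
  expect_lt(abs(mean(br$breadth) - expected), 4 * se)
  # fs-indels with longer neoORFs emit proportionally more peptide rows
  truth3 <- data.frame(variant_id = c("a", "b"), sample = "S1", gene = "G",
                       isoform = "G.T1", class = "fs_indel",
                       category = "LAST", neoorf_len = c(10L, 100L),
                       expressed = TRUE)
  b3 <- simulate_hla_binding(truth3, sim_config(seed = 29))
  n_a <- length(unique(b3$peptide[b3$variant_id == "a"]))
  n_b <- length(unique(b3$peptide[b3$variant_id == "b"]))
  expect_identical(n_a, sum(10L + c(9L, 10L, 11L) - 1L))
  expect_identical(n_b, sum(100L + c(9L, 10L, 11L) - 1L))
})

test_that("the calibrated defaults imply the published odds ratios", {
  cfg <- sim_config()
  or <- implied_enrichment_or(cfg)
  expect_equal(unname(or["LAST"]), 1.92, tolerance = 0.01)
  expect_equal(unname(or["PENULT_LE50"]), 1.90, tolerance = 0.01)
  expect_equal(unname(or["MIDDLE"]), 0.54, tolerance = 0.01)
  expect_equal(unname(or["FIRST"]), 1.00, tolerance = 0.01)
  sel <- implied_selection_or(cfg, fs_props = nmdescape:::.default_sel_fs)
  expect_equal(unname(sel["PENULT"]), 0.58, tolerance = 0.01)
  expect_equal(unname(sel["LAST"]), 0.65, tolerance = 0.01)
  expect_equal(unname(sel["MIDDLE"]), 1.57, tolerance = 0.01)
})

test_that("probabilities outside [0,1] and malformed configs are rejected", {
  expect_error(sim_config(snv_expression_prob = 1.4), "\\[0, 1\\]")
  expect_error(sim_config(category_props = c(FIRST = 0.5, MIDDLE = 0.6,
                                             PENULT_GT50 = 0, PENULT_LE50 = 0,
                                             LAST = 0)), "sum to 1")
  expect_error(sim_config(exon_count_range = c(0, 2)), "exon counts")
})
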