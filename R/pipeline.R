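#' Pipeline run configuration
#'
#' Bundles input paths, thresholds and the seed for an end-to-end run. Every
#' threshold defaults to the analysis' canonical value: +-10 nt indel
#' padding, >= 5 RNA alternative reads, RNA VAF >= 0.05, SNV somatic
#' p <= 0.01, indel somatic p < 5e-4, HLA binder rank < 0.5, NMD-efficiency
#' escape score < 0.25, and the pooled-median low-TMB threshold.
#'
#' @param simulate Generate inputs with [simulate_cohort()] instead of
#'   reading them from disk.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param gtf,fasta,isoform_expr,dna_variants,rna_indels,rna_snv_counts,protein,hla_binding,clinical
#'   Input paths used when `simulate = FALSE` (tables as written by
#'   [write_cohort()]).
#' @param padding,min_alt,min_vaf Expression-intersection thresholds.
#' @param binder_rank HLA binder rank cutoff.
#' @param low_tmb_threshold Fixed low-TMB nsSNV threshold, or `NULL` for the
#'   pooled median.
#' @param low_tmb_inclusive Use `<=` (default) rather than `<`.
#' @param seed Seed for the simulated branch.
#' @param outdir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(seed = seed),
                       gtf = NULL, fasta = NULL, isoform_expr = NULL,
                       dna_variants = NULL, rna_indels = NULL,
                       rna_snv_counts = NULL, protein = NULL,
                       hla_binding = NULL, clinical = NULL,
                       padding = 10, min_alt = 5, min_vaf = 0.05,
                       binder_rank = 0.5, low_tmb_threshold = NULL,
                       low_tmb_inclusive = TRUE, seed = 1L,
                       outdir = tempfile("nmdescape_run_")) {
  structure(list(simulate = simulate, sim = sim, gtf = gtf, fasta = fasta,
                 isoform_expr = isoform_expr, dna_variants = dna_variants,
                 rna_indels = rna_indels, rna_snv_counts = rna_snv_counts,
                 protein = protein, hla_binding = hla_binding,
                 clinical = clinical, padding = padding, min_alt = min_alt,
                 min_vaf = min_vaf, binder_rank = binder_rank,
                 low_tmb_threshold = low_tmb_threshold,
                 low_tmb_inclusive = low_tmb_inclusive,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

read_tsv_checked <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    stop("stage ", stage, ": input not found: ", path %||% "<NULL>")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full NMD-escape pipeline
#'
#' Executes the stages end to end: input assembly (simulation or files),
#' post-caller QC filters, DNA/RNA expression intersection, PTC/NMD
#' annotation on dominant isoforms, burden metrics, and the cohort analyses
#' (benefit associations for all four metrics with meta-analysis, low-TMB
#' stratification, joint logistic model, positional enrichment, VAF by
#' category, protein comparison, selection against stop-gains, HLA binding
#' breadth). Writes a tidy `results.tsv`, per-stage tables and a JSON run
#' manifest under `config$outdir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return List with all stage outputs (`summaries`, `associations`,
#'   `enrichment`, `vaf`, `protein_test`, `low_tmb`, `joint`, `selection`,
#'   `breadth`, `results`, `manifest`), invisibly writable.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[nmdescape] ", ...)
  t0 <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  say("stage 1/6: inputs")
  if (isTRUE(config$simulate)) {
    cohort <- simulate_cohort(config$sim)
    tx <- cohort$transcripts
    abundance <- cohort$abundance
    dna <- cohort$dna_variants
    rna_ind <- cohort$rna_indels
    rna_snv <- cohort$rna_snv_counts
    protein <- cohort$protein
    binding <- cohort$hla_binding
    clinical <- cohort$clinical
  } else {
    if (is.null(config$gtf) || !file.exists(config$gtf)) {
      stop("stage inputs: GTF not found: ", config$gtf %||% "<NULL>")
    }
    ab <- read_tsv_checked(config$isoform_expr, "inputs")
    tx <- read_transcript_models(config$gtf, config$fasta)
    abundance <- ab
    dna <- read_tsv_checked(config$dna_variants, "inputs")
    rna_ind <- read_tsv_checked(config$rna_indels, "inputs")
    rna_snv <- read_tsv_checked(config$rna_snv_counts, "inputs")
    protein <- read_tsv_checked(config$protein, "inputs")
    binding <- read_tsv_checked(config$hla_binding, "inputs")
    clinical <- read_tsv_checked(config$clinical, "inputs")
  }

  say("stage 2/6: QC filters")
  is_indel <- nchar(dna$ref) != nchar(dna$alt)
  snvs <- consensus_filter_snvs(dna[!is_indel, , drop = FALSE])
  indels <- filter_indels(dna[is_indel, , drop = FALSE])

  say("stage 3/6: expression intersection")
  indels <- match_indels_dna_rna(indels, rna_ind, padding = config$padding,
                                 min_alt = config$min_alt,
                                 min_vaf = config$min_vaf)
  snvs <- flag_expressed_snvs(snvs, rna_snv, min_alt = config$min_alt,
                              min_vaf = config$min_vaf)

  say("stage 4/6: NMD annotation")
  if (is.null(dna$class)) {
    dna$class <- classify_effects(dna, tx)
  }
  cls <- setNames(dna$class, dna$variant_id)
  ptc_in <- rbind(
    data.frame(variant_id = indels$variant_id, sample = indels$sample,
               contig = indels$contig, position = indels$position,
               ref = indels$ref, alt = indels$alt,
               class = cls[indels$variant_id],
               expressed = indels$expressed),
    data.frame(variant_id = snvs$variant_id, sample = snvs$sample,
               contig = snvs$contig, position = snvs$position,
               ref = snvs$ref, alt = snvs$alt,
               class = cls[snvs$variant_id], expressed = snvs$expressed))
  ptc_in <- ptc_in[ptc_in$class %in% c("fs_indel", "stop_gain"), ]
  ann <- annotate_variants(ptc_in[, setdiff(names(ptc_in), "expressed")],
                           tx, abundance = abundance)
  ann$expressed <- ptc_in$expressed[match(ann$variant_id,
                                          ptc_in$variant_id)]
  ann$rna_vaf <- indels$rna_vaf[match(ann$variant_id, indels$variant_id)]

  say("stage 5/6: burden metrics")
  per_variant <- rbind(
    data.frame(sample = snvs$sample, class = cls[snvs$variant_id],
               expressed = snvs$expressed, readthrough = FALSE),
    data.frame(sample = ann$sample, class = ann$class,
               expressed = ann$expressed, readthrough = ann$readthrough))
  per_variant <- per_variant[per_variant$class %in%
                               c("nsSNV", "fs_indel"), ]
  summaries <- compute_burden_metrics(per_variant, clinical,
                                      samples = clinical$sample)

  say("stage 6/6: cohort analyses")
  fs_ann <- ann[ann$class == "fs_indel" & ann$found, ]
  metrics <- c("nsSNV", "expressed_nsSNV", "fs_indel", "nmd_escape")
  associations <- lapply(metrics, function(m) {
    tryCatch(benefit_association(summaries, m), error = function(e) NULL)
  })
  names(associations) <- metrics
  enrichment <- tryCatch(
    positional_enrichment(fs_ann$category[fs_ann$expressed],
                          fs_ann$category[!fs_ann$expressed]),
    error = function(e) NULL)
  vaf <- tryCatch(
    vaf_by_category(fs_ann$category[fs_ann$expressed],
                    fs_ann$rna_vaf[fs_ann$expressed]),
    error = function(e) NULL)
  pk <- match(protein$variant_id, fs_ann$variant_id)
  protein_test <- tryCatch(
    protein_comparison(protein$abundance[!is.na(pk)],
                       fs_ann$expressed[pk[!is.na(pk)]]),
    error = function(e) NULL)
  low_tmb <- tryCatch(
    low_tmb_analysis(summaries, threshold = config$low_tmb_threshold,
                     inclusive = config$low_tmb_inclusive),
    error = function(e) NULL)
  joint <- tryCatch(multivariable_model(summaries), error = function(e) NULL)
  sg_ann <- ann[ann$class == "stop_gain" & ann$found, ]
  selection <- tryCatch(
    selection_position_or(fs_ann$category, sg_ann$category),
    error = function(e) NULL)
  breadth <- tryCatch(
    hla_binding_breadth(binding, rank_cutoff = config$binder_rank),
    error = function(e) NULL)

  results <- build_results_table(associations, enrichment, vaf,
                                 protein_test, low_tmb, joint, selection)
  utils::write.table(results, file.path(config$outdir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summaries, file.path(config$outdir, "summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann, file.path(config$outdir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("nmdescape")),
    seed = config$seed, simulate = config$simulate,
    thresholds = list(padding = config$padding, min_alt = config$min_alt,
                      min_vaf = config$min_vaf,
                      binder_rank = config$binder_rank),
    stages = list(dna_calls = nrow(dna), snvs_pass = nrow(snvs),
                  indels_pass = nrow(indels), annotated = nrow(ann),
                  samples = nrow(summaries)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done (", round(manifest$elapsed_sec, 1), "s)")
  invisible(list(summaries = summaries, annotations = ann,
                 associations = associations, enrichment = enrichment,
                 vaf = vaf, protein_test = protein_test, low_tmb = low_tmb,
                 joint = joint, selection = selection, breadth = breadth,
                 results = results, manifest = manifest,
                 outdir = config$outdir))
}

build_results_table <- function(associations, enrichment, vaf, protein_test,
                                low_tmb, joint, selection) {
  rows <- list()
  add <- function(analysis, cohort, metric, statistic, estimate,
                  ci_low = NA, ci_high = NA, p = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, cohort = cohort, metric = metric,
      statistic = statistic, estimate = estimate, ci_low = ci_low,
      ci_high = ci_high, p = p)
  }
  for (m in names(associations)) {
    a <- associations[[m]]
    if (is.null(a)) next
    for (i in seq_len(nrow(a$per_cohort))) {
      add("benefit_association", a$per_cohort$cohort[i], m, "U",
          a$per_cohort$statistic[i], p = a$per_cohort$p_value[i])
    }
    add("benefit_association", "meta", m, "chi2", a$meta$chi_square,
        p = a$meta$p_meta)
    add("benefit_contingency", "pooled", m, "OR", a$contingency$odds_ratio,
        a$contingency$ci_low, a$contingency$ci_high,
        a$contingency$p_value)
  }
  if (!is.null(enrichment)) for (i in seq_len(nrow(enrichment))) {
    add("positional_enrichment", "pooled", enrichment$category[i], "OR",
        enrichment$odds_ratio[i], enrichment$ci_low[i],
        enrichment$ci_high[i], enrichment$p_value[i])
  }
  if (!is.null(vaf)) {
    for (cc in names(vaf$medians)) {
      add("vaf_by_category", "pooled", cc, "median", vaf$medians[[cc]])
    }
    if (!is.null(vaf$test)) {
      add("vaf_by_category", "pooled", "all", "H", vaf$test$statistic,
          p = vaf$test$p_value)
    }
  }
  if (!is.null(protein_test)) {
    add("protein_comparison", "pooled", "abundance", "U",
        protein_test$statistic, p = protein_test$p_value)
  }
  if (!is.null(low_tmb) && !isTRUE(low_tmb$degenerate)) {
    add("low_tmb", "pooled", "nmd_escape", "OR",
        low_tmb$escape$contingency$odds_ratio,
        low_tmb$escape$contingency$ci_low,
        low_tmb$escape$contingency$ci_high,
        low_tmb$escape$contingency$p_value)
    add("low_tmb", "pooled", "nsSNV", "U", NA, p = low_tmb$tmb_p)
  }
  if (!is.null(joint)) {
    cf <- joint$fit$coefficients
    for (i in seq_len(nrow(cf))) {
      add("multivariable_model", "pooled", cf$term[i], "beta",
          cf$estimate[i], p = cf$p_value[i])
    }
    add("tmb_escape_correlation", "pooled", "r", "pearson", joint$r)
  }
  if (!is.null(selection)) for (i in seq_len(nrow(selection))) {
    add("selection", "pooled", selection$category[i], "OR",
        selection$odds_ratio[i], selection$ci_low[i],
        selection$ci_high[i], selection$p_value[i])
  }
  do.call(rbind, rows)
}
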