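#' Simulate a transcriptome
#'
#' Generates `n_genes` genes, each with 1-3 isoforms laid out on 22 contigs
#' with random strand, exon count and exon lengths drawn from the configured
#' ranges. Every transcript carries a short 5' UTR, a CDS opening with ATG,
#' free of internal in-frame stops and closing with a stop codon, and a
#' random 3' UTR. Isoform base abundances are drawn log-normally and are
#' distinct within a gene unless `allow_abundance_ties` is set.
#'
#' @param config A [sim_config()].
#' @return Named list of `transcript_model`s (names are isoform ids).
#' @export
simulate_transcriptome <- function(config) {
  with_seed(config$seed, simulate_transcriptome_impl(config))
}

simulate_transcriptome_impl <- function(config) {
  cursor <- setNames(rep(1L, 22), paste0("chr", 1:22))
  out <- list()
  for (g in seq_len(config$n_genes)) {
    gene <- sprintf("GENE%04d", g)
    contig <- paste0("chr", 1L + (g - 1L) %% 22L)
    n_iso <- rint(config$isoforms_range)
    base_ab <- rlnorm(n_iso, meanlog = 3, sdlog = 1)
    if (!config$allow_abundance_ties) {
      while (anyDuplicated(base_ab)) base_ab <- base_ab + runif(n_iso, 0, 1e-6)
    }
    strand <- sample(c("+", "-"), 1)
    for (k in seq_len(n_iso)) {
      iso <- sprintf("%s.T%d", gene, k)
      n_ex <- rint(config$exon_count_range)
      ex_len <- rint(config$exon_length_range, n_ex)
      L <- sum(ex_len)
      u5 <- sample(10:50, 1)
      u3 <- rint(config$utr3_length_range)
      u3 <- max(0L, min(u3, L - u5 - 30L))
      u5 <- max(1L, min(u5, L - u3 - 30L))
      cds_len <- L - u5 - u3
      cds_len <- cds_len - cds_len %% 3L
      u3 <- L - u5 - cds_len
      if (cds_len < 30) {   # 10 codons: too short to host a usable CDS
        stop("exon lengths too short to host a CDS in gene ", gene)
      }
      seq <- paste0(random_dna(u5), random_cds(cds_len %/% 3L),
                    random_dna(u3))
      introns <- if (n_ex > 1) sample(50:500, n_ex - 1, replace = TRUE) else integer()
      starts <- cursor[contig] + c(0L, cumsum(ex_len[-n_ex] + introns))
      ends <- starts + ex_len - 1L
      cursor[contig] <- max(ends) + 1000L
      exons <- data.frame(start = starts, end = ends)
      if (strand == "-") exons <- exons[rev(seq_len(n_ex)), , drop = FALSE]
      rownames(exons) <- NULL
      out[[iso]] <- transcript_model(gene = gene, isoform = iso,
                                     contig = contig, strand = strand,
                                     exons = exons, cds_start = u5 + 1L,
                                     cds_end = u5 + cds_len,
                                     abundance = base_ab[k], seq = seq)
    }
  }
  out
}

#' Per-sample isoform abundance tables
#'
#' Base isoform abundances jittered log-normally per sample (sd 0.2 on the
#' log scale), emulating tumor-specific isoform quantifications from which
#' the dominant isoform is chosen.
#'
#' @param transcripts List of `transcript_model`s.
#' @param config A [sim_config()].
#' @return data.frame with `sample`, `isoform`, `gene`, `abundance`.
#' @export
simulate_isoform_abundance <- function(transcripts, config) {
  with_seed(config$seed + 1L, {
    ids <- names(transcripts)
    base <- vapply(transcripts, `[[`, numeric(1), "abundance")
    genes <- vapply(transcripts, `[[`, character(1), "gene")
    samples <- sprintf("S%03d", seq_len(config$n_samples))
    do.call(rbind, lapply(samples, function(s) {
      data.frame(sample = s, isoform = ids, gene = genes,
                 abundance = base * rlnorm(length(ids), 0, 0.2),
                 row.names = NULL)
    }))
  })
}

# hamming-1 stop-codon substitutions for each codon, built once on demand
.sim_cache <- new.env(parent = emptyenv())

stopgain_subs <- function() {
  if (!is.null(.sim_cache$subs)) return(.sim_cache$subs)
  codons <- names(Biostrings::GENETIC_CODE)
  res <- lapply(codons, function(cd) {
    if (cd %in% STOP_CODONS) return(NULL)
    hits <- list()
    for (p in 1:3) for (st in STOP_CODONS) {
      tmp <- cd
      substr(tmp, p, p) <- substr(st, p, p)
      if (tmp == st) {
        hits[[length(hits) + 1]] <- data.frame(offset = p,
                                               alt = substr(st, p, p))
      }
    }
    if (length(hits)) unique(do.call(rbind, hits)) else NULL
  })
  names(res) <- codons
  .sim_cache$subs <- res
  res
}

# classify an mRNA position into the five categories for a transcript
position_category <- function(tx, pos, spans = exon_mrna_spans(tx)) {
  e <- which(spans$m_start <= pos & spans$m_end >= pos)[1]
  n <- nrow(spans)
  if (n == 1 || e == n) return("LAST")
  if (e == n - 1) {
    return(if (spans$m_end[e] - pos <= 50) "PENULT_LE50" else "PENULT_GT50")
  }
  if (e == 1) return("FIRST")
  "MIDDLE"
}

# candidate stop-gain sites on a transcript: data.frame of mRNA position,
# mRNA-sense ref/alt base, codon start, and PTC category
stopgain_candidates <- function(tx) {
  cs <- tx$cds_start; ce <- tx$cds_end
  spans <- exon_mrna_spans(tx)
  codon_starts <- seq(cs + 3L, ce - 5L, by = 3L)  # skip start + stop codon
  if (length(codon_starts) == 0) return(NULL)
  cods <- substring(tx$seq, codon_starts, codon_starts + 2L)
  all_subs <- stopgain_subs()
  rows <- lapply(seq_along(codon_starts), function(i) {
    subs <- all_subs[[cods[i]]]
    if (is.null(subs)) return(NULL)
    m <- codon_starts[i] + subs$offset - 1L
    data.frame(m_pos = m,
               ref_m = substring(cods[i], subs$offset, subs$offset),
               alt_m = subs$alt, codon_start = codon_starts[i])
  })
  cand <- do.call(rbind, rows)
  if (is.null(cand)) return(NULL)
  cand$category <- vapply(cand$codon_start, position_category, character(1),
                          tx = tx, spans = spans)
  cand
}

# anchor-region proposal (mRNA coords) for placing an fs-indel whose PTC
# should land in `target`; PTC typically falls a short distance downstream
# of the indel, so regions are widened 60 nt upstream
fs_anchor_region <- function(tx, target) {
  spans <- exon_mrna_spans(tx)
  n <- nrow(spans)
  cs <- tx$cds_start; ce <- tx$cds_end
  reg <- switch(target,
    FIRST = if (n >= 3) c(spans$m_start[1], spans$m_end[1]) else NULL,
    MIDDLE = if (n >= 4) c(spans$m_start[2], spans$m_end[n - 2]) else NULL,
    PENULT_GT50 = if (n >= 2) c(spans$m_start[n - 1], spans$m_end[n - 1] - 51L) else NULL,
    PENULT_LE50 = if (n >= 2) c(spans$m_end[n - 1] - 90L, spans$m_end[n - 1]) else NULL,
    LAST = c(spans$m_start[n], spans$m_end[n]))
  if (is.null(reg)) return(NULL)
  lo <- max(reg[1] - 60L, cs + 3L)
  hi <- min(reg[2], ce - 1L)
  if (lo > hi) return(NULL) else c(lo, hi)
}

# build a genomic-sense indel record anchored at mRNA position m
make_indel_at <- function(tx, m, is_ins, L) {
  spans <- exon_mrna_spans(tx)
  e <- which(spans$m_start <= m & spans$m_end >= m)[1]
  if (tx$strand == "+") {
    if (is_ins) {
      if (m >= spans$m_end[e]) return(NULL)   # would insert into an intron
      ref <- substr(tx$seq, m, m)
      alt <- paste0(ref, random_dna(L))
    } else {
      if (m + L > spans$m_end[e] || m + L > tx$cds_end) return(NULL)
      ref <- substr(tx$seq, m, m + L)
      alt <- substr(ref, 1, 1)
    }
  } else {
    if (is_ins) {
      if (m <= spans$m_start[e]) return(NULL)
      ref <- revcomp(substr(tx$seq, m, m))
      alt <- paste0(ref, random_dna(L))
    } else {
      if (m - L < spans$m_start[e] || m - L < tx$cds_start + 3L) return(NULL)
      ref <- revcomp(substr(tx$seq, m - L, m))
      alt <- substr(ref, 1, 1)
    }
  }
  list(contig = tx$contig, position = mrna_to_genomic(tx, m), ref = ref,
       alt = alt)
}

#' Simulate per-sample somatic variant tables
#'
#' Draws per-sample counts of nsSNVs, stop-gain SNVs and fs-indels from
#' negative binomial distributions around the configured burden means
#' (overdispersed, matching the heavy tails of tumor mutation burden), then
#' places each variant on the sample's dominant isoform of a random gene.
#' Stop-gain and fs-indel PTC placements are sampled so the truth category
#' proportions follow the configured categorical distributions; when a
#' requested category is not realisable after repeated attempts the variant
#' is placed unconstrained and counted in the `relaxed` attribute.
#'
#' @param transcripts Output of [simulate_transcriptome()].
#' @param abundance Output of [simulate_isoform_abundance()].
#' @param config A [sim_config()].
#' @return List with `variants` (DNA call table, QC fields populated so all
#'   calls pass the paper-default filters) and `truth` (per-variant class,
#'   gene, isoform, true PTC category and neoORF length).
#' @export
simulate_somatic_variants <- function(transcripts, abundance, config) {
  with_seed(config$seed + 2L, {
    simulate_somatic_variants_impl(transcripts, abundance, config)
  })
}

simulate_somatic_variants_impl <- function(transcripts, abundance, config) {
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  genes <- unique(vapply(transcripts, `[[`, character(1), "gene"))
  by_gene <- split(transcripts, vapply(transcripts, `[[`, character(1), "gene"))
  sg_cache <- new.env(parent = emptyenv())
  relaxed <- 0L
  vrows <- list(); trows <- list(); vid <- 0L

  dominant_for <- function(sample, gene) {
    sub <- abundance[abundance$sample == sample & abundance$gene == gene, ]
    select_dominant_isoform(by_gene[[gene]],
                            setNames(sub$abundance, sub$isoform))
  }
  dna_evidence <- function(n, indel = FALSE) {
    depth <- pmax(20L, rpois(n, 100))
    vaf <- pmin(0.95, pmax(0.06, rbeta(n, 3, 7)))
    alt <- pmax(3L, rbinom(n, depth, vaf))
    data.frame(alt_reads = alt, ref_reads = depth - alt,
               vaf = alt / depth,
               callers = if (indel) "primary" else "primary,secondary",
               somatic_p = if (indel) runif(n, 0, 4.9e-4) else
                 runif(n, 0, 0.009),
               high_confidence = TRUE)
  }
  emit <- function(sample, tx, v, class, category, neoorf_len) {
    vid <<- vid + 1L
    id <- sprintf("var%06d", vid)
    vrows[[vid]] <<- data.frame(
      variant_id = id, sample = sample, contig = v$contig,
      position = v$position, ref = v$ref, alt = v$alt, assay = "DNA",
      class = class, gene = tx$gene, dna_evidence(1, indel = grepl("indel", class)))
    trows[[vid]] <<- data.frame(
      variant_id = id, sample = sample, gene = tx$gene, isoform = tx$isoform,
      class = class, category = category %||% NA_character_,
      neoorf_len = neoorf_len %||% NA_integer_)
  }

  n_codon_sites <- function(tx) (tx$cds_end - tx$cds_start + 1L) %/% 3L

  for (s in samples) {
    n_ns <- rnbinom(1, mu = config$burden_means[["nsSNV"]],
                    size = config$burden_size)
    n_sg <- rnbinom(1, mu = config$burden_means[["stop_gain"]],
                    size = config$burden_size)
    n_fs <- rnbinom(1, mu = config$burden_means[["fs_indel"]],
                    size = config$burden_size)

    # nsSNVs: random CDS codon, substitution to a different non-stop residue
    for (i in seq_len(n_ns)) {
      placed <- FALSE
      for (att in 1:20) {
        tx <- dominant_for(s, sample(genes, 1))
        nc <- n_codon_sites(tx)
        k <- sample(2:(nc - 1L), 1)
        c0 <- tx$cds_start + 3L * (k - 1L)
        codon <- substr(tx$seq, c0, c0 + 2L)
        ref_aa <- translate_codon(codon)
        cands <- list()
        for (p in 1:3) for (b in DNA_BASES) {
          if (b == substr(codon, p, p)) next
          tmp <- codon; substr(tmp, p, p) <- b
          aa <- translate_codon(tmp)
          if (aa != ref_aa && aa != "*") {
            cands[[length(cands) + 1]] <- c(p = p, b = b)
          }
        }
        if (length(cands) == 0) next
        pick <- cands[[sample(length(cands), 1)]]
        m <- c0 + as.integer(pick["p"]) - 1L
        ref_m <- substr(tx$seq, m, m); alt_m <- pick["b"]
        minus <- tx$strand == "-"
        v <- list(contig = tx$contig, position = mrna_to_genomic(tx, m),
                  ref = if (minus) complement_base(ref_m) else ref_m,
                  alt = if (minus) complement_base(alt_m) else unname(alt_m))
        emit(s, tx, v, "nsSNV", NA_character_, NA_integer_)
        placed <- TRUE; break
      }
      if (!placed) stop("could not place an nsSNV anywhere")
    }

    # stop-gain SNVs: category-targeted nonsense substitutions
    for (i in seq_len(n_sg)) {
      target <- sample(EXON_CATEGORIES, 1,
                       prob = config$stopgain_category_props)
      placed <- FALSE
      for (att in 1:40) {
        g <- sample(genes, 1)
        tx <- dominant_for(s, g)
        key <- tx$isoform
        if (is.null(sg_cache[[key]])) {
          sg_cache[[key]] <- stopgain_candidates(tx)
        }
        cand <- sg_cache[[key]]
        if (is.null(cand)) next
        sel <- cand[cand$category == target, , drop = FALSE]
        if (nrow(sel) == 0 && att == 40) {  # relax on final attempt
          sel <- cand; relaxed <- relaxed + 1L
        }
        if (nrow(sel) == 0) next
        j <- sel[sample(nrow(sel), 1), ]
        minus <- tx$strand == "-"
        v <- list(contig = tx$contig,
                  position = mrna_to_genomic(tx, j$m_pos),
                  ref = if (minus) complement_base(j$ref_m) else j$ref_m,
                  alt = if (minus) complement_base(j$alt_m) else j$alt_m)
        emit(s, tx, v, "stop_gain", j$category, 0L)
        placed <- TRUE; break
      }
      if (!placed) stop("no stop-gain site available in any gene")
    }

    # fs-indels: category-targeted by rejection on the realised PTC
    for (i in seq_len(n_fs)) {
      target <- sample(EXON_CATEGORIES, 1, prob = config$category_props)
      placed <- FALSE
      for (att in 1:200) {
        g <- sample(genes, 1)
        tx <- dominant_for(s, g)
        reg <- fs_anchor_region(tx, target)
        if (is.null(reg)) next
        m <- if (reg[1] == reg[2]) reg[1] else sample(reg[1]:reg[2], 1)
        v <- make_indel_at(tx, m, is_ins = runif(1) < 0.4,
                           L = sample(c(1L, 2L), 1))
        if (is.null(v)) next
        ptc <- tryCatch(compute_ptc(v, tx), error = function(e) NULL)
        if (is.null(ptc)) next
        if (!ptc$found) next
        cat <- classify_ptc_exon_position(ptc, tx)$category
        relax <- att >= 150
        if (cat == target || relax) {
          if (cat != target) relaxed <- relaxed + 1L
          emit(s, tx, v, "fs_indel", cat, ptc$neoorf_len)
          placed <- TRUE; break
        }
      }
      if (!placed) stop("could not realise fs-indel PTC category ", target)
    }
  }
  variants <- do.call(rbind, vrows)
  truth <- do.call(rbind, trows)
  structure(list(variants = variants, truth = truth), relaxed = relaxed)
}

# Beta VAF draw at a category's configured median
draw_vaf <- function(n, median, concentration) {
  sh <- beta_shapes_for_median(median, concentration)
  rbeta(n, sh["a"], sh["b"])
}

# RNA read counts passing the >=5 alt reads / >=0.05 VAF thresholds, at a
# target allele fraction (redrawn until detectable, so noise-free truth
# consistency holds)
rna_counts_detectable <- function(vaf_true, depth_mean) {
  for (att in 1:100) {
    depth <- max(12L, rpois(1, depth_mean))
    alt <- rbinom(1, depth, vaf_true)
    if (alt >= 5 && alt / depth >= 0.05) {
      return(c(alt = alt, ref = depth - alt))
    }
  }
  c(alt = max(5L, as.integer(round(depth_mean * vaf_true))),
    ref = as.integer(round(depth_mean * (1 - vaf_true))))
}

#' Simulate RNA expression evidence and protein abundance
#'
#' Each variant is expressed with the category-dependent probability
#' (nsSNVs with `snv_expression_prob`). Expressed fs-indels receive an RNA
#' indel call whose position is jittered within 2 nt (alignment mismatch)
#' and whose VAF is Beta-distributed around the category median; expressed
#' SNVs (nsSNV and stop-gain) receive RNA allele counts at the exact DNA
#' position. RNA rows exist only for expressed variants. Protein abundance
#' per fs-indel gene is standard-normal baseline plus `protein_shift` when
#' the fs-indel is expressed.
#'
#' @param variants DNA variant table from [simulate_somatic_variants()].
#' @param truth Matching truth table.
#' @param config A [sim_config()].
#' @return List of `rna_indels`, `rna_snv_counts`, `protein`, and the
#'   `truth` table extended with `expressed` and `rna_vaf`.
#' @export
simulate_expression_evidence <- function(variants, truth, config) {
  with_seed(config$seed + 3L, {
    n <- nrow(truth)
    eprob <- ifelse(truth$class == "nsSNV", config$snv_expression_prob,
                    ifelse(is.na(truth$category), 0,
                           config$category_expression_prob[truth$category]))
    truth$expressed <- runif(n) < eprob
    truth$rna_vaf <- NA_real_
    med <- ifelse(truth$class == "nsSNV", 0.30,
                  config$category_vaf_median[truth$category])
    idx <- which(truth$expressed)
    truth$rna_vaf[idx] <- vapply(idx, function(i) {
      draw_vaf(1, med[i], config$vaf_concentration)
    }, numeric(1))

    vk <- match(truth$variant_id, variants$variant_id)
    ri <- list(); rs <- list()
    for (i in idx) {
      v <- variants[vk[i], ]
      cnt <- rna_counts_detectable(truth$rna_vaf[i], config$rna_depth_mean)
      if (truth$class[i] == "fs_indel") {
        ri[[length(ri) + 1]] <- data.frame(
          sample = v$sample, contig = v$contig,
          position = v$position + sample(-2:2, 1),
          ref = v$ref, alt = v$alt, assay = "RNA",
          alt_reads = unname(cnt["alt"]), ref_reads = unname(cnt["ref"]),
          vaf = unname(cnt["alt"] / sum(cnt)))
      } else {
        rs[[length(rs) + 1]] <- data.frame(
          sample = v$sample, contig = v$contig, position = v$position,
          ref = v$ref, alt = v$alt,
          alt_reads = unname(cnt["alt"]), ref_reads = unname(cnt["ref"]))
      }
    }
    empty_rna <- data.frame(sample = character(), contig = character(),
                            position = integer(), ref = character(),
                            alt = character(), assay = character(),
                            alt_reads = integer(), ref_reads = integer(),
                            vaf = numeric())
    fs <- truth[truth$class == "fs_indel", ]
    protein <- if (nrow(fs)) {
      data.frame(sample = fs$sample, gene = fs$gene,
                 variant_id = fs$variant_id,
                 abundance = rnorm(nrow(fs)) +
                   config$protein_shift * fs$expressed)
    } else {
      data.frame(sample = character(), gene = character(),
                 variant_id = character(), abundance = numeric())
    }
    list(rna_indels = if (length(ri)) do.call(rbind, ri) else empty_rna,
         rna_snv_counts = if (length(rs)) do.call(rbind, rs) else
           empty_rna[, setdiff(names(empty_rna), c("assay", "vaf"))],
         protein = protein, truth = truth)
  })
}

#' Simulate clinical outcomes
#'
#' Draws a binary clinical-benefit label per sample with probability keyed
#' on whether the sample's true NMD-escape count (expressed fs-indels) is
#' zero or at least one, and assigns cohort labels by the configured cohort
#' sizes.
#'
#' @param truth Truth table with `expressed` filled in.
#' @param config A [sim_config()].
#' @return data.frame `sample`, `cohort`, `true_escape_count`, `benefit`.
#' @export
simulate_clinical_outcomes <- function(truth, config) {
  with_seed(config$seed + 4L, {
    samples <- sprintf("S%03d", seq_len(config$n_samples))
    stray <- setdiff(unique(truth$sample), samples)
    if (length(stray)) {
      stop("truth table contains samples outside the configured cohort: ",
           paste(utils::head(stray, 3), collapse = ", "))
    }
    esc <- vapply(samples, function(s) {
      sum(truth$sample == s & truth$class == "fs_indel" & truth$expressed)
    }, numeric(1))
    p <- config$benefit_prob_by_escape[1 + (esc >= 1)]
    sizes <- config$cohort_sizes
    cohorts <- rep(paste0("cohort", seq_along(sizes)), times = sizes)
    cohorts <- rep_len(cohorts, length(samples))
    data.frame(sample = samples, cohort = cohorts,
               true_escape_count = as.integer(esc),
               benefit = runif(length(samples)) < p, row.names = NULL)
  })
}

#' Simulate an HLA binding-prediction table
#'
#' For every fs-indel with a positive neoORF length, and up to
#' `binding_max_nssnv` nsSNVs, emits one row per peptide x HLA allele over a
#' six-allele class I genotype with a percentile rank score. nsSNVs carry
#' one window per length containing the mutated residue; fs-indels carry
#' `neoORF + k - 1` windows per length, so longer neoORFs emit
#' proportionally more peptide rows. Each pair is a binder (rank drawn
#' below 0.5) with probability `binder_prob`.
#'
#' @param truth Truth table.
#' @param config A [sim_config()].
#' @return data.frame `variant_id`, `class`, `peptide`, `allele`, `rank`.
#' @export
simulate_hla_binding <- function(truth, config) {
  with_seed(config$seed + 5L, {
    fs <- truth[truth$class == "fs_indel" & !is.na(truth$neoorf_len) &
                  truth$neoorf_len > 0, ]
    ns <- truth[truth$class == "nsSNV", ]
    if (nrow(ns) > config$binding_max_nssnv) {
      ns <- ns[sample(nrow(ns), config$binding_max_nssnv), ]
    }
    muts <- rbind(
      if (nrow(fs)) data.frame(variant_id = fs$variant_id, class = "fs_indel",
                               n_pep = vapply(fs$neoorf_len, function(L) {
                                 sum(pmax(0L, L + config$peptide_lengths - 1L))
                               }, numeric(1))),
      if (nrow(ns)) data.frame(variant_id = ns$variant_id, class = "nsSNV",
                               n_pep = sum(config$peptide_lengths)))
    if (is.null(muts) || nrow(muts) == 0) {
      return(data.frame(variant_id = character(), class = character(),
                        peptide = character(), allele = character(),
                        rank = numeric()))
    }
    alleles <- sprintf("HLA-%02d", seq_len(config$n_hla_alleles))
    rows <- lapply(seq_len(nrow(muts)), function(i) {
      np <- muts$n_pep[i]
      if (np == 0) return(NULL)
      pep <- rep(sprintf("%s_pep%03d", muts$variant_id[i], seq_len(np)),
                 each = length(alleles))
      al <- rep(alleles, np)
      binder <- runif(length(pep)) < config$binder_prob
      data.frame(variant_id = muts$variant_id[i], class = muts$class[i],
                 peptide = pep, allele = al,
                 rank = ifelse(binder, runif(length(pep), 0, 0.5),
                               runif(length(pep), 0.5, 100)))
    })
    do.call(rbind, rows)
  })
}

#' Fast category-level draw of fs-indel truth
#'
#' Samples (category, expressed, RNA VAF) triples directly from the
#' configured categorical placement distribution, category expression
#' probabilities and VAF medians, bypassing sequence-level simulation. Used
#' for large statistical-recovery experiments where only the category-level
#' structure matters.
#'
#' @param n Number of variants.
#' @param config A [sim_config()].
#' @param props Optional placement proportions overriding
#'   `config$category_props`.
#' @param seed Optional seed (defaults to the configuration's).
#' @return data.frame `category`, `expressed`, `rna_vaf` (NA when not
#'   expressed).
#' @export
simulate_category_table <- function(n, config, props = NULL, seed = NULL) {
  run <- function() {
    p <- props %||% config$category_props
    category <- sample(EXON_CATEGORIES, n, replace = TRUE, prob = p)
    expressed <- runif(n) < config$category_expression_prob[category]
    rna_vaf <- rep(NA_real_, n)
    for (cat in EXON_CATEGORIES) {
      i <- which(expressed & category == cat)
      if (length(i)) {
        rna_vaf[i] <- draw_vaf(length(i), config$category_vaf_median[cat],
                               config$vaf_concentration)
      }
    }
    data.frame(category = category, expressed = expressed, rna_vaf = rna_vaf)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a full synthetic cohort
#'
#' Orchestrates [simulate_transcriptome()], [simulate_isoform_abundance()],
#' [simulate_somatic_variants()], [simulate_expression_evidence()],
#' [simulate_clinical_outcomes()] and [simulate_hla_binding()] under the
#' configuration's seed. Identical configurations yield identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` list: `transcripts`, `abundance`,
#'   `dna_variants`, `rna_indels`, `rna_snv_counts`, `protein`,
#'   `hla_binding`, `clinical`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  tx <- simulate_transcriptome(config)
  ab <- simulate_isoform_abundance(tx, config)
  sv <- simulate_somatic_variants(tx, ab, config)
  ev <- simulate_expression_evidence(sv$variants, sv$truth, config)
  cl <- simulate_clinical_outcomes(ev$truth, config)
  hla <- simulate_hla_binding(ev$truth, config)
  structure(list(transcripts = tx, abundance = ab,
                 dna_variants = sv$variants, rna_indels = ev$rna_indels,
                 rna_snv_counts = ev$rna_snv_counts, protein = ev$protein,
                 hla_binding = hla, clinical = cl, truth = ev$truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d transcripts, %d DNA variants (%d expressed in truth)\n",
              x$config$n_samples, length(x$transcripts),
              nrow(x$dna_variants), sum(x$truth$expressed)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the transcript annotation (GTF), spliced transcript sequences
#' (FASTA) and all tables (TSV) under `outdir` with stable column headers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_transcript_gtf(cohort$transcripts, file.path(outdir, "transcripts.gtf"))
  write_transcript_fasta(cohort$transcripts, file.path(outdir, "transcripts.fa"))
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(cohort$abundance, "isoform_abundance.tsv")
  tsv(cohort$dna_variants, "dna_variants.tsv")
  tsv(cohort$rna_indels, "rna_indels.tsv")
  tsv(cohort$rna_snv_counts, "rna_snv_counts.tsv")
  tsv(cohort$protein, "protein_abundance.tsv")
  tsv(cohort$hla_binding, "hla_binding.tsv")
  tsv(cohort$clinical, "clinical.tsv")
  tsv(cohort$truth, "truth.tsv")
  invisible(outdir)
}
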