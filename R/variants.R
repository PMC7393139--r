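#' Read somatic variant calls
#'
#' Reads a variant table from VCF or from a MAF-like tab-separated file into
#' the package's tidy variant representation: one row per sample x variant
#' allele with 1-based coordinates, multi-allelic records split, and shared
#' ref/alt bases trimmed (suffix first, then prefix) while retaining the
#' anchor base for indels.
#'
#' @param path File path.
#' @param dialect `"vcf"` or `"maf_tsv"`. The MAF-like dialect expects
#'   columns `sample`, `contig`, `position`, `ref`, `alt` and passes through
#'   any of `assay`, `callers` (comma-separated), `somatic_p`, `alt_reads`,
#'   `ref_reads`, `vaf`, `high_confidence`, `class`.
#' @return data.frame of variant calls; `vaf` is recomputed from read counts
#'   when both are present.
#' @export
read_variants <- function(path, dialect = c("maf_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "vcf") read_variants_vcf(path) else read_variants_maf(path)
}

read_variants_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample", "contig", "position", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  bad <- which(is.na(df$position) | df$position < 1 | df$ref == df$alt |
                 !grepl("^[ACGTacgt]+$", df$ref) |
                 !grepl("^[ACGTacgt]+$", df$alt))
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  }
  norm <- normalize_variants(df$position, df$ref, df$alt)
  df$position <- norm$position; df$ref <- norm$ref; df$alt <- norm$alt
  if (!is.null(df$alt_reads) && !is.null(df$ref_reads)) {
    tot <- df$alt_reads + df$ref_reads
    df$vaf <- ifelse(tot > 0, df$alt_reads / tot, NA_real_)
  }
  df
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(sample = character(), contig = character(),
                      position = integer(), ref = character(),
                      alt = character()))
  }
  samp <- if (ncol(v@gt) >= 2) colnames(v@gt)[2] else NA_character_
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) == 0 || anyNA(alts)) {
      stop("malformed VCF record at data line ", i, " of ", path)
    }
    data.frame(sample = samp, contig = fix$CHROM[i],
               position = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (any(is.na(df$position))) stop("malformed POS field in ", path)
  norm <- normalize_variants(df$position, df$ref, df$alt)
  df$position <- norm$position; df$ref <- norm$ref; df$alt <- norm$alt
  df
}

# Trim shared trailing then leading bases from ref/alt, keeping at least one
# base of each (the VCF anchor for indels) and advancing the position as
# leading bases are removed.
normalize_variants <- function(position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1L); a <- substr(a, 1, nchar(a) - 1L)
    }
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a))
      position[i] <- position[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(position = position, ref = ref, alt = alt)
}

#' Post-caller quality filters for somatic calls
#'
#' `consensus_filter_snvs` keeps an SNV when it was called by both the
#' primary and secondary caller with VAF > 2\% and a primary-caller somatic
#' p-value <= 0.01, or by the primary caller alone with VAF >= 5\% (again
#' with somatic p <= 0.01). "Primary" is the caller that supplies somatic
#' p-values (VarScan2-style); "secondary" is the consensus caller
#' (MuTect-style). `filter_indels` keeps indels flagged high-confidence with
#' somatic p strictly below 5e-4. Both filters preserve input order, are
#' idempotent, and with `detail = TRUE` return the full table with `keep`
#' and `filter_reason` columns instead of the filtered subset.
#'
#' @param calls data.frame with columns `vaf`, `callers` (comma-separated
#'   labels containing `"primary"`/`"secondary"`), `somatic_p`; indels also
#'   need `high_confidence` (logical).
#' @param primary,secondary Caller labels taking the two roles.
#' @param detail Return the annotated full table instead of the subset.
#' @return Filtered data.frame (or annotated table when `detail = TRUE`).
#' @export
consensus_filter_snvs <- function(calls, primary = "primary",
                                  secondary = "secondary", detail = FALSE) {
  if (nrow(calls) == 0) return(calls)
  caller_sets <- strsplit(calls$callers, ",", fixed = TRUE)
  has_p <- vapply(caller_sets, function(s) primary %in% trimws(s), logical(1))
  has_s <- vapply(caller_sets, function(s) secondary %in% trimws(s), logical(1))
  if (any(has_p & is.na(calls$somatic_p))) {
    i <- which(has_p & is.na(calls$somatic_p))[1]
    stop("missing somatic p-value on primary-caller call at row ", i,
         " (", calls$contig[i], ":", calls$position[i], ")")
  }
  p_ok <- has_p & !is.na(calls$somatic_p) & calls$somatic_p <= 0.01
  keep_both <- calls$vaf > 0.02 & has_p & has_s & p_ok
  keep_solo <- calls$vaf >= 0.05 & has_p & !has_s & p_ok
  keep <- keep_both | keep_solo
  if (detail) {
    calls$keep <- keep
    calls$filter_reason <- ifelse(keep, "pass",
      ifelse(!p_ok, "somatic_p",
             ifelse(has_s, "vaf_le_0.02", "vaf_lt_0.05_single_caller")))
    return(calls)
  }
  calls[keep, , drop = FALSE]
}

#' @rdname consensus_filter_snvs
#' @export
filter_indels <- function(calls, detail = FALSE) {
  if (nrow(calls) == 0) return(calls)
  if (is.null(calls$high_confidence) || is.null(calls$somatic_p)) {
    stop("indel calls need high_confidence and somatic_p columns")
  }
  keep <- !is.na(calls$high_confidence) & calls$high_confidence &
    !is.na(calls$somatic_p) & calls$somatic_p < 5e-4
  if (detail) {
    calls$keep <- keep
    calls$filter_reason <- ifelse(keep, "pass",
      ifelse(!calls$high_confidence | is.na(calls$high_confidence),
             "not_high_confidence", "somatic_p"))
    return(calls)
  }
  calls[keep, , drop = FALSE]
}

#' Classify the functional effect of a variant on a transcript
#'
#' SNVs inside the CDS are classified by translating the reference and
#' alternate codon: identical residue -> synonymous, stop residue ->
#' stop-gain, otherwise nsSNV. Indels inside the CDS are frameshift when the
#' length change is not a multiple of 3, otherwise in-frame. Positions
#' outside the CDS (including intronic) are non-coding. All effect logic
#' runs in spliced, strand-corrected mRNA space.
#'
#' @param variant List or one-row data.frame with `position`, `ref`, `alt`.
#' @param transcript A `transcript_model`.
#' @param sequence Optional spliced mRNA sequence.
#' @return One of `"nsSNV"`, `"synonymous"`, `"stop_gain"`, `"fs_indel"`,
#'   `"inframe_indel"`, `"non_coding"`.
#' @export
classify_effect <- function(variant, transcript, sequence = NULL) {
  seq <- sequence %||% transcript$seq
  pos <- variant$position; ref <- variant$ref; alt <- variant$alt
  lo <- min(transcript$exons$start); hi <- max(transcript$exons$end)
  if (pos < lo || pos > hi) {
    stop("variant does not overlap transcript ", transcript$isoform)
  }
  cs <- transcript$cds_start; ce <- transcript$cds_end
  if (nchar(ref) == nchar(alt)) {       # SNV (or MNV treated base-wise)
    m <- genomic_to_mrna(transcript, pos)
    if (is.na(m) || m < cs || m > ce) return("non_coding")
    if (is.na(seq)) stop("transcript ", transcript$isoform, " has no sequence")
    alt_m <- if (transcript$strand == "-") complement_base(alt) else alt
    c0 <- cs + 3L * ((m - cs) %/% 3L)
    codon <- substr(seq, c0, c0 + 2L)
    ref_aa <- translate_codon(codon)
    substr(codon, m - c0 + 1L, m - c0 + 1L) <- substr(alt_m, 1, 1)
    alt_aa <- translate_codon(codon)
    if (is.na(alt_aa)) return("non_coding")
    if (alt_aa == ref_aa) return("synonymous")
    if (alt_aa == "*") return("stop_gain")
    return("nsSNV")
  }
  m <- genomic_to_mrna(transcript, pos)
  if (is.na(m) || m < cs || m > ce) return("non_coding")
  if (abs(nchar(alt) - nchar(ref)) %% 3L != 0L) "fs_indel" else "inframe_indel"
}

#' @rdname classify_effect
#' @param variants data.frame of variant calls (`contig`, `position`, `ref`,
#'   `alt`, optionally `gene`).
#' @param transcripts Named list of `transcript_model`s; each variant is
#'   classified against its gene's stored-abundance dominant isoform.
#' @return `classify_effects`: character vector of effect classes.
#' @export
classify_effects <- function(variants, transcripts) {
  genes <- vapply(transcripts, `[[`, character(1), "gene")
  by_gene <- split(transcripts, genes)
  if (is.null(variants$gene)) variants$gene <- locate_gene(variants, transcripts)
  dom <- lapply(by_gene, select_dominant_isoform)
  vapply(seq_len(nrow(variants)), function(i) {
    classify_effect(variants[i, ], dom[[variants$gene[i]]])
  }, character(1))
}
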