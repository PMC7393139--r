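#' Designate expressed indels by DNA/RNA intersection
#'
#' A DNA indel is designated expressed when an RNA-called indel of the same
#' type (insertion vs deletion) lies on the same contig (and sample, when a
#' `sample` column is present) within `padding` nucleotides, with at least
#' `min_alt` alternative reads and RNA VAF at or above `min_vaf`. The
#' nearest qualifying RNA call is attached (ties broken towards the smaller
#' position); each RNA call supports at most one DNA call, assigned greedily
#' in DNA position order.
#'
#' @param dna_indels data.frame of QC-passed DNA indel calls (`contig`,
#'   `position`, `ref`, `alt`, optional `sample`).
#' @param rna_indels data.frame of RNA indel calls carrying `rna_alt_reads`
#'   (or `alt_reads`) and `rna_vaf` (or `vaf`), plus `contig`, `position`,
#'   `ref`, `alt`.
#' @param padding Maximum DNA-RNA position difference in nucleotides
#'   (inclusive); allows for minor alignment mismatches.
#' @param min_alt Minimum RNA alternative-read count (inclusive).
#' @param min_vaf Minimum RNA variant allele frequency (inclusive).
#' @return `dna_indels` with added columns `expressed`, `rna_position`,
#'   `rna_alt_reads`, `rna_vaf`, `match_distance`.
#' @export
match_indels_dna_rna <- function(dna_indels, rna_indels, padding = 10,
                                 min_alt = 5, min_vaf = 0.05) {
  if (padding < 0) stop("padding must be non-negative")
  out <- dna_indels
  out$expressed <- FALSE
  out$rna_position <- NA_integer_
  out$rna_alt_reads <- NA_integer_
  out$rna_vaf <- NA_real_
  out$match_distance <- NA_integer_
  if (nrow(dna_indels) == 0) return(out)
  rna <- rna_indels
  if (nrow(rna) > 0) {
    if (is.null(rna$rna_alt_reads)) rna$rna_alt_reads <- rna$alt_reads
    if (is.null(rna$rna_vaf)) rna$rna_vaf <- rna$vaf
    rna$sign <- sign(nchar(rna$alt) - nchar(rna$ref))
    rna <- rna[rna$rna_alt_reads >= min_alt & rna$rna_vaf >= min_vaf, ,
               drop = FALSE]
  }
  dna_sign <- sign(nchar(out$alt) - nchar(out$ref))
  has_sample <- !is.null(out$sample) && !is.null(rna$sample)
  used <- rep(FALSE, nrow(rna))
  ord <- order(out$position)
  for (i in ord) {
    if (nrow(rna) == 0) break
    cand <- which(!used &
                    rna$contig == out$contig[i] &
                    rna$sign == dna_sign[i] &
                    abs(rna$position - out$position[i]) <= padding)
    if (has_sample) cand <- cand[rna$sample[cand] == out$sample[i]]
    if (length(cand) == 0) next
    d <- abs(rna$position[cand] - out$position[i])
    best <- cand[d == min(d)]
    if (length(best) > 1) best <- best[which.min(rna$position[best])]
    best <- best[1]
    used[best] <- TRUE
    out$expressed[i] <- TRUE
    out$rna_position[i] <- rna$position[best]
    out$rna_alt_reads[i] <- rna$rna_alt_reads[best]
    out$rna_vaf[i] <- rna$rna_vaf[best]
    out$match_distance[i] <- abs(rna$position[best] - out$position[i])
  }
  out
}

#' Designate expressed SNVs from RNA allele counts
#'
#' An SNV is expressed when the RNA allele-count table holds, at the
#' identical position and alternate allele (no padding), at least `min_alt`
#' alternative reads and VAF at or above `min_vaf`.
#'
#' @param dna_snvs data.frame of QC-passed DNA SNV calls.
#' @param rna_allele_counts data.frame with `contig`, `position`, `alt`,
#'   `rna_alt_reads` (or `alt_reads`), `rna_ref_reads` (or `ref_reads`),
#'   optional `sample`.
#' @inheritParams match_indels_dna_rna
#' @return `dna_snvs` with added `expressed`, `rna_alt_reads`, `rna_vaf`.
#' @export
flag_expressed_snvs <- function(dna_snvs, rna_allele_counts, min_alt = 5,
                                min_vaf = 0.05) {
  out <- dna_snvs
  out$expressed <- FALSE
  out$rna_alt_reads <- NA_integer_
  out$rna_vaf <- NA_real_
  if (nrow(dna_snvs) == 0 || nrow(rna_allele_counts) == 0) return(out)
  rna <- rna_allele_counts
  if (is.null(rna$rna_alt_reads)) rna$rna_alt_reads <- rna$alt_reads
  if (is.null(rna$rna_ref_reads)) rna$rna_ref_reads <- rna$ref_reads
  tot <- rna$rna_alt_reads + rna$rna_ref_reads
  rna$rna_vaf <- ifelse(tot > 0, rna$rna_alt_reads / tot, 0)
  key <- function(d) {
    s <- if (!is.null(d$sample)) d$sample else ""
    paste(s, d$contig, d$position, d$alt, sep = "|")
  }
  idx <- match(key(out), key(rna))
  hit <- !is.na(idx)
  out$rna_alt_reads[hit] <- rna$rna_alt_reads[idx[hit]]
  out$rna_vaf[hit] <- rna$rna_vaf[idx[hit]]
  out$expressed <- hit & out$rna_alt_reads >= min_alt &
    out$rna_vaf >= min_vaf
  out$expressed[is.na(out$expressed)] <- FALSE
  out
}
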