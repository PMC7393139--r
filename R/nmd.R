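#' Select the dominant isoform of a gene
#'
#' Variant annotation is performed on the isoform with the highest
#' expression abundance for the gene in the sample under study. Ties are
#' broken deterministically towards the lexicographically smaller isoform
#' identifier.
#'
#' @param transcripts List of `transcript_model`s belonging to one gene.
#' @param abundances Optional named numeric vector (isoform -> abundance)
#'   overriding the abundances stored on the models.
#' @return The dominant `transcript_model`.
#' @export
select_dominant_isoform <- function(transcripts, abundances = NULL) {
  if (length(transcripts) == 0) stop("no isoforms supplied")
  ids <- vapply(transcripts, `[[`, character(1), "isoform")
  ab <- if (is.null(abundances)) {
    vapply(transcripts, `[[`, numeric(1), "abundance")
  } else {
    unname(abundances[ids])
  }
  if (anyNA(ab)) stop("missing abundance for isoform(s): ",
                      paste(ids[is.na(ab)], collapse = ", "))
  best <- which(ab == max(ab))
  if (length(best) > 1) best <- best[order(ids[best])][1]
  transcripts[[best]]
}

# Translate an mRNA edit (genomic indel under the VCF anchor-base
# convention) into spliced-transcript space. Returns the reference-mRNA
# slot where the edit applies: mutant = seq[1..del_start-1] + ins +
# seq[(del_start+del_len)..]. Everything from mutant position del_start
# onward is frame-shifted.
mrna_edit <- function(variant, tx) {
  ref <- variant$ref; alt <- variant$alt; pos <- variant$position
  stopifnot(nchar(ref) >= 1, nchar(alt) >= 1)
  L <- abs(nchar(alt) - nchar(ref))
  if (L == 0) stop("variant is not an indel")
  m_anchor <- genomic_to_mrna(tx, pos)
  if (is.na(m_anchor)) stop("indel anchor is intronic on ", tx$isoform)
  is_ins <- nchar(alt) > nchar(ref)
  if (is_ins) {
    ins_g <- substr(alt, nchar(ref) + 1, nchar(alt))
    if (tx$strand == "+") {
      list(del_start = m_anchor + 1L, del_len = 0L, ins = ins_g)
    } else {
      list(del_start = m_anchor, del_len = 0L, ins = revcomp(ins_g))
    }
  } else {
    # deleted genomic bases pos+1 .. pos+L must be exonic and contiguous
    # with the anchor in mRNA space
    m_last <- genomic_to_mrna(tx, pos + L)
    if (is.na(m_last) || abs(m_last - m_anchor) != L) {
      stop("deletion spans an exon junction on ", tx$isoform)
    }
    if (tx$strand == "+") {
      list(del_start = m_anchor + 1L, del_len = L, ins = "")
    } else {
      list(del_start = m_anchor - L, del_len = L, ins = "")
    }
  }
}

#' Premature termination codon after a frameshift
#'
#' Applies a frameshift indel to the spliced mRNA, then translates in the
#' shifted frame from the codon containing the first shifted nucleotide,
#' continuing through the 3' UTR if necessary, until the first stop codon.
#' `neoorf_len` counts the shifted-frame codons translated before that stop
#' (the neoORF length in amino acids); if no stop exists before the
#' transcript end the variant is flagged `readthrough` and no PTC position
#' is reported.
#'
#' @param variant List or one-row data.frame with `position` (1-based
#'   genomic), `ref`, `alt` (VCF anchor-base convention).
#' @param transcript A `transcript_model` with its spliced sequence.
#' @param sequence Optional spliced mRNA sequence overriding
#'   `transcript$seq`.
#' @return A `ptc_result`: `found`, `readthrough`, `ptc_mrna_pos` (first
#'   stop-codon nucleotide, mutant-mRNA coordinates), `ptc_ref_pos` (same
#'   position projected back onto the reference transcript, used for exon
#'   classification), `ptc_cds_pos`, `neoorf_len`, plus the wildtype protein
#'   prefix and shifted-frame residues for peptide derivation.
#' @export
compute_ptc <- function(variant, transcript, sequence = NULL) {
  seq <- sequence %||% transcript$seq
  if (is.na(seq)) stop("transcript ", transcript$isoform, " has no sequence")
  L <- abs(nchar(variant$alt) - nchar(variant$ref))
  if (L %% 3 == 0) stop("in-frame indel: not a frameshift")
  ed <- mrna_edit(variant, transcript)
  cs <- transcript$cds_start; ce <- transcript$cds_end
  if (ed$del_start <= cs + 2 || ed$del_start > ce) {
    stop("variant outside the CDS body of ", transcript$isoform)
  }
  ins_len <- nchar(ed$ins)
  mut <- paste0(substr(seq, 1, ed$del_start - 1), ed$ins,
                substr(seq, ed$del_start + ed$del_len, nchar(seq)))
  first_shift <- ed$del_start
  shift_codon <- cs + 3L * ((first_shift - cs) %/% 3L)
  # scan shifted-frame codons for the first stop
  i <- shift_codon
  ptc <- NA_integer_
  n <- nchar(mut)
  while (i + 2L <= n) {
    if (substr(mut, i, i + 2L) %in% STOP_CODONS) { ptc <- i; break }
    i <- i + 3L
  }
  map_ref <- function(j) {
    if (j < ed$del_start) j
    else if (j >= ed$del_start + ins_len) j - ins_len + ed$del_len
    else ed$del_start
  }
  prefix_aa <- if (shift_codon > cs) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(mut, cs, shift_codon - 1L))))
  } else ""
  if (is.na(ptc)) {
    return(structure(list(found = FALSE, readthrough = TRUE,
                          ptc_mrna_pos = NA_integer_,
                          ptc_ref_pos = NA_integer_,
                          ptc_cds_pos = NA_integer_,
                          neoorf_len = (n - shift_codon + 1L) %/% 3L,
                          prefix_aa = prefix_aa, neoorf_aa = NA_character_),
                     class = "ptc_result"))
  }
  neoorf_len <- (ptc - shift_codon) %/% 3L
  neoorf_aa <- if (neoorf_len > 0) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(mut, shift_codon, ptc - 1L))))
  } else ""
  ref_pos <- map_ref(ptc)
  structure(list(found = TRUE, readthrough = FALSE,
                 ptc_mrna_pos = as.integer(ptc),
                 ptc_ref_pos = as.integer(ref_pos),
                 ptc_cds_pos = as.integer(ref_pos - cs + 1L),
                 neoorf_len = as.integer(neoorf_len),
                 prefix_aa = prefix_aa, neoorf_aa = neoorf_aa),
            class = "ptc_result")
}

#' @rdname compute_ptc
#' @details `ptc_from_stopgain` handles nonsense SNVs, for which the PTC is
#'   the mutated codon itself and `neoorf_len = 0`; classification then uses
#'   the same exon-position rules, which apply equally to both mutation
#'   classes.
#' @export
ptc_from_stopgain <- function(variant, transcript, sequence = NULL) {
  seq <- sequence %||% transcript$seq
  if (is.na(seq)) stop("transcript ", transcript$isoform, " has no sequence")
  if (nchar(variant$ref) != 1 || nchar(variant$alt) != 1) {
    stop("not an SNV")
  }
  m <- genomic_to_mrna(transcript, variant$position)
  if (is.na(m)) stop("SNV is intronic on ", transcript$isoform)
  cs <- transcript$cds_start
  if (m < cs || m > transcript$cds_end) stop("SNV outside CDS")
  alt_m <- if (transcript$strand == "-") complement_base(variant$alt) else variant$alt
  c0 <- cs + 3L * ((m - cs) %/% 3L)
  codon <- substr(seq, c0, c0 + 2L)
  substr(codon, m - c0 + 1L, m - c0 + 1L) <- alt_m
  if (!codon %in% STOP_CODONS) stop("variant does not create a stop codon")
  prefix_aa <- if (c0 > cs) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seq, cs, c0 - 1L))))
  } else ""
  structure(list(found = TRUE, readthrough = FALSE,
                 ptc_mrna_pos = as.integer(c0), ptc_ref_pos = as.integer(c0),
                 ptc_cds_pos = as.integer(c0 - cs + 1L),
                 neoorf_len = 0L, prefix_aa = prefix_aa, neoorf_aa = ""),
            class = "ptc_result")
}

#' Classify a PTC's exon position into the five NMD categories
#'
#' Maps the PTC position (reference-transcript mRNA coordinates) onto the
#' exon containing it: last exon -> `LAST`; penultimate exon -> `PENULT_LE50`
#' when the PTC starts within 50 nt of the final exon junction, otherwise
#' `PENULT_GT50`; first exon -> `FIRST` (recording whether the PTC lies
#' within the first 200 nt of coding sequence); any other exon -> `MIDDLE`.
#' A single-exon transcript is `LAST` by convention, and in a two-exon
#' transcript the first exon is treated as penultimate. The 50-nt distance
#' is measured from the PTC's first nucleotide to the last nucleotide of the
#' penultimate exon.
#'
#' @param ptc A `ptc_result` with `found = TRUE`.
#' @param transcript The `transcript_model` the PTC was computed on.
#' @return An `nmd_annotation`: `category`, `dist_to_final_junction`
#'   (penultimate exon only), `within_first_200nt`, `neoorf_len`, `snorf`
#'   (neoORF >= 50 amino acids).
#' @export
classify_ptc_exon_position <- function(ptc, transcript) {
  if (!isTRUE(ptc$found)) stop("no PTC found (readthrough variant?)")
  pos <- ptc$ptc_ref_pos
  spans <- exon_mrna_spans(transcript)
  if (pos > max(spans$m_end) || pos < 1) {
    stop("PTC position beyond the end of ", transcript$isoform)
  }
  e <- which(spans$m_start <= pos & spans$m_end >= pos)[1]
  n <- nrow(spans)
  dist <- NA_integer_
  if (n == 1 || e == n) {
    category <- "LAST"
  } else if (e == n - 1) {
    dist <- spans$m_end[e] - pos
    category <- if (dist <= 50) "PENULT_LE50" else "PENULT_GT50"
  } else if (e == 1) {
    category <- "FIRST"
  } else {
    category <- "MIDDLE"
  }
  structure(list(category = category,
                 dist_to_final_junction = as.integer(dist),
                 within_first_200nt = isTRUE(ptc$ptc_cds_pos <= 200),
                 ptc_cds_pos = ptc$ptc_cds_pos,
                 neoorf_len = ptc$neoorf_len,
                 snorf = isTRUE(ptc$neoorf_len >= 50)),
            class = "nmd_annotation")
}

#' Predict NMD escape from an exon-position annotation
#'
#' The positional rule calls escape when the PTC lies in the last exon, in
#' the penultimate exon within 50 nt of the final exon junction, or in the
#' first exon within the first 200 nt of coding sequence. When an external
#' NMD-efficiency score is supplied, a score-based call (`score < 0.25`,
#' strict) is reported alongside.
#'
#' @param annotation An `nmd_annotation`.
#' @param nmd_efficiency_score Optional numeric efficiency score.
#' @return List with logical `escape_rule` and `escape_score` (`NA` when no
#'   score is supplied).
#' @export
predict_nmd_escape <- function(annotation, nmd_efficiency_score = NULL) {
  if (is.null(annotation$category) || is.na(annotation$category)) {
    stop("annotation has no category assigned")
  }
  rule <- annotation$category == "LAST" ||
    annotation$category == "PENULT_LE50" ||
    (annotation$category == "FIRST" && isTRUE(annotation$within_first_200nt))
  score <- if (is.null(nmd_efficiency_score)) NA else
    nmd_efficiency_score < 0.25
  list(escape_rule = rule, escape_score = score)
}

#' Mutant peptide windows over a neoORF
#'
#' Enumerates all windows of the requested lengths over the concatenation of
#' the wildtype protein prefix and the shifted-frame (neoORF) residues that
#' contain at least one shifted-frame residue. No window extends past the
#' premature stop. With `L` neoORF residues, at least `k - 1` upstream
#' residues and window length `k`, the count is `L + k - 1`.
#'
#' @param prefix_aa Wildtype residues upstream of the frameshift.
#' @param neoorf_aa Shifted-frame residues (may be `""`).
#' @param lengths Integer vector of window lengths (default 9, 10, 11).
#' @return List with `peptides` (data.frame: `peptide`, `length`, `start`)
#'   and `neoorf_tail` (the full mutated tail sequence, for use as a mass-
#'   spectrometry search library).
#' @export
neoorf_peptides <- function(prefix_aa, neoorf_aa, lengths = c(9L, 10L, 11L)) {
  if (any(lengths < 1)) stop("peptide length must be >= 1")
  np <- nchar(prefix_aa); L <- nchar(neoorf_aa)
  full <- paste0(prefix_aa, neoorf_aa)
  out <- lapply(lengths, function(k) {
    last_start <- nchar(full) - k + 1L
    first_start <- max(1L, np - k + 2L)  # must include >= 1 shifted residue
    if (L == 0 || last_start < first_start) return(NULL)
    starts <- first_start:last_start
    data.frame(peptide = substring(full, starts, starts + k - 1L),
               length = k, start = starts)
  })
  list(peptides = do.call(rbind, out) %||%
         data.frame(peptide = character(), length = integer(),
                    start = integer()),
       neoorf_tail = neoorf_aa)
}

#' Annotate fs-indels and stop-gain SNVs on their dominant isoforms
#'
#' For each variant, selects the gene's dominant isoform (per-sample
#' abundances when supplied), computes the PTC, classifies its exon
#' position, and applies the positional escape rule. Readthrough variants
#' (no stop before the transcript end) are flagged and carry no category.
#'
#' @param variants data.frame with columns `sample`, `contig`, `position`,
#'   `ref`, `alt`, `class` (`"fs_indel"` or `"stop_gain"`), and optionally
#'   `gene` and `variant_id`.
#' @param transcripts Named list of `transcript_model`s.
#' @param abundance Optional data.frame (`sample`, `isoform`, `abundance`)
#'   of per-sample isoform abundances.
#' @param nmd_scores Optional data.frame (`variant_id`,
#'   `nmd_efficiency_score`) of external efficiency scores.
#' @return data.frame with one row per variant x dominant isoform carrying
#'   the PTC position, exon category, neoORF length, SNORF and escape flags.
#' @export
annotate_variants <- function(variants, transcripts, abundance = NULL,
                              nmd_scores = NULL) {
  if (nrow(variants) == 0) {
    stop("no variants to annotate")
  }
  genes <- vapply(transcripts, `[[`, character(1), "gene")
  by_gene <- split(transcripts, genes)
  if (is.null(variants$variant_id)) {
    variants$variant_id <- sprintf("var%06d", seq_len(nrow(variants)))
  }
  if (is.null(variants$gene)) {
    variants$gene <- locate_gene(variants, transcripts)
  }
  score_map <- NULL
  if (!is.null(nmd_scores)) {
    score_map <- setNames(nmd_scores$nmd_efficiency_score,
                          nmd_scores$variant_id)
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    txs <- by_gene[[v$gene]]
    if (is.null(txs)) stop("gene ", v$gene, " absent from the annotation")
    ab <- NULL
    if (!is.null(abundance)) {
      sub <- abundance[abundance$sample == v$sample, ]
      ab <- setNames(sub$abundance, sub$isoform)
    }
    tx <- select_dominant_isoform(txs, ab)
    ptc <- if (v$class == "fs_indel") compute_ptc(v, tx)
           else ptc_from_stopgain(v, tx)
    base <- data.frame(variant_id = v$variant_id, sample = v$sample,
                       gene = v$gene, isoform = tx$isoform,
                       contig = v$contig, position = v$position,
                       ref = v$ref, alt = v$alt, class = v$class,
                       found = ptc$found, readthrough = ptc$readthrough,
                       stringsAsFactors = FALSE)
    if (!ptc$found) {
      return(cbind(base, data.frame(
        ptc_mrna_pos = NA_integer_, ptc_cds_pos = NA_integer_,
        category = NA_character_, dist_to_final_junction = NA_integer_,
        within_first_200nt = NA, neoorf_len = ptc$neoorf_len, snorf = NA,
        escape_rule = NA, escape_score = NA)))
    }
    ann <- classify_ptc_exon_position(ptc, tx)
    sc <- if (!is.null(score_map)) unname(score_map[v$variant_id]) else NULL
    if (!is.null(sc) && is.na(sc)) sc <- NULL
    esc <- predict_nmd_escape(ann, sc)
    cbind(base, data.frame(
      ptc_mrna_pos = ptc$ptc_mrna_pos, ptc_cds_pos = ptc$ptc_cds_pos,
      category = ann$category,
      dist_to_final_junction = ann$dist_to_final_junction,
      within_first_200nt = ann$within_first_200nt,
      neoorf_len = ann$neoorf_len, snorf = ann$snorf,
      escape_rule = esc$escape_rule, escape_score = esc$escape_score))
  })
  do.call(rbind, rows)
}

# find the gene whose transcript span contains each variant position
locate_gene <- function(variants, transcripts) {
  tab <- data.frame(
    contig = vapply(transcripts, `[[`, character(1), "contig"),
    lo = vapply(transcripts, function(t) min(t$exons$start), numeric(1)),
    hi = vapply(transcripts, function(t) max(t$exons$end), numeric(1)),
    gene = vapply(transcripts, `[[`, character(1), "gene"))
  vapply(seq_len(nrow(variants)), function(i) {
    hit <- which(tab$contig == variants$contig[i] &
                   tab$lo <= variants$position[i] &
                   tab$hi >= variants$position[i])
    if (length(hit) == 0) {
      stop("variant at ", variants$contig[i], ":", variants$position[i],
           " overlaps no transcript")
    }
    tab$gene[hit[1]]
  }, character(1))
}
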