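#' Transcript model
#'
#' A light container for one transcript isoform: its exon structure in
#' genomic coordinates, CDS bounds on the spliced mRNA, strand, expression
#' abundance and (optionally) the spliced mRNA sequence. All downstream
#' premature-termination-codon (PTC) logic operates in spliced,
#' strand-corrected mRNA space; the genomic-to-mRNA projection implemented
#' here is the only strand-aware step.
#'
#' @param gene Gene identifier.
#' @param isoform Isoform identifier (unique within the annotation).
#' @param contig Contig/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive
#'   genomic coordinates), ordered 5' to 3' in mRNA space (descending
#'   genomic coordinate for minus-strand transcripts).
#' @param cds_start,cds_end 1-based CDS bounds on the spliced transcript.
#' @param abundance Isoform expression abundance (arbitrary units).
#' @param seq Spliced mRNA sequence (character scalar), or `NA`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, isoform, contig, strand, exons,
                             cds_start, cds_end, abundance = NA_real_,
                             seq = NA_character_) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            all(exons$end >= exons$start))
  widths <- exons$end - exons$start + 1L
  tx_len <- sum(widths)
  if (nrow(exons) > 1) {
    ord <- if (strand == "+") exons$start else -exons$start
    if (any(diff(ord) <= 0)) {
      stop("exons of ", isoform, " are not ordered 5'->3' in mRNA space")
    }
    # non-overlap in genomic space
    g <- exons[order(exons$start), ]
    if (any(g$start[-1] <= g$end[-nrow(g)])) {
      stop("exons of ", isoform, " overlap")
    }
  }
  if (cds_end - cds_start + 1 < 3) stop("CDS of ", isoform, " shorter than 3 nt")
  if (cds_start < 1 || cds_end > tx_len) stop("CDS bounds of ", isoform,
                                              " outside transcript")
  if (!is.na(seq) && nchar(seq) != tx_len) {
    stop("sequence length does not match exon widths for ", isoform)
  }
  structure(list(gene = gene, isoform = isoform, contig = contig,
                 strand = strand, exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 abundance = abundance, seq = seq),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s, %s strand, %d exon(s), %d nt, CDS %d-%d)\n",
              x$isoform, x$gene, x$strand, nrow(x$exons),
              transcript_length(x), x$cds_start, x$cds_end))
  invisible(x)
}

#' @rdname transcript_model
#' @param tx A `transcript_model`.
#' @export
transcript_length <- function(tx) {
  sum(tx$exons$end - tx$exons$start + 1L)
}

#' Exon spans on the spliced transcript
#'
#' @param tx A `transcript_model`.
#' @return data.frame with one row per exon (in mRNA order) and columns
#'   `m_start`, `m_end`: the exon's span on the spliced transcript.
#' @export
exon_mrna_spans <- function(tx) {
  w <- tx$exons$end - tx$exons$start + 1L
  m_end <- cumsum(w)
  data.frame(exon = seq_along(w), m_start = m_end - w + 1L, m_end = m_end)
}

#' Project genomic coordinates onto the spliced transcript (and back)
#'
#' @param tx A `transcript_model`.
#' @param gpos Vector of 1-based genomic positions.
#' @return `genomic_to_mrna`: integer vector of 1-based mRNA positions
#'   (`NA` for intronic positions); errors if any position is outside the
#'   transcript's genomic span.
#' @export
genomic_to_mrna <- function(tx, gpos) {
  spans <- exon_mrna_spans(tx)
  lo <- min(tx$exons$start); hi <- max(tx$exons$end)
  if (any(gpos < lo | gpos > hi)) {
    stop("position outside the genomic span of ", tx$isoform)
  }
  vapply(gpos, function(p) {
    i <- which(tx$exons$start <= p & tx$exons$end >= p)
    if (length(i) == 0) return(NA_integer_)
    if (tx$strand == "+") {
      as.integer(spans$m_start[i] + (p - tx$exons$start[i]))
    } else {
      as.integer(spans$m_start[i] + (tx$exons$end[i] - p))
    }
  }, integer(1))
}

#' @rdname genomic_to_mrna
#' @param mpos Vector of 1-based mRNA positions.
#' @export
mrna_to_genomic <- function(tx, mpos) {
  spans <- exon_mrna_spans(tx)
  if (any(mpos < 1 | mpos > transcript_length(tx))) {
    stop("mRNA position outside ", tx$isoform)
  }
  vapply(mpos, function(m) {
    i <- which(spans$m_start <= m & spans$m_end >= m)[1]
    if (tx$strand == "+") {
      as.integer(tx$exons$start[i] + (m - spans$m_start[i]))
    } else {
      as.integer(tx$exons$end[i] - (m - spans$m_start[i]))
    }
  }, integer(1))
}

#' Write and read transcript annotations
#'
#' `write_transcript_gtf` serialises a list of `transcript_model`s as GTF
#' (exon and CDS features carrying `gene_id`/`transcript_id` attributes);
#' `write_transcript_fasta` writes the spliced mRNA sequences.
#' `read_transcript_models` rebuilds the models from a GTF + FASTA pair.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_transcript_gtf <- function(transcripts, path) {
  rows <- lapply(transcripts, function(tx) {
    spans <- exon_mrna_spans(tx)
    ex <- data.frame(contig = tx$contig, start = tx$exons$start,
                     end = tx$exons$end, strand = tx$strand,
                     type = "exon", gene = tx$gene, isoform = tx$isoform)
    ex$phase <- NA_integer_
    # project CDS (mRNA coords) onto genomic per-exon segments
    cds <- lapply(seq_len(nrow(spans)), function(i) {
      s <- max(spans$m_start[i], tx$cds_start)
      e <- min(spans$m_end[i], tx$cds_end)
      if (s > e) return(NULL)
      g <- sort(mrna_to_genomic(tx, c(s, e)))
      data.frame(contig = tx$contig, start = g[1], end = g[2],
                 strand = tx$strand, type = "CDS", gene = tx$gene,
                 isoform = tx$isoform,
                 phase = (3L - (s - tx$cds_start) %% 3L) %% 3L)
    })
    rbind(ex, do.call(rbind, cds))
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- df$gene
  S4Vectors::mcols(gr)$transcript_id <- df$isoform
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_transcript_gtf
#' @export
write_transcript_fasta <- function(transcripts, path) {
  seqs <- vapply(transcripts, `[[`, character(1), "seq")
  names(seqs) <- vapply(transcripts, `[[`, character(1), "isoform")
  if (anyNA(seqs)) stop("transcripts without sequence cannot be written")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_transcript_gtf
#' @param gtf_path,fasta_path Paths to the annotation written by
#'   `write_transcript_gtf`/`write_transcript_fasta` (or any GTF with exon
#'   and CDS features and a matching transcript FASTA).
#' @param abundance Optional data.frame with columns `isoform`, `abundance`.
#' @return `read_transcript_models`: named list of `transcript_model`s.
#' @export
read_transcript_models <- function(gtf_path, fasta_path = NULL,
                                   abundance = NULL) {
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as.data.frame(gr)
  seqs <- NULL
  if (!is.null(fasta_path)) {
    if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
    fa <- Biostrings::readDNAStringSet(fasta_path)
    seqs <- setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
  }
  ab <- NULL
  if (!is.null(abundance)) {
    ab <- setNames(abundance$abundance, abundance$isoform)
  }
  out <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", ]
    strand <- as.character(ex$strand[1])
    ord <- if (strand == "+") order(ex$start) else order(-ex$start)
    exons <- data.frame(start = ex$start[ord], end = ex$end[ord])
    iso <- d$transcript_id[1]
    tx0 <- transcript_model(gene = d$gene_id[1], isoform = iso,
                            contig = as.character(ex$seqnames[1]),
                            strand = strand, exons = exons,
                            cds_start = 1L, cds_end = 3L)
    cds <- d[d$type == "CDS", ]
    if (nrow(cds) == 0) stop("transcript ", iso, " has no CDS features")
    # CDS bounds on the spliced transcript from the genomic CDS segments
    gpos <- c(cds$start, cds$end)
    mpos <- genomic_to_mrna(tx0, gpos)
    transcript_model(gene = d$gene_id[1], isoform = iso,
                     contig = as.character(ex$seqnames[1]), strand = strand,
                     exons = exons,
                     cds_start = min(mpos), cds_end = max(mpos),
                     abundance = if (!is.null(ab)) unname(ab[iso]) else NA_real_,
                     seq = if (!is.null(seqs)) unname(seqs[iso]) else NA_character_)
  })
  out[order(names(out))]
}
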