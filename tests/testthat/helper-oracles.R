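# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: the mutant transcript is rebuilt by direct
# genomic string surgery, translation runs from the start codon over the
# whole mutant mRNA, and the exon-category rules are re-derived with
# findInterval arithmetic.

# rebuild the mutant spliced mRNA by editing the genomic exon sequence
oracle_mutant_mrna <- function(tx, v) {
  spans <- exon_mrna_spans(tx)
  exseq <- vapply(seq_len(nrow(spans)), function(i) {
    s <- substr(tx$seq, spans$m_start[i], spans$m_end[i])
    if (tx$strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    } else s
  }, character(1))
  e <- which(tx$exons$start <= v$position & tx$exons$end >= v$position)
  stopifnot(length(e) == 1)
  off <- v$position - tx$exons$start[e] + 1L
  stopifnot(substr(exseq[e], off, off + nchar(v$ref) - 1L) == v$ref)
  exseq[e] <- paste0(substr(exseq[e], 1, off - 1L), v$alt,
                     substr(exseq[e], off + nchar(v$ref), nchar(exseq[e])))
  paste(vapply(seq_along(exseq), function(i) {
    if (tx$strand == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(exseq[i])))
    } else exseq[i]
  }, character(1)), collapse = "")
}

# translate the full mutant mRNA from the start codon; report the position
# (mutant mRNA coordinates) of the first nucleotide of the first stop codon,
# or NA when translation runs through the transcript end
oracle_first_stop <- function(mut, cds_start) {
  n_codons <- (nchar(mut) - cds_start + 1L) %/% 3L
  if (n_codons < 1) return(NA_integer_)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(mut, cds_start, cds_start + 3L * n_codons - 1L)),
    if.fuzzy.codon = "X"))
  k <- regexpr("*", prot, fixed = TRUE)
  if (k < 0) return(NA_integer_)
  as.integer(cds_start + 3L * (k - 1L))
}

# independent re-derivation of the five-way exon category from a reference
# mRNA position
oracle_category <- function(tx, pos) {
  w <- tx$exons$end - tx$exons$start + 1L
  ends <- cumsum(w)
  e <- findInterval(pos - 1L, c(0L, ends))  # exon index containing pos
  n <- length(w)
  if (n == 1L || e == n) return("LAST")
  if (e == n - 1L) {
    return(if (ends[e] - pos <= 50L) "PENULT_LE50" else "PENULT_GT50")
  }
  if (e == 1L) return("FIRST")
  "MIDDLE"
}

# full-enumeration two-sided Fisher exact p for a 2x2 table (probabilities
# <= observed rule on the null hypergeometric)
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  pr <- dhyper(x, c1, n - c1, r1)
  obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
# (doubling of the smaller tail, capped at 1)
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  pl <- mean(us <= u_obs); pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# tie-corrected Kruskal-Wallis H evaluated directly from the formula
oracle_kw_h <- function(groups) {
  v <- unlist(groups)
  n <- length(v)
  r <- rank(v)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / sizes) - 3 * (n + 1)
  t <- table(v)
  h / (1 - sum(t^3 - t) / (n^3 - n))
}

# chi-square upper tail at even degrees of freedom, closed form
oracle_chisq_even_df <- function(x, df) {
  k <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# small transcriptome reused by the PTC oracle tests
oracle_transcriptome <- function(seed = 42, n_genes = 40) {
  simulate_transcriptome(sim_config(n_samples = 1, cohort_sizes = 1,
                                    n_genes = n_genes, seed = seed))
}

# draw one random fs-indel (uniform anchor, no category targeting) on a
# random transcript; returns list(tx, v)
random_fs_indel <- function(txs) {
  repeat {
    tx <- txs[[sample(length(txs), 1)]]
    lo <- tx$cds_start + 3L; hi <- tx$cds_end - 1L
    m <- sample(lo:hi, 1)
    v <- nmdescape:::make_indel_at(tx, m, is_ins = runif(1) < 0.4,
                                   L = sample(c(1L, 2L), 1))
    if (is.null(v)) next
    ok <- tryCatch({compute_ptc(v, tx); TRUE}, error = function(e) FALSE)
    if (ok) return(list(tx = tx, v = v))
  }
}

# simple single-exon toy transcript with a given CDS and 3' UTR
toy_tx <- function(cds, utr3, utr5 = "", gene = "G1", iso = "G1.T1",
                   strand = "+", offset = 100L) {
  seq <- paste0(utr5, cds, utr3)
  transcript_model(gene, iso, "chr1", strand,
                   data.frame(start = offset + 1L,
                              end = offset + nchar(seq)),
                   cds_start = nchar(utr5) + 1L,
                   cds_end = nchar(utr5) + nchar(cds),
                   abundance = 1, seq = seq)
}
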