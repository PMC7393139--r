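test_that("dominant isoform selection is argmax with lexicographic ties", {
  txs <- list(toy_tx("ATGAAACCCTAA", "ACGTACGT", gene = "G", iso = "G.A"),
              toy_tx("ATGAAACCCTAA", "ACGTACGT", gene = "G", iso = "G.B"))
  expect_identical(
    select_dominant_isoform(txs, c(G.A = 10, G.B = 3))$isoform, "G.A")
  expect_identical(
    select_dominant_isoform(txs, c(G.B = 5, G.A = 5))$isoform, "G.A")
  expect_identical(select_dominant_isoform(txs[2], c(G.B = 1))$isoform,
                   "G.B")
  expect_error(select_dominant_isoform(list()), "no isoforms")
})

test_that("compute_ptc reproduces the worked single-exon deletion", {
  # CDS ATG AAA CCC GGG TAA, 3'UTR TTAACGTACGTACGT; delete CDS position 4
  tx <- toy_tx("ATGAAACCCGGGTAA", "TTAACGTACGTACGT")
  v <- list(contig = "chr1", position = 103L, ref = "GA", alt = "G")
  p <- compute_ptc(v, tx)
  expect_true(p$found)
  expect_identical(p$ptc_mrna_pos, 16L)   # mutant frame: ATG AAC CCG GGT AAT TAA
  expect_identical(p$neoorf_len, 4L)
  expect_identical(p$neoorf_aa, "NPGN")
  expect_identical(classify_ptc_exon_position(p, tx)$category, "LAST")
})

test_that("an insertion creating an immediate stop has neoORF length zero", {
  tx <- toy_tx("ATGAAACCCGGGTAA", "TTAACGTACGTACGT")
  # insert T after mRNA position 3: codon 2 becomes TAA
  v <- list(contig = "chr1", position = 103L, ref = "G", alt = "GT")
  p <- compute_ptc(v, tx)
  expect_true(p$found)
  expect_identical(p$neoorf_len, 0L)
  expect_identical(p$ptc_mrna_pos, 4L)
})

test_that("a stop-free shifted tail is reported as readthrough", {
  tx <- toy_tx("ATGAAAAAATAA", strrep("CA", 10))
  v <- list(contig = "chr1", position = 104L, ref = "AA", alt = "A")
  p <- compute_ptc(v, tx)
  expect_false(p$found)
  expect_true(p$readthrough)
  expect_error(classify_ptc_exon_position(p, tx), "no PTC")
})

test_that("compute_ptc rejects in-frame indels and non-CDS variants", {
  tx <- toy_tx("ATGAAACCCGGGTAA", "TTAACGTACGTACGT")
  expect_error(compute_ptc(list(contig = "chr1", position = 103L,
                                ref = "GAAA", alt = "G"), tx), "in-frame")
  expect_error(compute_ptc(list(contig = "chr1", position = 118L,
                                ref = "TA", alt = "T"), tx), "outside the CDS")
})

test_that("exon-position classification follows the five-way rules", {
  mk_ptc <- function(pos, cds_pos = pos, neoorf = 10L) {
    structure(list(found = TRUE, readthrough = FALSE,
                   ptc_mrna_pos = pos, ptc_ref_pos = pos,
                   ptc_cds_pos = cds_pos, neoorf_len = neoorf),
              class = "ptc_result")
  }
  two_exon <- transcript_model("g", "t2", "chr1", "+",
                               data.frame(start = c(1, 401),
                                          end = c(300, 600)),
                               cds_start = 10, cds_end = 480,
                               abundance = 1)
  a <- classify_ptc_exon_position(mk_ptc(260L), two_exon)
  expect_identical(a$category, "PENULT_LE50")
  expect_identical(a$dist_to_final_junction, 40L)
  b <- classify_ptc_exon_position(mk_ptc(240L), two_exon)
  expect_identical(b$category, "PENULT_GT50")
  expect_identical(b$dist_to_final_junction, 60L)

  five_exon <- transcript_model("g", "t5", "chr1", "+",
                                data.frame(start = c(1, 201, 401, 601, 801),
                                           end = c(100, 300, 500, 700, 900)),
                                cds_start = 10, cds_end = 480, abundance = 1)
  expect_identical(classify_ptc_exon_position(mk_ptc(250L),
                                              five_exon)$category, "MIDDLE")
  expect_identical(classify_ptc_exon_position(mk_ptc(50L),
                                              five_exon)$category, "FIRST")
  single <- toy_tx("ATGAAACCCGGGTAA", "TTAACGT")
  expect_identical(classify_ptc_exon_position(mk_ptc(10L), single)$category,
                   "LAST")
  expect_error(classify_ptc_exon_position(mk_ptc(5000L), five_exon),
               "beyond the end")
})

test_that("perturbing the PTC across the 50-nt boundary only flips the penultimate bins", {
  two_exon <- transcript_model("g", "t2", "chr1", "+",
                               data.frame(start = c(1, 401),
                                          end = c(300, 600)),
                               cds_start = 10, cds_end = 480, abundance = 1)
  mk <- function(pos) structure(list(found = TRUE, ptc_ref_pos = pos,
                                     ptc_cds_pos = pos - 9L,
                                     neoorf_len = 5L),
                                class = "ptc_result")
  for (pos in c(230L, 270L, 290L)) {
    at <- classify_ptc_exon_position(mk(pos), two_exon)
    just_below <- classify_ptc_exon_position(mk(249L), two_exon)
    just_above <- classify_ptc_exon_position(mk(250L), two_exon)
    expect_identical(just_below$category, "PENULT_GT50")  # dist 51
    expect_identical(just_above$category, "PENULT_LE50")  # dist 50
    expect_true(at$category %in% c("PENULT_GT50", "PENULT_LE50"))
  }
})

test_that("the positional escape rule and the score threshold behave as specified", {
  mk <- function(cat, cds_pos = 100L) {
    structure(list(category = cat, within_first_200nt = cds_pos <= 200,
                   ptc_cds_pos = cds_pos, neoorf_len = 10L,
                   snorf = FALSE), class = "nmd_annotation")
  }
  expect_true(predict_nmd_escape(mk("LAST"))$escape_rule)
  expect_true(predict_nmd_escape(mk("PENULT_LE50"))$escape_rule)
  expect_false(predict_nmd_escape(mk("PENULT_GT50"))$escape_rule)
  expect_false(predict_nmd_escape(mk("MIDDLE"))$escape_rule)
  expect_true(predict_nmd_escape(mk("FIRST", 150L))$escape_rule)
  expect_false(predict_nmd_escape(mk("FIRST", 250L))$escape_rule)
  expect_false(predict_nmd_escape(mk("MIDDLE"), 0.25)$escape_score)
  expect_true(predict_nmd_escape(mk("MIDDLE"), 0.249)$escape_score)
})

test_that("peptide windows tile the neoORF without crossing the stop", {
  # enumeration oracle: k-length windows over prefix+neoORF that contain
  # >= 1 shifted residue and do not extend past the stop. With L novel
  # residues and >= k-1 upstream residues this yields exactly L windows
  # (the L + k - 1 candidate starts lose k - 1 to the stop-side clip).
  p1 <- neoorf_peptides(strrep("K", 20), "W", lengths = 9L)
  expect_identical(nrow(p1$peptides), 1L)
  expect_true(all(grepl("W", p1$peptides$peptide)))
  # neoORF of 0 residues gives no mutant peptides
  p0 <- neoorf_peptides(strrep("K", 20), "", lengths = c(9L, 10L, 11L))
  expect_identical(nrow(p0$peptides), 0L)
  # 131 novel residues: 131 distinct 9-mers, all containing novel sequence
  set.seed(1)
  tail131 <- paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                          131, replace = TRUE), collapse = "")
  p131 <- neoorf_peptides(strrep("A", 30), tail131, lengths = 9L)
  expect_identical(nrow(p131$peptides), 131L)
  # junction windows span the frameshift: with a short prefix the count
  # clips at the sequence start
  p_short <- neoorf_peptides("KK", strrep("G", 4), lengths = 9L)
  expect_identical(nrow(p_short$peptides), 0L)  # only 6 residues in total
  # property: counts match L + k - 1 clipped at the prefix end
  for (rep in 1:20) {
    L <- sample(0:40, 1); np <- sample(0:15, 1); k <- sample(8:11, 1)
    pep <- neoorf_peptides(strrep("A", np), strrep("G", L), lengths = k)
    expected <- if (L == 0) 0L else {
      first <- max(1L, np - k + 2L); last <- np + L - k + 1L
      max(0L, last - first + 1L)
    }
    expect_identical(nrow(pep$peptides), as.integer(expected))
  }
  expect_error(neoorf_peptides("AAA", "G", lengths = 0L), ">= 1")
})

test_that("stop-gain PTCs classify with neoORF length zero", {
  tx <- toy_tx("ATGTACAAACCCGGGTAA", "TTAACGTACGT")
  # codon 2 TAC -> TAA via C>A at mRNA position 6 (genomic 106)
  v <- list(contig = "chr1", position = 106L, ref = "C", alt = "A")
  p <- ptc_from_stopgain(v, tx)
  expect_true(p$found)
  expect_identical(p$neoorf_len, 0L)
  expect_identical(p$ptc_mrna_pos, 4L)
  ann <- classify_ptc_exon_position(p, tx)
  expect_identical(ann$category, "LAST")
  expect_false(ann$snorf)
  expect_error(ptc_from_stopgain(list(contig = "chr1", position = 104L,
                                      ref = "A", alt = "C"), tx),
               "does not create a stop")
})
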