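test_that("ESE masks flag exactly the covered positions", {
  expect_identical(which(mask_ese_positions("AAGAAGAA",
                                            hexamer_set("GAAGAA"))), 3:8)
  expect_false(any(mask_ese_positions("CCCCCCCC", hexamer_set("GAAGAA"))))
  expect_false(any(mask_ese_positions("GANGAA", hexamer_set("GAAGAA"))))
  expect_length(mask_ese_positions("ACGT", hexamer_set("GAAGAA")), 4)
  # monotone in the motif set, idempotent, bounded by 6 x occurrences
  set.seed(3)
  for (i in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    small <- fix_pool(30, i)
    big <- hexamer_set(unique(c(as.character(small),
                                as.character(fix_pool(40, i + 9)))))
    m_small <- mask_ese_positions(seq, small)
    m_big <- mask_ese_positions(seq, big)
    expect_true(all(which(m_small) %in% which(m_big)))
    n_occ <- sum(vapply(seq_len(195), function(p)
      substr(seq, p, p + 5) %in% as.character(big), logical(1)))
    expect_lte(sum(m_big), 6 * n_occ)
  }
})

test_that("composite profile sequence follows the windowing rules", {
  mk <- function(L) paste(rep("A", L), collapse = "")
  intr <- paste(rep("C", 120), collapse = "")
  # exon of 300: 100 + 50 + 100 + 50 + 100
  c300 <- merged_profile_sequence(mk(300), intr, intr)
  expect_equal(nchar(c300$seq), 400)
  expect_equal(as.integer(table(c300$region)[c("exon_start", "exon_core",
                                               "exon_end")]),
               c(50L, 100L, 50L))
  # exon of 120: flanks only, composite 300
  c120 <- merged_profile_sequence(mk(120), intr, intr)
  expect_equal(nchar(c120$seq), 300)
  expect_false(any(c120$region == "exon_core"))
  # exon of 80: overlapping windows deduplicated, whole exon used
  c80 <- merged_profile_sequence(mk(80), intr, intr)
  expect_equal(nchar(c80$seq), 280)
  # first exonic base has distance 1; intron positions count away from the
  # junction
  expect_equal(c300$distance[101], 1)
  expect_equal(c300$distance[100], 1)   # last intron5 base
  expect_equal(c300$distance[1], 100)
  expect_error(merged_profile_sequence(mk(50), intr, intr), "50 nt")
  expect_error(merged_profile_sequence(mk(120), "ACGT", intr),
               "insufficient")
})

test_that("back-translation mirrors the peptide template", {
  aln <- backtranslate_alignment("ME-K", "MEQK", "ATGGAAAAA",
                                 "ATGGAACAAAAA")
  expect_equal(aln$seq1, "ATGGAA---AAA")
  expect_equal(aln$seq2, "ATGGAACAAAAA")
  expect_error(backtranslate_alignment("M", "M", "ATT", "ATG"),
               "mismatch")
  expect_error(backtranslate_alignment("ME", "M", "ATGGAA", "ATG"),
               "length")
  # gap-free alignments reproduce the CDS in triplets; round trip through
  # translation recovers the peptides
  set.seed(8)
  for (i in 1:4) {
    cds <- fix_cds(12)
    pep <- paste(translate_codons(substring(cds, seq(1, 33, 3),
                                            seq(3, 35, 3))), collapse = "")
    aln <- backtranslate_alignment(pep, pep, cds, cds)
    expect_equal(aln$seq1, substr(cds, 1, 33))
    back <- substring(gsub("-", "", aln$seq1), seq(1, 33, 3), seq(3, 35, 3))
    expect_equal(paste(translate_codons(back), collapse = ""), pep)
  }
})

test_that("four-fold site detection respects codon families and symmetry", {
  expect_equal(fourfold_sites(list(seq1 = "GCT", seq2 = "GCC")), 3L)
  expect_length(fourfold_sites(list(seq1 = "TTT", seq2 = "TTC")), 0)
  expect_length(fourfold_sites(list(seq1 = "CTT", seq2 = "GTT")), 0)
  expect_length(fourfold_sites(list(seq1 = "GCT", seq2 = "---")), 0)
  set.seed(5)
  for (i in 1:4) {
    s1 <- fix_cds(20)
    s2 <- fix_cds(20)
    expect_identical(fourfold_sites(list(seq1 = s1, seq2 = s2)),
                     fourfold_sites(list(seq1 = s2, seq2 = s1)))
  }
})

test_that("ortholog exon filtering rejects and tallies as constructed", {
  set.seed(12)
  good <- list(gene_id = "g_good", ortholog_type = "one2one",
               sp1 = list(cds = fix_cds(30), exon_lens = c(21, 48, 21)),
               sp2 = list(cds = fix_cds(30), exon_lens = c(21, 48, 21)))
  no_atg <- good
  no_atg$gene_id <- "g_noatg"
  no_atg$sp1$cds <- sub("^ATG", "TTG", no_atg$sp1$cds)
  paralog <- good
  paralog$gene_id <- "g_para"
  paralog$ortholog_type <- "one2many"
  lendiff <- list(gene_id = "g_len", ortholog_type = "one2one",
                  sp1 = list(cds = fix_cds(40), exon_lens = c(10, 100, 10)),
                  sp2 = list(cds = fix_cds(42), exon_lens = c(10, 106, 10)))
  count_mism <- list(gene_id = "g_cnt", ortholog_type = "one2one",
                     sp1 = list(cds = fix_cds(30), exon_lens = c(30, 30, 30)),
                     sp2 = list(cds = fix_cds(30), exon_lens = c(30, 60)))
  res <- filter_ortholog_exons(list(good, no_atg, paralog, lendiff,
                                    count_mism))
  expect_equal(unname(res$tally["retained"]), 1L)
  expect_equal(unname(res$tally["bad_cds"]), 1L)
  expect_equal(unname(res$tally["not_one2one"]), 1L)
  expect_equal(unname(res$tally["exon_length_diff"]), 1L)
  expect_equal(unname(res$tally["exon_count_mismatch"]), 1L)
  expect_equal(unique(res$pairs$gene_id), "g_good")
  # retained exon chunks are frame-trimmed
  expect_true(all(nchar(res$pairs$seq1) %% 3 == 0))
  # duplicate resolution keeps the longest sp1 transcript
  dup_short <- good
  dup_short$sp1 <- list(cds = fix_cds(20), exon_lens = c(15, 30, 15))
  dup_short$sp2 <- dup_short$sp1
  res2 <- filter_ortholog_exons(list(good, dup_short))
  expect_equal(nchar(res2$pairs$seq1[1]), nchar(res$pairs$seq1[1]))
  # idempotent: filtering the same input twice gives identical output
  res3 <- filter_ortholog_exons(list(good, no_atg, paralog, lendiff,
                                     count_mism))
  expect_identical(res, res3)
})

test_that("exon tables validate sequences and intron lengths", {
  expect_error(exon_table(data.frame(exon_id = "e1")), "missing")
  expect_error(exon_table(data.frame(exon_id = "e1", exon_seq = "ACGU")),
               "ACGTN")
  tab <- exon_table(data.frame(exon_id = "e1", exon_seq = "acgtac",
                               up_intron_seq = "AAAA", up_intron_len = 10))
  expect_equal(tab$exon_seq, "ACGTAC")
  expect_error(
    exon_table(data.frame(exon_id = "e1", exon_seq = "ACGTAC",
                          up_intron_seq = "AAAA", up_intron_len = 2)),
    "intron length")
})
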