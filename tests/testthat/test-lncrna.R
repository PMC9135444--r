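test_that("ORF scanning matches direct translation on the worked examples", {
  r <- find_orfs("ATGAAATGA")
  expect_equal(r$orfs$length_codons[1], 3)  # ATG AAA TGA, stop counted
  expect_equal(r$longest_nt, 9L)
  expect_equal(find_orfs("CCCCCC")$longest_nt, 0L)
  expect_equal(nrow(find_orfs("CCCCCC")$orfs), 0)
  expect_error(find_orfs("ACGTXX"), "non-nucleotide")
  # ORF without an in-transcript stop is truncated at the end
  expect_equal(find_orfs("ATGAAAAAA")$longest_nt, 9L)
})

test_that("longest ORF equals the exhaustive three-frame scan oracle", {
  set.seed(11)
  for (k in 1:50) {
    s <- random_dna(300)
    expect_equal(find_orfs(s)$longest_nt, oracle_longest_orf_nt(s))
  }
})

test_that("coding scores behave at the limits and are ORF-monotone", {
  cfg <- run_config()
  # no ORF at all -> minimal orf score, noncoding at defaults
  cp0 <- coding_potential(strrep("T", 300), config = cfg)
  expect_equal(cp0$longest_orf_nt, 0L)
  expect_false(cp0$is_coding)
  # ORF covering 90% of 900 nt with coding-biased hexamers -> coding
  scp <- cernapipe:::sense_codon_probs()
  set.seed(1)
  cds <- paste(sample(names(scp), 268, TRUE, prob = scp), collapse = "")
  seqc <- paste0(strrep("C", 45), "ATG", cds, "TAA", strrep("C", 45))
  cpc <- coding_potential(seqc, config = cfg)
  expect_true(cpc$is_coding)
  expect_gt(cpc$hexamer_score, 0)
  # extending the longest ORF never decreases the orf score
  set.seed(2)
  prev <- -Inf
  for (ncod in c(10, 30, 60, 120)) {
    s <- paste0("ATG", strrep("GCA", ncod), "TAA", strrep("C", 600 - 3 * ncod))
    sc <- coding_potential(s, config = cfg)$orf_score
    expect_gte(sc, prev)
    prev <- sc
  }
  # hexamer score defined as 0 for sequences shorter than 6 nt
  expect_equal(coding_potential("ACGT", config = cfg)$hexamer_score, 0)
})

test_that("threshold calibration separates simulated coding/noncoding", {
  set.seed(3)
  scp <- cernapipe:::sense_codon_probs()
  coding <- stats::setNames(vapply(1:40, function(i) {
    paste0(random_dna(60), "ATG",
           paste(sample(names(scp), 180, TRUE, prob = scp), collapse = ""),
           "TAA", random_dna(120))
  }, character(1)), paste0("c", 1:40))
  noncoding <- stats::setNames(vapply(1:40, function(i)
    cernapipe:::rand_noncoding_seq(500), character(1)), paste0("n", 1:40))
  cfg <- calibrate_coding_thresholds(coding, noncoding, run_config())
  lab <- c(coding_potential_table(coding, cfg)$is_coding,
           !coding_potential_table(noncoding, cfg)$is_coding)
  expect_gte(mean(lab), 0.95)
})

test_that("candidate filtering applies both boundaries and is idempotent", {
  tx <- data.frame(
    transcript_id = c("short", "boundary", "lowcov", "unknown", "good"),
    gene_id = paste0("g", 1:5), chrom = "chr1",
    start = c(1, 1000, 2000, 4000, 6000),
    end = c(150, 1199, 2499, 4499, 6999),
    strand = "+", coverage = c(0.9, 0.5, 0.3, NA, 0.8),
    source = "assembled")
  ann <- make_annotation(tx)
  f <- filter_candidates(ann, run_config())
  expect_equal(f$retained,
               c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(f$reason[1], "length")       # 150 nt: too short
  expect_true(is.na(f$reason[2]))           # exactly 200 nt kept
  expect_equal(f$reason[3], "coverage")     # 500 nt but coverage 0.3
  expect_equal(f$reason[4], "coverage")     # unknown coverage fails
  # disabling the coverage filter lets unknown coverage through
  f2 <- filter_candidates(ann, run_config(apply_coverage_filter = FALSE))
  expect_true(f2$retained[4])
  # idempotent and order-independent
  ann_rev <- make_annotation(tx[5:1, ])
  f3 <- filter_candidates(ann_rev, run_config())
  expect_equal(f3$retained[match(f$transcript_id, f3$transcript_id)],
               f$retained)
})

test_that("genomic classification follows the five-class precedence", {
  genes <- data.frame(
    transcript_id = c("tg1", "tg2"), gene_id = c("G1", "G2"),
    chrom = "chr1", start = c(10000, 30000), end = c(12202, 30802),
    strand = "+", source = "annotated")
  gene_exons <- rbind(
    data.frame(transcript_id = "tg1", chrom = "chr1", start = 10000,
               end = 10399, strand = "+"),
    data.frame(transcript_id = "tg1", chrom = "chr1", start = 11800,
               end = 12202, strand = "+"),
    data.frame(transcript_id = "tg2", chrom = "chr1", start = 30000,
               end = 30802, strand = "+"))
  ann <- make_annotation(genes, gene_exons)
  cands <- data.frame(
    transcript_id = c("anti", "sens", "intr", "bidi", "inter", "gap"),
    gene_id = paste0(c("anti", "sens", "intr", "bidi", "inter", "gap"),
                     "_loc"),
    chrom = "chr1",
    start = c(10300, 10350, 10600, 9100, 50000, 29100),
    end = c(10700, 10750, 11000, 9500, 50400, 29500),
    strand = c("-", "+", "+", "-", "+", "+"),
    coverage = 0.9, source = "assembled")
  cls <- classify_lncrna(make_annotation(cands), ann, run_config())
  got <- stats::setNames(cls$class, cls$transcript_id)
  expect_equal(got[["anti"]], "antisense")   # exon overlap, opposite strand
  expect_equal(got[["sens"]], "sense")       # exon overlap, same strand
  expect_equal(got[["intr"]], "intronic")    # fully inside the intron
  expect_equal(got[["bidi"]], "bidirectional") # divergent start 500 nt away
  expect_equal(got[["inter"]], "intergenic") # ~19 kb from nearest gene
  # same-strand upstream neighbour is not bidirectional
  expect_equal(got[["gap"]], "intergenic")
  expect_false(any(is.na(cls$class)))        # total function, one label each
})

test_that("structure summaries conserve counts and match a groupby oracle", {
  tx_l <- data.frame(transcript_id = paste0("l", 1:10),
                     gene_id = paste0("l", 1:10, "_loc"),
                     chrom = rep(c("chr1", "chr2"), 5),
                     start = seq(1000, by = 5000, length.out = 10),
                     end = seq(1000, by = 5000, length.out = 10) +
                       c(250, 400, 800, 1500, 2500, 300, 450, 900, 1600,
                         2600) - 1,
                     strand = "+", source = "assembled")
  tx_m <- data.frame(transcript_id = paste0("m", 1:4),
                     gene_id = paste0("gm", 1:4), chrom = "chr1",
                     start = seq(100000, by = 5000, length.out = 4),
                     end = seq(100000, by = 5000, length.out = 4) + 999,
                     strand = "+", source = "annotated")
  s <- summarize_structure(make_annotation(tx_l), make_annotation(tx_m))
  expect_equal(sum(s$length$lncRNA), 10)
  expect_equal(sum(s$length$mRNA), 4)
  expect_equal(sum(s$exons$lncRNA[s$exons$bin == "1"]), 10)
  byhand <- table(tx_l$chrom)
  expect_equal(s$chromosome$lncRNA[match(names(byhand), s$chromosome$bin)],
               as.integer(byhand))
})
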