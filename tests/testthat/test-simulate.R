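test_that("generator output is deterministic under a fixed seed", {
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  cfg <- simulation_config(rng_seed = 99L)
  generate_cerna_dataset(cfg, d1)
  generate_cerna_dataset(cfg, d2)
  for (f in c("genome.fa", "annotation.gff3", "assembled.gtf",
              "transcripts.fa", "mirnas.fa", "expression.tsv",
              "truth.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("planted counts equal the generator configuration exactly", {
  demo <- get_demo()
  truth <- demo$truth
  cfg <- truth$config
  cls <- table(truth$lncrna_classes$class)
  expect_equal(as.integer(cls[names(cfg$n_lncrnas)]),
               unname(as.integer(cfg$n_lncrnas)))
  expect_equal(nrow(truth$cis_pairs), cfg$n_cis)
  expect_equal(nrow(truth$trans_pairs), cfg$n_trans)
  expect_equal(nrow(truth$precursors), cfg$n_precursor)
  expect_equal(nrow(truth$cerna_triples), cfg$n_cerna)
  expect_equal(nrow(truth$decoys), 5)
  expect_equal(length(truth$coding_ids), cfg$n_genes)
  # every planted id exists in the emitted files
  seqs <- read_fasta(file.path(demo$dir, "transcripts.fa"))
  expect_true(all(truth$lncrna_classes$transcript_id %in% names(seqs)))
  expect_true(all(truth$coding_ids %in% names(seqs)))
})

test_that("emitted transcript sequences match spliced genome extraction", {
  demo <- get_demo()
  genome <- read_fasta(file.path(demo$dir, "genome.fa"))
  asm <- read_gtf(file.path(demo$dir, "assembled.gtf"))
  seqs <- read_fasta(file.path(demo$dir, "transcripts.fa"))
  extracted <- cernapipe:::spliced_sequences(genome, asm$exons)
  expect_identical(unname(as.character(extracted[names(seqs)])),
                   unname(as.character(seqs)))
})

test_that("planted interaction content satisfies its screens by construction", {
  demo <- get_demo()
  truth <- demo$truth
  seqs <- stats::setNames(
    as.character(read_fasta(file.path(demo$dir, "transcripts.fa"))),
    names(read_fasta(file.path(demo$dir, "transcripts.fa"))))
  mirs <- stats::setNames(
    as.character(read_fasta(file.path(demo$dir, "mirnas.fa"))),
    names(read_fasta(file.path(demo$dir, "mirnas.fa"))))
  cfg <- run_config()
  # planted eTM sites score at or below the cutoff
  for (r in seq_len(nrow(truth$etm_pairs))) {
    hits <- predict_etms(mirs[truth$etm_pairs$mirna_id[r]],
                         seqs[truth$etm_pairs$lncrna_id[r]], 2.5, cfg)
    expect_gte(nrow(hits), 1)
    expect_lte(min(hits$score), 2.5)
  }
  # planted trans pairs beat the duplex energy cutoff
  for (r in seq_len(nrow(truth$trans_pairs))) {
    e <- duplex_energy(seqs[[truth$trans_pairs$lncrna_id[r]]],
                       seqs[[truth$trans_pairs$mrna_id[r]]], cfg)$energy
    expect_lt(e, -50)
  }
  # planted precursors carry the mature verbatim at the recorded offset
  for (r in seq_len(nrow(truth$precursors))) {
    lnc <- seqs[[truth$precursors$lncrna_id[r]]]
    off <- truth$precursors$match_offset[r]
    mat <- mirs[[truth$precursors$mirna_id[r]]]
    expect_identical(substr(lnc, off, off + nchar(mat) - 1), mat)
  }
})

test_that("expression simulation reflects the planted effects", {
  demo <- get_demo()
  truth <- demo$truth
  expr <- read_expression_table(file.path(demo$dir, "expression.tsv"),
                                file.path(demo$dir, "design.tsv"))
  expect_equal(ncol(expr$values), 9)  # 3 conditions x 3 replicates
  expect_true(all(expr$values > 0))
  lv <- log2(expr$values)
  for (r in seq_len(nrow(truth$de_truth))) {
    row <- truth$de_truth[r, ]
    trt <- rowMeans(lv[row$transcript_id,
                       expr$design$condition == row$condition,
                       drop = FALSE])
    ctl <- rowMeans(lv[row$transcript_id,
                       expr$design$condition == "NH4NO3", drop = FALSE])
    expect_equal(unname(trt - ctl), row$effect_log2, tolerance = 1)
  }
  # a transcript with no planted effect has log2FC near 0 in both contrasts
  null_ids <- setdiff(rownames(expr$values),
                      truth$de_truth$transcript_id)[1:10]
  for (ct in c("NO3", "NH4")) {
    lfc <- log2_fold_change(expr, ct, "NH4NO3", 0.1)
    expect_lt(max(abs(lfc[null_ids])), 1)
  }
})

test_that("chance ORFs in noncoding sequence are interrupted", {
  set.seed(83)
  for (k in 1:10) {
    s <- cernapipe:::rand_noncoding_seq(600)
    expect_lte(find_orfs(s)$longest_nt, 120)
  }
})
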