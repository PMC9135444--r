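test_that("site scoring reproduces the penalty scheme on worked cases", {
  cfg <- run_config()
  # perfect complement scores 0
  set.seed(43)
  for (k in 1:10) {
    m <- random_dna(21)
    expect_equal(score_mirna_target(m, cernapipe:::revcomp(m), cfg)$score, 0)
  }
  # single G:U wobble at miRNA position 5 (strict zone) scores 0.5
  m <- "AACCGAACCAACCAACCAACC"            # position 5 is G
  site <- cernapipe:::revcomp(m)
  s2 <- site
  substr(s2, 17, 17) <- "T"              # partner of position 5: C -> T (G:T)
  r <- score_mirna_target(m, s2, cfg)
  expect_equal(r$score, 0.5)
  expect_equal(r$strict_penalty, 0.5)
  expect_equal(substr(r$alignment, 5, 5), "o")
  # two strict mismatches plus one strict G:U = 2.5, accepted at the cutoff
  s3 <- site
  substr(s3, 17, 17) <- "T"              # G:U at position 5
  substr(s3, 19, 19) <- "C"              # mismatch at position 3 (A:C)
  substr(s3, 14, 14) <- "C"              # mismatch at position 8 (C:C)
  r3 <- score_mirna_target(m, s3, cfg)
  expect_equal(r3$score, 2.5)
  hits <- predict_targets(c(mir = m), c(tx = paste0("AAAA", s3, "AAAA")),
                          cutoff = 2.5, cfg)
  expect_equal(nrow(hits), 1)
  expect_error(score_mirna_target("ACGTACGTACGT", "ACGT"), "15 nt")
})

test_that("site score is monotone under added mismatches", {
  set.seed(47)
  cfg <- run_config()
  for (k in 1:10) {
    m <- random_dna(21)
    site <- cernapipe:::revcomp(m)
    prev <- 0
    pos <- sample(21, 4)
    for (p in pos) {
      b <- substr(site, p, p)
      repl <- setdiff(c("A", "C", "G", "T"), b)[sample(3, 1)]
      substr(site, p, p) <- repl
      sc <- score_mirna_target(m, site, cfg)$score
      expect_gte(sc, prev - 1e-9)
      prev <- sc
    }
  }
})

test_that("banded alignment equals exhaustive enumeration with gaps", {
  set.seed(53)
  cfg <- run_config()
  for (k in 1:40) {
    n <- sample(15:22, 1)
    m <- random_dna(n)
    site <- random_dna(n + sample(-2:2, 1))
    expect_equal(score_mirna_target(m, site, cfg)$score,
                 oracle_target_score(m, site, cfg),
                 label = paste(m, site))
  }
  # gapped sites: deleting a site base forces a "missing" penalty the DP
  # must place optimally
  for (k in 1:10) {
    m <- random_dna(21)
    site <- cernapipe:::revcomp(m)
    cut <- sample(3:19, 1)
    site <- paste0(substr(site, 1, cut - 1), substr(site, cut + 1, 21))
    expect_equal(score_mirna_target(m, site, cfg)$score,
                 oracle_target_score(m, site, cfg))
  }
})

test_that("target scanning finds planted sites and nothing else", {
  set.seed(59)
  cfg <- run_config()
  m <- random_dna(21)
  tx <- paste0(cernapipe:::rand_noncoding_seq(400),
               cernapipe:::revcomp(m),
               cernapipe:::rand_noncoding_seq(380))
  hits <- predict_targets(c(mir1 = m), c(t1 = tx), 2.5, cfg)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 0)
  expect_equal(hits$start, 401)
  expect_equal(hits$end, 421)
  # a transcript with no window under the cutoff yields an empty table
  none <- predict_targets(c(mir1 = strrep("A", 21)),
                          c(t1 = strrep("A", 200)), 2.5, cfg)
  expect_equal(nrow(none), 0)
  # above-cutoff site is not reported: three strict-zone self-pair
  # mismatches (X:X never pairs), nominal score 3
  site <- cernapipe:::revcomp(m)
  for (p in c(10, 12, 14)) substr(site, p, p) <- substr(m, 22 - p, 22 - p)
  sc <- score_mirna_target(m, site, cfg)$score
  if (sc > 2.5) {
    h2 <- predict_targets(c(mir1 = m), c(t1 = paste0("CCCC", site, "CCCC")),
                          2.5, cfg)
    expect_equal(nrow(h2), 0)
  }
})

test_that("one lncRNA can mimic several miRNAs (1-3 sites per eTM)", {
  set.seed(61)
  cfg <- run_config()
  ms <- vapply(1:3, function(i) random_dna(21), character(1))
  names(ms) <- paste0("mir", 1:3)
  lnc <- c(L1 = paste0(cernapipe:::rand_noncoding_seq(60),
                       cernapipe:::revcomp(ms[1]),
                       cernapipe:::rand_noncoding_seq(30),
                       cernapipe:::revcomp(ms[2]),
                       cernapipe:::rand_noncoding_seq(30),
                       cernapipe:::revcomp(ms[3]),
                       cernapipe:::rand_noncoding_seq(60)))
  hits <- predict_etms(ms, lnc, 2.5, cfg)
  expect_equal(nrow(hits), 3)
  expect_setequal(hits$mirna_id, names(ms))
  expect_true(all(hits$type == "eTM"))
})

test_that("precursor detection needs an exact match on the right chromosome", {
  set.seed(67)
  cfg <- run_config()
  m <- c(mirA = random_dna(21))
  arm <- paste0(random_dna(20), m[["mirA"]], random_dna(19))
  hair <- paste0(arm, random_dna(8), cernapipe:::revcomp(arm))
  lnc <- c(P1 = paste0(cernapipe:::rand_noncoding_seq(150), hair,
                       cernapipe:::rand_noncoding_seq(150)))
  hits <- find_precursor_loci(lnc, m, c(mirA = "chr3"), c(P1 = "chr3"), cfg)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$match_offset, 171L)
  expect_true(hits$hairpin_pass)
  # one substitution breaks the 100%-identity rule
  mut <- lnc
  substr(mut, 171, 171) <- if (substr(mut, 171, 171) == "A") "C" else "A"
  expect_equal(nrow(find_precursor_loci(mut, m, c(mirA = "chr3"),
                                        c(P1 = "chr3"), cfg)), 0)
  # wrong chromosome is filtered even with a perfect match
  expect_equal(nrow(find_precursor_loci(lnc, m, c(mirA = "chr1"),
                                        c(P1 = "chr3"), cfg)), 0)
})

test_that("the hairpin rule needs the mature within one arm", {
  cfg <- run_config()
  set.seed(71)
  arm <- random_dna(30)
  hp <- paste0(arm, "TTTTTT", cernapipe:::revcomp(arm))
  # mature inside the 5' arm: fully paired
  r <- hairpin_check(hp, 5, 21, cfg)
  expect_true(r$hairpin_pass)
  expect_equal(r$paired_fraction, 1.0)
  # mature straddling the loop apex: partners on both sides, fails
  r2 <- hairpin_check(hp, 23, 21, cfg)
  expect_false(r2$hairpin_pass)
})

test_that("base-pair maximization equals exhaustive enumeration", {
  set.seed(73)
  cfg <- run_config()
  for (k in 1:25) {
    s <- random_dna(sample(10:24, 1))
    expect_equal(cernapipe:::cpp_nussinov(s, cfg$min_hairpin_loop)$n_pairs,
                 oracle_nussinov_pairs(s, cfg$min_hairpin_loop),
                 label = s)
  }
})
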