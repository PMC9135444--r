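test_that("cis pairing is inclusive at the window and measures gaps", {
  lnc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000, 100499),
                                strand = "+")
  S4Vectors::mcols(lnc)$transcript_id <- "L1"
  mkg <- function(start, end, id, chrom = "chr1") {
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                strand = "-")
    S4Vectors::mcols(g)$gene_id <- id
    g
  }
  genes <- suppressWarnings(
    c(mkg(200500, 201000, "at_window"),     # gap exactly 100,000
      mkg(200501, 201000, "past_window"),   # gap 100,001
      mkg(100300, 100700, "overlap"),
      mkg(100000, 100499, "elsewhere", "chr9")))
  hits <- cis_targets(lnc, genes, 100000L)
  expect_setequal(hits$mrna_id, c("at_window", "overlap"))
  expect_equal(hits$distance_nt[hits$mrna_id == "at_window"], 100000L)
  expect_equal(hits$distance_nt[hits$mrna_id == "overlap"], 0L)
  expect_equal(hits$relative_position[hits$mrna_id == "overlap"],
               "overlapping")
})

test_that("cis prediction equals a brute-force all-pairs distance scan", {
  set.seed(23)
  starts_l <- sample(1:500000, 15)
  lnc <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 15, TRUE),
    IRanges::IRanges(starts_l, starts_l + 400), strand = "+")
  S4Vectors::mcols(lnc)$transcript_id <- paste0("L", 1:15)
  starts_g <- sample(1:500000, 25)
  genes <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 25, TRUE),
    IRanges::IRanges(starts_g, starts_g + 1000),
    strand = sample(c("+", "-"), 25, TRUE))
  S4Vectors::mcols(genes)$gene_id <- paste0("G", 1:25)
  w <- 50000L
  got <- cis_targets(lnc, genes, w)
  # oracle: direct all-pairs interval arithmetic
  want <- list()
  for (i in 1:15) for (j in 1:25) {
    if (as.character(GenomicRanges::seqnames(lnc[i])) !=
        as.character(GenomicRanges::seqnames(genes[j]))) next
    gap <- max(0L, max(GenomicRanges::start(genes[j]) -
                         GenomicRanges::end(lnc[i]),
                       GenomicRanges::start(lnc[i]) -
                         GenomicRanges::end(genes[j])) - 1L)
    if (gap <= w)
      want[[length(want) + 1]] <- paste0("L", i, "|G", j, "|", gap)
  }
  expect_setequal(paste0(got$lncrna_id, "|", got$mrna_id, "|",
                         got$distance_nt),
                  unlist(want))
})

test_that("duplex energy is 0 without pairs and orders GC above AU", {
  expect_equal(duplex_energy(strrep("A", 12), strrep("C", 12))$energy, 0)
  gc <- duplex_energy(strrep("G", 10), strrep("C", 10))$energy
  au <- duplex_energy(strrep("A", 10), strrep("T", 10))$energy
  expect_lt(gc, au)
  expect_lt(au, 0)
  expect_error(duplex_energy("", "ACGT"), "empty")
})

test_that("duplex energy is symmetric and ignores non-pairing padding", {
  set.seed(31)
  for (k in 1:20) {
    a <- random_dna(sample(8:20, 1)); b <- random_dna(sample(8:20, 1))
    e1 <- duplex_energy(a, b)$energy
    expect_equal(duplex_energy(b, a)$energy, e1)
  }
  a <- "GGGGCCCGGG"
  b <- "CCCGGGCCCC"
  e <- duplex_energy(a, b)$energy
  # poly-A cannot pair with anything in a G/C-only partner
  expect_equal(duplex_energy(a, paste0("AAAA", b, "AAAAA"))$energy, e)
})

test_that("duplex DP equals exhaustive one-loop enumeration", {
  set.seed(37)
  st <- nn_stack_table()
  cfg <- run_config()
  for (k in 1:60) {
    a <- random_dna(sample(4:12, 1)); b <- random_dna(sample(4:12, 1))
    expect_equal(duplex_energy(a, b, cfg, st)$energy,
                 oracle_duplex_energy(a, b, st, cfg$loop_open,
                                      cfg$loop_ext, cfg$max_loop),
                 tolerance = 1e-9, label = paste(a, b))
  }
})

test_that("trans screening is strict at the energy cutoff", {
  set.seed(41)
  r <- random_dna(30, prob = c(0, 0.5, 0.5, 0))
  lnc <- c(L1 = paste0(random_dna(50), cernapipe:::revcomp(r),
                       random_dna(50)),
           L2 = random_dna(130))
  mrna <- c(M1 = paste0(random_dna(40), r, random_dna(40)))
  e <- duplex_energy(lnc[["L1"]], mrna[["M1"]])$energy
  expect_lt(e, -50)                      # planted complement beats -50
  hits <- trans_targets(lnc, mrna, cutoff = -50)
  expect_equal(hits$lncrna_id, "L1")
  expect_equal(hits$energy[1], e)
  # exactly at the cutoff is excluded ("less than" is strict)
  expect_equal(nrow(trans_targets(lnc, mrna, cutoff = e)), 0)
  expect_equal(nrow(trans_targets(lnc["L2"], mrna, cutoff = -50)), 0)
})
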