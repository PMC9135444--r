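# Synthetic dataset generator. Emulates the study design the pipeline is
# built for: three nitrogen conditions x three replicates, log-normal FPKM
# noise, lncRNAs planted in all five genomic configurations, and planted
# cis / trans / precursor / eTM / ceRNA relationships plus decoy triples
# (each violating exactly one ceRNA condition), all recorded in a
# machine-readable truth bundle.

#' Simulation configuration
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length (nt).
#' @param n_genes total annotated genes (>= 36 to host all constructs).
#' @param n_lncrnas named integer vector: planted lncRNAs per genomic class
#'   (`intergenic` must cover the interaction-carrying lncRNAs:
#'   `n_cis + n_trans + n_precursor + n_cerna + 5` decoys).
#' @param n_mirnas mature miRNAs (>= `n_cerna + 2 + 5 + n_precursor`).
#' @param n_cis,n_trans,n_precursor,n_cerna planted relationship counts.
#' @param n_extra_de additional differentially expressed mRNAs without a
#'   planted interaction.
#' @param effect_size_log2 planted |log2 fold change| of DE transcripts.
#' @param noise_sd_log2 SD of the Gaussian noise on the log2-FPKM scale.
#' @param n_replicates replicates per condition.
#' @param conditions condition labels; the second is the control that every
#'   contrast compares against.
#' @param baseline_log2_mean,baseline_log2_sd baseline log2-FPKM
#'   distribution.
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_chromosomes = 3L,
                              chrom_length = 300000L,
                              n_genes = 40L,
                              n_lncrnas = c(intergenic = 25L, antisense = 3L,
                                            sense = 3L, intronic = 3L,
                                            bidirectional = 3L),
                              n_mirnas = 16L,
                              n_cis = 5L, n_trans = 4L,
                              n_precursor = 3L, n_cerna = 6L,
                              n_extra_de = 4L,
                              effect_size_log2 = 2.0,
                              noise_sd_log2 = 0.25,
                              n_replicates = 3L,
                              conditions = c("NO3", "NH4NO3", "NH4"),
                              baseline_log2_mean = 4,
                              baseline_log2_sd = 1,
                              rng_seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_lncrnas = n_lncrnas,
              n_mirnas = as.integer(n_mirnas),
              n_cis = as.integer(n_cis), n_trans = as.integer(n_trans),
              n_precursor = as.integer(n_precursor),
              n_cerna = as.integer(n_cerna),
              n_extra_de = as.integer(n_extra_de),
              effect_size_log2 = effect_size_log2,
              noise_sd_log2 = noise_sd_log2,
              n_replicates = as.integer(n_replicates),
              conditions = conditions,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              rng_seed = as.integer(rng_seed))
  n_roles <- cfg$n_cis + cfg$n_trans + cfg$n_precursor + cfg$n_cerna + 5L
  stopifnot(cfg$n_chromosomes >= 3, cfg$noise_sd_log2 > 0,
            cfg$n_replicates >= 2, length(cfg$conditions) == 3,
            all(cfg$n_lncrnas >= 0),
            cfg$n_lncrnas[["intergenic"]] >= n_roles,
            cfg$n_mirnas >= cfg$n_cerna + 2L + 5L + cfg$n_precursor,
            cfg$n_genes >= 12L + cfg$n_cis + cfg$n_cerna + cfg$n_trans +
              5L + cfg$n_extra_de)
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Noncoding sequence: AT-biased composition (as in plant noncoding DNA) and
# no long chance ORF -- any ORF beyond `max_orf_nt` is interrupted with a
# stop codon, since genuinely noncoding transcripts must lack coding
# capacity for the planted truth label to be correct. Rarely, a draw
# resists disruption (stop insertions in one frame can erase stops in
# another); such draws are discarded and redrawn.
rand_noncoding_seq <- function(n) {
  for (try in 1:20) {
    s <- tryCatch(
      disrupt_orfs(rand_seq(n, prob = c(0.30, 0.20, 0.20, 0.30))),
      error = function(e) NULL)
    if (!is.null(s)) return(s)
  }
  stop("could not generate a noncoding sequence of length ", n)
}

disrupt_orfs <- function(seq, max_orf_nt = 120L, protected = NULL,
                         max_iter = 200L) {
  for (iter in seq_len(max_iter)) {
    orfs <- find_orfs(seq)$orfs
    long <- orfs[orfs$length_codons * 3L > max_orf_nt, , drop = FALSE]
    if (nrow(long) == 0) return(seq)
    o <- long[1, ]
    cods <- seq.int(o$start + 3L, o$start + (o$length_codons - 2L) * 3L,
                    by = 3L)
    if (!is.null(protected) && nrow(protected) > 0) {
      ok <- vapply(cods, function(p)
        !any(p <= protected[, 2] & (p + 2L) >= protected[, 1]), logical(1))
      cods <- cods[ok]
    }
    if (length(cods) == 0)
      stop("cannot interrupt a chance ORF without touching a planted ",
           "site; regenerate with a different seed")
    # midpoint first; later iterations rotate the position so that
    # interacting frames cannot oscillate forever
    p <- cods[1L + (ceiling(length(cods) / 2) - 1L + (iter - 1L)) %%
                length(cods)]
    substr(seq, p, p + 2L) <- "TAA"
  }
  stop("chance ORFs resisted disruption after ", max_iter, " attempts")
}

# mRNA transcript: 5'UTR + ATG + sense codons + stop + 3'UTR. The CDS is
# sampled from the same codon-usage model the hexamer score assumes.
make_mrna_seq <- function(n_codons = 200L, utr5 = 60L, utr3 = 140L) {
  scp <- sense_codon_probs()
  cds <- paste(sample(names(scp), n_codons - 1L, replace = TRUE,
                      prob = scp), collapse = "")
  paste0(rand_seq(utr5), "ATG", cds,
         sample(STOP_CODONS, 1), rand_seq(utr3))
}

#' Generate a toy genome, annotation and assembled transcript set
#'
#' Lays out annotated genes and lncRNA loci so every lncRNA satisfies its
#' planted genomic class by construction (antisense/sense lncRNAs overlap
#' an exon on the opposite/same strand, intronic lncRNAs sit fully inside
#' an intron, bidirectional lncRNAs start head-to-head within 1,000 nt of a
#' gene start, intergenic lncRNAs keep >= 2 kb clearance). Interaction
#' content is NOT planted yet (see [plant_interactions()]); sequences here
#' are raw. Also emits "junk" assembled transcripts that must fail the
#' length or coverage filter.
#'
#' @param config a [simulation_config()].
#' @return A list (class `sim_dataset`): `genome` (DNAStringSet),
#'   `annotation` and `assembled` ([tx_annotation]), `tx_seqs` (named
#'   character: spliced sequences of assembled transcripts),
#'   `mirna_seqs`, and `truth` (partial [planted truth][read_truth]).
#' @export
generate_genome_and_annotation <- function(config = simulation_config()) {
  set.seed(config$rng_seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  cursor <- stats::setNames(rep(5000L, config$n_chromosomes), chroms)
  if (config$chrom_length < 250000L)
    stop("chromosome too small to place the requested features; ",
         "increase chrom_length (>= 250000)")

  genes <- list(); txs <- list(); exons <- list()   # annotated
  asm_txs <- list(); asm_exons <- list()            # assembled models
  tx_seqs <- character(0)
  lnc_class <- character(0)

  gid_n <- 0L; lnc_n <- 0L
  next_gid <- function() { gid_n <<- gid_n + 1L; sprintf("g%03d", gid_n) }
  next_lid <- function(role) {
    lnc_n <<- lnc_n + 1L
    sprintf("lnc_%s_%02d", role, lnc_n)
  }
  take <- function(chrom, len, gap = 3000L) {
    s <- cursor[[chrom]]
    if (s + len > config$chrom_length - 2000L)
      stop("chromosome too small to place requested features on ", chrom,
           "; increase chrom_length in the simulation config")
    cursor[[chrom]] <<- s + len + gap
    s
  }
  add_gene <- function(chrom, strand = "+", exon_lens = 803L,
                       intron_lens = integer(0), n_codons = 200L,
                       at = NULL, gap = 3000L) {
    gid <- next_gid()
    span <- sum(exon_lens) + sum(intron_lens)
    s <- if (is.null(at)) take(chrom, span, gap) else at
    ex_starts <- s + cumsum(c(0L, exon_lens[-length(exon_lens)] +
                                intron_lens))
    ex <- gr_one(chrom, ex_starts, ex_starts + exon_lens - 1L, strand)
    tid <- paste0(gid, ".1")
    utr3 <- sum(exon_lens) - 60L - n_codons * 3L
    seqv <- make_mrna_seq(n_codons, 60L, utr3)
    genes[[gid]] <<- gr_one(chrom, s, s + span - 1L, strand)
    txr <- gr_one(chrom, s, s + span - 1L, strand)
    txs[[tid]] <<- txr
    exons[[tid]] <<- ex
    asm_txs[[tid]] <<- list(r = txr, cov = round(stats::runif(1, 0.7, 1), 3),
                            gene = gid)
    asm_exons[[tid]] <<- ex
    tx_seqs[[tid]] <<- seqv
    list(gid = gid, tid = tid, start = s, end = s + span - 1L, exons = ex)
  }
  add_lnc <- function(role, class, chrom, strand, len, at = NULL,
                      gap = 3000L, seqv = NULL, cov = NULL) {
    lid <- next_lid(role)
    s <- if (is.null(at)) take(chrom, len, gap) else at
    r <- gr_one(chrom, s, s + len - 1L, strand)
    if (is.null(seqv)) seqv <- rand_noncoding_seq(len)
    stopifnot(nchar(seqv) == len)
    asm_txs[[lid]] <<- list(r = r, cov = if (is.null(cov))
      round(stats::runif(1, 0.6, 1), 3) else cov, gene = paste0(lid, "_loc"))
    asm_exons[[lid]] <<- r
    tx_seqs[[lid]] <<- seqv
    lnc_class[[lid]] <<- class
    lid
  }

  # --- chr1: genomic-class exemplars -------------------------------------
  for (k in seq_len(config$n_lncrnas[["antisense"]])) {
    g <- add_gene("chr1", "+")
    # overlaps the last 60 nt of the gene's exon, opposite strand;
    # sequence is derived from the genome after assembly (marker NA)
    len <- 400L
    add_lnc("as", "antisense", "chr1", "-", len, at = g$end - 59L,
            seqv = strrep("N", len))
    cursor[["chr1"]] <- g$end - 59L + len + 3000L
  }
  for (k in seq_len(config$n_lncrnas[["sense"]])) {
    g <- add_gene("chr1", "+")
    len <- 400L
    add_lnc("se", "sense", "chr1", "+", len, at = g$end - 59L,
            seqv = strrep("N", len))
    cursor[["chr1"]] <- g$end - 59L + len + 3000L
  }
  for (k in seq_len(config$n_lncrnas[["intronic"]])) {
    g <- add_gene("chr1", "+", exon_lens = c(400L, 403L),
                  intron_lens = 1400L)
    add_lnc("in", "intronic", "chr1", "+", 400L, at = g$start + 700L)
  }
  for (k in seq_len(config$n_lncrnas[["bidirectional"]])) {
    len <- 420L
    gapd <- sample(200:800, 1)
    s <- take("chr1", len + gapd + 2203L)
    add_lnc("bi", "bidirectional", "chr1", "-", len, at = s)
    add_gene("chr1", "+", at = s + len - 1L + gapd)
  }
  # plain intergenic exemplars on chr1 (those without an interaction role)
  n_roles <- config$n_cis + config$n_trans + config$n_precursor +
    config$n_cerna + 5L
  for (k in seq_len(config$n_lncrnas[["intergenic"]] - n_roles)) {
    add_lnc("ig", "intergenic", "chr1", "+", sample(420:650, 1))
  }
  # junk assembled transcripts: fail length or coverage filter
  junk_ids <- character(0)
  for (k in 1:2) {
    lid <- sprintf("junk_short_%d", k)
    s <- take("chr1", 150L)
    asm_txs[[lid]] <- list(r = gr_one("chr1", s, s + 149L, "+"), cov = 0.9,
                           gene = paste0(lid, "_loc"))
    asm_exons[[lid]] <- gr_one("chr1", s, s + 149L, "+")
    tx_seqs[[lid]] <- rand_seq(150L)
    junk_ids <- c(junk_ids, lid)
  }
  for (k in 1:2) {
    lid <- sprintf("junk_lowcov_%d", k)
    s <- take("chr1", 500L)
    asm_txs[[lid]] <- list(r = gr_one("chr1", s, s + 499L, "+"), cov = 0.3,
                           gene = paste0(lid, "_loc"))
    asm_exons[[lid]] <- gr_one("chr1", s, s + 499L, "+")
    tx_seqs[[lid]] <- rand_seq(500L)
    junk_ids <- c(junk_ids, lid)
  }

  # --- chr2: cis constructs (lncRNA ... gap ... gene) --------------------
  cis_gaps <- c(2000L, 10000L, 30000L, 60000L, 95000L)
  cis_gaps <- cis_gaps[seq_len(min(config$n_cis, length(cis_gaps)))]
  if (config$n_cis > length(cis_gaps))
    cis_gaps <- c(cis_gaps, sample(2000:95000, config$n_cis - length(cis_gaps)))
  cis_pairs <- NULL
  for (k in seq_len(config$n_cis)) {
    len <- 500L
    s <- take("chr2", len + cis_gaps[k] + 803L, gap = 4000L)
    lid <- add_lnc("cis", "intergenic", "chr2", "+", len, at = s)
    g <- add_gene("chr2", "+", at = s + len + cis_gaps[k])
    cis_pairs <- rbind(cis_pairs, data.frame(
      lncrna_id = lid, gene_id = g$gid, distance_nt = cis_gaps[k],
      stringsAsFactors = FALSE))
  }

  # --- chr3: interaction lncRNAs and target mRNAs ------------------------
  role_ids <- list(cerna_lnc = character(0), cerna_mrna = character(0),
                   trans_lnc = character(0), trans_mrna = character(0),
                   precursor_lnc = character(0),
                   decoy_lnc = character(0), decoy_mrna = character(0),
                   extra_de = character(0))
  for (k in seq_len(config$n_cerna)) {
    role_ids$cerna_lnc <- c(role_ids$cerna_lnc,
                            add_lnc("ce", "intergenic", "chr3", "+", 520L))
    role_ids$cerna_mrna <- c(role_ids$cerna_mrna, add_gene("chr3", "+")$tid)
  }
  for (k in seq_len(config$n_trans)) {
    role_ids$trans_lnc <- c(role_ids$trans_lnc,
                            add_lnc("tr", "intergenic", "chr3", "+", 520L))
    role_ids$trans_mrna <- c(role_ids$trans_mrna, add_gene("chr3", "+")$tid)
  }
  for (k in seq_len(config$n_precursor)) {
    role_ids$precursor_lnc <- c(role_ids$precursor_lnc,
                                add_lnc("pre", "intergenic", "chr3", "+", 428L))
  }
  for (k in 1:5) {
    role_ids$decoy_lnc <- c(role_ids$decoy_lnc,
                            add_lnc("dec", "intergenic", "chr3", "+", 520L))
    role_ids$decoy_mrna <- c(role_ids$decoy_mrna, add_gene("chr3", "+")$tid)
  }
  for (k in seq_len(config$n_extra_de)) {
    role_ids$extra_de <- c(role_ids$extra_de, add_gene("chr3", "+")$tid)
  }
  # background genes fill remaining quota on chr1 (varied exon counts)
  while (gid_n < config$n_genes) {
    shape <- sample(1:3, 1)
    if (shape == 1) add_gene("chr1", sample(c("+", "-"), 1))
    else if (shape == 2) add_gene("chr1", "+", exon_lens = c(400L, 403L),
                                  intron_lens = 600L)
    else add_gene("chr1", "+", exon_lens = c(300L, 250L, 253L),
                  intron_lens = c(500L, 700L))
  }

  # --- mature miRNAs ------------------------------------------------------
  mirna_ids <- sprintf("mir%02d", seq_len(config$n_mirnas))
  mirna_seqs <- stats::setNames(
    vapply(mirna_ids, function(i) rand_seq(21L), character(1)), mirna_ids)
  mirna_chrom <- stats::setNames(rep(c("chr1", "chr2"),
                                     length.out = config$n_mirnas),
                                 mirna_ids)

  # --- containers ---------------------------------------------------------
  ann_genes <- unlist(GenomicRanges::GRangesList(genes))
  S4Vectors::mcols(ann_genes) <- S4Vectors::DataFrame(gene_id = names(genes))
  names(ann_genes) <- NULL
  ann_tx <- unlist(GenomicRanges::GRangesList(txs))
  S4Vectors::mcols(ann_tx) <- S4Vectors::DataFrame(
    transcript_id = names(txs),
    gene_id = sub("\\.1$", "", names(txs)),
    coverage = NA_real_, source = "annotated")
  names(ann_tx) <- NULL
  ann_ex <- lapply(names(txs), function(tid) {
    ex <- exons[[tid]]
    S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
      transcript_id = rep(tid, length(ex)))
    ex
  })
  annotation <- tx_annotation(
    ann_genes, ann_tx,
    stats::setNames(GenomicRanges::GRangesList(ann_ex), names(txs)))

  aids <- names(asm_txs)
  asm_gr <- unlist(GenomicRanges::GRangesList(
    lapply(asm_txs, function(x) x$r)))
  S4Vectors::mcols(asm_gr) <- S4Vectors::DataFrame(
    transcript_id = aids,
    gene_id = vapply(asm_txs, function(x) x$gene, character(1)),
    coverage = vapply(asm_txs, function(x) x$cov, numeric(1)),
    source = "assembled")
  names(asm_gr) <- NULL
  asm_exl <- lapply(aids, function(tid) {
    ex <- asm_exons[[tid]]
    S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
      transcript_id = rep(tid, length(ex)))
    ex
  })
  assembled <- tx_annotation(
    asm_gr[match(aids, S4Vectors::mcols(asm_gr)$transcript_id)],
    asm_gr, stats::setNames(GenomicRanges::GRangesList(asm_exl), aids))
  # assembled "genes" slot is irrelevant downstream; reuse annotation genes
  assembled$genes <- ann_genes

  truth <- list(
    lncrna_classes = data.frame(transcript_id = names(lnc_class),
                                class = unname(unlist(lnc_class)),
                                stringsAsFactors = FALSE),
    coding_ids = names(txs),
    junk = data.frame(
      transcript_id = junk_ids,
      reason = rep(c("length", "coverage"), each = 2),
      stringsAsFactors = FALSE),
    cis_pairs = cis_pairs,
    roles = role_ids,
    mirna_chrom = data.frame(mirna_id = mirna_ids,
                             chrom = unname(mirna_chrom),
                             stringsAsFactors = FALSE),
    config = config)
  class(truth) <- "planted_truth"

  structure(list(genome = NULL, annotation = annotation,
                 assembled = assembled, tx_seqs = tx_seqs,
                 mirna_seqs = mirna_seqs, truth = truth),
            class = "sim_dataset")
}

# Replace a subsequence of a transcript, guarding bounds and double-plants.
plant_site <- function(seqs, tid, at, insert, planted_env) {
  s <- seqs[[tid]]
  if (is.null(s)) stop("unknown transcript for planting: ", tid)
  end <- at + nchar(insert) - 1L
  if (at < 1 || end > nchar(s))
    stop("site placement out of bounds for ", tid)
  key <- paste0(tid, ":", at, "-", end)
  used <- planted_env$regions[[tid]]
  if (!is.null(used) && any(at <= used[, 2] & end >= used[, 1]))
    stop("site placement collision on ", tid, " at ", at, "-", end,
         "; regenerate with different offsets")
  planted_env$regions[[tid]] <- rbind(used, c(at, end))
  substr(s, at, end) <- insert
  seqs[[tid]] <- s
  seqs
}

#' Plant interaction content into the generated sequences
#'
#' Inserts, by construction: exact mature-miRNA copies inside constructed
#' stem-loops (precursor lncRNAs, mature fully within one arm); perfect
#' 30-nt G/C complementarity stretches for trans pairs (duplex energy far
#' below -50 by the stacking table's weakest G/C stack); perfect-complement
#' miRNA sites on eTM lncRNAs and target mRNA 3'UTRs (site score 0); and
#' the decoy constructs, each failing exactly one ceRNA condition. Also
#' assigns the planted differential-expression truth (which transcript has
#' which signed effect in which contrast).
#'
#' @param dataset output of [generate_genome_and_annotation()].
#' @param config the same [simulation_config()].
#' @return The dataset with updated `tx_seqs`, a filled `truth` (adds
#'   `trans_pairs`, `precursors`, `etm_pairs`, `cerna_triples`, `decoys`,
#'   `de_truth`) and a `genome` built so extracted spliced transcript
#'   sequences match `tx_seqs` exactly.
#' @export
plant_interactions <- function(dataset, config = dataset$truth$config) {
  set.seed(config$rng_seed + 1L)
  seqs <- dataset$tx_seqs
  mir <- dataset$mirna_seqs
  roles <- dataset$truth$roles
  planted <- new.env()
  planted$regions <- list()
  treatments <- config$conditions[c(1, 3)]
  control <- config$conditions[2]
  contrasts <- paste0(treatments, "_vs_", control)
  de_rows <- list()
  add_de <- function(tid, contrast_idx, direction) {
    de_rows[[length(de_rows) + 1]] <<- data.frame(
      transcript_id = tid, contrast = contrasts[contrast_idx],
      condition = treatments[contrast_idx], direction = direction,
      effect_log2 = if (direction == "up") config$effect_size_log2
                    else -config$effect_size_log2,
      stringsAsFactors = FALSE)
  }
  # mRNA 3'UTR planting offset: transcripts are UTR5(60)+ORF(603)+UTR3(140)
  utr3_at <- function(slot) 60L + 603L + 10L + (slot - 1L) * 40L

  # ceRNA triples: shared miRNA site on lncRNA (eTM) and mRNA (target),
  # both DE with concordant direction; contrasts and directions alternate
  mk <- 0L
  etm_pairs <- NULL; cerna <- NULL
  dirs <- rep(c("up", "down"), length.out = config$n_cerna)
  for (k in seq_len(config$n_cerna)) {
    mk <- mk + 1L
    mid <- names(mir)[mk]
    L <- roles$cerna_lnc[k]; M <- roles$cerna_mrna[k]
    site <- revcomp(mir[[mid]])
    seqs <- plant_site(seqs, L, 101L, site, planted)
    seqs <- plant_site(seqs, M, utr3_at(1L), site, planted)
    ci <- ((k - 1L) %% 2L) + 1L
    add_de(L, ci, dirs[k]); add_de(M, ci, dirs[k])
    etm_pairs <- rbind(etm_pairs, data.frame(
      mirna_id = mid, lncrna_id = L, stringsAsFactors = FALSE))
    cerna <- rbind(cerna, data.frame(
      lncrna_id = L, mirna_id = mid, mrna_id = M,
      contrast = contrasts[ci], direction = dirs[k],
      stringsAsFactors = FALSE))
  }
  # one eTM lncRNA carries sites for two additional miRNAs (1-3 per eTM)
  for (extra in 1:2) {
    mk <- mk + 1L
    mid <- names(mir)[mk]
    L <- roles$cerna_lnc[1]
    seqs <- plant_site(seqs, L, 101L + extra * 30L, revcomp(mir[[mid]]),
                       planted)
    etm_pairs <- rbind(etm_pairs, data.frame(
      mirna_id = mid, lncrna_id = L, stringsAsFactors = FALSE))
  }
  # decoys: each fails exactly one ceRNA condition
  decoy_truth <- NULL
  decoy_spec <- list(
    c(type = "discordant_direction", lnc_de = "up", mrna_de = "down",
      lnc_site = "yes", mrna_site = "yes"),
    c(type = "lncrna_not_de", lnc_de = "null", mrna_de = "up",
      lnc_site = "yes", mrna_site = "yes"),
    c(type = "mrna_not_de", lnc_de = "up", mrna_de = "null",
      lnc_site = "yes", mrna_site = "yes"),
    c(type = "no_etm_site", lnc_de = "up", mrna_de = "up",
      lnc_site = "no", mrna_site = "yes"),
    c(type = "no_target_site", lnc_de = "up", mrna_de = "up",
      lnc_site = "yes", mrna_site = "no"))
  for (k in seq_along(decoy_spec)) {
    mk <- mk + 1L
    mid <- names(mir)[mk]
    sp <- decoy_spec[[k]]
    L <- roles$decoy_lnc[k]; M <- roles$decoy_mrna[k]
    site <- revcomp(mir[[mid]])
    if (sp[["lnc_site"]] == "yes") seqs <- plant_site(seqs, L, 101L, site,
                                                      planted)
    if (sp[["mrna_site"]] == "yes") seqs <- plant_site(seqs, M, utr3_at(1L),
                                                       site, planted)
    if (sp[["lnc_de"]] != "null") add_de(L, 1L, sp[["lnc_de"]])
    if (sp[["mrna_de"]] != "null") add_de(M, 1L, sp[["mrna_de"]])
    decoy_truth <- rbind(decoy_truth, data.frame(
      type = sp[["type"]], lncrna_id = L, mirna_id = mid, mrna_id = M,
      contrast = contrasts[1], stringsAsFactors = FALSE))
  }
  # trans pairs: 30-nt GC-rich complementary stretch in lncRNA and mRNA
  # (mixed composition, so the insert cannot dominate the hexamer score);
  # the stretch is re-drawn until its own duplex energy clears the -50
  # screen with margin. Both members are DE so they enter the screen.
  trans_pairs <- NULL
  stacks <- nn_stack_table()
  for (k in seq_len(config$n_trans)) {
    for (try in 1:50) {
      r <- rand_seq(30L, prob = c(0.15, 0.35, 0.35, 0.15))
      e <- cpp_duplex_energy_min(revcomp(r), r, stacks, 3, 0.5, 8L)
      if (e < -60) break
      if (try == 50) stop("could not construct a stable trans stretch")
    }
    L <- roles$trans_lnc[k]; M <- roles$trans_mrna[k]
    seqs <- plant_site(seqs, M, utr3_at(2L), r, planted)
    seqs <- plant_site(seqs, L, 201L, revcomp(r), planted)
    add_de(L, 1L, "up"); add_de(M, 1L, "up")
    trans_pairs <- rbind(trans_pairs, data.frame(
      lncrna_id = L, mrna_id = M, stringsAsFactors = FALSE))
  }
  # precursors: mature copy inside a constructed stem-loop (arm 60 nt,
  # loop 8 nt, perfect inverted repeat); mature fully in the 5' arm.
  # miRNA chromosome reassigned to the precursor's chromosome (chr3).
  precursors <- NULL
  mirna_chrom <- stats::setNames(dataset$truth$mirna_chrom$chrom,
                                 dataset$truth$mirna_chrom$mirna_id)
  for (k in seq_len(config$n_precursor)) {
    mk <- mk + 1L
    mid <- names(mir)[mk]
    L <- roles$precursor_lnc[k]
    arm <- paste0(rand_seq(20L), mir[[mid]], rand_seq(19L))
    hair <- paste0(arm, rand_seq(8L), revcomp(arm))
    seqs <- plant_site(seqs, L, 151L, hair, planted)  # 428-nt lncRNA
    # for ORF disruption, only the mature copy itself is untouchable: a
    # stop codon elsewhere in the stem still leaves >= 18/21 mature
    # positions paired, well above the hairpin rule's 60%
    planted$regions[[L]] <- matrix(c(171L, 191L), 1)
    mirna_chrom[mid] <- "chr3"
    precursors <- rbind(precursors, data.frame(
      lncrna_id = L, mirna_id = mid, match_offset = 151L + 20L,
      stringsAsFactors = FALSE))
  }
  # re-disrupt any chance ORF the planted inserts may have created,
  # without touching the planted regions themselves
  for (lid in c(roles$cerna_lnc, roles$trans_lnc, roles$precursor_lnc,
                roles$decoy_lnc)) {
    seqs[[lid]] <- disrupt_orfs(seqs[[lid]],
                                protected = planted$regions[[lid]])
  }
  # cis lncRNAs must be DE to enter the cis screen; extra DE mRNAs
  for (lid in dataset$truth$cis_pairs$lncrna_id) add_de(lid, 1L, "up")
  for (k in seq_along(roles$extra_de))
    add_de(roles$extra_de[k], ((k - 1L) %% 2L) + 1L,
           sample(c("up", "down"), 1))

  dataset$tx_seqs <- seqs
  dataset$truth$etm_pairs <- etm_pairs
  dataset$truth$cerna_triples <- cerna
  dataset$truth$decoys <- decoy_truth
  dataset$truth$trans_pairs <- trans_pairs
  dataset$truth$precursors <- precursors
  dataset$truth$de_truth <- do.call(rbind, de_rows)
  dataset$truth$mirna_chrom <- data.frame(
    mirna_id = names(mirna_chrom), chrom = unname(mirna_chrom),
    stringsAsFactors = FALSE)
  dataset$genome <- build_genome(dataset, config)
  # derive genome-backed sequences (fills antisense/sense placeholders and
  # guarantees transcript FASTA == spliced extraction from the genome)
  dataset$tx_seqs <- stats::setNames(
    as.character(spliced_sequences(dataset$genome,
                                   dataset$assembled$exons)),
    names(dataset$assembled$exons))
  dataset
}

# Random chromosomes with every transcript's sequence written in at its
# exon coordinates (strand-aware). Genes first, lncRNAs second, so lncRNAs
# overlapping genes (sense/antisense) take their sequence from the gene.
build_genome <- function(dataset, config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  # AT-biased background, matching the noncoding sequence model
  genome <- lapply(chroms, function(ch)
    rand_seq(config$chrom_length, prob = c(0.30, 0.20, 0.20, 0.30)))
  names(genome) <- chroms
  write_in <- function(tid) {
    ex <- dataset$assembled$exons[[tid]]
    if (is.null(ex)) ex <- dataset$annotation$exons[[tid]]
    ex <- ex[order(GenomicRanges::start(ex))]
    ch <- as.character(GenomicRanges::seqnames(ex))[1]
    s <- dataset$tx_seqs[[tid]]
    if (grepl("N", s, fixed = TRUE)) return(invisible())  # derived later
    if (as.character(GenomicRanges::strand(ex))[1] == "-") s <- revcomp(s)
    offs <- cumsum(c(1L, GenomicRanges::width(ex)))
    for (e in seq_along(ex)) {
      piece <- substr(s, offs[e], offs[e + 1] - 1L)
      g <- genome[[ch]]
      substr(g, GenomicRanges::start(ex)[e], GenomicRanges::end(ex)[e]) <- piece
      genome[[ch]] <<- g
    }
  }
  tids <- names(dataset$assembled$exons)
  is_mrna <- tids %in% S4Vectors::mcols(
    dataset$annotation$transcripts)$transcript_id
  for (tid in tids[is_mrna]) write_in(tid)
  for (tid in tids[!is_mrna]) write_in(tid)
  Biostrings::DNAStringSet(unlist(genome))
}

#' Simulate the FPKM expression matrix from the planted truth
#'
#' log2 FPKM = baseline + planted signed effect (applied in the treatment
#' condition of the transcript's assigned contrast) + Gaussian noise with
#' SD `noise_sd_log2`; FPKM = 2^(log2 FPKM), hence strictly positive and
#' log-normally distributed. Deterministic given the config seed.
#'
#' @param truth a filled `planted_truth` (after [plant_interactions()]).
#' @param config a [simulation_config()].
#' @param transcript_ids transcripts to simulate (default: all ids known to
#'   the truth bundle).
#' @return An [expr_matrix] of FPKM.
#' @export
simulate_expression <- function(truth, config = truth$config,
                                transcript_ids = NULL) {
  set.seed(config$rng_seed + 2L)
  if (is.null(transcript_ids))
    transcript_ids <- c(truth$coding_ids, truth$lncrna_classes$transcript_id,
                        truth$junk$transcript_id)
  n <- length(transcript_ids)
  design <- data.frame(
    sample = paste0(rep(config$conditions, each = config$n_replicates), "_r",
                    rep(seq_len(config$n_replicates),
                        length(config$conditions))),
    condition = rep(config$conditions, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(config$conditions)),
    stringsAsFactors = FALSE)
  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  eff <- matrix(0, n, nrow(design),
                dimnames = list(transcript_ids, design$sample))
  if (!is.null(truth$de_truth)) {
    for (r in seq_len(nrow(truth$de_truth))) {
      row <- truth$de_truth[r, ]
      eff[row$transcript_id, design$condition == row$condition] <-
        eff[row$transcript_id, design$condition == row$condition] +
        row$effect_log2
    }
  }
  noise <- matrix(stats::rnorm(n * nrow(design), 0, config$noise_sd_log2),
                  n, nrow(design))
  vals <- 2^(baseline + eff + noise)
  dimnames(vals) <- list(transcript_ids, design$sample)
  expr_matrix(vals, design)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [generate_genome_and_annotation()], [plant_interactions()] and
#' [simulate_expression()] and writes: `genome.fa`, `annotation.gff3`,
#' `assembled.gtf`, `transcripts.fa`, `mirnas.fa`, `mirna_chrom.tsv`,
#' `expression.tsv`, `design.tsv`, `term_map.tsv` and `truth.yaml` into
#' `out_dir`. Byte-identical under a fixed seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the in-memory `sim_dataset` (with `$expr` attached).
#' @export
generate_cerna_dataset <- function(config = simulation_config(),
                                   out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_genome_and_annotation(config)
  ds <- plant_interactions(ds, config)
  expr <- simulate_expression(ds$truth, config)
  ds$expr <- expr
  write_fasta(ds$genome, file.path(out_dir, "genome.fa"))
  write_gff3(ds$annotation, file.path(out_dir, "annotation.gff3"))
  write_gtf(ds$assembled, file.path(out_dir, "assembled.gtf"))
  write_fasta(Biostrings::DNAStringSet(ds$tx_seqs),
              file.path(out_dir, "transcripts.fa"))
  write_fasta(Biostrings::DNAStringSet(ds$mirna_seqs),
              file.path(out_dir, "mirnas.fa"))
  utils::write.table(ds$truth$mirna_chrom,
                     file.path(out_dir, "mirna_chrom.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_table(expr, file.path(out_dir, "expression.tsv"),
                         file.path(out_dir, "design.tsv"))
  # toy term map: one term concentrated on the ceRNA mRNAs + random terms
  set.seed(config$rng_seed + 3L)
  mrna_ids <- ds$truth$coding_ids
  tm <- rbind(
    data.frame(term = "T_network",
               gene = unique(c(ds$truth$roles$cerna_mrna,
                               sample(mrna_ids, 2))),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:4, function(k) data.frame(
      term = sprintf("T_rand%d", k), gene = sample(mrna_ids, 6),
      stringsAsFactors = FALSE))))
  utils::write.table(tm, file.path(out_dir, "term_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth(ds$truth, file.path(out_dir, "truth.yaml"))
  invisible(ds)
}

#' Write / read the planted-truth bundle (YAML)
#' @param truth a `planted_truth` list.
#' @param path YAML file.
#' @export
write_truth <- function(truth, path) {
  ser <- lapply(unclass(truth), function(x) {
    if (is.data.frame(x)) as.list(x)
    else if (inherits(x, "sim_config")) unclass(x)
    else x
  })
  ser$config$n_lncrnas <- as.list(ser$config$n_lncrnas)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()` returns the `planted_truth` list.
#' @export
read_truth <- function(path) {
  raw <- yaml::read_yaml(path)
  dfs <- c("lncrna_classes", "junk", "cis_pairs", "mirna_chrom",
           "etm_pairs", "cerna_triples", "decoys", "trans_pairs",
           "precursors", "de_truth")
  for (f in intersect(dfs, names(raw)))
    raw[[f]] <- as.data.frame(raw[[f]], stringsAsFactors = FALSE)
  if (!is.null(raw$config)) {
    raw$config$n_lncrnas <- unlist(raw$config$n_lncrnas)
    raw$config <- do.call(simulation_config, raw$config)
  }
  class(raw) <- "planted_truth"
  raw
}
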