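# In-code fixtures shared across test files.

# Build a minimal tx_annotation from a data.frame of transcripts
# (columns: transcript_id, gene_id, chrom, start, end, strand, coverage,
# source) with single-exon transcripts unless exon rows are supplied.
make_annotation <- function(tx, exons = NULL) {
  gr <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    coverage = if ("coverage" %in% names(tx)) tx$coverage else NA_real_,
    source = if ("source" %in% names(tx)) tx$source else "annotated")
  if (is.null(exons)) exons <- tx
  exl <- lapply(tx$transcript_id, function(tid) {
    e <- exons[exons$transcript_id == tid, , drop = FALSE]
    eg <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                                 strand = e$strand)
    S4Vectors::mcols(eg) <- S4Vectors::DataFrame(
      transcript_id = rep(tid, nrow(e)))
    eg
  })
  genes <- unlist(range(GenomicRanges::split(
    gr, factor(tx$gene_id, levels = unique(tx$gene_id)))))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = names(genes))
  names(genes) <- NULL
  tx_annotation(genes, gr,
                stats::setNames(GenomicRanges::GRangesList(exl),
                                tx$transcript_id))
}

simple_expr <- function(values, conditions, reps = NULL) {
  if (is.null(reps))
    reps <- as.integer(unlist(lapply(table(conditions)[unique(conditions)],
                                     seq_len)))
  design <- data.frame(sample = colnames(values), condition = conditions,
                       replicate = reps, stringsAsFactors = FALSE)
  expr_matrix(values, design)
}

# Shared demo dataset + pipeline run, generated once per test session.
demo_cache <- new.env()
get_demo <- function() {
  if (is.null(demo_cache$res)) {
    dir <- file.path(tempdir(), "cernapipe_demo")
    out <- file.path(tempdir(), "cernapipe_demo_out")
    demo_cache$ds <- generate_demo(1L, dir)
    demo_cache$dir <- dir
    demo_cache$out <- out
    demo_cache$truth <- read_truth(file.path(dir, "truth.yaml"))
    demo_cache$res <- run_cerna_pipeline(dir, out)
  }
  demo_cache
}
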