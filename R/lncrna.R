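#' Filter assembled transcripts into lncRNA candidate input
#'
#' Retains a transcript iff its spliced length is at least
#' `min_length_nt` and its assembly read coverage is at least
#' `min_coverage`; both boundaries are kept (a 200-nt transcript at
#' coverage 0.5 passes the defaults). Unknown coverage fails the coverage
#' filter unless the filter is disabled in the configuration. Filtering is
#' idempotent and order-independent; a rejection reason is recorded for
#' every dropped transcript.
#'
#' @param assembled a [tx_annotation] of assembled transcripts.
#' @param config a [run_config()].
#' @return data.frame with `transcript_id`, `spliced_length`, `coverage`,
#'   `retained`, `reason` (`NA`, `"length"` or `"coverage"`; length is
#'   checked first).
#' @export
filter_candidates <- function(assembled, config = run_config()) {
  tx <- assembled$transcripts
  len <- spliced_lengths(assembled)
  cov <- S4Vectors::mcols(tx)$coverage
  id <- S4Vectors::mcols(tx)$transcript_id
  len <- unname(len[id])
  fail_len <- len < config$min_length_nt
  fail_cov <- if (config$apply_coverage_filter)
    is.na(cov) | cov < config$min_coverage else rep(FALSE, length(id))
  reason <- rep(NA_character_, length(id))
  reason[fail_cov] <- "coverage"
  reason[fail_len] <- "length"
  data.frame(transcript_id = id, spliced_length = len, coverage = cov,
             retained = !(fail_len | fail_cov), reason = reason,
             stringsAsFactors = FALSE)
}

#' Classify lncRNA candidates by genomic context
#'
#' Assigns exactly one of five labels per candidate, first match wins:
#' \enumerate{
#'   \item \strong{antisense}: exonic overlap with an annotated exon on the
#'     opposite strand;
#'   \item \strong{sense}: exonic overlap on the same strand;
#'   \item \strong{intronic}: transcript fully contained within an intron
#'     of an annotated gene (either strand);
#'   \item \strong{bidirectional}: no overlap with any annotated gene, and
#'     transcription start within `bidirectional_window` nt of a gene's
#'     start in divergent (head-to-head) orientation;
#'   \item \strong{intergenic}: otherwise.
#' }
#'
#' @param candidates a [tx_annotation] holding the candidate transcripts.
#' @param annotation the reference [tx_annotation] (annotated genes).
#' @param config a [run_config()].
#' @return data.frame with `transcript_id`, `class`, `evidence_gene`
#'   (nearest/overlapping annotated gene, `NA` if none on the chromosome)
#'   and `relation` (human-readable evidence).
#' @export
classify_lncrna <- function(candidates, annotation, config = run_config()) {
  cand_tx <- candidates$transcripts
  cid <- S4Vectors::mcols(cand_tx)$transcript_id
  ann_ex <- unlist(annotation$exons)
  ann_tid2gene <- stats::setNames(
    as.character(S4Vectors::mcols(annotation$transcripts)$gene_id),
    S4Vectors::mcols(annotation$transcripts)$transcript_id)
  ann_ex_gene <- unname(ann_tid2gene[S4Vectors::mcols(ann_ex)$transcript_id])
  genes <- annotation$genes

  # introns: per annotated transcript, gaps between its exons
  introns <- GenomicRanges::psetdiff(
    unlist(range(annotation$exons)), annotation$exons)
  intron_gene <- rep(unname(ann_tid2gene[names(annotation$exons)]),
                     lengths(introns))
  introns <- unlist(introns)

  n <- length(cand_tx)
  cls <- rep("intergenic", n)
  egene <- rep(NA_character_, n)
  relation <- rep(NA_character_, n)

  for (k in seq_len(n)) {
    ex <- candidates$exons[[cid[k]]]
    txr <- cand_tx[k]
    hits <- GenomicRanges::findOverlaps(ex, ann_ex, ignore.strand = TRUE)
    if (length(hits) > 0) {
      same <- as.character(GenomicRanges::strand(ann_ex))[
        S4Vectors::subjectHits(hits)] ==
        as.character(GenomicRanges::strand(txr))
      if (any(!same)) {
        cls[k] <- "antisense"
        g <- ann_ex_gene[S4Vectors::subjectHits(hits)[!same][1]]
        egene[k] <- g
        relation[k] <- paste0("exonic overlap, opposite strand of ", g)
        next
      }
      cls[k] <- "sense"
      g <- ann_ex_gene[S4Vectors::subjectHits(hits)[1]]
      egene[k] <- g
      relation[k] <- paste0("exonic overlap, same strand as ", g)
      next
    }
    if (length(introns) > 0) {
      w <- GenomicRanges::findOverlaps(txr, introns, type = "within",
                                       ignore.strand = TRUE)
      if (length(w) > 0) {
        cls[k] <- "intronic"
        g <- intron_gene[S4Vectors::subjectHits(w)[1]]
        egene[k] <- g
        relation[k] <- paste0("contained in intron of ", g)
        next
      }
    }
    # overlap with a gene body (no exon overlap, not intronic) blocks the
    # bidirectional test; such candidates fall through to intergenic
    ovl_gene <- GenomicRanges::findOverlaps(txr, genes, ignore.strand = TRUE)
    if (length(ovl_gene) == 0 && length(genes) > 0) {
      cstr <- as.character(GenomicRanges::strand(txr))
      ctss <- if (cstr == "+") GenomicRanges::start(txr)
              else GenomicRanges::end(txr)
      gstr <- as.character(GenomicRanges::strand(genes))
      gtss <- ifelse(gstr == "+", GenomicRanges::start(genes),
                     GenomicRanges::end(genes))
      samechrom <- as.character(GenomicRanges::seqnames(genes)) ==
        as.character(GenomicRanges::seqnames(txr))
      opposite <- gstr != cstr & gstr %in% c("+", "-")
      tss_plus <- if (cstr == "+") rep(ctss, length(genes)) else gtss
      tss_minus <- if (cstr == "+") gtss else rep(ctss, length(genes))
      divergent <- tss_minus <= tss_plus
      d <- abs(gtss - ctss)
      ok <- samechrom & opposite & divergent & d <= config$bidirectional_window
      if (any(ok)) {
        j <- which(ok)[which.min(d[ok])]
        cls[k] <- "bidirectional"
        egene[k] <- S4Vectors::mcols(genes)$gene_id[j]
        relation[k] <- sprintf("divergent start %d nt from %s",
                               d[j], egene[k])
        next
      }
    }
    if (cls[k] == "intergenic" && length(genes) > 0) {
      gs <- genes[as.character(GenomicRanges::seqnames(genes)) ==
                  as.character(GenomicRanges::seqnames(txr))]
      if (length(gs) > 0) {
        dd <- GenomicRanges::distance(txr, gs, ignore.strand = TRUE)
        j <- which.min(dd)
        egene[k] <- S4Vectors::mcols(gs)$gene_id[j]
        relation[k] <- sprintf("nearest gene %s at %d nt", egene[k], dd[j])
      }
    }
  }
  data.frame(transcript_id = cid, class = cls, evidence_gene = egene,
             relation = relation, stringsAsFactors = FALSE)
}

#' Structural summary tables for lncRNAs vs mRNAs
#'
#' @param lncrnas,mrnas [tx_annotation] objects for the two transcript sets.
#' @param lnc_seqs,mrna_seqs optional sequences; when given, ORF-length bins
#'   are included.
#' @param length_breaks,orf_breaks bin edges (right-open; last bin open).
#' @return A list of data.frames: `length`, `exons`, `chromosome` and
#'   (when sequences are given) `orf`; counts in each table sum to the
#'   input set sizes.
#' @export
summarize_structure <- function(lncrnas, mrnas,
                                lnc_seqs = NULL, mrna_seqs = NULL,
                                length_breaks = c(0, 200, 500, 1000, 2000, Inf),
                                orf_breaks = c(0, 1, 100, 300, 500, Inf)) {
  bin_counts <- function(x, breaks) {
    table(cut(x, breaks = breaks, right = FALSE, include.lowest = TRUE))
  }
  two_set <- function(lv, mv, breaks) {
    tl <- bin_counts(lv, breaks); tm <- bin_counts(mv, breaks)
    data.frame(bin = names(tl), lncRNA = as.integer(tl),
               mRNA = as.integer(tm), stringsAsFactors = FALSE)
  }
  out <- list(
    length = two_set(spliced_lengths(lncrnas), spliced_lengths(mrnas),
                     length_breaks),
    exons = {
      mx <- max(lengths(lncrnas$exons), lengths(mrnas$exons), 1)
      le <- table(factor(lengths(lncrnas$exons), levels = 1:mx))
      me <- table(factor(lengths(mrnas$exons), levels = 1:mx))
      data.frame(bin = names(le), lncRNA = as.integer(le),
                 mRNA = as.integer(me), stringsAsFactors = FALSE)
    },
    chromosome = {
      chroms <- sort(unique(c(
        as.character(GenomicRanges::seqnames(lncrnas$transcripts)),
        as.character(GenomicRanges::seqnames(mrnas$transcripts)))))
      lc <- table(factor(as.character(
        GenomicRanges::seqnames(lncrnas$transcripts)), levels = chroms))
      mc <- table(factor(as.character(
        GenomicRanges::seqnames(mrnas$transcripts)), levels = chroms))
      data.frame(bin = chroms, lncRNA = as.integer(lc),
                 mRNA = as.integer(mc), stringsAsFactors = FALSE)
    })
  if (!is.null(lnc_seqs) && !is.null(mrna_seqs)) {
    lorf <- vapply(as.character(lnc_seqs),
                   function(s) find_orfs(s)$longest_nt, integer(1))
    morf <- vapply(as.character(mrna_seqs),
                   function(s) find_orfs(s)$longest_nt, integer(1))
    out$orf <- two_set(lorf, morf, orf_breaks)
  }
  out
}
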