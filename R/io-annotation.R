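#' Transcript annotation container
#'
#' Bundles gene ranges, transcript ranges and per-transcript exon lists.
#' Intervals follow the Bioconductor convention (1-based, closed), so GFF3
#' and GTF coordinates round-trip unchanged.
#'
#' @param genes [GenomicRanges::GRanges] with an mcol `gene_id`.
#' @param transcripts `GRanges` with mcols `transcript_id`, `gene_id`,
#'   `coverage` (fraction or `NA` when unknown) and
#'   `source` (`"annotated"` or `"assembled"`).
#' @param exons [GenomicRanges::GRangesList] named by transcript id; exons
#'   must be non-overlapping and lie on the transcript's chrom/strand.
#' @return An object of class `tx_annotation`.
#' @export
tx_annotation <- function(genes, transcripts, exons) {
  stopifnot(methods::is(genes, "GRanges"),
            methods::is(transcripts, "GRanges"),
            methods::is(exons, "GRangesList"))
  tid <- S4Vectors::mcols(transcripts)$transcript_id
  if (is.null(tid) || anyDuplicated(tid))
    stop("transcripts need unique transcript_id mcols")
  if (!setequal(names(exons), tid))
    stop("exon list names must match transcript ids")
  exons <- exons[tid]
  for (k in seq_along(exons)) {
    ex <- exons[[k]]
    if (length(ex) == 0) stop("transcript without exons: ", tid[k])
    if (length(ex) > 1) {
      ex <- ex[order(GenomicRanges::start(ex))]
      if (any(GenomicRanges::start(ex)[-1] <=
              GenomicRanges::end(ex)[-length(ex)]))
        stop("overlapping exons in transcript ", tid[k])
      exons[[k]] <- ex
    }
  }
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("tx_annotation: %d genes, %d transcripts (%s)\n",
              length(x$genes), length(x$transcripts),
              paste(names(table(S4Vectors::mcols(x$transcripts)$source)),
                    collapse = "/")))
  invisible(x)
}

#' Spliced length of each transcript (sum of exon widths)
#' @param annotation a `tx_annotation`.
#' @return Named integer vector.
#' @export
spliced_lengths <- function(annotation) {
  w <- sum(GenomicRanges::width(annotation$exons))
  stats::setNames(as.integer(w), names(annotation$exons))
}

gr_one <- function(chrom, start, end, strand) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

#' Read a GFF3 reference annotation
#'
#' Expects gene / mRNA (or transcript) / exon features linked by ID/Parent
#' attributes. Exons whose Parent does not resolve to a transcript are an
#' error, as are records with end < start; malformed input is rejected, not
#' repaired.
#'
#' @param path GFF3 file.
#' @return A [tx_annotation] with `source = "annotated"`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) > 0) {
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = as.character(genes$ID))
  }
  tx <- gr[type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA")]
  if (length(tx) == 0) stop("no transcript features in ", path)
  tx_parent <- vapply(as.list(tx$Parent), function(p)
    if (length(p) > 0) p[1] else NA_character_, character(1))
  tids <- as.character(tx$ID)
  if (anyNA(tids)) stop("transcript feature without ID attribute in ", path)
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
    transcript_id = tids, gene_id = tx_parent,
    coverage = NA_real_, source = "annotated")
  ex <- gr[type == "exon"]
  ex_parent <- vapply(as.list(ex$Parent), function(p)
    if (length(p) > 0) p[1] else NA_character_, character(1))
  orphan <- is.na(ex_parent) | !(ex_parent %in% tids)
  if (any(orphan))
    stop("exon feature(s) with missing or unresolvable Parent: ",
         paste(utils::head(paste0(GenomicRanges::seqnames(ex)[orphan], ":",
                                  GenomicRanges::start(ex)[orphan]), 5),
               collapse = ", "))
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(transcript_id = ex_parent)
  exl <- GenomicRanges::split(ex, factor(ex_parent, levels = tids))
  tx_annotation(genes, tx, exl)
}

#' Read assembled transcript models from a GTF file
#'
#' Expects transcript and exon features with `transcript_id`/`gene_id`
#' attributes; an optional `cov` attribute (assembler read coverage) is read
#' into `coverage`, recorded as `NA` when absent.
#'
#' @param path GTF file.
#' @return A [tx_annotation] with `source = "assembled"` (the `genes` slot
#'   holds one range per `gene_id` spanning its transcripts).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  type <- as.character(gr$type)
  tx <- gr[type == "transcript"]
  ex <- gr[type == "exon"]
  if (length(tx) == 0 || length(ex) == 0)
    stop("GTF must contain transcript and exon features: ", path)
  tids <- as.character(tx$transcript_id)
  if (anyNA(tids) | any(tids == ""))
    stop("transcript feature without transcript_id attribute in ", path)
  if (anyDuplicated(tids))
    stop("duplicate transcript_id in ", path, ": ",
         paste(unique(tids[duplicated(tids)]), collapse = ", "))
  cov <- if ("cov" %in% names(S4Vectors::mcols(tx)))
    suppressWarnings(as.numeric(tx$cov)) else rep(NA_real_, length(tx))
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
    transcript_id = tids,
    gene_id = as.character(tx$gene_id),
    coverage = cov, source = "assembled")
  ex_tid <- as.character(ex$transcript_id)
  if (!all(ex_tid %in% tids))
    stop("exon with transcript_id lacking a transcript feature: ",
         paste(utils::head(setdiff(ex_tid, tids), 5), collapse = ", "))
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(transcript_id = ex_tid)
  exl <- GenomicRanges::split(ex, factor(ex_tid, levels = tids))
  genes <- unlist(range(GenomicRanges::split(
    tx, factor(as.character(tx$gene_id)))))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = names(genes))
  names(genes) <- NULL
  tx_annotation(genes, tx, exl)
}

#' Write a reference annotation to GFF3
#' @param annotation a [tx_annotation].
#' @param path output file.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  g$type <- "gene"; g$ID <- g$gene_id; g$Parent <- NA_character_
  tx <- annotation$transcripts
  feat <- S4Vectors::DataFrame(
    gene_id = NA_character_, type = "mRNA",
    ID = tx$transcript_id, Parent = tx$gene_id)
  tx2 <- tx
  S4Vectors::mcols(tx2) <- feat
  ex <- unlist(annotation$exons)
  exg <- ex
  S4Vectors::mcols(exg) <- S4Vectors::DataFrame(
    gene_id = NA_character_, type = "exon",
    ID = NA_character_, Parent = ex$transcript_id)
  all <- c(g, tx2, exg)
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Write assembled transcript models to GTF (with a `cov` attribute)
#' @param annotation a [tx_annotation].
#' @param path output file.
#' @export
write_gtf <- function(annotation, path) {
  tx <- annotation$transcripts
  feat <- S4Vectors::DataFrame(
    type = "transcript", gene_id = tx$gene_id,
    transcript_id = tx$transcript_id,
    cov = ifelse(is.na(tx$coverage), NA_character_,
                 sprintf("%.4f", tx$coverage)))
  tx2 <- tx
  S4Vectors::mcols(tx2) <- feat
  ex <- unlist(annotation$exons)
  tid2gene <- stats::setNames(as.character(tx$gene_id), tx$transcript_id)
  exg <- ex
  S4Vectors::mcols(exg) <- S4Vectors::DataFrame(
    type = "exon", gene_id = unname(tid2gene[ex$transcript_id]),
    transcript_id = ex$transcript_id, cov = NA_character_)
  all <- c(tx2, exg)
  all <- all[order(as.factor(GenomicRanges::seqnames(all)),
                   GenomicRanges::start(all))]
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}
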