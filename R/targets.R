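#' Nearest-neighbour stacking parameter table
#'
#' Loads the 6x6 helix stacking free-energy matrix (kcal/mol) used by
#' [duplex_energy()]. Rows/columns are pair types `AU, UA, CG, GC, GU, UG`
#' (first base on strand A). Watson-Crick values follow the standard Turner
#' parameters; G:U wobble entries are Turner-style approximations. A custom
#' table with the same layout can be supplied to recalibrate the energy
#' scale.
#'
#' @param path TSV with columns `pair1`, `pair2`, `dg`; defaults to the
#'   table shipped with the package.
#' @return Numeric 6x6 matrix with dimnames.
#' @export
nn_stack_table <- function(path = system.file("extdata", "nn_stacks.tsv",
                                              package = "cernapipe")) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  lv <- c("AU", "UA", "CG", "GC", "GU", "UG")
  m <- matrix(NA_real_, 6, 6, dimnames = list(lv, lv))
  m[cbind(match(df$pair1, lv), match(df$pair2, lv))] <- df$dg
  if (anyNA(m)) stop("incomplete stacking table: ", path)
  m
}

#' Minimum intermolecular duplex free energy (one-loop model)
#'
#' Computes the minimum interaction free energy over all antiparallel
#' duplexes between `seq_a` and `seq_b` under a nearest-neighbour stacking
#' model (Watson-Crick plus G:U pairs). A duplex is a single helix,
#' optionally interrupted by one interior loop/bulge penalized with an
#' affine cost (`loop_open + loop_ext * unpaired`, at most `max_loop`
#' unpaired bases); no intramolecular structure is considered. The energy
#' is 0 exactly when no stabilizing duplex exists. The computation is
#' symmetric in its two arguments.
#'
#' @param seq_a,seq_b nucleotide strings (T and U equivalent).
#' @param config a [run_config()] (loop cost parameters).
#' @param stacks stacking matrix from [nn_stack_table()].
#' @return A list: `energy` (kcal/mol, <= 0), `n_pairs`, and the paired
#'   region coordinates `a_start`/`a_end`/`b_start`/`b_end` (1-based, `NA`
#'   when no duplex), plus `pairs_a`/`pairs_b` (paired positions) and a
#'   dot-bar `structure` string over the region of `seq_a`.
#' @export
duplex_energy <- function(seq_a, seq_b, config = run_config(),
                          stacks = nn_stack_table()) {
  seq_a <- canonicalize_seq(as.character(seq_a))
  seq_b <- canonicalize_seq(as.character(seq_b))
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  r <- cpp_duplex_energy(seq_a, seq_b, stacks,
                         config$loop_open, config$loop_ext, config$max_loop)
  if (r$n_pairs > 0) {
    pos <- r$pairs_a - r$a_start + 1
    s <- rep(".", r$a_end - r$a_start + 1)
    s[pos] <- "|"
    r$structure <- paste(s, collapse = "")
  } else {
    r$structure <- ""
  }
  r
}

#' Predict cis target genes by genomic proximity
#'
#' Emits a (lncRNA, gene) pair iff the gene lies on the same chromosome and
#' the gap between the two intervals is at most `window_nt` (inclusive;
#' overlap counts as distance 0). Strand is ignored for pairing.
#'
#' @param lncrnas `GRanges` (or [tx_annotation]) of the differentially
#'   expressed lncRNAs, with `transcript_id` mcols.
#' @param genes `GRanges` of annotated genes with `gene_id` mcols (or a
#'   [tx_annotation], whose `genes` slot is used).
#' @param window_nt maximum gap in nt.
#' @return data.frame `lncrna_id`, `mrna_id`, `distance_nt`,
#'   `relative_position` (`upstream`/`downstream`/`overlapping`, relative
#'   to the lncRNA in genomic orientation), sorted by distance.
#' @export
cis_targets <- function(lncrnas, genes, window_nt = 100000L) {
  if (inherits(lncrnas, "tx_annotation")) lncrnas <- lncrnas$transcripts
  if (inherits(genes, "tx_annotation")) genes <- genes$genes
  if (length(lncrnas) == 0 || length(genes) == 0)
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      distance_nt = integer(),
                      relative_position = character()))
  hits <- GenomicRanges::findOverlaps(lncrnas, genes,
                                      maxgap = window_nt,
                                      ignore.strand = TRUE)
  if (length(hits) == 0)
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      distance_nt = integer(),
                      relative_position = character()))
  ql <- lncrnas[S4Vectors::queryHits(hits)]
  sg <- genes[S4Vectors::subjectHits(hits)]
  d <- GenomicRanges::distance(ql, sg, ignore.strand = TRUE)
  # distance() is NA only for cross-chromosome pairs, which findOverlaps
  # never returns; gap semantics: adjacent intervals have distance 0
  pos <- ifelse(d == 0 &
                  GenomicRanges::start(sg) <= GenomicRanges::end(ql) &
                  GenomicRanges::end(sg) >= GenomicRanges::start(ql),
                "overlapping",
                ifelse(GenomicRanges::end(sg) < GenomicRanges::start(ql),
                       "upstream", "downstream"))
  out <- data.frame(
    lncrna_id = S4Vectors::mcols(ql)$transcript_id,
    mrna_id = S4Vectors::mcols(sg)$gene_id,
    distance_nt = as.integer(d),
    relative_position = pos, stringsAsFactors = FALSE)
  out <- out[out$distance_nt <= window_nt, , drop = FALSE]
  out <- out[order(out$distance_nt, out$lncrna_id, out$mrna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict trans targets by duplex free energy
#'
#' Scores every (lncRNA, mRNA) sequence pair with [duplex_energy()] and
#' retains pairs with energy strictly below `cutoff` (an energy of exactly
#' the cutoff is excluded). Sorted by energy, most stable first.
#'
#' @param lnc_seqs,mrna_seqs named character vectors / `DNAStringSet`s.
#' @param cutoff retain iff energy < cutoff.
#' @param config a [run_config()].
#' @param stacks stacking matrix from [nn_stack_table()].
#' @return data.frame `lncrna_id`, `mrna_id`, `energy`.
#' @export
trans_targets <- function(lnc_seqs, mrna_seqs, cutoff = -50,
                          config = run_config(), stacks = nn_stack_table()) {
  lnc_seqs <- stats::setNames(canonicalize_seq(as.character(lnc_seqs)),
                              names(lnc_seqs))
  mrna_seqs <- stats::setNames(canonicalize_seq(as.character(mrna_seqs)),
                               names(mrna_seqs))
  rows <- list()
  for (li in seq_along(lnc_seqs)) {
    for (mi in seq_along(mrna_seqs)) {
      e <- cpp_duplex_energy_min(lnc_seqs[[li]], mrna_seqs[[mi]], stacks,
                                 config$loop_open, config$loop_ext,
                                 config$max_loop)
      if (e < cutoff) {
        rows[[length(rows) + 1]] <- data.frame(
          lncrna_id = names(lnc_seqs)[li],
          mrna_id = names(mrna_seqs)[mi],
          energy = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      energy = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(out$energy, out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
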