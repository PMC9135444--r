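#' Score a miRNA against an aligned target site
#'
#' Plant-style penalty scoring of an antiparallel miRNA:site duplex. miRNA
#' positions are indexed from the 5' end; positions within the strict
#' matching zone (defaults 2-13) take penalty 1 per mismatch or gap
#' ("missing" position) and 0.5 per G:U wobble, positions outside the zone
#' take half those penalties (0.5 / 0.25). The minimum-score alignment over
#' all gap placements (at most `max_gaps` gaps; a gap consuming a miRNA
#' position is a missing target base, a gap consuming a site base is a
#' target bulge, penalized at the next miRNA position's zone) is found by
#' dynamic programming.
#'
#' @param mirna_seq mature miRNA, 5'->3' (>= 15 nt).
#' @param site_seq target site, 5'->3'.
#' @param config a [run_config()].
#' @return A list: `score`, `alignment` (one symbol per alignment column
#'   from the miRNA 5' end: `|` Watson-Crick, `o` G:U, `x` mismatch, `-`
#'   missing target base, `^` bulged target base), `n_gaps`,
#'   `strict_penalty`, `nonstrict_penalty`.
#' @export
score_mirna_target <- function(mirna_seq, site_seq, config = run_config()) {
  mirna_seq <- canonicalize_seq(as.character(mirna_seq))
  site_seq <- canonicalize_seq(as.character(site_seq))
  if (nchar(mirna_seq) < 15)
    stop("miRNA shorter than 15 nt: ", mirna_seq)
  cpp_target_score(mirna_seq, site_seq,
                   config$mismatch_penalty[["strict"]],
                   config$gu_penalty[["strict"]],
                   config$mismatch_penalty[["nonstrict"]],
                   config$gu_penalty[["nonstrict"]],
                   config$strict_zone[1], config$strict_zone[2],
                   config$max_gaps)
}

#' Scan transcripts for miRNA target sites
#'
#' Every window of width |miRNA| +/- `max_gaps` in every transcript is
#' scored with [score_mirna_target()]; windows at or below
#' `target_score_cutoff` (inclusive, so a score of exactly 2.5 is kept
#' under the defaults) are candidate sites. Per (miRNA, transcript),
#' overlapping candidates are resolved to minimal-score non-overlapping
#' sites; ties break to the leftmost start, then the shortest site.
#'
#' @param mirna_seqs named mature miRNA sequences.
#' @param transcript_seqs named transcript sequences.
#' @param cutoff maximum site score (inclusive).
#' @param config a [run_config()].
#' @param label value for the `type` column (e.g. `"target"` or `"eTM"`).
#' @return data.frame `mirna_id`, `rna_id`, `start`, `end`, `score`,
#'   `n_gaps`, `strict_penalty`, `nonstrict_penalty`, `alignment`, `type`.
#' @export
predict_targets <- function(mirna_seqs, transcript_seqs,
                            cutoff = 2.5, config = run_config(),
                            label = "target") {
  mirna_seqs <- stats::setNames(canonicalize_seq(as.character(mirna_seqs)),
                                names(mirna_seqs))
  transcript_seqs <- stats::setNames(
    canonicalize_seq(as.character(transcript_seqs)), names(transcript_seqs))
  if (any(nchar(mirna_seqs) < 15)) stop("miRNA shorter than 15 nt")
  rows <- list()
  for (mi in seq_along(mirna_seqs)) {
    for (ti in seq_along(transcript_seqs)) {
      hits <- cpp_scan_targets(
        mirna_seqs[[mi]], transcript_seqs[[ti]], cutoff,
        config$mismatch_penalty[["strict"]], config$gu_penalty[["strict"]],
        config$mismatch_penalty[["nonstrict"]],
        config$gu_penalty[["nonstrict"]],
        config$strict_zone[1], config$strict_zone[2], config$max_gaps)
      if (nrow(hits) == 0) next
      keep <- select_nonoverlapping(hits)
      keep$mirna_id <- names(mirna_seqs)[mi]
      keep$rna_id <- names(transcript_seqs)[ti]
      rows[[length(rows) + 1]] <- keep
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(), rna_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      n_gaps = integer(), strict_penalty = numeric(),
                      nonstrict_penalty = numeric(), alignment = character(),
                      type = character()))
  out <- do.call(rbind, rows)
  out$type <- label
  out <- out[, c("mirna_id", "rna_id", "start", "end", "score", "n_gaps",
                 "strict_penalty", "nonstrict_penalty", "alignment", "type")]
  out <- out[order(out$mirna_id, out$rna_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Greedy minimal-score non-overlapping site selection; deterministic
# tie-break: score, then leftmost start, then shortest.
select_nonoverlapping <- function(hits) {
  o <- order(hits$score, hits$start, hits$end - hits$start)
  hits <- hits[o, , drop = FALSE]
  kept <- logical(nrow(hits))
  occupied <- integer(0)
  for (k in seq_len(nrow(hits))) {
    span <- hits$start[k]:hits$end[k]
    if (!any(span %in% occupied)) {
      kept[k] <- TRUE
      occupied <- c(occupied, span)
    }
  }
  hits[kept, , drop = FALSE]
}

#' Predict endogenous target mimics (eTMs) on lncRNAs
#'
#' Identical scanning and scoring as [predict_targets()], with
#' differentially expressed lncRNAs as the targets; hits are labelled
#' `eTM`. A single lncRNA may carry sites for several miRNAs.
#'
#' @inheritParams predict_targets
#' @param lnc_seqs named DE-lncRNA sequences.
#' @return As [predict_targets()], `type = "eTM"`.
#' @export
predict_etms <- function(mirna_seqs, lnc_seqs, cutoff = 2.5,
                         config = run_config()) {
  predict_targets(mirna_seqs, lnc_seqs, cutoff, config, label = "eTM")
}

#' Detect lncRNAs that can act as miRNA precursors
#'
#' A precursor hit requires the mature miRNA sequence to occur verbatim
#' (100% identity, sense orientation) inside the lncRNA and, when a
#' chromosome map is supplied, the lncRNA to lie on the miRNA's annotated
#' chromosome. Each exact match is then submitted to [hairpin_check()];
#' only hits whose local secondary structure passes the stem-loop rule are
#' reported with `hairpin_pass = TRUE`.
#'
#' @param lnc_seqs named lncRNA sequences.
#' @param mirna_seqs named mature miRNA sequences.
#' @param mirna_chrom optional named vector mapping miRNA id -> chromosome.
#' @param lnc_chrom optional named vector mapping lncRNA id -> chromosome
#'   (required when `mirna_chrom` is given).
#' @param config a [run_config()].
#' @param require_hairpin drop hits failing the hairpin rule (default).
#' @return data.frame `lncrna_id`, `mirna_id`, `match_offset` (1-based),
#'   `chrom`, `hairpin_pass`, `paired_fraction`.
#' @export
find_precursor_loci <- function(lnc_seqs, mirna_seqs, mirna_chrom = NULL,
                                lnc_chrom = NULL, config = run_config(),
                                require_hairpin = TRUE) {
  lnc_seqs <- stats::setNames(canonicalize_seq(as.character(lnc_seqs)),
                              names(lnc_seqs))
  mirna_seqs <- stats::setNames(canonicalize_seq(as.character(mirna_seqs)),
                                names(mirna_seqs))
  rows <- list()
  for (mi in seq_along(mirna_seqs)) {
    mid <- names(mirna_seqs)[mi]
    mseq <- mirna_seqs[[mi]]
    for (li in seq_along(lnc_seqs)) {
      lid <- names(lnc_seqs)[li]
      if (!is.null(mirna_chrom)) {
        if (is.null(lnc_chrom))
          stop("lnc_chrom required when mirna_chrom is given")
        if (is.na(mirna_chrom[mid]) || is.na(lnc_chrom[lid]) ||
            mirna_chrom[mid] != lnc_chrom[lid]) next
      }
      offs <- gregexpr(mseq, lnc_seqs[[li]], fixed = TRUE)[[1]]
      if (offs[1] == -1) next
      for (off in as.integer(offs)) {
        hp <- hairpin_check(lnc_seqs[[li]], off, nchar(mseq), config)
        if (require_hairpin && !hp$hairpin_pass) next
        rows[[length(rows) + 1]] <- data.frame(
          lncrna_id = lid, mirna_id = mid, match_offset = off,
          chrom = if (is.null(lnc_chrom)) NA_character_
                  else unname(lnc_chrom[lid]),
          hairpin_pass = hp$hairpin_pass,
          paired_fraction = hp$paired_fraction,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(lncrna_id = character(), mirna_id = character(),
                      match_offset = integer(), chrom = character(),
                      hairpin_pass = logical(), paired_fraction = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(out$lncrna_id, out$mirna_id, out$match_offset), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stem-loop check around a mature miRNA match
#'
#' Folds a window of `hairpin_flank` nt on each side of the mature match
#' (clipped at the sequence ends) by base-pair maximization (Nussinov
#' dynamic programming, Watson-Crick plus G:U pairs, minimum hairpin loop
#' `min_hairpin_loop`). The check passes iff at least `hairpin_min_paired`
#' of the mature positions are paired and all their partners lie on one
#' side of the mature span (i.e. the mature sits in one arm of a
#' stem-loop; a mature straddling the loop apex fails).
#'
#' @param lncrna_seq full lncRNA sequence.
#' @param match_offset 1-based offset of the mature match.
#' @param mature_len mature miRNA length.
#' @param config a [run_config()].
#' @return A list: `hairpin_pass`, `paired_fraction`, `structure` (partner
#'   vector over the window, 0 = unpaired), `window_start`.
#' @export
hairpin_check <- function(lncrna_seq, match_offset, mature_len,
                          config = run_config()) {
  lncrna_seq <- canonicalize_seq(as.character(lncrna_seq))
  n <- nchar(lncrna_seq)
  ws <- max(1L, match_offset - config$hairpin_flank)
  we <- min(n, match_offset + mature_len - 1L + config$hairpin_flank)
  window <- substr(lncrna_seq, ws, we)
  fold <- cpp_nussinov(window, config$min_hairpin_loop)
  partner <- fold$partner
  ms <- match_offset - ws + 1L           # mature span in window coords
  me <- ms + mature_len - 1L
  partners <- partner[ms:me]
  paired <- partners > 0
  frac <- mean(paired)
  one_arm <- if (!any(paired)) FALSE else {
    p <- partners[paired]
    all(p > me) || all(p < ms)
  }
  list(hairpin_pass = frac >= config$hairpin_min_paired && one_arm,
       paired_fraction = frac,
       structure = partner,
       window_start = ws)
}
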