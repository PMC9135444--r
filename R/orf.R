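# Coding-potential stand-in: two independent scores combined with the same
# conjunction logic as the original two-classifier screen (a transcript is a
# lncRNA candidate only when BOTH scores fall below their thresholds).
#   orf score      -- monotone in longest-ORF length and ORF coverage
#   hexamer score  -- in-frame log-odds of a codon-usage hexamer model
#                     against a uniform background

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Position-specific base weights of the codon-usage model (GC-biased third
# position, as in plant coding sequence). Shared by the score and by the
# synthetic generator, which samples CDS codons from the same model.
codon_position_weights <- function() {
  list(c(A = 0.20, C = 0.30, G = 0.35, T = 0.15),
       c(A = 0.25, C = 0.30, G = 0.30, T = 0.15),
       c(A = 0.10, C = 0.35, G = 0.40, T = 0.15))
}

# Probability of each of the 64 codons under the product model.
codon_probs <- function() {
  w <- codon_position_weights()
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  p <- w[[1]][grid$b1] * w[[2]][grid$b2] * w[[3]][grid$b3]
  stats::setNames(as.numeric(p), paste0(grid$b1, grid$b2, grid$b3))
}

# Sense-codon distribution used when sampling synthetic CDS.
sense_codon_probs <- function() {
  p <- codon_probs()
  p <- p[!(names(p) %in% STOP_CODONS)]
  p / sum(p)
}

# log2 odds per hexamer (two adjacent in-frame codons) vs uniform 1/4096.
hexamer_log_odds <- function(hexamers) {
  cp <- codon_probs()
  c1 <- substr(hexamers, 1, 3)
  c2 <- substr(hexamers, 4, 6)
  lo <- log2(cp[c1] * cp[c2] * 4096)
  lo[is.na(lo)] <- 0  # hexamers containing N contribute nothing
  unname(lo)
}

#' Scan a transcript for open reading frames
#'
#' Scans the three forward frames. An ORF starts at ATG and runs to the
#' first in-frame stop (the stop codon is counted) or, when no in-frame
#' stop exists, is truncated at the transcript end. ATGs inside an already
#' open ORF of the same frame do not open nested ORFs. A transcript with no
#' ATG reports a longest ORF of length 0.
#'
#' @param seq nucleotide string (T and U equivalent).
#' @return A list with `orfs` (data.frame `start`, `end`, `frame`,
#'   `length_codons` in transcript coordinates) and `longest_nt`
#'   (nt length of the longest ORF, 0 if none).
#' @export
find_orfs <- function(seq) {
  seq <- canonicalize_seq(as.character(seq))
  if (nchar(seq) == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", seq))
    stop("non-nucleotide characters in sequence")
  n <- nchar(seq)
  rows <- list()
  for (f in 0:2) {
    if (n - f < 3) next
    starts <- seq.int(1 + f, n - 2, by = 3)
    cods <- substring(seq, starts, starts + 2)
    open <- NA_integer_
    for (k in seq_along(cods)) {
      if (is.na(open)) {
        if (cods[k] == "ATG") open <- k
      } else if (cods[k] %in% STOP_CODONS) {
        rows[[length(rows) + 1]] <- c(starts[open], starts[k] + 2, f,
                                      k - open + 1)
        open <- NA_integer_
      }
    }
    if (!is.na(open)) {
      k <- length(cods)
      rows[[length(rows) + 1]] <- c(starts[open], starts[k] + 2, f,
                                    k - open + 1)
    }
  }
  if (length(rows) == 0) {
    orfs <- data.frame(start = integer(), end = integer(),
                       frame = integer(), length_codons = integer())
  } else {
    m <- do.call(rbind, rows)
    orfs <- data.frame(start = m[, 1], end = m[, 2], frame = m[, 3],
                       length_codons = m[, 4])
    orfs <- orfs[order(-orfs$length_codons, orfs$start), , drop = FALSE]
    rownames(orfs) <- NULL
  }
  list(orfs = orfs,
       longest_nt = if (nrow(orfs)) max(orfs$length_codons) * 3L else 0L)
}

#' Coding-potential scores for one transcript
#'
#' `orf_score` increases with both the longest ORF's length and the
#' fraction of the transcript it covers; `hexamer_score` is the mean
#' in-frame hexamer log2-odds (codon-usage model vs uniform) over the
#' longest ORF (over the whole sequence in frame 1 when no ORF exists;
#' defined as 0 for sequences shorter than 6 nt). A transcript is called
#' coding unless both scores are strictly below their thresholds.
#'
#' @param seq nucleotide string.
#' @param orfs optional result of [find_orfs()] (recomputed if missing).
#' @param config a [run_config()]; supplies `coding_score_thresholds`.
#' @return A list with `orf_score`, `hexamer_score`, `longest_orf_nt`,
#'   `orf_coverage`, `is_coding`.
#' @export
coding_potential <- function(seq, orfs = NULL, config = run_config()) {
  seq <- canonicalize_seq(as.character(seq))
  if (is.null(orfs)) orfs <- find_orfs(seq)
  len <- nchar(seq)
  orf_nt <- orfs$longest_nt
  orf_cov <- orf_nt / len
  orf_score <- 4 * (orf_cov - 0.5) + 2 * log2((orf_nt + 1) / 300)
  if (len < 6) {
    hex_score <- 0
  } else {
    if (orf_nt >= 6) {
      top <- orfs$orfs[1, ]
      region <- substr(seq, top$start, top$end)
    } else {
      region <- seq
    }
    hs <- seq.int(1, nchar(region) - 5, by = 3)
    hex_score <- mean(hexamer_log_odds(substring(region, hs, hs + 5)))
  }
  th <- config$coding_score_thresholds
  list(orf_score = orf_score,
       hexamer_score = hex_score,
       longest_orf_nt = orf_nt,
       orf_coverage = orf_cov,
       is_coding = !(orf_score < th[1] && hex_score < th[2]))
}

#' Coding-potential table for a set of sequences
#' @param seqs named character vector or `DNAStringSet`.
#' @param config a [run_config()].
#' @return data.frame with one row per sequence.
#' @export
coding_potential_table <- function(seqs, config = run_config()) {
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs))) stop("sequences must be named")
  out <- lapply(seqs, coding_potential, config = config)
  data.frame(transcript_id = names(seqs),
             orf_score = vapply(out, `[[`, numeric(1), "orf_score"),
             hexamer_score = vapply(out, `[[`, numeric(1), "hexamer_score"),
             longest_orf_nt = vapply(out, function(o)
               as.integer(o$longest_orf_nt), integer(1)),
             orf_coverage = vapply(out, `[[`, numeric(1), "orf_coverage"),
             is_coding = vapply(out, `[[`, logical(1), "is_coding"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Calibrate coding-score thresholds on labelled sequence sets
#'
#' Sets each threshold at the midpoint between the class means of the
#' corresponding score, computed on user-supplied (e.g. simulated) coding
#' and non-coding sequences.
#'
#' @param coding_seqs,noncoding_seqs named character vectors/`DNAStringSet`s.
#' @param config a [run_config()] to update.
#' @return The config with `coding_score_thresholds` replaced.
#' @export
calibrate_coding_thresholds <- function(coding_seqs, noncoding_seqs,
                                        config = run_config()) {
  a <- coding_potential_table(coding_seqs, config)
  b <- coding_potential_table(noncoding_seqs, config)
  config$coding_score_thresholds <- c(
    orf = (mean(a$orf_score) + mean(b$orf_score)) / 2,
    hexamer = (mean(a$hexamer_score) + mean(b$hexamer_score)) / 2)
  config
}
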