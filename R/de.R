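#' FPKM from fragment counts
#'
#' FPKM = fragments x 1e9 / (spliced length in nt x total mapped fragments
#' in the sample). Linear in fragments, inverse-linear in length and in the
#' library total.
#'
#' @param fragments integer matrix, transcripts x samples.
#' @param spliced_lengths_nt named vector of transcript lengths (nt).
#' @param library_totals per-sample total mapped fragments (recycled if
#'   length 1).
#' @param design design data.frame (see [expr_matrix()]).
#' @return An [expr_matrix] of FPKM values.
#' @export
compute_fpkm <- function(fragments, spliced_lengths_nt, library_totals,
                         design) {
  fragments <- as.matrix(fragments)
  if (any(library_totals <= 0)) stop("zero or negative library total")
  lens <- spliced_lengths_nt[rownames(fragments)]
  if (anyNA(lens)) stop("missing spliced length for some transcripts")
  if (any(lens <= 0)) stop("non-positive spliced length")
  totals <- rep(library_totals, length.out = ncol(fragments))
  fpkm <- sweep(fragments * 1e9 / as.numeric(lens), 2, totals, "/")
  expr_matrix(fpkm, design)
}

cols_for_condition <- function(x, condition) {
  idx <- which(x$design$condition == condition)
  if (length(idx) == 0) stop("condition not present: ", condition)
  idx
}

#' Per-transcript log2 fold change between two conditions
#'
#' `log2((mean FPKM treatment + pseudocount) / (mean FPKM control +
#' pseudocount))`; swapping the two conditions negates the result exactly.
#'
#' @param x an [expr_matrix] of FPKM.
#' @param treatment,control condition labels.
#' @param pseudocount added to both means before the ratio.
#' @return Named numeric vector.
#' @export
log2_fold_change <- function(x, treatment, control, pseudocount = 0.1) {
  ti <- cols_for_condition(x, treatment)
  ci <- cols_for_condition(x, control)
  mt <- rowMeans(x$values[, ti, drop = FALSE])
  mc <- rowMeans(x$values[, ci, drop = FALSE])
  log2((mt + pseudocount) / (mc + pseudocount))
}

#' Two-sample test for differential expression
#'
#' Two-sample t-test on log2(FPKM + pseudocount), computed per transcript
#' (vectorized). The default is the pooled-variance (Student) test, which
#' holds its nominal type-I error at the very small replicate numbers
#' typical of this design (n = 3 per condition); `var_equal = FALSE`
#' switches to Welch's unequal-variance form, which is conservative at
#' these sizes. Transcripts with zero variance in both groups get p = 1
#' when the group means are equal and p = 0 otherwise.
#'
#' @param x an [expr_matrix].
#' @param treatment,control condition labels (each needs >= 2 replicates).
#' @param pseudocount added before the log2 transform.
#' @param var_equal pool the group variances (default) or use Welch's
#'   approximation.
#' @return Named numeric vector of p-values in \[0, 1\].
#' @export
de_test <- function(x, treatment, control, pseudocount = 0.1,
                    var_equal = TRUE) {
  ti <- cols_for_condition(x, treatment)
  ci <- cols_for_condition(x, control)
  if (length(ti) < 2 || length(ci) < 2)
    stop("each group needs at least 2 replicates")
  a <- log2(x$values[, ti, drop = FALSE] + pseudocount)
  b <- log2(x$values[, ci, drop = FALSE] + pseudocount)
  t_rows(a, b, var_equal)
}

# Vectorized two-sample t-test over matrix rows (cross-checked against
# t.test in the unit suite).
t_rows <- function(a, b, var_equal = TRUE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
  } else {
    se2 <- v1 / n1 + v2 / n2
  }
  p <- rep(NA_real_, nrow(a))
  degenerate <- se2 == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  ok <- !degenerate
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- if (var_equal) n1 + n2 - 2 else
    se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  stats::setNames(p, rownames(a))
}

#' Call differential expression with fixed screening thresholds
#'
#' A transcript is significant iff p < `de_p_cutoff` AND |log2FC| >
#' `de_lfc_cutoff`, both strict (so |log2FC| = 1 exactly, or p = 0.05
#' exactly, is not significant under the defaults). Direction is `up` when
#' log2FC > 0, `down` when < 0, `none` for non-significant transcripts. An
#' optional Benjamini-Hochberg FDR column is emitted for reference; it does
#' not enter the call.
#'
#' @param log2fc named vector from [log2_fold_change()].
#' @param p named vector from [de_test()] (same order).
#' @param config a [run_config()].
#' @param contrast label recorded in the result.
#' @return A `de_result` data.frame: `transcript_id`, `contrast`, `log2fc`,
#'   `p_value`, `fdr`, `significant`, `direction`.
#' @export
call_de <- function(log2fc, p, config = run_config(), contrast = NA_character_) {
  stopifnot(length(log2fc) == length(p),
            all(is.finite(log2fc)), all(p >= 0 & p <= 1))
  sig <- p < config$de_p_cutoff & abs(log2fc) > config$de_lfc_cutoff
  dir <- ifelse(!sig, "none", ifelse(log2fc > 0, "up", "down"))
  out <- data.frame(transcript_id = names(log2fc), contrast = contrast,
                    log2fc = unname(log2fc), p_value = unname(p),
                    fdr = unname(stats::p.adjust(p, method = "BH")),
                    significant = unname(sig), direction = unname(dir),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Differential expression for one contrast
#'
#' Convenience wrapper: fold change, test and call in one step.
#' @param x an [expr_matrix] of FPKM.
#' @param treatment,control condition labels.
#' @param config a [run_config()].
#' @return A `de_result` data.frame (see [call_de()]).
#' @export
differential_expression <- function(x, treatment, control,
                                    config = run_config()) {
  lfc <- log2_fold_change(x, treatment, control, config$pseudocount)
  p <- de_test(x, treatment, control, config$pseudocount)
  call_de(lfc, p, config, contrast = paste0(treatment, "_vs_", control))
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control`;
#' the returned fold change is `2^-ddCt`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (vectors recycle).
#' @return Fold change(s).
#' @export
ddct_relative_expression <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  stopifnot(all(is.finite(c(ct_target_treated, ct_ref_treated,
                            ct_target_control, ct_ref_control))))
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
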