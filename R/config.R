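#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults reproduce the screening rules used throughout the package:
#' transcripts shorter than 200 nt or with assembly read-coverage below 0.5
#' are dropped; a transcript is a long non-coding candidate only when both
#' coding-potential scores fall below their thresholds (ORF score < -1 and
#' hexamer score < 0); cis targets are genes within 100 kb; trans targets
#' require duplex free energy strictly below -50; miRNA target and
#' target-mimic sites require a penalty score of at most 2.5; differential
#' expression requires p < 0.05 and |log2 fold change| > 1.
#'
#' @param min_length_nt minimum spliced transcript length (nt) retained.
#' @param min_coverage minimum assembly coverage fraction retained.
#' @param coding_score_thresholds numeric length-2 `c(orf, hexamer)`;
#'   a transcript is non-coding iff both scores are strictly below these.
#' @param cis_window_nt maximum genomic gap (nt, inclusive) for cis pairing.
#' @param trans_energy_cutoff duplex energy must be strictly below this.
#' @param target_score_cutoff maximum (inclusive) miRNA target-site penalty.
#' @param de_p_cutoff,de_lfc_cutoff strict significance cutoffs for
#'   differential expression calls.
#' @param pseudocount added to FPKM before any log2.
#' @param strict_zone integer length-2: first/last miRNA position (from the
#'   5' end) of the strict matching zone.
#' @param mismatch_penalty,gu_penalty named numeric `c(strict=, nonstrict=)`
#'   penalties for mismatch/gap and G:U wobble respectively.
#' @param max_gaps maximum gaps ("missing"/bulged positions) per site.
#' @param hairpin_flank nt of flank on each side of a mature match folded
#'   when checking for a precursor stem-loop.
#' @param hairpin_min_paired minimum fraction of mature positions paired.
#' @param min_hairpin_loop minimum hairpin loop size for base pairing.
#' @param loop_open,loop_ext,max_loop affine interior-loop cost and maximum
#'   unpaired bases per loop in the duplex energy model.
#' @param bidirectional_window nt between divergent transcription starts for
#'   the bidirectional lncRNA class.
#' @param apply_coverage_filter set `FALSE` to disable the coverage filter
#'   (transcripts with unknown coverage then pass).
#' @param rng_seed optional integer recorded in output provenance headers.
#' @return An object of class `cerna_config` (a validated named list).
#' @export
run_config <- function(min_length_nt = 200,
                       min_coverage = 0.5,
                       coding_score_thresholds = c(orf = -1, hexamer = 0),
                       cis_window_nt = 100000L,
                       trans_energy_cutoff = -50,
                       target_score_cutoff = 2.5,
                       de_p_cutoff = 0.05,
                       de_lfc_cutoff = 1.0,
                       pseudocount = 0.1,
                       strict_zone = c(2L, 13L),
                       mismatch_penalty = c(strict = 1.0, nonstrict = 0.5),
                       gu_penalty = c(strict = 0.5, nonstrict = 0.25),
                       max_gaps = 2L,
                       hairpin_flank = 150L,
                       hairpin_min_paired = 0.6,
                       min_hairpin_loop = 3L,
                       loop_open = 3.0,
                       loop_ext = 0.5,
                       max_loop = 8L,
                       bidirectional_window = 1000L,
                       apply_coverage_filter = TRUE,
                       rng_seed = NULL) {
  cfg <- list(
    min_length_nt = as.integer(min_length_nt),
    min_coverage = as.numeric(min_coverage),
    coding_score_thresholds = as.numeric(coding_score_thresholds),
    cis_window_nt = as.integer(cis_window_nt),
    trans_energy_cutoff = as.numeric(trans_energy_cutoff),
    target_score_cutoff = as.numeric(target_score_cutoff),
    de_p_cutoff = as.numeric(de_p_cutoff),
    de_lfc_cutoff = as.numeric(de_lfc_cutoff),
    pseudocount = as.numeric(pseudocount),
    strict_zone = as.integer(strict_zone),
    mismatch_penalty = mismatch_penalty,
    gu_penalty = gu_penalty,
    max_gaps = as.integer(max_gaps),
    hairpin_flank = as.integer(hairpin_flank),
    hairpin_min_paired = as.numeric(hairpin_min_paired),
    min_hairpin_loop = as.integer(min_hairpin_loop),
    loop_open = as.numeric(loop_open),
    loop_ext = as.numeric(loop_ext),
    max_loop = as.integer(max_loop),
    bidirectional_window = as.integer(bidirectional_window),
    apply_coverage_filter = isTRUE(apply_coverage_filter),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  stopifnot(
    length(cfg$coding_score_thresholds) == 2,
    length(cfg$strict_zone) == 2, cfg$strict_zone[1] >= 1,
    cfg$strict_zone[2] >= cfg$strict_zone[1],
    cfg$cis_window_nt >= 0, cfg$min_length_nt >= 0,
    cfg$pseudocount >= 0, cfg$max_gaps >= 0,
    all(is.finite(unlist(cfg[c("min_coverage", "trans_energy_cutoff",
                               "target_score_cutoff", "de_p_cutoff",
                               "de_lfc_cutoff")])))
  )
  class(cfg) <- "cerna_config"
  cfg
}

#' @export
print.cerna_config <- function(x, ...) {
  cat("ceRNA pipeline configuration\n")
  cat(sprintf("  filter: length >= %d nt, coverage >= %.2f (%s)\n",
              x$min_length_nt, x$min_coverage,
              if (x$apply_coverage_filter) "enabled" else "disabled"))
  cat(sprintf("  coding: non-coding iff orf < %g and hexamer < %g\n",
              x$coding_score_thresholds[1], x$coding_score_thresholds[2]))
  cat(sprintf("  cis window %d nt | trans energy < %g | site score <= %g\n",
              x$cis_window_nt, x$trans_energy_cutoff, x$target_score_cutoff))
  cat(sprintf("  DE: p < %g and |log2FC| > %g (pseudocount %g)\n",
              x$de_p_cutoff, x$de_lfc_cutoff, x$pseudocount))
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Any field of [run_config()] may appear in the file; missing fields keep
#' their defaults.
#' @param path YAML file.
#' @return A `cerna_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# Short hash of a configuration, used in provenance headers.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(config), file = f)
  substr(unname(tools::md5sum(f)), 1, 12)
}

# Provenance line written at the top of every tabular output.
provenance_line <- function(config, seed = config$rng_seed) {
  sprintf("# cernapipe %s | config %s | seed %s",
          as.character(utils::packageVersion("cernapipe")),
          config_hash(config),
          if (is.null(seed)) "NA" else as.character(seed))
}

write_tsv_with_header <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(provenance_line(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_skip_header <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
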