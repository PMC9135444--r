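#' Assemble ceRNA triples under the concordance conditions
#'
#' A triple (lncRNA L, miRNA m, mRNA M) is emitted iff (1) L carries an eTM
#' site for m and M carries a target site for m, (2) both L and M are
#' significantly differentially expressed in the contrast, and (3) their
#' fold-change directions agree (both up or both down). Duplicates are
#' collapsed; output is sorted by (lncRNA, miRNA, mRNA). Triples are
#' contrast-specific: the same interaction may appear for several
#' contrasts, each carrying its own direction evidence.
#'
#' @param etm_hits data.frame from [predict_etms()] (miRNA sites on lncRNAs).
#' @param target_hits data.frame from [predict_targets()] (sites on mRNAs).
#' @param de_lnc,de_mrna `de_result` data.frames for lncRNAs and mRNAs.
#' @param contrast contrast label; must match the `contrast` column of the
#'   DE tables (ignored rows are dropped).
#' @return data.frame `lncrna_id`, `mirna_id`, `mrna_id`, `contrast`,
#'   `lnc_direction`, `mrna_direction`, `etm_score`, `target_score`.
#' @export
build_cerna_network <- function(etm_hits, target_hits, de_lnc, de_mrna,
                                contrast) {
  empty <- data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character(), contrast = character(),
                      lnc_direction = character(),
                      mrna_direction = character(),
                      etm_score = numeric(), target_score = numeric())
  de_lnc <- de_lnc[de_lnc$contrast == contrast & de_lnc$significant, ,
                   drop = FALSE]
  de_mrna <- de_mrna[de_mrna$contrast == contrast & de_mrna$significant, ,
                     drop = FALSE]
  if (nrow(etm_hits) == 0 || nrow(target_hits) == 0 ||
      nrow(de_lnc) == 0 || nrow(de_mrna) == 0) return(empty)
  lnc_dir <- stats::setNames(de_lnc$direction, de_lnc$transcript_id)
  mrna_dir <- stats::setNames(de_mrna$direction, de_mrna$transcript_id)
  e <- etm_hits[etm_hits$rna_id %in% names(lnc_dir), , drop = FALSE]
  t <- target_hits[target_hits$rna_id %in% names(mrna_dir), , drop = FALSE]
  if (nrow(e) == 0 || nrow(t) == 0) return(empty)
  m <- merge(
    data.frame(mirna_id = e$mirna_id, lncrna_id = e$rna_id,
               etm_score = e$score, stringsAsFactors = FALSE),
    data.frame(mirna_id = t$mirna_id, mrna_id = t$rna_id,
               target_score = t$score, stringsAsFactors = FALSE),
    by = "mirna_id")
  if (nrow(m) == 0) return(empty)
  m$lnc_direction <- unname(lnc_dir[m$lncrna_id])
  m$mrna_direction <- unname(mrna_dir[m$mrna_id])
  m <- m[m$lnc_direction == m$mrna_direction, , drop = FALSE]
  if (nrow(m) == 0) return(empty)
  m$contrast <- contrast
  m <- m[!duplicated(m[, c("lncrna_id", "mirna_id", "mrna_id")]), ,
         drop = FALSE]
  m <- m[order(m$lncrna_id, m$mirna_id, m$mrna_id),
         c("lncrna_id", "mirna_id", "mrna_id", "contrast",
           "lnc_direction", "mrna_direction", "etm_score", "target_score")]
  rownames(m) <- NULL
  m
}

#' Rank hub lncRNAs by degree
#'
#' Degree of a lncRNA = number of distinct miRNA and mRNA neighbours in the
#' triple set. Ties break lexicographically by id; the ranking is
#' deterministic.
#'
#' @param triples data.frame from [build_cerna_network()].
#' @param top_k number of top lncRNAs to return (default all).
#' @return data.frame `lncrna_id`, `degree`, sorted by decreasing degree.
#' @export
hub_nodes <- function(triples, top_k = Inf) {
  if (nrow(triples) == 0)
    return(data.frame(lncrna_id = character(), degree = integer()))
  deg <- vapply(split(triples, triples$lncrna_id), function(d)
    length(unique(c(d$mirna_id, d$mrna_id))), integer(1))
  out <- data.frame(lncrna_id = names(deg), degree = unname(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$lncrna_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value per term with Benjamini-Hochberg FDR
#' across the tested terms; terms with zero overlap are omitted.
#'
#' @param foreground character vector of gene ids (must be a subset of
#'   `background`).
#' @param background character vector (the gene universe).
#' @param term_map named list term -> character vector of gene ids, or a
#'   two-column data.frame (`term`, `gene`).
#' @return data.frame `term_id`, `overlap`, `foreground_size`,
#'   `background_size`, `term_size`, `p_value`, `fdr`, sorted by p-value.
#' @export
enrich_terms <- function(foreground, background, term_map) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground contains ids absent from the background: ",
         paste(utils::head(setdiff(foreground, background), 5),
               collapse = ", "))
  if (is.data.frame(term_map))
    term_map <- split(as.character(term_map[[2]]),
                      as.character(term_map[[1]]))
  rows <- lapply(names(term_map), function(tm) {
    genes <- intersect(unique(term_map[[tm]]), background)
    k <- length(intersect(genes, foreground))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, length(genes),
                       length(background) - length(genes),
                       length(foreground), lower.tail = FALSE)
    data.frame(term_id = tm, overlap = k,
               foreground_size = length(foreground),
               background_size = length(background),
               term_size = length(genes), p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(term_id = character(), overlap = integer(),
                      foreground_size = integer(),
                      background_size = integer(), term_size = integer(),
                      p_value = numeric(), fdr = numeric()))
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node and edge counts of a ceRNA network
#'
#' @param triples data.frame from [build_cerna_network()] (one or several
#'   contrasts pooled).
#' @return A list: `n_lncrna`, `n_mirna`, `n_mrna`, `n_edges` (unique
#'   lncRNA-miRNA plus miRNA-mRNA node pairs), `n_triples`.
#' @export
summarize_network <- function(triples) {
  edges <- unique(rbind(
    data.frame(a = triples$lncrna_id, b = triples$mirna_id),
    data.frame(a = triples$mirna_id, b = triples$mrna_id)))
  list(n_lncrna = length(unique(triples$lncrna_id)),
       n_mirna = length(unique(triples$mirna_id)),
       n_mrna = length(unique(triples$mrna_id)),
       n_edges = nrow(edges),
       n_triples = nrow(unique(triples[, c("lncrna_id", "mirna_id",
                                           "mrna_id")])))
}
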