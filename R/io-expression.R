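#' Expression matrix with experimental design
#'
#' @param values numeric matrix, transcripts x samples, non-negative
#'   (FPKM or fragment counts).
#' @param design data.frame with columns `sample`, `condition`, `replicate`;
#'   one row per column of `values`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, design) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (any(values < 0)) stop("negative expression values are not allowed")
  if (is.null(rownames(values))) stop("values must have transcript rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated transcript id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  stopifnot(is.data.frame(design),
            all(c("sample", "condition", "replicate") %in% names(design)))
  if (is.null(colnames(values))) colnames(values) <- design$sample
  missing <- setdiff(colnames(values), design$sample)
  if (length(missing) > 0)
    stop("sample(s) without a design label: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  reps <- table(design$condition)
  if (any(reps < 2))
    warning("condition(s) with fewer than 2 replicates: ",
            paste(names(reps)[reps < 2], collapse = ", "))
  structure(list(values = values, design = design), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s x%d", names(table(x$design$condition)),
                            as.integer(table(x$design$condition))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression table with its design sidecar
#'
#' The expression file is TSV: first column transcript id, remaining columns
#' one per sample. The design file is TSV with columns `sample`,
#' `condition`, `replicate`. Lines starting with `#` are ignored.
#'
#' @param path expression TSV.
#' @param design_path design TSV.
#' @return An [expr_matrix].
#' @export
read_expression_table <- function(path, design_path) {
  raw <- read_tsv_skip_header(path, check.names = FALSE)
  if (ncol(raw) < 2) stop("expression table needs id plus sample columns")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicated transcript id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                   path, if (length(bad)) bad[1] else NA_integer_,
                   names(vals)[j]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  design <- read_tsv_skip_header(design_path)
  expr_matrix(m, design)
}

#' Write an expression matrix (and design) to TSV
#' @param x an [expr_matrix].
#' @param path expression TSV path.
#' @param design_path design TSV path (default: `<path>` with `.design.tsv`).
#' @param config optional `cerna_config` for the provenance header.
#' @export
write_expression_table <- function(x, path,
                                   design_path = sub("\\.tsv$", ".design.tsv", path),
                                   config = NULL) {
  df <- data.frame(transcript_id = rownames(x$values),
                   x$values, check.names = FALSE)
  write_tsv_with_header(df, path, config)
  write_tsv_with_header(x$design, design_path, config)
  invisible(path)
}

#' Write a ceRNA network as edge and node tables
#'
#' Produces `<prefix>_edges.tsv` (columns `source`, `target`, `edge_type`
#' with types `lncRNA-miRNA` and `miRNA-mRNA`) and `<prefix>_nodes.tsv`
#' (columns `node`, `node_type`, `de_direction`), loadable by any generic
#' graph viewer.
#'
#' @param triples data.frame of ceRNA triples
#'   (see [build_cerna_network()]); may be empty.
#' @param prefix output path prefix.
#' @param config optional `cerna_config` for provenance headers.
#' @return Invisibly, the two file paths.
#' @export
write_network <- function(triples, prefix, config = NULL) {
  if (nrow(triples) > 0) {
    edges <- unique(rbind(
      data.frame(source = triples$lncrna_id, target = triples$mirna_id,
                 edge_type = "lncRNA-miRNA", stringsAsFactors = FALSE),
      data.frame(source = triples$mirna_id, target = triples$mrna_id,
                 edge_type = "miRNA-mRNA", stringsAsFactors = FALSE)))
    nodes <- unique(rbind(
      data.frame(node = triples$lncrna_id, node_type = "lncRNA",
                 de_direction = triples$lnc_direction,
                 stringsAsFactors = FALSE),
      data.frame(node = triples$mirna_id, node_type = "miRNA",
                 de_direction = NA_character_, stringsAsFactors = FALSE),
      data.frame(node = triples$mrna_id, node_type = "mRNA",
                 de_direction = triples$mrna_direction,
                 stringsAsFactors = FALSE)))
    nodes <- nodes[!duplicated(nodes$node), , drop = FALSE]
    edges <- edges[order(edges$edge_type, edges$source, edges$target), ]
    nodes <- nodes[order(nodes$node_type, nodes$node), ]
  } else {
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character())
    nodes <- data.frame(node = character(), node_type = character(),
                        de_direction = character())
  }
  ef <- paste0(prefix, "_edges.tsv")
  nf <- paste0(prefix, "_nodes.tsv")
  write_tsv_with_header(edges, ef, config)
  write_tsv_with_header(nodes, nf, config)
  invisible(c(edges = ef, nodes = nf))
}
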