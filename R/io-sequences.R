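#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and canonicalized to the DNA alphabet (U -> T);
#' T and U are treated as equivalent by all pairing logic, so mature miRNAs
#' supplied as RNA and genomic sequence supplied as DNA interoperate.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id (first token of
#'   each header); full headers kept in `mcols(x)$description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) return(Biostrings::DNAStringSet())
  headers <- names(raw)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1)
  if (anyNA(ids) || any(ids == ""))
    stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0))
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0], collapse = ", "))
  seqs <- canonicalize_seq(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- headers
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# Uppercase and map U -> T (internal canonical alphabet is DNA).
canonicalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Reverse complement for plain character vectors (DNA alphabet).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract the spliced sequence of each transcript from chromosome sequences.
# `exons` is a GRangesList named by transcript id; minus-strand transcripts
# are reverse-complemented and exons read in transcription order.
spliced_sequences <- function(genome, exons) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  out <- vapply(seq_along(exons), function(k) {
    ex <- exons[[k]]
    ex <- ex[order(GenomicRanges::start(ex))]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    pieces <- substring(as.character(genome[[chrom]]),
                        GenomicRanges::start(ex), GenomicRanges::end(ex))
    s <- paste(pieces, collapse = "")
    if (as.character(GenomicRanges::strand(ex))[1] == "-") s <- revcomp(s)
    s
  }, character(1))
  names(out) <- names(exons)
  Biostrings::DNAStringSet(out)
}
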