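# Readers and writers for the pipeline's plain-text formats.

#' Read / write the long expression table
#'
#' Tab-separated with columns gene_id, tissue, day, fpkm, fpkm_sd (a
#' reference_gene_id column is carried through when present).
#'
#' @param path file path.
#' @param x expression data frame.
#' @return \code{read_expression} returns the data frame.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("gene_id", "tissue", "day", "fpkm", "fpkm_sd"),
              "expression table")
  df
}

#' @rdname read_expression
#' @export
write_expression <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tabular sequence-similarity hit table
#'
#' Accepts either the pipeline's 5-column layout (query, subject, pident,
#' bitscore, evalue) or a full 12-column tabular BLAST (outfmt 6) file
#' without header, from which the needed columns are extracted.
#'
#' @param path file path.
#' @return data frame with columns query, subject, pident, bitscore, evalue.
#' @export
read_hit_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("query", first, fixed = TRUE)) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    assert_cols(df, c("query", "subject", "bitscore", "evalue"), "hit table")
    if (is.null(df$pident)) df$pident <- NA_real_
    return(df[, c("query", "subject", "pident", "bitscore", "evalue")])
  }
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) == 12L) {
    # standard outfmt 6: qseqid sseqid pident length mismatch gapopen
    #                    qstart qend sstart send evalue bitscore
    data.frame(query = raw[[1]], subject = raw[[2]], pident = raw[[3]],
               bitscore = raw[[12]], evalue = raw[[11]],
               stringsAsFactors = FALSE)
  } else if (ncol(raw) >= 5L) {
    setNames(raw[, 1:5], c("query", "subject", "pident", "bitscore", "evalue"))
  } else {
    stop("unrecognized hit table layout: ", path)
  }
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Pivot the long expression table to per-tissue matrices
#'
#' @param expression long expression data frame.
#' @param tissue tissue to extract.
#' @return list with \code{x} (genes x timepoints FPKM matrix), \code{sd}
#'   (matching uncertainty matrix) and \code{days}.
#' @export
expression_matrix <- function(expression, tissue) {
  assert_cols(expression, c("gene_id", "tissue", "day", "fpkm", "fpkm_sd"))
  df <- expression[expression$tissue == tissue, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows for tissue: ", tissue)
  days <- sort(unique(df$day))
  genes <- unique(df$gene_id)
  x <- matrix(NA_real_, length(genes), length(days),
              dimnames = list(genes, days))
  s <- x
  idx <- cbind(match(df$gene_id, genes), match(df$day, days))
  x[idx] <- df$fpkm
  s[idx] <- df$fpkm_sd
  if (anyNA(x)) stop("expression table is not a complete gene x day grid")
  list(x = x, sd = s, days = days)
}
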