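# AlignmentMatrix: a gap-aware multiple sequence alignment held as a
# character matrix (rows = sequences, columns = alignment positions) over
# {A,C,G,T,N,-}. Built from FASTA via Biostrings; kept as plain characters
# because every downstream statistic is a per-column count.

#' Construct an alignment matrix
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (uppercase, `-` for gaps). Ambiguity codes other than N are mapped to N
#'   with a message.
#' @return an `alignment_matrix` object
#' @export
alignment_matrix <- function(seqs) {
  if (length(seqs) < 2) stop2("an alignment needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop2("sequences must have unique names")
  w <- nchar(seqs)
  if (length(unique(w)) != 1) {
    off <- names(seqs)[w != max(w)]
    stop2("unequal row lengths in alignment; offending rows: ",
          paste(off, collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bad <- !(mat %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) {
    message(sum(bad), " ambiguous character(s) mapped to N")
    mat[bad] <- "N"
  }
  structure(list(names = names(seqs), mat = mat), class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat("alignment_matrix: ", nrow(x$mat), " sequences x ", ncol(x$mat),
      " columns\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param aln an `alignment_matrix`
#' @return integer column count
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' Number of aligned sequences
#' @param aln an `alignment_matrix`
#' @return integer row count
#' @export
aln_nseq <- function(aln) nrow(aln$mat)

#' Remove gaps from one alignment row
#' @param aln an `alignment_matrix`
#' @param row row name or index
#' @return ungapped sequence string
#' @export
aln_ungap <- function(aln, row) {
  v <- aln$mat[row, ]
  chars_to_seq(v[v != "-"])
}

#' Read a FASTA multiple sequence alignment
#'
#' All records must have identical lengths (an aligned FASTA); ragged input
#' is a hard error naming the offending records.
#' @param path FASTA file
#' @return an `alignment_matrix`
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2) stop2("alignment in ", path, " has fewer than 2 sequences")
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  alignment_matrix(seqs)
}

#' Write an alignment (or plain sequences) as FASTA
#' @param x an `alignment_matrix` or a named character vector
#' @param path output file
#' @param width line wrap width
#' @return invisibly, `path`
#' @export
write_fasta <- function(x, path, width = 70) {
  seqs <- if (inherits(x, "alignment_matrix"))
    stats::setNames(apply(x$mat, 1, paste, collapse = ""), x$names) else x
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write records as a tab-separated table with a header line
#'
#' Numeric columns are rendered at a fixed significant precision so that
#' re-reading reproduces the records to the rendered precision.
#' @param df data frame of homogeneous rows
#' @param path output file
#' @param digits significant digits for numeric columns
#' @return invisibly, `path`
#' @export
write_table <- function(df, path, digits = 6) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop2("failed writing table to ", path, ": ",
                         conditionMessage(ok))
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path input file
#' @return data frame
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
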