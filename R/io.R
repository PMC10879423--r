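#' Read a unigene set from FASTA
#'
#' Reads a FASTA file into a named DNA set. Record ids are the first
#' whitespace-delimited token of each header and must be unique; empty
#' records are rejected.
#'
#' @param path path to a FASTA file.
#' @param set_label optional label describing the set (e.g. \code{"ccs"});
#'   stored as the \code{"set_label"} attribute.
#' @return a \code{Biostrings::DNAStringSet} with unique names.
#' @export
read_fasta <- function(path, set_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup)) stop("duplicate unigene ids in ", path, ": ", paste(dup, collapse = ", "))
  if (any(Biostrings::width(x) == 0L)) {
    bad <- names(x)[Biostrings::width(x) == 0L]
    stop("empty records in ", path, ": ", paste(bad, collapse = ", "))
  }
  if (!is.null(set_label)) attr(x, "set_label") <- set_label
  x
}

#' Write a unigene set to FASTA
#'
#' @param x named character vector or DNAStringSet.
#' @param path output path.
#' @param width line-wrap column (default 80).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  x <- as_seqs(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = width)
  invisible(path)
}

#' Read / write an expression table
#'
#' Expression tables are TSV files with a header row
#' \code{unigene_id<TAB>sample...}; rows are unigenes, columns samples.
#'
#' @param path a TSV path.
#' @return a numeric matrix with unigene rownames and sample colnames,
#'   carrying a \code{"mode"} attribute (\code{"counts"} or \code{"tpm"}).
#' @param mode value mode of the table.
#' @export
read_expression <- function(path, mode = c("counts", "tpm")) {
  mode <- match.arg(mode)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expression table needs an id column and >= 1 sample column")
  ids <- as.character(d[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate unigene ids: ", paste(dup, collapse = ", "))
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative expression values")
  rownames(m) <- ids
  attr(m, "mode") <- mode
  m
}

#' @rdname read_expression
#' @param x expression matrix.
#' @export
write_expression <- function(x, path) {
  d <- data.frame(unigene_id = rownames(x), x, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a simulation truth ledger
#'
#' The ledger has one row per emitted unigene with columns
#' \code{unigene_id, set_label, source_isoform, trunc5, trunc3, label,
#' parent1, parent2}.
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_ledger <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NONE")
}

#' @rdname read_ledger
#' @param ledger ledger data.frame (e.g. \code{truth$emissions}).
#' @export
write_ledger <- function(ledger, path) {
  cols <- c("unigene_id", "set_label", "source_isoform", "trunc5", "trunc3",
            "label", "parent1", "parent2")
  d <- ledger[, cols]
  for (ch in c("source_isoform", "parent1", "parent2")) {
    d[[ch]][is.na(d[[ch]])] <- "NONE"
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
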