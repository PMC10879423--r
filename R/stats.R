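#' Contig length and composition statistics
#'
#' Summary statistics of a unigene set in the style of assembly reports:
#' sequence count, maximum/mean/median length, N50 and GC content.
#'
#' N50 is the largest length L such that sequences of length >= L together
#' contain at least half of the summed bases (computed by descending
#' cumulative sum). The median of an even number of lengths is the lower
#' middle value, so all reported lengths are integers actually present in
#' the set. GC content is (G+C)/(A+C+G+T) * 100; N bases are excluded from
#' the denominator.
#'
#' @param x named character vector or DNAStringSet.
#' @return a list of class \code{"length_stats"} with fields \code{n},
#'   \code{max_len}, \code{mean_len}, \code{median_len}, \code{n50},
#'   \code{gc_ratio}.
#' @export
length_stats <- function(x) {
  x <- as_seqs(x)
  if (!length(x)) stop("empty unigene set")
  len <- unname(nchar(x))
  sorted <- sort(len, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1L]]
  freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x), c("A", "C", "G", "T"))
  tot <- colSums(freq)
  out <- list(
    n = length(x),
    max_len = max(len),
    mean_len = mean(len),
    median_len = lower_median(len),
    n50 = n50,
    gc_ratio = unname((tot[["G"]] + tot[["C"]]) / sum(tot) * 100)
  )
  class(out) <- "length_stats"
  out
}

## lower middle value for even n; deterministic integer output
lower_median <- function(len) {
  s <- sort(len)
  s[ceiling(length(s) / 2)]
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf("unigene set: n=%d  max=%d  mean=%.1f  median=%d  N50=%d  GC=%.2f%%\n",
              x$n, x$max_len, x$mean_len, x$median_len, x$n50, x$gc_ratio))
  invisible(x)
}

#' Transcripts-per-million normalisation
#'
#' Converts a counts matrix to TPM. Per column, \code{rate_i =
#' count_i / length_i} and \code{tpm_i = rate_i / sum(rate) * 1e6}, so every
#' non-degenerate column sums to one million. The effective length is the
#' full transcript length; no fragment-length correction is applied, which
#' keeps the transformation exactly reproducible from the counts table.
#'
#' @param counts numeric matrix of non-negative counts (rows = unigenes).
#' @param lengths named numeric vector of transcript lengths covering every
#'   row of \code{counts}.
#' @return TPM matrix with the \code{"mode"} attribute set to \code{"tpm"}.
#'   All-zero columns stay all-zero, with a warning.
#' @export
compute_tpm <- function(counts, lengths) {
  if (is.null(rownames(counts))) stop("counts matrix must have unigene rownames")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stop("no length for unigene(s): ", paste(head(missing, 10L), collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("non-positive transcript length")
  rate <- counts / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero column(s): ", paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  attr(tpm, "mode") <- "tpm"
  tpm
}
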