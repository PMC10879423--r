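#' Predict the coding region of a unigene
#'
#' Deterministic six-frame ORF scan (three forward frames and three on the
#' reverse complement). Among complete ORFs (ATG through stop with no
#' internal in-frame stop) of at least \code{min_aa} residues, the longest
#' is returned; ties are broken in favour of the + strand, then the smallest
#' forward-axis \code{cds_start}. Coordinates are always reported 0-based
#' half-open on the forward sequence. With \code{allow_partial}, ORFs
#' truncated by the sequence ends (missing the start or the stop codon) are
#' also eligible and flagged.
#'
#' @param seq a single DNA string over A/C/G/T/N.
#' @param min_aa minimum ORF length in residues (stop codon excluded).
#' @param allow_partial admit end-truncated ORFs, flagged \code{partial5}
#'   (no start codon) or \code{partial3} (no stop codon).
#' @return \code{NULL} if no qualifying ORF, else a list with
#'   \code{strand}, \code{cds_start}, \code{cds_end}, \code{aa_len} and
#'   \code{completeness}.
#' @export
predict_cds <- function(seq, min_aa = 100, allow_partial = FALSE) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters")
  cands <- rbind(orfs_one_strand(seq, "+", allow_partial),
                 orfs_one_strand(seq, "-", allow_partial))
  if (is.null(cands) || !nrow(cands)) return(NULL)
  cands <- cands[cands$aa_len >= min_aa, , drop = FALSE]
  if (!nrow(cands)) return(NULL)
  ## longest first; ties: + strand, then smallest forward cds_start
  cands <- cands[order(-cands$aa_len, cands$strand != "+", cands$cds_start), ,
                 drop = FALSE]
  as.list(cands[1L, ])
}

## all complete (and optionally partial) ORFs of one strand, coordinates
## mapped back to the forward axis
orfs_one_strand <- function(fwd, strand, allow_partial) {
  s <- if (strand == "+") fwd else revcomp(fwd)
  n <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    prev <- 0L
    for (si in stop_idx) {
      seg <- if (prev + 1L <= si - 1L) (prev + 1L):(si - 1L) else integer()
      a <- seg[is_atg[seg]][1L]
      if (!is.na(a)) {
        out[[length(out) + 1L]] <-
          orf_record(starts[a] - 1L, starts[si] + 2L, n, strand, "complete")
      }
      if (allow_partial && prev == 0L && si > 1L && !any(is_atg[seg])) {
        ## runs into the 5' end of this strand without a start codon
        out[[length(out) + 1L]] <-
          orf_record(starts[1L] - 1L, starts[si] + 2L, n, strand, "partial5")
      }
      prev <- si
    }
    if (allow_partial) {
      tail_seg <- if (prev + 1L <= length(codons)) (prev + 1L):length(codons) else integer()
      a <- tail_seg[is_atg[tail_seg]][1L]
      if (!is.na(a)) {
        out[[length(out) + 1L]] <-
          orf_record(starts[a] - 1L, starts[length(codons)] + 2L, n, strand, "partial3")
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

orf_record <- function(start0, end0, n, strand, completeness) {
  ## start0/end0: 0-based half-open on the scanned strand
  if (strand == "-") {
    tmp <- start0
    start0 <- n - end0
    end0 <- n - tmp
  }
  aa <- (end0 - start0) %/% 3L - (completeness != "partial3")
  data.frame(strand = strand, cds_start = start0, cds_end = end0,
             aa_len = aa, completeness = completeness,
             stringsAsFactors = FALSE)
}

#' Predict coding regions for a whole unigene set
#'
#' @param x named character vector or DNAStringSet.
#' @inheritParams predict_cds
#' @return data.frame with one row per unigene that has a qualifying ORF:
#'   \code{unigene_id, strand, cds_start, cds_end, aa_len, completeness}.
#' @export
predict_cds_set <- function(x, min_aa = 100, allow_partial = FALSE) {
  x <- as_seqs(x)
  rows <- lapply(names(x), function(id) {
    r <- predict_cds(x[[id]], min_aa = min_aa, allow_partial = allow_partial)
    if (is.null(r)) return(NULL)
    cbind(data.frame(unigene_id = id, stringsAsFactors = FALSE),
          as.data.frame(r, stringsAsFactors = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(unigene_id = character(), strand = character(),
                      cds_start = integer(), cds_end = integer(),
                      aa_len = integer(), completeness = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
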