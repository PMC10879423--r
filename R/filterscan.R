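#' Filter a unigene set by a TPM threshold
#'
#' A unigene survives when its TPM values aggregated across samples reach
#' the threshold. The default aggregation is the maximum across samples (a
#' unigene expressed at or above the threshold in any tissue survives);
#' \code{"any_sample"} is a synonym, \code{"mean"} averages instead. A
#' threshold of 0 keeps everything.
#'
#' @param x unigene set (ids taken from names) or a character vector of ids.
#' @param tpm TPM matrix covering all ids of \code{x}.
#' @param threshold TPM cutoff (>= comparison).
#' @param rule aggregation rule across samples.
#' @return character vector of surviving ids, in input order.
#' @export
filter_by_tpm <- function(x, tpm, threshold, rule = c("max", "any_sample", "mean")) {
  rule <- match.arg(rule)
  ids <- if (is.character(x) && is.null(names(x))) x else names(as_seqs(x))
  missing <- setdiff(ids, rownames(tpm))
  if (length(missing)) {
    stop("unigene(s) missing from the expression matrix: ",
         paste(head(missing, 10L), collapse = ", "))
  }
  m <- tpm[ids, , drop = FALSE]
  agg <- switch(rule,
                max = ,
                any_sample = apply(m, 1L, max),
                mean = rowMeans(m))
  ids[agg >= threshold]
}

#' Scan TPM thresholds for cross-set convergence
#'
#' Applies \code{\link{filter_by_tpm}} at each threshold to every set and
#' tabulates survivor counts and length statistics. The convergence score
#' of a threshold is the maximum over set pairs of the larger of the
#' relative survivor-count difference and the relative median-length
#' difference (both of the form |a-b| / max(a,b), hence symmetric in set
#' order). The selected threshold is the smallest scanned threshold whose
#' score is at most \code{tolerance}; scores are undefined (NA) where a set
#' is empty after filtering.
#'
#' @param sets named list of unigene sets.
#' @param tpm_tables named list of TPM matrices, one per set.
#' @param thresholds TPM cutoffs to scan, in increasing order.
#' @param tolerance maximum convergence score accepted.
#' @param rule aggregation rule, see \code{\link{filter_by_tpm}}.
#' @return object of class \code{"threshold_scan"}: list with \code{table}
#'   (one row per set x threshold), \code{scores}, \code{survivors}
#'   (nested list of surviving ids) and \code{selected_threshold}
#'   (NA when no threshold converges).
#' @export
threshold_scan <- function(sets, tpm_tables, thresholds = c(0, 1, 5, 10),
                           tolerance = 0.25, rule = "max") {
  stopifnot(is.list(sets), length(sets) >= 2L,
            all(names(sets) %in% names(tpm_tables)))
  thresholds <- sort(thresholds)
  rows <- list()
  survivors <- list()
  for (th in thresholds) {
    survivors[[as.character(th)]] <- list()
    for (s in names(sets)) {
      ids <- filter_by_tpm(sets[[s]], tpm_tables[[s]], th, rule = rule)
      survivors[[as.character(th)]][[s]] <- ids
      st <- if (length(ids)) length_stats(as_seqs(sets[[s]])[ids]) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        set_label = s, threshold = th, n = length(ids),
        mean_len = if (is.null(st)) NA_real_ else st$mean_len,
        median_len = if (is.null(st)) NA_integer_ else st$median_len,
        n50 = if (is.null(st)) NA_integer_ else st$n50,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  scores <- vapply(thresholds, function(th) {
    sub <- tab[tab$threshold == th, ]
    if (any(sub$n == 0L)) return(NA_real_)
    sc <- 0
    for (i in seq_len(nrow(sub) - 1L)) for (j in (i + 1L):nrow(sub)) {
      sc <- max(sc,
                abs(sub$n[i] - sub$n[j]) / max(sub$n[i], sub$n[j]),
                abs(sub$median_len[i] - sub$median_len[j]) /
                  max(sub$median_len[i], sub$median_len[j]))
    }
    sc
  }, numeric(1))
  ok <- which(!is.na(scores) & scores <= tolerance)
  structure(list(
    table = tab,
    scores = data.frame(threshold = thresholds, score = scores),
    survivors = survivors,
    selected_threshold = if (length(ok)) thresholds[min(ok)] else NA_real_,
    tolerance = tolerance, rule = rule
  ), class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("TPM threshold scan (rule:", x$rule, ")\n")
  print(x$table, row.names = FALSE)
  cat("convergence scores:\n")
  print(x$scores, row.names = FALSE)
  cat("selected threshold:",
      if (is.na(x$selected_threshold)) "none" else x$selected_threshold,
      sprintf("(tolerance %.2f)\n", x$tolerance))
  invisible(x)
}
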