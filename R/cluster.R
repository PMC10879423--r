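#' Z-score expression rows
#'
#' Centres and scales each row to mean 0 and sample standard deviation 1.
#' Rows without variance (including all-zero rows) cannot be scaled and are
#' dropped with a warning.
#'
#' @param m numeric matrix (unigenes x samples, >= 2 columns).
#' @return the scaled matrix, possibly with fewer rows.
#' @export
zscore_rows <- function(m) {
  if (ncol(m) < 2L) stop("need >= 2 samples to z-score")
  sds <- apply(m, 1L, sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning(sum(drop), " constant row(s) dropped: ",
            paste(head(rownames(m)[drop], 5L), collapse = ", "))
    m <- m[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  sweep(sweep(m, 1L, rowMeans(m)), 1L, sds, "/")
}

#' Agglomerative hierarchical clustering (WPGMA / complete linkage)
#'
#' Standard agglomerative merging on Euclidean row distances. WPGMA
#' ("McQuitty") sets the distance from a merged cluster to any other as the
#' simple average of its children's distances; complete linkage takes the
#' maximum. When several pairs tie at the minimal distance, the pair whose
#' clusters have the lexicographically smallest member labels is merged, so
#' the partition is invariant to row order. Returns an \code{hclust}
#' compatible object (plottable, usable with \code{stats::cutree} for
#' monotone linkages).
#'
#' @param m numeric matrix of observations in rows (>= 2 rows), or a
#'   \code{dist} object.
#' @param linkage \code{"wpgma"} or \code{"complete"}.
#' @return object of classes \code{c("uniset_hclust", "hclust")}.
#' @export
hcluster <- function(m, linkage = c("wpgma", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(m, "dist")) {
    d <- as.matrix(m)
  } else {
    if (nrow(m) < 2L) stop("need >= 2 rows to cluster")
    d <- as.matrix(dist(m))
  }
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  ## cluster bookkeeping: node id as in hclust merge (-obs or +step),
  ## tag = lexicographically smallest member label (for tie-breaks)
  active <- seq_len(n)
  node <- -seq_len(n)
  tag <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(d) <- Inf
  for (step in seq_len(n - 1L)) {
    dd <- d[active, active, drop = FALSE]
    mn <- min(dd)
    hit <- which(dd <= mn + 0, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit) > 1L) {
      key_a <- pmin(tag[active[hit[, 1]]], tag[active[hit[, 2]]])
      key_b <- pmax(tag[active[hit[, 1]]], tag[active[hit[, 2]]])
      hit <- hit[order(key_a, key_b, method = "radix")[1L], , drop = FALSE]
    }
    a <- active[hit[1, 1]]; b <- active[hit[1, 2]]
    merge[step, ] <- sort(c(node[a], node[b]))
    height[step] <- d[a, b]
    upd <- switch(linkage,
                  wpgma = (d[a, ] + d[b, ]) / 2,
                  complete = pmax(d[a, ], d[b, ]))
    d[a, ] <- upd
    d[, a] <- upd
    d[a, a] <- Inf
    node[a] <- step
    tag[a] <- min(tag[a], tag[b])
    active <- setdiff(active, b)
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(merge, n), labels = labels,
                 method = linkage, dist.method = "euclidean",
                 call = match.call()),
            class = c("uniset_hclust", "hclust"))
}

leaf_order <- function(merge, n) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  if (n == 1L) return(1L)
  expand(nrow(merge))
}

#' Cut a dendrogram into k groups
#'
#' Applies the first n-k merges of the tree (equivalently, removes the k-1
#' last merges; for monotone linkages this removes the k-1 highest merges,
#' matching \code{stats::cutree}). Group labels are integers 1..k in order
#' of first appearance along the input rows.
#'
#' @param tree output of \code{\link{hcluster}}.
#' @param k number of groups (1 <= k <= n).
#' @return named integer vector of group labels.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be between 1 and the number of leaves")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  reps <- integer(n - 1L)  # leaf representative of each merge node
  steps <- n - k
  for (s in seq_len(n - 1L)) {
    ab <- vapply(tree$merge[s, ], function(v) if (v < 0) -v else reps[v],
                 integer(1))
    reps[s] <- ab[1]
    if (s <= steps) parent[find(ab[2])] <- find(ab[1])
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab <- stats::setNames(match(root, unique(root)), tree$labels)
  lab
}
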