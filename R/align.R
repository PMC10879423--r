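## k-mer anchored detection of shared sequence blocks between unigenes.
##
## Exact k-mer matches are collapsed into maximal exact segments, chained
## colinearly (query and target positions both increasing, bounded gaps and
## diagonal shifts), merged across small same-diagonal gaps with mismatch
## counting, and extended ungapped at the chain ends under a match/mismatch
## score. Coordinates in all exported output are 0-based half-open; the
## internal representation is 1-based inclusive.

kmer_strings <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1L), k:n)
}

## maximal exact-match segments between q and t (forward orientation)
match_segments <- function(q, t, k, max_occ = 8L) {
  qk <- kmer_strings(q, k)
  tk <- kmer_strings(t, k)
  if (!length(qk) || !length(tk)) return(NULL)
  tmap <- split(seq_along(tk), tk)
  tmap <- tmap[lengths(tmap) <= max_occ]
  hits <- tmap[qk]
  nh <- lengths(hits)
  if (sum(nh) == 0L) return(NULL)
  qpos <- rep.int(seq_along(qk), nh)
  tpos <- unlist(hits, use.names = FALSE)
  d <- tpos - qpos
  o <- order(d, qpos)
  qpos <- qpos[o]; tpos <- tpos[o]; d <- d[o]
  ## collapse runs of consecutive anchors on one diagonal
  brk <- c(TRUE, diff(d) != 0L | diff(qpos) != 1L)
  grp <- cumsum(brk)
  q0 <- qpos[brk]
  q1 <- tapply(qpos, grp, function(v) v[length(v)]) + k - 1L
  data.frame(q0 = q0, q1 = as.integer(q1), t0 = tpos[brk],
             t1 = as.integer(q1 + d[brk]), diag = d[brk],
             len = as.integer(q1 - q0 + 1L))
}

## colinear chaining of segments by dynamic programming; returns a list of
## disjoint chains (data.frames of segments ordered by query position)
chain_segments <- function(seg, max_gap = 500L, max_shift = 500L, min_score = 15) {
  seg <- seg[order(seg$q0, seg$t0), , drop = FALSE]
  n <- nrow(seg)
  if (n > 5000L) {  # guard against repeat-dense inputs
    seg <- seg[order(-seg$len), , drop = FALSE][1:5000, ]
    seg <- seg[order(seg$q0, seg$t0), , drop = FALSE]
    n <- nrow(seg)
  }
  score <- as.numeric(seg$len)
  back <- integer(n)
  for (i in seq_len(n)[-1]) {
    j <- seq_len(i - 1L)
    ok <- seg$q0[j] < seg$q0[i] & seg$t0[j] < seg$t0[i] &
      seg$q0[i] - seg$q1[j] <= max_gap & seg$t0[i] - seg$t1[j] <= max_gap &
      abs(seg$diag[i] - seg$diag[j]) <= max_shift
    if (!any(ok)) next
    jj <- j[ok]
    overlap <- pmax(0L, seg$q1[jj] - seg$q0[i] + 1L, seg$t1[jj] - seg$t0[i] + 1L)
    gain <- score[jj] + seg$len[i] - overlap -
      0.01 * abs(seg$diag[i] - seg$diag[jj])
    b <- which.max(gain)
    if (gain[b] > score[i]) {
      score[i] <- gain[b]
      back[i] <- jj[b]
    }
  }
  used <- rep(FALSE, n)
  chains <- list()
  repeat {
    cand <- which(!used)
    if (!length(cand)) break
    best <- cand[which.max(score[cand])]
    if (score[best] < min_score) break
    path <- integer()
    i <- best
    while (i != 0L && !used[i]) {
      path <- c(i, path)
      i <- back[i]
    }
    used[path] <- TRUE
    ## drop whole chains that reuse segments of an accepted chain
    chains[[length(chains) + 1L]] <- list(seg = seg[path, , drop = FALSE],
                                          score = score[best])
  }
  chains
}

## merge same-diagonal segments across small gaps (counting matches in the
## gap by direct comparison) and convert a chain to blocks
chain_to_blocks <- function(chain, qraw, traw, merge_gap = 100L) {
  s <- chain$seg
  blocks <- list()
  cur <- list(q0 = s$q0[1], q1 = s$q1[1], t0 = s$t0[1], t1 = s$t1[1],
              matches = s$len[1], diag = s$diag[1])
  if (nrow(s) > 1L) for (i in 2:nrow(s)) {
    gap_q <- s$q0[i] - cur$q1 - 1L
    if (s$diag[i] == cur$diag && gap_q <= merge_gap && gap_q >= 0L) {
      if (gap_q > 0L) {
        idx <- (cur$q1 + 1L):(s$q0[i] - 1L)
        cur$matches <- cur$matches + sum(qraw[idx] == traw[idx + cur$diag])
      }
      cur$q1 <- s$q1[i]; cur$t1 <- s$t1[i]
      cur$matches <- cur$matches + s$len[i]
    } else {
      ## clip overlap with the previous block
      q0 <- s$q0[i]; t0 <- s$t0[i]; m <- s$len[i]
      clip <- max(0L, cur$q1 - q0 + 1L, cur$t1 - t0 + 1L)
      if (clip > 0L) { q0 <- q0 + clip; t0 <- t0 + clip; m <- m - clip }
      if (m <= 0L) next
      blocks[[length(blocks) + 1L]] <- cur
      cur <- list(q0 = q0, q1 = s$q1[i], t0 = t0, t1 = s$t1[i],
                  matches = m, diag = s$diag[i])
    }
  }
  blocks[[length(blocks) + 1L]] <- cur
  do.call(rbind, lapply(blocks, as.data.frame))
}

## ungapped outward extension of the terminal blocks of a chain under a
## +1/-2 match/mismatch score (extend to the maximum-score prefix)
extend_ends <- function(blocks, qraw, traw) {
  first <- 1L
  last <- nrow(blocks)
  e <- min(blocks$q0[first], blocks$t0[first]) - 1L
  if (e > 0L) {
    qi <- blocks$q0[first] - seq_len(e)
    ti <- blocks$t0[first] - seq_len(e)
    m <- qraw[qi] == traw[ti]
    sc <- cumsum(ifelse(m, 1, -2))
    best <- which.max(sc)
    if (sc[best] > 0) {
      blocks$q0[first] <- blocks$q0[first] - best
      blocks$t0[first] <- blocks$t0[first] - best
      blocks$matches[first] <- blocks$matches[first] + sum(m[seq_len(best)])
    }
  }
  e <- min(length(qraw) - blocks$q1[last], length(traw) - blocks$t1[last])
  if (e > 0L) {
    qi <- blocks$q1[last] + seq_len(e)
    ti <- blocks$t1[last] + seq_len(e)
    m <- qraw[qi] == traw[ti]
    sc <- cumsum(ifelse(m, 1, -2))
    best <- which.max(sc)
    if (sc[best] > 0) {
      blocks$q1[last] <- blocks$q1[last] + best
      blocks$t1[last] <- blocks$t1[last] + best
      blocks$matches[last] <- blocks$matches[last] + sum(m[seq_len(best)])
    }
  }
  blocks
}

## blocks of all chains for one orientation; 1-based inclusive coordinates
strand_blocks <- function(q, t, k, max_occ = 8L) {
  seg <- match_segments(q, t, k, max_occ)
  if (is.null(seg)) return(NULL)
  chains <- chain_segments(seg)
  if (!length(chains)) return(NULL)
  qraw <- charToRaw(q)
  traw <- charToRaw(t)
  out <- lapply(seq_along(chains), function(ci) {
    b <- chain_to_blocks(chains[[ci]], qraw, traw)
    b <- extend_ends(b, qraw, traw)
    b$chain <- ci
    b$chain_score <- chains[[ci]]$score
    b
  })
  do.call(rbind, out)
}

## greedy pruning so that reported blocks never overlap on the query:
## chains are taken in score order; blocks clashing with kept ones are
## dropped
prune_query_overlaps <- function(blocks) {
  o <- order(-blocks$chain_score, -blocks$matches, blocks$q0)
  blocks <- blocks[o, , drop = FALSE]
  kept <- logical(nrow(blocks))
  ends <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(blocks))) {
    if (nrow(ends) == 0 ||
        all(blocks$q1[i] < ends[, 1] | blocks$q0[i] > ends[, 2])) {
      kept[i] <- TRUE
      ends <- rbind(ends, c(blocks$q0[i], blocks$q1[i]))
    }
  }
  blocks[kept, , drop = FALSE]
}

#' Shared sequence blocks between two unigenes
#'
#' Detects regions shared by \code{query} and \code{target} on both strands
#' by exact k-mer anchoring, colinear chaining and ungapped extension.
#' Blocks shorter than \code{min_block} or below \code{min_identity} are
#' dropped. Within one call, reported blocks never overlap on the query.
#'
#' @param query,target DNA strings (single sequences), or length-1 named
#'   character vectors whose names become \code{q_id}/\code{t_id}.
#' @param k anchor k-mer size.
#' @param min_block minimum reported block length in bases.
#' @param min_identity minimum block identity (matches / block length).
#' @return data.frame with columns \code{q_id, t_id, q_start, q_end,
#'   t_start, t_end, strand, matches, block_len, identity, chain}
#'   (coordinates 0-based half-open on the forward axes of both sequences).
#' @export
shared_blocks <- function(query, target, k = 15L, min_block = 100L,
                          min_identity = 0.95) {
  q_id <- names(query) %||% "query"
  t_id <- names(target) %||% "target"
  q <- toupper(unname(query[[1]]))
  t <- toupper(unname(target[[1]]))
  if (nchar(q) < k || nchar(t) < k) return(empty_blocks(q_id, t_id))
  fw <- strand_blocks(q, t, k)
  if (!is.null(fw)) fw$strand <- "+"
  qr <- revcomp(q)
  rv <- strand_blocks(qr, t, k)
  if (!is.null(rv)) {
    rv$strand <- "-"
    n <- nchar(q)
    q0 <- n - rv$q1 + 1L    # mirror to forward axis
    rv$q1 <- n - rv$q0 + 1L
    rv$q0 <- q0
    rv$chain <- rv$chain + if (is.null(fw)) 0L else max(fw$chain)
  }
  blocks <- rbind(fw, rv)
  if (is.null(blocks) || !nrow(blocks)) return(empty_blocks(q_id, t_id))
  blocks$block_len <- blocks$q1 - blocks$q0 + 1L
  blocks <- blocks[blocks$block_len >= max(min_block, 1L) &
                   blocks$matches / blocks$block_len >= min_identity, ,
                   drop = FALSE]
  if (!nrow(blocks)) return(empty_blocks(q_id, t_id))
  blocks <- prune_query_overlaps(blocks)
  out <- data.frame(
    q_id = q_id, t_id = t_id,
    q_start = blocks$q0 - 1L, q_end = blocks$q1,
    t_start = blocks$t0 - 1L, t_end = blocks$t1,
    strand = blocks$strand, matches = as.integer(blocks$matches),
    block_len = blocks$block_len,
    identity = blocks$matches / blocks$block_len,
    chain = blocks$chain, stringsAsFactors = FALSE)
  out[order(out$q_start), ]
}

empty_blocks <- function(q_id = character(), t_id = character()) {
  data.frame(q_id = character(), t_id = character(), q_start = integer(),
             q_end = integer(), t_start = integer(), t_end = integer(),
             strand = character(), matches = integer(), block_len = integer(),
             identity = numeric(), chain = integer(), stringsAsFactors = FALSE)
}

#' Pairwise identity over the shorter sequence
#'
#' CD-HIT-EST style identity: total matching bases across the best chain of
#' shared blocks, divided by the length of the shorter sequence. A sequence
#' fully contained in a longer one therefore scores 1.0. Symmetric in its
#' arguments.
#'
#' For each anchored diagonal the match count is also taken as the direct
#' base-by-base tally over the full mutual overlap at that offset, which is
#' exact for substitution-only divergence however dense the substitutions;
#' the chained multi-diagonal count covers insertion-bearing pairs. The
#' larger of the two counts is used.
#'
#' @param a,b DNA strings.
#' @param k anchor k-mer size.
#' @return identity in [0, 1].
#' @export
pairwise_identity <- function(a, b, k = 15L) {
  a <- toupper(unname(a[[1]]))
  b <- toupper(unname(b[[1]]))
  shorter <- min(nchar(a), nchar(b))
  if (shorter == 0L) stop("empty sequence")
  if (shorter < k) {
    return(if (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE) ||
               grepl(revcomp(a), b, fixed = TRUE)) 1 else 0)
  }
  traw <- charToRaw(b)
  best <- 0
  for (q in list(a, revcomp(a))) {
    bl <- strand_blocks(q, b, k)
    if (is.null(bl)) next
    pruned <- prune_query_overlaps(bl)
    best <- max(best, sum(pruned$matches))
    ## full-overlap tally on the strongest anchored diagonals
    qraw <- charToRaw(q)
    by_diag <- tapply(bl$matches, bl$t0 - bl$q0, sum)
    diags <- as.integer(names(sort(by_diag, decreasing = TRUE)))
    for (d in head(diags, 3L)) {
      i0 <- max(1L, 1L - d)
      i1 <- min(length(qraw), length(traw) - d)
      if (i1 <= i0) next
      idx <- i0:i1
      best <- max(best, sum(qraw[idx] == traw[idx + d]))
    }
  }
  min(1, best / shorter)
}
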