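## Redundancy collapse, cross-set homology grouping and structural
## classification of group members against their representative.

## strand-agnostic candidate pairs sharing at least `min_shared` distinct
## canonical k-mers, found through a sparse kmer x sequence incidence matrix
kmer_candidate_pairs <- function(seqs, k = 15L, min_shared = 5L) {
  seqs <- as_seqs(seqs)
  n <- length(seqs)
  if (n < 2L) return(data.frame(i = integer(), j = integer()))
  per_seq <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character())
    kf <- kmer_strings(s, k)
    kr <- rev(kmer_strings(revcomp(s), k))
    unique(pmin(kf, kr))
  })
  lens <- lengths(per_seq)
  keys <- factor(unlist(per_seq, use.names = FALSE))
  m <- Matrix::sparseMatrix(i = as.integer(keys),
                            j = rep.int(seq_len(n), lens),
                            x = 1,
                            dims = c(nlevels(keys), n))
  shared <- Matrix::crossprod(m)
  tri <- Matrix::which(shared >= min_shared, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  data.frame(i = tri[, 1], j = tri[, 2])
}

#' Greedy redundancy collapse with CD-HIT-EST semantics
#'
#' Sequences are visited in order of decreasing length (ties broken by
#' id); each sequence joins the first earlier representative whose pairwise
#' identity over the shorter sequence exceeds \code{identity_threshold},
#' otherwise it founds a new representative. Because identity is measured
#' over the shorter sequence, a sequence fully contained in an earlier,
#' longer one is collapsed. A shared-k-mer prefilter skips pairs that cannot
#' reach the threshold.
#'
#' @param x named character vector or DNAStringSet.
#' @param identity_threshold identity above which a sequence is redundant.
#' @param k anchor k-mer size for the identity computation.
#' @param prefilter_k k-mer size of the candidate prefilter.
#' @return list with \code{representatives} (ids in greedy order),
#'   \code{redundant} (named character: member id -> representative id) and
#'   \code{order} (the visiting order).
#' @export
dedup_greedy <- function(x, identity_threshold = 0.90, k = 15L,
                         prefilter_k = 12L) {
  x <- as_seqs(x)
  if (!length(x)) stop("empty unigene set")
  ord <- order(-nchar(x), names(x), method = "radix")
  x <- x[ord]
  cand <- kmer_candidate_pairs(x, k = prefilter_k, min_shared = 1L)
  cand_of <- split(cand$i, cand$j)  # earlier index -> listed under later
  rank_of <- integer(length(x))
  is_rep <- logical(length(x))
  rep_of <- character(length(x))
  names(rep_of) <- names(x)
  for (i in seq_along(x)) {
    earlier <- cand_of[[as.character(i)]]
    earlier <- earlier[is_rep[earlier]]
    assigned <- FALSE
    for (j in sort(earlier)) {
      if (pairwise_identity(x[[i]], x[[j]], k = k) > identity_threshold) {
        rep_of[i] <- names(x)[j]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) is_rep[i] <- TRUE
  }
  list(representatives = names(x)[is_rep],
       redundant = rep_of[!is_rep],
       order = names(x))
}

#' Group unigenes across sets by shared sequence blocks
#'
#' Computes qualifying shared blocks between all pairs of unigenes passing a
#' shared-k-mer prefilter (within and across sets) and returns the connected
#' components of the resulting graph. The representative of each group is
#' the longest member of \code{anchor_set} (the near-full-length reference
#' set), falling back to the longest member overall; ties break by id.
#'
#' @param sets named list of unigene sets (named character vectors or
#'   DNAStringSets); names are the set labels.
#' @param blocks optional precomputed block table; if \code{NULL} blocks are
#'   computed here with the longer sequence of each pair as query.
#' @param k,min_block,min_identity block detection parameters
#'   (see \code{\link{shared_blocks}}).
#' @param min_shared prefilter: minimum shared distinct canonical k-mers.
#' @param anchor_set label of the set anchoring representatives; defaults to
#'   the first set.
#' @return object of class \code{"homology_groups"}: list with
#'   \code{members} (group_id, unigene_id, set_label, length, is_rep),
#'   \code{blocks}, \code{seqs}, \code{anchor_set}.
#' @export
build_groups <- function(sets, blocks = NULL, k = 15L, min_block = 100L,
                         min_identity = 0.95, min_shared = 5L,
                         anchor_set = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  anchor_set <- anchor_set %||% names(sets)[1L]
  seqs <- unlist(lapply(sets, as_seqs))
  set_of <- rep(names(sets), vapply(sets, length, integer(1)))
  names(seqs) <- unlist(lapply(sets, function(s) names(as_seqs(s))))
  names(set_of) <- names(seqs)
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup)) stop("unigene ids duplicated across sets: ",
                        paste(head(dup, 5L), collapse = ", "))
  if (is.null(blocks)) {
    cand <- kmer_candidate_pairs(seqs, k = k, min_shared = min_shared)
    out <- vector("list", nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      ## longer sequence as query so multi-copy members chain on their axis
      if (nchar(seqs[[i]]) < nchar(seqs[[j]])) { tmp <- i; i <- j; j <- tmp }
      b <- shared_blocks(seqs[i], seqs[j], k = k, min_block = min_block,
                         min_identity = min_identity)
      if (nrow(b)) out[[r]] <- b
    }
    blocks <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(blocks)) blocks <- empty_blocks()
  }
  ## union-find over the block graph
  parent <- seq_along(seqs)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- stats::setNames(seq_along(seqs), names(seqs))
  if (nrow(blocks)) {
    for (r in seq_len(nrow(blocks))) {
      a <- find(idx[[blocks$q_id[r]]]); b <- find(idx[[blocks$t_id[r]]])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  comp <- vapply(seq_along(seqs), find, integer(1))
  ## stable group ids: numbered by the smallest member id in each component
  first_id <- tapply(names(seqs), comp, function(v) sort(v)[1L])
  comp_rank <- stats::setNames(rank(first_id, ties.method = "first"),
                               names(first_id))
  gid <- sprintf("grp%04d", comp_rank[as.character(comp)])
  members <- data.frame(group_id = gid, unigene_id = names(seqs),
                        set_label = unname(set_of), length = nchar(seqs),
                        is_rep = FALSE, stringsAsFactors = FALSE,
                        row.names = NULL)
  members <- members[order(members$group_id, members$unigene_id), ]
  for (g in unique(members$group_id)) {
    rows <- which(members$group_id == g)
    members$is_rep[rows[pick_rep(members[rows, ], anchor_set)]] <- TRUE
  }
  structure(list(members = members, blocks = blocks, seqs = seqs,
                 anchor_set = anchor_set),
            class = "homology_groups")
}

## index (within the group rows) of the preferred representative
pick_rep <- function(rows, anchor_set) {
  pool <- which(rows$set_label == anchor_set)
  if (!length(pool)) pool <- seq_len(nrow(rows))
  pool[order(-rows$length[pool], rows$unigene_id[pool], method = "radix")[1L]]
}

#' @export
print.homology_groups <- function(x, ...) {
  n_multi <- sum(table(x$members$group_id) > 1L)
  cat(sprintf("homology groups: %d groups (%d with >1 member), %d members, %d blocks\n",
              length(unique(x$members$group_id)), n_multi,
              nrow(x$members), nrow(x$blocks)))
  invisible(x)
}

## m-axis and partner-axis intervals of every block involving member `id`
member_block_view <- function(blocks, id) {
  q_side <- blocks$q_id == id
  t_side <- blocks$t_id == id
  rbind(
    if (any(q_side)) data.frame(partner = blocks$t_id[q_side],
                                m_start = blocks$q_start[q_side],
                                m_end = blocks$q_end[q_side],
                                p_start = blocks$t_start[q_side],
                                p_end = blocks$t_end[q_side],
                                matches = blocks$matches[q_side],
                                chain = blocks$chain[q_side],
                                stringsAsFactors = FALSE),
    if (any(t_side)) data.frame(partner = blocks$q_id[t_side],
                                m_start = blocks$t_start[t_side],
                                m_end = blocks$t_end[t_side],
                                p_start = blocks$q_start[t_side],
                                p_end = blocks$q_end[t_side],
                                matches = blocks$matches[t_side],
                                chain = blocks$chain[t_side],
                                stringsAsFactors = FALSE)
  )
}

## connected components of the member graph after deleting `drop`
components_without <- function(ids, edges, drop = character()) {
  keep <- setdiff(ids, drop)
  parent <- stats::setNames(seq_along(keep), keep)
  find <- function(i) { while (parent[[i]] != i) { parent[[i]] <<- parent[[parent[[i]]]]; i <- parent[[i]] }; i }
  e <- edges[edges$a %in% keep & edges$b %in% keep, , drop = FALSE]
  idx <- stats::setNames(seq_along(keep), keep)
  for (r in seq_len(nrow(e))) {
    a <- find(idx[[e$a[r]]]); b <- find(idx[[e$b[r]]])
    if (a != b) parent[[max(a, b)]] <- min(a, b)
  }
  split(keep, vapply(seq_along(keep), find, integer(1)))
}

#' Classify group members against their representative
#'
#' For every homology group, members are compared with the group
#' representative in aligned coordinates: members whose alignment reaches
#' the representative's terminus (within \code{margin}) and that run past
#' it by at least \code{margin} bases are UTR-end extensions; an internal
#' alignment discontinuity of at least \code{min_isoform_gap} bases on
#' either sequence marks an isoform variant; a member carrying two disjoint
#' near-complete copies of two partners that remain connected without it is
#' a concatenation; a member whose removal disconnects the group (a bridge
#' between two otherwise unrelated components) is a chimera. Everything
#' else is faithful. Members collapsed by \code{\link{dedup_greedy}} can be
#' supplied via \code{redundant} and are reported with call
#' \code{redundant}.
#'
#' A member may extend both ends of the representative, in which case it
#' receives one row per extended end; all other calls are exclusive, with
#' priority chimera > concatenation > isoform_variant > extension.
#'
#' @param groups a \code{"homology_groups"} object.
#' @param cds_calls optional output of \code{\link{predict_cds_set}}; when
#'   given, members without a predicted CDS are not classified.
#' @param margin minimum UTR-end extension (and terminus slack), bases.
#' @param min_isoform_gap minimum internal discontinuity for an isoform
#'   call, bases.
#' @param redundant named character vector (member -> representative) from
#'   \code{\link{dedup_greedy}}.
#' @param redundant_sets optional named character vector (member -> set
#'   label) for the entries of \code{redundant}.
#' @param k anchor k-mer size for detail chains.
#' @return data.frame with columns \code{unigene_id, set_label, group_id,
#'   call, ref_id, ev_ext5, ev_ext3, ev_gap, partner1, partner2}.
#' @export
classify_members <- function(groups, cds_calls = NULL, margin = 20L,
                             min_isoform_gap = 50L, redundant = NULL,
                             redundant_sets = NULL, k = 15L) {
  stopifnot(inherits(groups, "homology_groups"))
  members <- groups$members
  seqs <- groups$seqs
  blocks <- groups$blocks
  if (!is.null(cds_calls)) {
    keep <- members$unigene_id %in% cds_calls$unigene_id
    members <- members[keep, , drop = FALSE]
  }
  edges <- if (nrow(blocks)) data.frame(a = blocks$q_id, b = blocks$t_id,
                                        stringsAsFactors = FALSE)
           else data.frame(a = character(), b = character())
  calls <- list()
  emit <- function(id, set, gid, call, ref, e5 = NA, e3 = NA, gap = NA,
                   p1 = NA_character_, p2 = NA_character_) {
    calls[[length(calls) + 1L]] <<- data.frame(
      unigene_id = id, set_label = set, group_id = gid, call = call,
      ref_id = ref, ev_ext5 = e5, ev_ext3 = e3, ev_gap = gap,
      partner1 = p1, partner2 = p2, stringsAsFactors = FALSE)
  }
  set_of <- stats::setNames(members$set_label, members$unigene_id)

  for (g in unique(members$group_id)) {
    ids <- members$unigene_id[members$group_id == g]
    if (length(ids) == 1L) {
      emit(ids, set_of[[ids]], g, "faithful", ids)
      next
    }
    ## chimera pass: bridge members whose removal splits the group
    chimeras <- character()
    chim_partners <- list()
    for (m in sort(ids)) {
      comps <- components_without(ids, edges, drop = c(m, chimeras))
      view <- member_block_view(blocks, m)
      touched <- comps[vapply(comps, function(cc) any(cc %in% view$partner),
                              logical(1))]
      if (length(touched) >= 2L) {
        best <- vapply(touched, function(cc) {
          v <- view[view$partner %in% cc, , drop = FALSE]
          v$partner[which.max(v$matches)]
        }, character(1))
        sizes <- vapply(touched, length, integer(1))
        top2 <- order(-sizes)[1:2]
        chimeras <- c(chimeras, m)
        chim_partners[[m]] <- unname(best[top2])
      }
    }
    for (m in chimeras) {
      emit(m, set_of[[m]], g, "chimera", NA_character_,
           p1 = chim_partners[[m]][1], p2 = chim_partners[[m]][2])
    }
    ## classify the remaining members inside their sub-component
    comps <- components_without(ids, edges, drop = chimeras)
    for (cc in comps) {
      ## concatenations are identified first: a member carrying two disjoint
      ## near-complete partner copies must not anchor the group
      concats <- list()
      for (m in sort(cc)) {
        co <- concat_partners(m, cc, seqs, blocks)
        if (!is.null(co)) concats[[m]] <- co
      }
      rows <- members[match(cc, members$unigene_id), , drop = FALSE]
      plain <- !(cc %in% names(concats))
      ref <- if (any(plain)) {
        cc[plain][pick_rep(rows[plain, , drop = FALSE], groups$anchor_set)]
      } else cc[pick_rep(rows, groups$anchor_set)]
      emit(ref, set_of[[ref]], g, "faithful", ref)
      for (m in setdiff(sort(cc), ref)) {
        cl <- classify_one(m, ref, cc, seqs, blocks, margin,
                           min_isoform_gap, k)
        if (is.null(cl)) {
          warning("member ", m, " has no alignment to representative ", ref,
                  "; excluded")
          next
        }
        ## extension evidence is independent of internal structure: an
        ## isoform variant, or a concatenation whose first/last joined
        ## copy reaches the representative's terminus, still completes
        ## the representative's UTR ends
        ext5 <- !is.na(cl$ext5) && cl$ext5 >= margin
        ext3 <- !is.na(cl$ext3) && cl$ext3 >= margin
        if (ext5) emit(m, set_of[[m]], g, "utr5_extension", ref,
                       e5 = cl$ext5, e3 = cl$ext3, gap = cl$gap)
        if (ext3) emit(m, set_of[[m]], g, "utr3_extension", ref,
                       e5 = cl$ext5, e3 = cl$ext3, gap = cl$gap)
        if (m %in% names(concats)) {
          emit(m, set_of[[m]], g, "concatenation", ref,
               e5 = cl$ext5, e3 = cl$ext3,
               p1 = concats[[m]][1], p2 = concats[[m]][2])
        } else if (cl$call == "isoform_variant") {
          emit(m, set_of[[m]], g, "isoform_variant", ref, e5 = cl$ext5,
               e3 = cl$ext3, gap = cl$gap)
        } else if (cl$call == "faithful" && !ext5 && !ext3) {
          emit(m, set_of[[m]], g, "faithful", ref, e5 = cl$ext5,
               e3 = cl$ext3, gap = cl$gap)
        }
      }
    }
  }
  if (!is.null(redundant) && length(redundant)) {
    grp_of <- stats::setNames(members$group_id, members$unigene_id)
    for (m in names(redundant)) {
      rep_id <- redundant[[m]]
      s <- if (!is.null(redundant_sets) && m %in% names(redundant_sets))
        redundant_sets[[m]] else NA_character_
      emit(m, s, unname(grp_of[rep_id]), "redundant", rep_id)
    }
  }
  do.call(rbind, calls)
}

## concatenation evidence for member m: two near-complete copies of group
## partners occupying disjoint, jointly near-complete stretches of m. After
## redundancy collapse the joined transcripts usually survive as a single
## member elsewhere, so the two copy chains may come from one partner.
concat_partners <- function(m, cc, seqs, blocks) {
  mlen <- nchar(seqs[[m]])
  view <- member_block_view(blocks, m)
  view <- view[view$partner %in% setdiff(cc, m), , drop = FALSE]
  if (!nrow(view)) return(NULL)
  ch <- split(view, paste(view$partner, view$chain))
  cov <- vapply(ch, function(v) {
    (max(v$p_end) - min(v$p_start)) / nchar(seqs[[v$partner[1]]])
  }, numeric(1))
  ch <- ch[cov >= 0.7]
  if (length(ch) < 2L) return(NULL)
  info <- data.frame(
    partner = vapply(ch, function(v) v$partner[1], character(1)),
    m0 = vapply(ch, function(v) min(v$m_start), numeric(1)),
    m1 = vapply(ch, function(v) max(v$m_end), numeric(1)),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(info) - 1L)) for (j in (i + 1L):nrow(info)) {
    ov <- min(info$m1[i], info$m1[j]) - max(info$m0[i], info$m0[j])
    span <- sum(info$m1[c(i, j)] - info$m0[c(i, j)])
    if (ov <= 30 && span >= 0.8 * mlen) {
      p <- sort(c(info$partner[i], info$partner[j]))
      return(c(p[1], p[2]))
    }
  }
  NULL
}

## single-member classification against the sub-component representative
classify_one <- function(m, ref, cc, seqs, blocks, margin, min_isoform_gap, k) {
  mlen <- nchar(seqs[[m]])
  ## detail chain against the representative
  det <- shared_blocks(seqs[m], seqs[ref], k = k, min_block = 30L,
                       min_identity = 0.90)
  if (!nrow(det)) return(NULL)
  strand_matches <- tapply(det$matches, det$strand, sum)
  strand <- names(strand_matches)[which.max(strand_matches)]
  det <- det[det$strand == strand, , drop = FALSE]
  if (strand == "-") {  # orient member to the representative's strand
    q0 <- mlen - det$q_end
    det$q_end <- mlen - det$q_start
    det$q_start <- q0
  }
  det <- det[order(det$q_start), , drop = FALSE]
  reflen <- nchar(seqs[[ref]])
  gap <- 0
  if (nrow(det) > 1L) {
    gq <- det$q_start[-1] - det$q_end[-nrow(det)]
    gt <- det$t_start[-1] - det$t_end[-nrow(det)]
    gap <- max(0, gq, gt)
  }
  ## 5' evidence: earliest member bases aligning at the representative's 5'
  ## terminus (for concatenations this is the first joined copy); 3'
  ## evidence symmetric with the last copy
  c5 <- which(det$t_start <= margin)
  c3 <- which(reflen - det$t_end <= margin)
  ext5 <- if (length(c5)) {
    b5 <- c5[which.min(det$q_start[c5])]
    det$q_start[b5] - det$t_start[b5]
  } else NA
  ext3 <- if (length(c3)) {
    b3 <- c3[which.max(det$q_end[c3])]
    (mlen - det$q_end[b3]) - (reflen - det$t_end[b3])
  } else NA
  if (gap >= min_isoform_gap) {
    return(list(call = "isoform_variant", ext5 = ext5, ext3 = ext3,
                gap = gap, p1 = NA_character_, p2 = NA_character_))
  }
  if ((!is.na(ext5) && ext5 >= margin) || (!is.na(ext3) && ext3 >= margin)) {
    return(list(call = "extension", ext5 = ext5, ext3 = ext3, gap = gap,
                p1 = NA_character_, p2 = NA_character_))
  }
  list(call = "faithful", ext5 = ext5, ext3 = ext3, gap = gap,
       p1 = NA_character_, p2 = NA_character_)
}

## do two members share the same block structure (colinear, near-complete
## mutual coverage, no discordant internal gap)?
same_structure <- function(a, b, min_isoform_gap = 50L, k = 15L) {
  la <- nchar(a[[1]]); lb <- nchar(b[[1]])
  det <- shared_blocks(a, b, k = k, min_block = 30L, min_identity = 0.90)
  if (!nrow(det)) return(FALSE)
  sm <- tapply(det$matches, det$strand, sum)
  det <- det[det$strand == names(sm)[which.max(sm)], , drop = FALSE]
  det <- det[order(det$q_start), , drop = FALSE]
  matched <- sum(det$matches)
  if (matched / la < 0.9 || matched / lb < 0.9) return(FALSE)
  if (nrow(det) > 1L) {
    gq <- det$q_start[-1] - det$q_end[-nrow(det)]
    gt <- det$t_start[-1] - det$t_end[-nrow(det)]
    if (max(gq, gt) >= min_isoform_gap) return(FALSE)
  }
  TRUE
}

#' Cross-set reconciliation report
#'
#' Per-set tallies of structural calls, set-exclusive isoform variants
#' (isoform calls whose block structure matches no member of any other
#' set in the group) and missing groups (groups with no member from the
#' set).
#'
#' @param groups a \code{"homology_groups"} object.
#' @param calls output of \code{\link{classify_members}}.
#' @param min_isoform_gap gap used for the structure comparison.
#' @param k anchor k-mer size.
#' @return object of class \code{"reconcile_report"}: list with
#'   \code{per_set} (one row per set), \code{n_groups}, and the ids of
#'   set-exclusive isoform members in \code{exclusive_isoforms}.
#' @export
summarize_reconcile <- function(groups, calls, min_isoform_gap = 50L, k = 15L) {
  stopifnot(inherits(groups, "homology_groups"))
  members <- groups$members
  sets <- unique(members$set_label)
  call_types <- c("faithful", "utr5_extension", "utr3_extension",
                  "isoform_variant", "concatenation", "chimera", "redundant")
  exclusive <- character()
  iso <- calls[calls$call == "isoform_variant", , drop = FALSE]
  for (r in seq_len(nrow(iso))) {
    m <- iso$unigene_id[r]
    g <- iso$group_id[r]
    others <- members$unigene_id[members$group_id == g &
                                 members$set_label != iso$set_label[r]]
    matched <- FALSE
    for (n in others) {
      if (same_structure(groups$seqs[m], groups$seqs[n],
                         min_isoform_gap = min_isoform_gap, k = k)) {
        matched <- TRUE
        break
      }
    }
    if (!matched) exclusive <- c(exclusive, m)
  }
  grp_sets <- split(members$set_label, members$group_id)
  per_set <- do.call(rbind, lapply(sets, function(s) {
    in_set <- calls$set_label == s & !is.na(calls$set_label)
    tal <- vapply(call_types, function(ct) {
      length(unique(calls$unigene_id[in_set & calls$call == ct]))
    }, integer(1))
    data.frame(set_label = s,
               members = sum(members$set_label == s),
               t(tal),
               isoform_only = sum(exclusive %in%
                                  calls$unigene_id[in_set]),
               missing_groups = sum(!vapply(grp_sets, function(v) s %in% v,
                                            logical(1))),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_set = per_set,
                 n_groups = length(grp_sets),
                 exclusive_isoforms = exclusive),
            class = "reconcile_report")
}

#' @export
print.reconcile_report <- function(x, ...) {
  cat(sprintf("reconcile report: %d groups\n", x$n_groups))
  print(x$per_set, row.names = FALSE)
  invisible(x)
}
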