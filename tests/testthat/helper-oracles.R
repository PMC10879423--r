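# Independent brute-force oracles used to verify the package's
# implementations. Each oracle is written from the definition, not from the
# implementation it checks.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_at_rate <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

## length statistics straight from the definitions
oracle_length_stats <- function(seqs) {
  len <- unname(nchar(seqs))
  s <- sort(len, decreasing = TRUE)
  n50 <- NA
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= sum(len) / 2) { n50 <- l; break }
  }
  tallies <- table(factor(unlist(strsplit(seqs, "")),
                          levels = c("A", "C", "G", "T", "N")))
  denom <- sum(tallies[c("A", "C", "G", "T")])
  list(n = length(seqs), max_len = max(len), mean_len = mean(len),
       median_len = sort(len)[ceiling(length(len) / 2)], n50 = n50,
       gc_ratio = unname((tallies[["G"]] + tallies[["C"]]) / denom * 100))
}

## exhaustive six-frame ORF enumeration; returns the best (longest complete
## ORF >= min_aa, ties + strand then smallest forward start) or NULL
oracle_orf <- function(seq, min_aa = 100) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  n <- nchar(seq)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (start in seq_len(n)) {
      if (substr(s, start, start + 2) != "ATG") next
      pos <- start
      repeat {
        codon <- substr(s, pos, pos + 2)
        if (nchar(codon) < 3) break
        if (codon %in% c("TAA", "TAG", "TGA")) {
          aa <- (pos - start) / 3
          if (aa >= min_aa) {
            cs <- start - 1; ce <- pos + 2
            if (strand == "-") { tmp <- cs; cs <- n - ce; ce <- n - tmp }
            cand <- list(strand = strand, cds_start = cs, cds_end = ce, aa_len = aa)
            if (is.null(best) || cand$aa_len > best$aa_len ||
                (cand$aa_len == best$aa_len &&
                 (cand$strand == "+" && best$strand == "-" ||
                  (cand$strand == best$strand && cand$cds_start < best$cds_start)))) {
              best <- cand
            }
          }
          break
        }
        pos <- pos + 3
      }
    }
  }
  best
}

## alignment-based identity over the shorter sequence (independent route)
oracle_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  score_one <- function(p) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(p), Biostrings::DNAString(b),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
      gapOpening = 10, gapExtension = 4)
    Biostrings::nmatch(aln)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  max(score_one(a), score_one(rc)) / nchar(a)
}

## brute-force CD-HIT-style greedy collapse using oracle_identity
oracle_dedup <- function(seqs, threshold = 0.90) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- character()
  assign_to <- setNames(character(), character())
  for (id in names(seqs)) {
    hit <- NA_character_
    for (r in reps) {
      if (oracle_identity(seqs[[id]], seqs[[r]]) > threshold) { hit <- r; break }
    }
    if (is.na(hit)) reps <- c(reps, id) else assign_to[id] <- hit
  }
  list(representatives = reps, redundant = assign_to)
}

## direct agglomeration from the linkage recurrences, naive minimum search
oracle_hclust_merges <- function(m, linkage) {
  d <- as.matrix(dist(m))
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  clusters <- as.list(seq_len(nrow(d)))
  tags <- labels
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      key <- sort(c(tags[i], tags[j]))
      if (is.null(best) || d_ij(d, i, j) < best$d - 1e-12 ||
          (abs(d_ij(d, i, j) - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = d_ij(d, i, j), key = key)
      }
    }
    i <- best$i; j <- best$j
    merges[[length(merges) + 1L]] <- list(
      members = sort(c(unlist(clusters[[i]]), unlist(clusters[[j]]))),
      height = best$d)
    new_d <- switch(linkage,
                    wpgma = (d[i, ] + d[j, ]) / 2,
                    complete = pmax(d[i, ], d[j, ]))
    d[i, ] <- new_d; d[, i] <- new_d; d[i, i] <- 0
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    tags[i] <- min(tags[i], tags[j])
    d <- d[-j, -j, drop = FALSE]
    clusters[[j]] <- NULL
    tags <- tags[-j]
  }
  merges
}
d_ij <- function(d, i, j) d[i, j]

## member sets merged at each step of an hcluster tree, for comparison with
## the oracle
tree_merge_members <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(tree$merge[s, 1]), grab(tree$merge[s, 2])))
  }
  sets
}
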