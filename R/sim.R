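## Synthetic multi-unigene-set study generator.
##
## The generator emulates the study design the package is built to analyse:
## one near-full-length long-read consensus set whose members often miss
## stretches of 5'/3' UTR and under-sample low-expression isoforms, plus one
## or more assembly-like sets that carry complete UTR ends, a large majority
## of short low-TPM noise fragments, occasional chimeras/concatenations and
## near-duplicate redundant variants. Every emission is recorded in a truth
## ledger so downstream stages can be scored by recovery.

STOP_CODONS <- c("TAA", "TAG", "TGA")
TISSUES <- c("leaf", "stem", "root", "flower")

## fraction of a gene's abundance allotted to each tissue, per expression
## pattern: a = leaf+root, b = leaf+flower, c = stem+root, d = stem+flower.
PATTERN_PROFILES <- rbind(
  a = c(leaf = 0.44, stem = 0.06, root = 0.44, flower = 0.06),
  b = c(leaf = 0.44, stem = 0.06, root = 0.06, flower = 0.44),
  c = c(leaf = 0.06, stem = 0.44, root = 0.44, flower = 0.06),
  d = c(leaf = 0.06, stem = 0.44, root = 0.06, flower = 0.44)
)

non_stop_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, STOP_CODONS)
}

#' Simulate a ground-truth transcriptome
#'
#' Generates genes with a random protein-coding region (ATG through stop, no
#' internal in-frame stop), random 5'/3' UTRs, optional alternatively spliced
#' isoforms (an in-frame cassette-like insertion of at least
#' \code{min_isoform_gap} bases), a lognormal gene abundance and one of four
#' tissue expression patterns (a: leaf+root high, b: leaf+flower, c:
#' stem+root, d: stem+flower). Isoform abundances are on the TPM scale: the
#' summed abundance of all transcripts is one million, so realised TPM in an
#' emitted set tracks the assigned abundance.
#'
#' @param n_genes number of genes (>= 1).
#' @param isoforms_per_gene list with \code{mean_extra} (Poisson mean of
#'   additional isoforms per gene) and \code{max} (cap on isoforms per gene).
#' @param seed integer seed; all downstream randomness derives from it.
#' @param utr5_range,utr3_range UTR length ranges in bases.
#' @param cds_aa_range coding length range in residues (stop excluded).
#' @param isoform_gap_range length range (bases) of the isoform insertion;
#'   rounded up to a codon multiple.
#' @param abundance_sdlog lognormal sd of gene abundance.
#' @param primary_share fraction of a gene's abundance on its primary
#'   isoform; the remainder is split equally among minor isoforms.
#' @return an object of class \code{"sim_truth"}: a list with
#'   \code{transcripts} (one row per isoform), an empty emission ledger,
#'   per-isoform tissue mean abundances, and the seed.
#' @export
simulate_truth <- function(n_genes = 120,
                           isoforms_per_gene = list(mean_extra = 0.5, max = 4),
                           seed = 1,
                           utr5_range = c(30, 300),
                           utr3_range = c(50, 500),
                           cds_aa_range = c(100, 500),
                           isoform_gap_range = c(60, 150),
                           abundance_sdlog = 1.5,
                           primary_share = 0.8) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (!is.list(isoforms_per_gene) ||
      is.null(isoforms_per_gene$mean_extra) || is.null(isoforms_per_gene$max) ||
      isoforms_per_gene$mean_extra < 0 || isoforms_per_gene$max < 1) {
    stop("invalid isoform distribution spec: need list(mean_extra >= 0, max >= 1)")
  }
  seeds <- derive_seeds(seed, 4L, salt = 1L)
  codons <- non_stop_codons()
  codons_noatg <- setdiff(codons, "ATG")

  rows <- list()
  means <- list()
  with_seed(seeds[1L], {
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("g%04d", g)
      n_iso <- 1L + min(rpois(1L, isoforms_per_gene$mean_extra),
                        isoforms_per_gene$max - 1L)
      aa <- sample(cds_aa_range[1]:cds_aa_range[2], 1L)
      cds <- paste0("ATG",
                    paste(sample(codons_noatg, aa - 1L, replace = TRUE), collapse = ""),
                    sample(STOP_CODONS, 1L))
      utr5 <- random_dna(sample(utr5_range[1]:utr5_range[2], 1L))
      utr3 <- random_dna(sample(utr3_range[1]:utr3_range[2], 1L))
      gene_w <- rlnorm(1L, meanlog = 0, sdlog = abundance_sdlog)
      pattern <- sample(rownames(PATTERN_PROFILES), 1L)
      shares <- if (n_iso == 1L) 1 else
        c(primary_share, rep((1 - primary_share) / (n_iso - 1L), n_iso - 1L))
      for (j in seq_len(n_iso)) {
        iso_cds <- cds
        if (j > 1L) {
          gap_codons <- ceiling(sample(isoform_gap_range[1]:isoform_gap_range[2], 1L) / 3)
          ins <- paste(sample(codons_noatg, gap_codons, replace = TRUE), collapse = "")
          at <- 3L * sample(seq_len(nchar(cds) / 3 - 2L), 1L)  # codon boundary, interior
          iso_cds <- paste0(substr(cds, 1L, at), ins,
                            substr(cds, at + 1L, nchar(cds)))
        }
        iso_id <- sprintf("%s.i%d", gene_id, j)
        seqn <- paste0(utr5, iso_cds, utr3)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, isoform_id = iso_id, sequence = seqn,
          cds_start = nchar(utr5), cds_end = nchar(utr5) + nchar(iso_cds),
          utr5_len = nchar(utr5), utr3_len = nchar(utr3),
          abundance = gene_w * shares[j], pattern = pattern,
          is_primary = j == 1L, stringsAsFactors = FALSE)
        means[[iso_id]] <- gene_w * shares[j] * 4 * PATTERN_PROFILES[pattern, ]
      }
    }
  })
  tx <- do.call(rbind, rows)
  scale <- 1e6 / sum(tx$abundance)
  tx$abundance <- tx$abundance * scale
  mmat <- do.call(rbind, means) * scale
  rownames(mmat) <- tx$isoform_id
  colnames(mmat) <- TISSUES

  structure(list(
    transcripts = tx,
    emissions = empty_ledger(),
    emission_means = mmat[0, , drop = FALSE],
    isoform_means = mmat,
    sets = list(),
    seed = seed,
    stage_seeds = seeds
  ), class = "sim_truth")
}

empty_ledger <- function() {
  data.frame(unigene_id = character(), set_label = character(),
             source_isoform = character(), trunc5 = integer(),
             trunc3 = integer(), label = character(),
             parent1 = character(), parent2 = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d transcripts (%d genes), seed %s\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              format(x$seed)))
  for (s in names(x$sets)) {
    cat(sprintf("  set '%s': %d unigenes\n", s, length(x$sets[[s]])))
  }
  invisible(x)
}

ledger_row <- function(id, set, source, t5, t3, label, p1 = NA_character_,
                       p2 = NA_character_) {
  data.frame(unigene_id = id, set_label = set, source_isoform = source,
             trunc5 = as.integer(t5), trunc3 = as.integer(t3), label = label,
             parent1 = p1, parent2 = p2, stringsAsFactors = FALSE)
}

add_emissions <- function(truth, set_label, seqs, ledger, means) {
  truth$sets[[set_label]] <- seqs
  truth$emissions <- rbind(truth$emissions, ledger)
  truth$emission_means <- rbind(truth$emission_means, means)
  truth
}

#' Emit a long-read consensus ("CCS-like") unigene set
#'
#' Samples isoforms with probability increasing in their summed abundance
#' (Poisson capture at the given depth), so low-expression isoforms are
#' frequently absent. Each detected isoform is emitted once, truncated at
#' each end by a geometric-distributed number of bases (capped at the UTR
#' length, so the CDS stays intact), with substitution errors at
#' \code{error_rate}.
#'
#' @param truth a \code{sim_truth}.
#' @param sampling_depth effective number of reads driving detection.
#' @param trunc_mean mean of the geometric truncation per end, in bases.
#' @param error_rate per-base substitution rate.
#' @param set_label label for the emitted set.
#' @param include_isoforms,exclude_isoforms isoform ids to force into or
#'   out of the emission, overriding the capture draw (planting controls).
#' @param seed optional override; defaults to a sub-seed of the truth seed.
#' @return the updated \code{sim_truth} with \code{sets[[set_label]]} and
#'   new ledger rows (label \code{faithful} or \code{utr_truncated}).
#' @export
emit_ccs_set <- function(truth, sampling_depth = 4000, trunc_mean = 30,
                         error_rate = 0.001, set_label = "ccs",
                         include_isoforms = NULL, exclude_isoforms = NULL,
                         seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (sampling_depth == 0) {
    warning("sampling_depth = 0: emitting an empty set")
    return(add_emissions(truth, set_label, character(),
                         empty_ledger(), truth$emission_means[0, , drop = FALSE]))
  }
  seed <- seed %||% derive_seeds(truth$seed, 1L, salt = 2L)
  tx <- truth$transcripts
  w <- tx$abundance / sum(tx$abundance)
  p_geom <- 1 / (1 + trunc_mean)  # P(X = 0) for a geometric with this mean
  with_seed(seed, {
    detected <- runif(nrow(tx)) < (1 - exp(-sampling_depth * w))
    detected[tx$isoform_id %in% include_isoforms] <- TRUE
    detected[tx$isoform_id %in% exclude_isoforms] <- FALSE
    idx <- which(detected)
    seqs <- character(length(idx))
    led <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      t5 <- if (trunc_mean > 0) min(rgeom(1L, p_geom), tx$utr5_len[i]) else 0L
      t3 <- if (trunc_mean > 0) min(rgeom(1L, p_geom), tx$utr3_len[i]) else 0L
      s <- substr(tx$sequence[i], t5 + 1L, nchar(tx$sequence[i]) - t3)
      s <- mutate_seq(s, error_rate)
      id <- sprintf("%s_%05d", set_label, k)
      seqs[k] <- s
      led[[k]] <- ledger_row(id, set_label, tx$isoform_id[i], t5, t3,
                             if (t5 + t3 > 0) "utr_truncated" else "faithful")
    }
  })
  led <- if (length(idx)) do.call(rbind, led) else empty_ledger()
  names(seqs) <- led$unigene_id
  means <- truth$isoform_means[tx$isoform_id[idx], , drop = FALSE]
  rownames(means) <- led$unigene_id
  add_emissions(truth, set_label, seqs, led, means)
}

#' Emit an assembly-like unigene set
#'
#' True transcripts whose expression clears a stochastic capture model are
#' emitted full length (complete UTR ends, so assembly-like members can
#' extend the ends of the CCS-like set). On top of these the set receives:
#' short random noise fragments with low assigned expression (TPM-scale mean
#' uniform in [0.05, 2]), making up a configurable fraction of the set;
#' chimeras joining segments of two distinct genes; concatenations joining
#' two isoforms of one gene end to end; and redundant near-duplicate
#' variants at 92-99 percent identity.
#'
#' @param truth a \code{sim_truth}.
#' @param style \code{"hybrid"} (better capture of low-expression
#'   transcripts) or \code{"shortread"}.
#' @param noise_multiplier noise fragments per non-noise emission; the
#'   default puts the noise fraction of the set at 0.885.
#' @param chimera_rate,concat_rate,redundancy_rate per-true-emission
#'   probabilities of the corresponding artifact.
#' @param capture expected capture intensity of an average-abundance
#'   transcript; emission probability is \code{1 - exp(-capture * w / mean(w))}.
#' @param noise_len_meanlog,noise_len_sdlog lognormal noise fragment length
#'   (median 400 bp by default).
#' @param include_isoforms,exclude_isoforms isoform ids to force into or out
#'   of the emission, overriding the capture draw (used to plant
#'   set-exclusive isoforms).
#' @param set_label,seed as in \code{\link{emit_ccs_set}}.
#' @return the updated \code{sim_truth}.
#' @export
emit_assembly_set <- function(truth, style = c("hybrid", "shortread"),
                              noise_multiplier = 0.885 / 0.115,
                              chimera_rate = 0.05, concat_rate = 0.04,
                              redundancy_rate = 0.04,
                              capture = NULL,
                              noise_len_meanlog = log(400), noise_len_sdlog = 0.5,
                              include_isoforms = NULL, exclude_isoforms = NULL,
                              set_label = NULL, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  style <- match.arg(style)
  for (r in c(chimera_rate, concat_rate, redundancy_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (noise_multiplier < 0) stop("noise_multiplier must be >= 0")
  capture <- capture %||% switch(style, hybrid = 60, shortread = 40)
  set_label <- set_label %||% style
  seed <- seed %||% derive_seeds(truth$seed, 1L,
                                 salt = if (style == "hybrid") 3L else 4L)
  tx <- truth$transcripts
  w <- tx$abundance / sum(tx$abundance)

  with_seed(seed, {
    p <- 1 - exp(-capture * w / mean(w))
    emit <- runif(nrow(tx)) < p
    emit[tx$isoform_id %in% include_isoforms] <- TRUE
    emit[tx$isoform_id %in% exclude_isoforms] <- FALSE
    idx <- which(emit)
    n_true <- length(idx)

    seqs <- tx$sequence[idx]
    led <- ledger_row(sprintf("%s_%05d", set_label, seq_len(n_true)),
                      set_label, tx$isoform_id[idx], 0L, 0L, "faithful")
    means <- truth$isoform_means[tx$isoform_id[idx], , drop = FALSE]
    counter <- n_true

    new_emission <- function(seqn, row, mu) {
      seqs <<- c(seqs, seqn)
      led <<- rbind(led, row)
      means <<- rbind(means, mu)
      counter <<- counter + 1L
    }

    ## chimeras: 5' piece of one gene joined to the 3' piece of another
    n_chim <- rbinom(1L, n_true, chimera_rate)
    if (n_chim > 0 && length(unique(tx$gene_id[idx])) >= 2L) {
      for (j in seq_len(n_chim)) {
        repeat {
          pa <- sample(idx, 2L)
          if (tx$gene_id[pa[1]] != tx$gene_id[pa[2]]) break
        }
        a <- tx$sequence[pa[1]]; b <- tx$sequence[pa[2]]
        cut_a <- round(runif(1L, 0.45, 0.65) * nchar(a))
        cut_b <- round(runif(1L, 0.35, 0.55) * nchar(b))
        seqn <- paste0(substr(a, 1L, cut_a), substr(b, cut_b + 1L, nchar(b)))
        id <- sprintf("%s_%05d", set_label, counter + 1L)
        new_emission(seqn,
                     ledger_row(id, set_label, NA_character_, 0L, 0L, "chimera",
                                tx$isoform_id[pa[1]], tx$isoform_id[pa[2]]),
                     (truth$isoform_means[tx$isoform_id[pa[1]], , drop = FALSE] +
                      truth$isoform_means[tx$isoform_id[pa[2]], , drop = FALSE]) / 2)
      }
    }

    ## concatenations: two isoforms of one gene joined end to end
    n_con <- rbinom(1L, n_true, concat_rate)
    multi <- names(which(table(tx$gene_id) >= 2L))
    if (n_con > 0 && length(multi)) {
      for (j in seq_len(n_con)) {
        g <- sample(multi, 1L)
        iso <- which(tx$gene_id == g)
        pa <- if (length(iso) == 2L) iso else sample(iso, 2L)
        seqn <- paste0(tx$sequence[pa[1]], tx$sequence[pa[2]])
        id <- sprintf("%s_%05d", set_label, counter + 1L)
        new_emission(seqn,
                     ledger_row(id, set_label, NA_character_, 0L, 0L, "concatenation",
                                tx$isoform_id[pa[1]], tx$isoform_id[pa[2]]),
                     (truth$isoform_means[tx$isoform_id[pa[1]], , drop = FALSE] +
                      truth$isoform_means[tx$isoform_id[pa[2]], , drop = FALSE]) / 2)
      }
    }

    ## redundant near-duplicates of members of this set (92-99% identity)
    n_red <- rbinom(1L, n_true, redundancy_rate)
    if (n_red > 0 && n_true > 0) {
      for (j in seq_len(n_red)) {
        src <- sample(n_true, 1L)
        div <- runif(1L, 0.01, 0.08)
        seqn <- mutate_seq(tx$sequence[idx[src]], div)
        id <- sprintf("%s_%05d", set_label, counter + 1L)
        new_emission(seqn,
                     ledger_row(id, set_label, tx$isoform_id[idx[src]], 0L, 0L,
                                "redundant_variant", tx$isoform_id[idx[src]]),
                     truth$isoform_means[tx$isoform_id[idx[src]], , drop = FALSE] * 0.5)
      }
    }

    ## short low-expression noise fragments
    n_noise <- round(noise_multiplier * counter)
    if (n_noise > 0) {
      for (j in seq_len(n_noise)) {
        len <- max(150L, min(3000L, round(rlnorm(1L, noise_len_meanlog, noise_len_sdlog))))
        a <- runif(1L, 0.05, 2)
        id <- sprintf("%s_%05d", set_label, counter + 1L)
        mu <- matrix(a, 1L, length(TISSUES), dimnames = list(id, TISSUES))
        new_emission(random_dna(len),
                     ledger_row(id, set_label, NA_character_, 0L, 0L, "noise_fragment"),
                     mu)
      }
    }
  })

  names(seqs) <- led$unigene_id
  rownames(means) <- led$unigene_id
  add_emissions(truth, set_label, seqs, led, means)
}

#' Simulate tissue count matrices for emitted sets
#'
#' Draws negative-binomial counts for each emitted unigene in each of
#' \code{tissues * reps} samples. The mean of unigene i in sample s is
#' proportional to its inherited tissue abundance times its length times the
#' library size, so TPM computed from the counts recovers the assigned
#' TPM-scale abundance. Noise fragments carry their own low means; chimeras
#' and concatenations average their parents'; redundant variants split reads
#' with their source.
#'
#' @param truth a \code{sim_truth} with emitted sets.
#' @param sets set labels to simulate (default: all emitted).
#' @param tissues,reps study layout; sample names are \code{tissue_rep}.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); values below 1e-8 fall back to Poisson.
#' @param library_sizes single value or per-sample vector of total counts.
#' @param seed optional override seed.
#' @return the updated \code{sim_truth} with \code{counts[[set]]} matrices.
#' @export
simulate_counts <- function(truth, sets = names(truth$sets), tissues = 4,
                            reps = 3, dispersion = 0.05, library_sizes = 2e7,
                            seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (reps < 2) warning("fewer than 2 replicates: expression clustering will be degraded")
  if (tissues > length(TISSUES)) stop("at most ", length(TISSUES), " tissues supported")
  seed <- seed %||% derive_seeds(truth$seed, 1L, salt = 5L)
  tissue_names <- TISSUES[seq_len(tissues)]
  samples <- as.vector(t(outer(tissue_names, seq_len(reps), paste, sep = "_")))
  lib <- rep_len(library_sizes, length(samples))
  sub <- derive_seeds(seed, length(sets), salt = 6L)
  truth$counts <- truth$counts %||% list()
  for (si in seq_along(sets)) {
    s <- sets[si]
    ids <- names(truth$sets[[s]])
    if (!length(ids)) {
      truth$counts[[s]] <- matrix(0, 0, length(samples),
                                  dimnames = list(NULL, samples))
      next
    }
    mu_t <- truth$emission_means[ids, tissue_names, drop = FALSE]
    len <- nchar(truth$sets[[s]])
    cnt <- matrix(0, length(ids), length(samples),
                  dimnames = list(ids, samples))
    with_seed(sub[si], {
      for (j in seq_along(samples)) {
        t_idx <- (j - 1L) %/% reps + 1L
        mass <- mu_t[, t_idx] * len
        mu <- lib[j] * mass / sum(mass)
        cnt[, j] <- if (dispersion < 1e-8) rpois(length(mu), mu) else
          rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      }
    })
    attr(cnt, "mode") <- "counts"
    truth$counts[[s]] <- cnt
  }
  truth
}

#' Default simulated study
#'
#' Runs the full generator at its default study conditions: one CCS-like set
#' and two assembly-like sets (hybrid and short-read style) with an 88.5
#' percent noise fraction, followed by tissue count simulation for 4 tissues
#' x 3 replicates.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param ... passed to \code{\link{simulate_truth}}.
#' @return a \code{sim_truth} with sets \code{ccs}, \code{hybrid},
#'   \code{shortread} and matching count matrices.
#' @export
simulate_study <- function(seed = 42, n_genes = 120, ...) {
  truth <- simulate_truth(n_genes = n_genes, seed = seed, ...)
  truth <- emit_ccs_set(truth)
  truth <- emit_assembly_set(truth, style = "hybrid")
  truth <- emit_assembly_set(truth, style = "shortread")
  simulate_counts(truth)
}
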