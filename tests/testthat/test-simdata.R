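test_that("truth transcripts satisfy the construction invariants", {
  truth <- simulate_truth(n_genes = 1, isoforms_per_gene = list(mean_extra = 0, max = 1),
                          seed = 7)
  tx <- truth$transcripts
  expect_equal(nrow(tx), 1L)
  expect_equal((tx$cds_end - tx$cds_start) %% 3, 0)
  expect_gte(tx$cds_end - tx$cds_start, 300)
  expect_equal(substr(tx$sequence, tx$cds_start + 1, tx$cds_start + 3), "ATG")

  truth <- simulate_truth(n_genes = 40, seed = 3)
  tx <- truth$transcripts
  expect_true(all((tx$cds_end - tx$cds_start) %% 3 == 0))
  expect_true(all(tx$utr5_len == tx$cds_start))
  expect_true(all(tx$utr3_len == nchar(tx$sequence) - tx$cds_end))
  cds <- substr(tx$sequence, tx$cds_start + 1, tx$cds_end)
  ## no internal in-frame stop codon
  for (s in cds) {
    starts <- seq(1, nchar(s) - 2, 3)
    codons <- substring(s, starts, starts + 2)
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
  }
  ## total abundance is on the TPM scale
  expect_equal(sum(tx$abundance), 1e6, tolerance = 1e-6)
})

test_that("identical seeds give byte-identical truth and emissions", {
  t1 <- simulate_study(seed = 9, n_genes = 25)
  t2 <- simulate_study(seed = 9, n_genes = 25)
  expect_identical(t1$transcripts, t2$transcripts)
  expect_identical(t1$emissions, t2$emissions)
  expect_identical(t1$sets, t2$sets)
  expect_identical(t1$counts, t2$counts)
  t3 <- simulate_study(seed = 10, n_genes = 25)
  expect_false(identical(t1$emissions, t3$emissions))
})

test_that("isoform counts follow the configured distribution", {
  truth <- simulate_truth(n_genes = 200, isoforms_per_gene = list(mean_extra = 0.5, max = 4),
                          seed = 3)
  extra <- table(truth$transcripts$gene_id) - 1L
  ## mean of a Poisson(0.5) capped at 3; binomial sampling error ~ 3 sd
  capped_mean <- sum(pmin(0:10, 3) * dpois(0:10, 0.5))
  se <- sd(extra) / sqrt(length(extra))
  expect_lt(abs(mean(extra) - capped_mean), 4 * se + 1e-9)
})

test_that("CCS emission truncates, errs and under-samples as configured", {
  truth <- simulate_truth(n_genes = 30, seed = 5)
  ## no-noise limit: emissions equal their source transcripts exactly
  clean <- emit_ccs_set(truth, sampling_depth = 1e5, trunc_mean = 0,
                        error_rate = 0)
  led <- clean$emissions
  src <- truth$transcripts$sequence[match(led$source_isoform,
                                          truth$transcripts$isoform_id)]
  expect_identical(unname(clean$sets$ccs), src)
  expect_true(all(led$label == "faithful"))

  ## truncated fraction matches the closed-form geometric mass
  truth2 <- simulate_truth(n_genes = 150, seed = 8)
  ccs <- emit_ccs_set(truth2, sampling_depth = 1e5, trunc_mean = 30,
                      error_rate = 0)
  led <- ccs$emissions
  frac <- mean(led$trunc5 + led$trunc3 > 0)
  p0 <- 1 / 31  # P(geometric draw = 0) at mean 30
  want <- 1 - p0^2
  se <- sqrt(want * (1 - want) / nrow(led))
  expect_lt(abs(frac - want), 4 * se + 0.01)
  ## truncation never eats into the CDS
  tx <- truth2$transcripts[match(led$source_isoform, truth2$transcripts$isoform_id), ]
  expect_true(all(led$trunc5 <= tx$utr5_len))
  expect_true(all(led$trunc3 <= tx$utr3_len))

  ## the lowest-expression decile is mostly absent at small depth
  truth3 <- simulate_truth(n_genes = 100, seed = 2)
  w <- truth3$transcripts$abundance
  low <- truth3$transcripts$isoform_id[w <= quantile(w, 0.1)]
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    e <- emit_ccs_set(truth3, sampling_depth = 300, seed = s)
    total <- total + length(low)
    hits <- hits + sum(low %in% e$emissions$source_isoform)
  }
  expect_lte(hits / total, 0.20)
})

test_that("assembly emission plants noise, chimeras and redundancy at rate", {
  truth <- simulate_truth(n_genes = 60, seed = 13)
  ## clean limit: exactly the captured truth transcripts, full length
  clean <- emit_assembly_set(truth, style = "hybrid", noise_multiplier = 0,
                             chimera_rate = 0, concat_rate = 0,
                             redundancy_rate = 0, capture = 1e6)
  led <- clean$emissions
  expect_setequal(led$source_isoform, truth$transcripts$isoform_id)
  expect_identical(unname(clean$sets$hybrid),
                   truth$transcripts$sequence[match(led$source_isoform,
                                                    truth$transcripts$isoform_id)])

  ## default noise multiplier yields the configured noise fraction
  full <- emit_assembly_set(truth, style = "shortread")
  led <- full$emissions[full$emissions$set_label == "shortread", ]
  expect_lt(abs(mean(led$label == "noise_fragment") - 0.885), 0.01)

  ## chimera count is binomial around rate * n_true
  truth2 <- simulate_truth(n_genes = 200, isoforms_per_gene = list(mean_extra = 0, max = 1),
                           seed = 11)
  e <- emit_assembly_set(truth2, style = "hybrid", chimera_rate = 0.05,
                         capture = 1e6, noise_multiplier = 0)
  led <- e$emissions
  n_true <- sum(led$label == "faithful")
  n_chim <- sum(led$label == "chimera")
  sd3 <- 3 * sqrt(n_true * 0.05 * 0.95)
  expect_lt(abs(n_chim - 0.05 * n_true), sd3)
  ## chimera and concatenation rows carry exactly two parents
  two <- led[led$label %in% c("chimera", "concatenation"), ]
  expect_true(all(!is.na(two$parent1) & !is.na(two$parent2)))
  expect_true(all(is.na(led$parent1[led$label == "noise_fragment"])))

  expect_error(emit_assembly_set(truth, chimera_rate = 1.5), "rates")
})

test_that("every emitted sequence has exactly one ledger row", {
  truth <- simulate_study(seed = 4, n_genes = 30)
  for (s in names(truth$sets)) {
    ids <- names(truth$sets[[s]])
    rows <- truth$emissions[truth$emissions$set_label == s, ]
    expect_setequal(ids, rows$unigene_id)
    expect_equal(anyDuplicated(rows$unigene_id), 0L)
  }
  expect_equal(anyDuplicated(truth$emissions$unigene_id), 0L)
})

test_that("simulated counts follow the negative-binomial model", {
  truth <- simulate_truth(n_genes = 40, seed = 6)
  truth <- emit_assembly_set(truth, style = "hybrid", noise_multiplier = 0,
                             chimera_rate = 0, concat_rate = 0,
                             redundancy_rate = 0, capture = 1e6)

  ## Poisson limit: variance/mean ratio near 1 across unigenes
  pois <- simulate_counts(truth, dispersion = 0, library_sizes = 5e6, seed = 1)
  cnt <- pois$counts$hybrid
  tiss <- sub("_[0-9]+$", "", colnames(cnt))
  ratios <- unlist(lapply(unique(tiss), function(t) {
    m <- cnt[, tiss == t, drop = FALSE]
    mu <- rowMeans(m)
    keep <- mu > 50
    apply(m[keep, ], 1, var) / mu[keep]
  }))
  expect_lt(abs(mean(ratios) - 1), 0.15)

  ## symmetry: equal means and lengths give TPM ~ 1e6 / n
  n <- 50
  seqs <- setNames(vapply(rep(1000, n), random_seq, character(1)),
                   sprintf("u%02d", 1:n))
  truth_eq <- simulate_truth(n_genes = 5, seed = 3)
  truth_eq$sets$flat <- seqs
  truth_eq$emission_means <- rbind(
    truth_eq$emission_means,
    matrix(100, n, 4, dimnames = list(names(seqs),
                                      colnames(truth_eq$isoform_means))))
  truth_eq <- simulate_counts(truth_eq, sets = "flat", dispersion = 0.01,
                              library_sizes = 2e7, seed = 2)
  tpm <- compute_tpm(truth_eq$counts$flat, nchar(seqs))
  expect_lt(max(abs(rowMeans(tpm) - 1e6 / n) / (1e6 / n)), 0.15)

  ## pattern a (leaf+root high): root mean TPM above flower mean TPM
  truth_p <- simulate_truth(n_genes = 50, seed = 12)
  truth_p <- emit_assembly_set(truth_p, style = "hybrid", noise_multiplier = 0,
                               chimera_rate = 0, concat_rate = 0,
                               redundancy_rate = 0, capture = 1e6)
  wins <- 0L
  for (s in 1:20) {
    cc <- simulate_counts(truth_p, library_sizes = 5e6, seed = s)
    tpm <- compute_tpm(cc$counts$hybrid, nchar(cc$sets$hybrid))
    led <- cc$emissions
    pat <- cc$transcripts$pattern[match(led$source_isoform,
                                        cc$transcripts$isoform_id)]
    a_ids <- led$unigene_id[pat == "a"]
    root <- rowMeans(tpm[a_ids, grepl("^root", colnames(tpm)), drop = FALSE])
    flower <- rowMeans(tpm[a_ids, grepl("^flower", colnames(tpm)), drop = FALSE])
    if (mean(root) > mean(flower)) wins <- wins + 1L
  }
  expect_gte(wins / 20, 0.95)

  expect_warning(simulate_counts(truth, reps = 1, seed = 1), "replicates")
})
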