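test_that("greedy collapse removes duplicates and keeps unrelated sequences", {
  set.seed(61)
  a <- random_seq(400)
  dd <- dedup_greedy(c(x = a, y = a))
  expect_equal(length(dd$representatives), 1L)
  expect_equal(length(dd$redundant), 1L)

  unrelated <- setNames(vapply(sample(200:500, 30, TRUE), random_seq, character(1)),
                        sprintf("u%02d", 1:30))
  dd <- dedup_greedy(unrelated)
  expect_setequal(dd$representatives, names(unrelated))

  ## a sequence contained in a longer one is redundant (shorter-seq identity)
  contained <- c(long = a, short = substr(a, 50, 349))
  dd <- dedup_greedy(contained)
  expect_equal(dd$representatives, "long")
  expect_equal(unname(dd$redundant["short"]), "long")
})

test_that("greedy collapse equals the all-pairs brute-force oracle", {
  set.seed(62)
  for (i in 1:25) {
    n_base <- sample(3:8, 1)
    seqs <- character()
    for (b in seq_len(n_base)) {
      base <- random_seq(sample(150:400, 1))
      seqs[sprintf("b%02d_0", b)] <- base
      for (cpy in seq_len(sample(0:2, 1))) {
        div <- runif(1, 0.01, 0.08)
        dup <- mutate_at_rate(base, div)
        if (runif(1) < 0.3) dup <- substr(dup, 1, round(nchar(dup) * runif(1, 0.6, 0.95)))
        seqs[sprintf("b%02d_%d", b, cpy)] <- dup
      }
    }
    got <- dedup_greedy(seqs, identity_threshold = 0.90)
    want <- oracle_dedup(seqs, threshold = 0.90)
    expect_setequal(got$representatives, want$representatives)
    expect_equal(sort(names(got$redundant)), sort(names(want$redundant)))
    expect_equal(unname(got$redundant[sort(names(got$redundant))]),
                 unname(want$redundant[sort(names(want$redundant))]))
  }
})

test_that("three copies across three sets form one group anchored on the first set", {
  set.seed(63)
  a <- random_seq(800)
  g <- build_groups(list(ccs = c(c1 = substr(a, 30, 770)),
                         s2 = c(h1 = a), s3 = c(t1 = a)))
  expect_equal(length(unique(g$members$group_id)), 1L)
  expect_equal(g$members$unigene_id[g$members$is_rep], "c1")

  ## unrelated members stay singletons
  g2 <- build_groups(list(ccs = c(c1 = random_seq(600)),
                          s2 = c(h1 = random_seq(600))))
  expect_equal(length(unique(g2$members$group_id)), 2L)
})

test_that("groups partition the member universe", {
  run <- get_default_run()
  members <- run$groups$members
  expect_equal(anyDuplicated(members$unigene_id), 0L)
  all_coding <- unlist(lapply(names(run$sets), function(s) {
    ids <- run$dedup[[s]]$representatives
    ids[ids %in% run$cds$unigene_id]
  }))
  expect_setequal(members$unigene_id, all_coding)
})

test_that("UTR extensions are called with exact evidence", {
  set.seed(64)
  core <- random_seq(900)
  ext <- paste0(random_seq(50), core, random_seq(50))
  g <- build_groups(list(ccs = c(anchor = core), s2 = c(longer = ext)))
  calls <- classify_members(g)
  e5 <- calls[calls$call == "utr5_extension", ]
  e3 <- calls[calls$call == "utr3_extension", ]
  expect_equal(e5$unigene_id, "longer")
  expect_equal(e5$ev_ext5, 50)
  expect_equal(e3$ev_ext3, 50)
  ## anchored member is the faithful reference
  expect_equal(calls$call[calls$unigene_id == "anchor"], "faithful")
})

test_that("a concatenation of two relatives is recognised and cited", {
  set.seed(65)
  utr5 <- random_seq(80); utr3 <- random_seq(90)
  backbone <- random_seq(600)
  iso1 <- paste0(utr5, backbone, utr3)
  iso2 <- paste0(utr5, substr(backbone, 1, 300), random_seq(90),
                 substr(backbone, 301, 600), utr3)
  concat <- paste0(iso1, iso2)
  g <- build_groups(list(ccs = c(c_iso1 = substr(iso1, 41, nchar(iso1) - 30)),
                         s2 = c(h_cat = concat),
                         s3 = c(t_iso1 = iso1, t_iso2 = iso2)))
  calls <- classify_members(g)
  cat_call <- calls[calls$call == "concatenation", ]
  expect_equal(unique(cat_call$unigene_id), "h_cat")
  expect_true(all(c(cat_call$partner1, cat_call$partner2) %in%
                  c("t_iso1", "t_iso2", "c_iso1")))
  ## the concatenation also evidences both truncated ends of the anchor
  expect_equal(sort(calls$call[calls$unigene_id == "h_cat"]),
               sort(c("concatenation", "utr5_extension", "utr3_extension")))
  e <- calls[calls$unigene_id == "h_cat" & calls$call == "utr5_extension", ]
  expect_equal(e$ev_ext5, 40)
})

test_that("a chimera bridging two genes is flagged, not its neighbours", {
  set.seed(66)
  geneA <- random_seq(1000)
  geneB <- random_seq(1100)
  chim <- paste0(substr(geneA, 1, 550), substr(geneB, 500, 1100))
  g <- build_groups(list(ccs = c(a1 = geneA, b1 = geneB),
                         s2 = c(mix = chim, a2 = geneA, b2 = geneB)))
  expect_equal(length(unique(g$members$group_id)), 1L)  # merged by the bridge
  calls <- classify_members(g)
  expect_equal(calls$call[calls$unigene_id == "mix"], "chimera")
  others <- calls[calls$unigene_id != "mix", ]
  expect_false(any(others$call %in% c("chimera", "concatenation")))
  ## partners come from the two different sides
  cp <- calls[calls$unigene_id == "mix", c("partner1", "partner2")]
  sideA <- c("a1", "a2"); sideB <- c("b1", "b2")
  expect_true((cp$partner1 %in% sideA) != (cp$partner2 %in% sideA))
})

test_that("chimera flagging is order-independent", {
  set.seed(67)
  geneA <- random_seq(900); geneB <- random_seq(950)
  chim <- paste0(substr(geneA, 1, 500), substr(geneB, 400, 950))
  sets1 <- list(ccs = c(a1 = geneA, b1 = geneB), s2 = c(mix = chim, a2 = geneA))
  sets2 <- list(ccs = c(b1 = geneB, a1 = geneA), s2 = c(a2 = geneA, mix = chim))
  c1 <- classify_members(build_groups(sets1))
  c2 <- classify_members(build_groups(sets2))
  c1 <- c1[order(c1$unigene_id, c1$call), c("unigene_id", "call")]
  c2 <- c2[order(c2$unigene_id, c2$call), c("unigene_id", "call")]
  rownames(c1) <- rownames(c2) <- NULL
  expect_equal(c1, c2)
})

test_that("isoform variants are separated from indel jitter by the gap floor", {
  set.seed(68)
  utr5 <- random_seq(60); utr3 <- random_seq(70)
  backbone <- random_seq(700)
  base <- paste0(utr5, backbone, utr3)
  variant <- paste0(utr5, substr(backbone, 1, 350), random_seq(80),
                    substr(backbone, 351, 700), utr3)
  g <- build_groups(list(ccs = c(anchor = base), s2 = c(var = variant)))
  calls <- classify_members(g)
  iso <- calls[calls$call == "isoform_variant", ]
  expect_equal(iso$unigene_id, "var")
  expect_lte(abs(iso$ev_gap - 80), 28)  # +/- (k-1) per junction side
})

test_that("summary bookkeeping matches membership and exclusivity", {
  set.seed(69)
  base <- random_seq(800)
  g <- build_groups(list(ccs = c(c1 = base), s2 = c(h1 = base)))
  calls <- classify_members(g)
  rep1 <- summarize_reconcile(g, calls)
  expect_equal(rep1$per_set$members, c(1L, 1L))
  expect_equal(rep1$per_set$isoform_only, c(0L, 0L))
  ## removing one set's members increments that set's missing count
  expect_equal(rep1$per_set$missing_groups, c(0L, 0L))
  g2 <- build_groups(list(ccs = c(c1 = base), s2 = c(h1 = random_seq(700))))
  rep2 <- summarize_reconcile(g2, classify_members(g2))
  expect_equal(rep2$per_set$missing_groups[rep2$per_set$set_label == "ccs"], 1L)
  expect_equal(rep2$per_set$missing_groups[rep2$per_set$set_label == "s2"], 1L)
})

test_that("planted set-exclusive isoforms are reported for their set only", {
  sc <- plant_exclusive_scenario(seed = 42, n_plant = 6)
  run <- run_pipeline(truth = sc$truth)
  led <- run$truth$emissions
  planted_emis <- led$unigene_id[led$set_label == "hybrid" &
                                 led$source_isoform %in% sc$planted]
  found <- planted_emis %in% run$report$exclusive_isoforms
  expect_gte(mean(found), 0.9)
  per <- run$report$per_set
  expect_gte(per$isoform_only[per$set_label == "hybrid"], length(sc$planted) - 1)
  expect_equal(per$isoform_only[per$set_label == "shortread"], 0L)
})
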