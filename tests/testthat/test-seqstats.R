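test_that("FASTA round-trips and rejects malformed input", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "GGCC"), tmp)
  x <- read_fasta(tmp)
  expect_equal(length(x), 2L)
  expect_equal(unname(Biostrings::width(x)), c(4L, 4L))

  set.seed(11)
  seqs <- vapply(sample(50:300, 200, TRUE), random_seq, character(1))
  names(seqs) <- sprintf("u%03d", seq_along(seqs))
  out <- tempfile(fileext = ".fasta")
  write_fasta(seqs, out, width = 80)
  back <- as.character(read_fasta(out))
  expect_identical(back, seqs)

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(read_fasta(dup), "a")
})

test_that("length statistics match the brute-force oracle", {
  expect_equal(length_stats(c(x = strrep("A", 100)))$n50, 100)
  st <- length_stats(c(a = strrep("A", 50), b = strrep("A", 50),
                       c = strrep("A", 100)))
  expect_equal(st$n50, 100)
  expect_equal(length_stats(c(x = "GGCC"))$gc_ratio, 100)
  expect_equal(length_stats(c(x = "ACGT"))$gc_ratio, 50)
  ## N is excluded from the GC denominator
  expect_equal(length_stats(c(x = "GCNN"))$gc_ratio, 100)

  set.seed(21)
  for (i in 1:60) {
    n <- sample(1:40, 1)
    seqs <- vapply(sample(10:500, n, TRUE), random_seq, character(1))
    names(seqs) <- sprintf("s%02d", seq_len(n))
    got <- length_stats(seqs)
    want <- oracle_length_stats(seqs)
    expect_equal(got$n, want$n)
    expect_equal(got$max_len, want$max_len)
    expect_equal(got$mean_len, want$mean_len)
    expect_equal(got$median_len, want$median_len)
    expect_equal(got$n50, want$n50)
    expect_equal(got$gc_ratio, want$gc_ratio, tolerance = 1e-12)
  }
  expect_error(length_stats(character()), "empty")
})

test_that("TPM columns sum to one million and scale invariance holds", {
  counts <- matrix(c(10, 10), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(counts, c(a = 1000, b = 1000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))

  counts <- matrix(c(0, 5), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(compute_tpm(counts, c(a = 100, b = 200))[, 1]), c(0, 1e6))

  counts <- matrix(c(3, 7, 10), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  tpm <- compute_tpm(counts, c(a = 300, b = 700, c = 1000))
  expect_equal(unname(tpm[, 1]), rep(1e6 / 3, 3), tolerance = 1e-9)

  set.seed(5)
  for (i in 1:40) {
    n <- sample(2:60, 1); p <- sample(1:6, 1)
    cnt <- matrix(rpois(n * p, 50), n, p,
                  dimnames = list(sprintf("u%02d", 1:n), sprintf("s%d", 1:p)))
    len <- setNames(sample(200:3000, n, TRUE), rownames(cnt))
    tpm <- compute_tpm(cnt, len)
    expect_true(all(abs(colSums(tpm) - 1e6) <= 1e6 * 1e-6))
    sc <- compute_tpm(sweep(cnt, 2, c(2, rep(1, p - 1)), "*")[, 1, drop = FALSE],
                      len)
    expect_equal(sc[, 1], tpm[, 1], tolerance = 1e-9)
  }

  expect_error(compute_tpm(matrix(1, 1, 1, dimnames = list("a", "s")),
                           c(b = 10)), "a")
  zero <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_warning(z <- compute_tpm(zero, c(a = 10, b = 10)), "all-zero")
  expect_true(all(z == 0))
})

test_that("expression tables round-trip through TSV", {
  m <- matrix(rpois(12, 20), 4, 3,
              dimnames = list(sprintf("u%d", 1:4), c("root_1", "root_2", "leaf_1")))
  tmp <- tempfile(fileext = ".tsv")
  write_expression(m, tmp)
  back <- read_expression(tmp)
  expect_equal(unclass(back)[seq_along(m)], as.double(m))
  expect_equal(rownames(back), rownames(m))
})
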