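#' @importFrom stats rbinom rgeom rlnorm rnbinom rpois runif sd dist cutree median
#' @importFrom utils head read.delim write.table
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Coerce a unigene set (DNAStringSet or named character vector) to a named,
## upper-case character vector. Names are required and must be unique.
as_seqs <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("unigene set must be a character vector or DNAStringSet")
  if (!length(x)) return(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("all sequences must be named")
  }
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup)) stop("duplicate unigene ids: ", paste(dup, collapse = ", "))
  toupper(x)
}

## One top-level seed fans out into per-stage sub-seeds so that adding a stage
## never perturbs the stream of another. Values stay below 2^31.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed((as.integer(seed) + 7919L * as.integer(salt)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Substitute bases at the given per-base rate, never into the original base.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  if (!length(hit)) return(seq)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}
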