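## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that simulators are reproducible without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Keeps independent simulators decoupled when driven from one master seed.
#' Result is kept within the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562L) + 1L
}

#' Random integer composition: `n` parts >= `min_each` summing to `total`
#' @noRd
partition_int <- function(total, n, min_each = 1L) {
  total <- as.integer(total)
  n <- as.integer(n)
  if (n == 0L) {
    if (total != 0L) stop("partition_int: cannot split ", total, " into 0 parts")
    return(integer(0))
  }
  extra <- total - n * min_each
  if (extra < 0L) {
    stop("infeasible partition: ", total, " nt cannot cover ", n,
         " parts of at least ", min_each, " nt each")
  }
  as.integer(rmultinom(1L, extra, rep(1 / n, n))[, 1L]) + min_each
}

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Codon bookkeeping built on the standard genetic code shipped with
## Biostrings; stop codons are TAA/TAG/TGA.
stop_codons <- function() {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
}

sense_codons <- function() {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
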