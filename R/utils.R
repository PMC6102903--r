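#' @useDynLib phageome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef rlnorm
#' @importFrom utils read.table write.table
NULL

# run code under a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Reverse-complement a nucleotide string
#'
#' @param seq a single nucleotide string (IUPAC bases; non-ACGT become N).
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_revcomp(seq)
}
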