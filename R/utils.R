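# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that simulation functions are
#' deterministic under their `seed` argument without disturbing the caller's
#' RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Derive a stream-specific child seed from a master seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  (as.double(seed) * 1009 + offset) %% 2147483647
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# sort order used everywhere: chromosome (as character), then start
genomic_order <- function(chrom, start) {
  order(as.character(chrom), start)
}

is_genomically_sorted <- function(chrom, start) {
  identical(seq_along(start), genomic_order(chrom, start))
}
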