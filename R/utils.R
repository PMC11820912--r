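# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user-level streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Numerically stable softmax
#'
#' @param x A numeric vector of logits, or a matrix whose rows are logit
#'   vectors.
#' @return Probabilities of the same shape; each vector/row is nonnegative and
#'   sums to one. Invariant under adding a constant to all logits.
#' @examples
#' softmax(c(0, 0))       # 0.5 0.5
#' softmax(c(3, 3) + 10)  # unchanged by the shift
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

# Row-wise softmax for matrices (kept separate so the hot path avoids the
# is.matrix() branch and apply() overhead).
softmax_rows <- function(x) {
  m <- as.numeric(do.call(pmax, lapply(seq_len(ncol(x)), function(j) x[, j])))
  e <- exp(x - m)
  e / rowSums(e)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}
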