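# Internal utilities: scoped seeding and deterministic seed derivation.

# Evaluate `expr` under a temporary RNG seed, restoring the global RNG state
# afterwards. With seed = NULL the expression runs on the ambient RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed
#'
#' Mixes a master seed with stream identifiers (e.g. iteration number and
#' population index) into a new seed below 2^31, so that every episode and
#' every sampling round in a training run is independently reproducible and
#' independent of evaluation order.
#'
#' @param ... integers to mix (master seed first).
#' @return a single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  if (any(!is.finite(parts))) stop("seed components must be finite")
  z <- 11.0
  m <- 2147483647  # 2^31 - 1
  for (v in parts) {
    # multiplier small enough that z * 69069 + v stays exact in doubles
    z <- (z * 69069 + (v %% m) + 1) %% m
  }
  as.integer(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relu <- function(x) pmax(x, 0)
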