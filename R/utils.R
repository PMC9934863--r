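#' @importFrom rlang abort warn .data
#' @importFrom stats lm coef quantile rbinom runif rnorm rbeta sd var predict
#'   complete.cases prcomp setNames
#' @importFrom utils combn head tail
NULL

# Evaluate `code` with a temporarily fixed RNG state, restoring the caller's.
with_seed <- function(seed, code) {
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
    set.seed(seed)
  }
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Counter-based derivation so pipeline stages can be rerun independently
#' while all randomness flows from a single master seed. Results stay below
#' 2^31 so they are valid R integer seeds.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (0, 1, 2, ...).
#' @return An integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), is.numeric(stage))
  as.integer((abs(master) * 48271 + stage * 16807 + 12345) %% 2147483647L)
}

check_probability <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

check_positive <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite.", name))
  }
  invisible(x)
}
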