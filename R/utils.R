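# Internal helpers: seed plumbing and input checks.

#' Derive a reproducible child seed from a master seed and a key string
#'
#' All stochastic stages (noise injection, the synthetic generator) draw their
#' seeds through this function so that a single master seed determines every
#' random draw in a dataset or grid run, independent of evaluation order.
#'
#' @param master integer master seed.
#' @param key character scalar naming the consumer (e.g. "seq03/a/WCLC_125...").
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds inside R's int range
  h <- (master %% m)
  for (cp in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 31 + cp) %% m
  }
  as.integer(h)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}
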