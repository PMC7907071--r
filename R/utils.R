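# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# derive a deterministic substream seed from a master seed; keeps
# results below 2^31 so they remain valid R integers
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

# fixed-decimal rendering; round() in R is round-half-to-even, which is
# what the report layer promises
fmt_num <- function(x, digits) {
  formatC(round(x, digits), format = "f", digits = digits)
}

z_quantile <- function(level) stats::qnorm(1 - (1 - level) / 2)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number in (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}

assert_positive_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}
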