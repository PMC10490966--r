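# Internal helpers shared across modules.

# Round half away from zero (printed tables use this convention, whereas
# base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible sub-stream seed from a master seed and a text tag,
# so that adding pipeline stages or epochs never perturbs the draws of
# earlier ones. Keeps the result in [1, 2^31 - 2].
substream_seed <- function(master, tag) {
  h <- 0
  for (k in utf8ToInt(as.character(tag))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 * 69069 + h) %% 2147483645 + 1)
}

# Evaluate expr under a temporary RNG state seeded from (master, tag).
with_substream <- function(master, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, tag))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
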