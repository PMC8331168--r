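#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All stochastic steps in the pipeline draw from streams derived by stable
#' named sub-seeding of one root seed, so partial reruns (say, regenerating
#' chromatograms without redrawing the spectral library) stay reproducible.
#' The derivation is a small multiplicative hash of the stream name folded
#' into the root seed, kept inside the 32-bit signed integer range.
#'
#' @param seed integer root seed.
#' @param name character scalar naming the stream (e.g. `"library"`,
#'   `"xic-noise"`).
#' @return an integer seed, deterministic in `(seed, name)`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L, nchar(name) > 0L)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% m
  as.integer((abs(as.numeric(seed)) %% m + h * 7919) %% m)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
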