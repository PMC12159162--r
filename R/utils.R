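#' @keywords internal
"_PACKAGE"

# Deterministic per-component RNG substream: one top-level seed, offset by a
# stable hash of the component name so components draw independent streams.
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) + h) %% .Machine$integer.max)
}

with_substream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, component))
  force(expr)
}

#' Min-max scale a numeric vector to [0, 1]
#'
#' Constant vectors (max equals min) are mapped to all zeros with a warning,
#' mirroring how degenerate statistics are displayed in dot heatmaps.
#'
#' @param x numeric vector, all finite.
#' @return numeric vector in \[0, 1\].
#' @export
minmax_scale <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  rng <- range(x)
  if (rng[2] == rng[1]) {
    warning("constant vector: min-max scaling degenerate, returning zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
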