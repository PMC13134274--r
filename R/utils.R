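#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor ecdf kmeans median p.adjust pt quantile rbinom rexp
#'   rlnorm rnorm rpois runif sd setNames t.test var wilcox.test fisher.test
#'   phyper complete.cases
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic stages of the package draw their randomness from one master
#' seed via named substreams, so an individual data layer (e.g. only the Hi-C
#' matrices) can be regenerated without replaying the whole simulation.
#'
#' @param seed master integer seed.
#' @param name character scalar naming the substream.
#' @return an integer seed in [0, 2^31).
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
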