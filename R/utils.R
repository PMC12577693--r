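#' @importFrom stats cor loess median p.adjust pnorm predict quantile rnbinom
#'   rnorm runif sd setNames var wilcox.test rmultinom
#' @importFrom utils read.csv write.csv head
NULL

BRAIN_REGIONS <- c("forebrain", "hindbrain", "midbrain")
SUBREGIONS <- c("dorsal", "ventral")

#' Derive a child seed from a master seed and a stage tag
#'
#' All stochastic stages of the pipeline draw their seed from a single master
#' seed via this function, so each stage is independently reproducible.
#'
#' @param seed master integer seed
#' @param tag character stage tag
#' @return an integer seed < 2^31
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# argmax with lexicographic tie-break on names
argmax_lex <- function(x) {
  stopifnot(!is.null(names(x)))
  m <- max(x)
  cand <- sort(names(x)[x == m])
  cand[[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
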