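## small shared helpers (internal)

logit <- function(p) log(p) - log1p(-p)

invlogit <- function(x) {
  ## numerically stable on both tails
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' Derive a stage-specific random seed
#'
#' All randomness in the package flows from a single master seed; each stage
#' (simulation, fitting starts, MCMC, bootstrap) uses an independent substream
#' derived deterministically from the master seed and a stage label, so that
#' re-running one stage never perturbs another.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ## multiplicative hash mod a prime below 2^31
  p <- 2147483629
  as.integer((abs(seed) %% p) * 48271 %% p + h * 16807 %% p) %% p + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Highest density interval of a sample
#'
#' Narrowest contiguous interval containing a given fraction of the draws.
#'
#' @param draws numeric vector of posterior draws.
#' @param mass interval mass, default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(is.numeric(draws), length(draws) >= 2, mass > 0, mass < 1)
  x <- sort(draws)
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(x[i], x[i + k])
}

stop_ct <- function(...) stop(sprintf(...), call. = FALSE)

warn_ct <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
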