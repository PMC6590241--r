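# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in msiqc take an explicit `seed` argument and
#' route their draws through this helper, so that a call is reproducible and
#' never perturbs the global random-number stream of the session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single integer, got %s", deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic counter scheme: stage `k` of master seed `s` uses
#' `(s + 99991 * k) mod (2^31 - 1)`, kept strictly positive. One master seed
#' therefore fixes every random draw of a multi-stage pipeline run.
#'
#' @param master Master integer seed.
#' @param stage Stage counter (non-negative integer).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stage) {
  m <- 2147483647
  s <- (as.double(master) %% m + 99991 * (as.double(stage) %% m)) %% m
  as.integer(if (s == 0) 1 else s)
}

# Percentile with linear interpolation between order statistics (type 7),
# the convention fixed by the package for all percentile computations.
pct_quantile <- function(x, pct) {
  stats::quantile(x, probs = pct / 100, type = 7, names = FALSE)
}

# Odd window length (in points) covering `width` units on an axis with
# median spacing `spacing`, clamped to [3, n (odd)].
odd_window <- function(width, spacing, n) {
  k <- max(3L, as.integer(round(width / spacing)))
  if (k %% 2L == 0L) k <- k + 1L
  kmax <- if (n %% 2L == 1L) n else n - 1L
  min(k, max(kmax, 3L))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
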