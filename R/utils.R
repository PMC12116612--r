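#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict rnorm runif rbinom rbeta qnorm pnorm dnorm
#'   sd approx uniroot setNames cor
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_semg <- function(msg, class) {
  stop(structure(class = c(class, "semgcobb_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

MEASUREMENT_WEEKS <- c(0L, 8L, 16L, 24L)

assert_week <- function(week) {
  if (!is_scalar_number(week) || !(week %in% MEASUREMENT_WEEKS)) {
    abort_semg(sprintf("`week` must be one of {%s}, got %s",
                       paste(MEASUREMENT_WEEKS, collapse = ", "),
                       paste(week, collapse = ",")),
               "semgcobb_bad_week")
  }
  as.integer(week)
}

# Truncated-normal sampler via inverse CDF; exact on [lo, hi].
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

tnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

# Truncated normal whose *truncated* mean equals `target_mean`: the latent
# location is solved so truncation does not shift the requested moment.
rtruncnorm_cal <- function(n, target_mean, sd, lo, hi) {
  if (sd == 0 || n == 0L) return(rep(pmin(pmax(target_mean, lo), hi), n))
  f <- function(mu) tnorm_mean(mu, sd, lo, hi) - target_mean
  mu <- uniroot(f, lower = target_mean - 6 * sd, upper = target_mean + 6 * sd,
                tol = 1e-10)$root
  rtruncnorm(n, mu, sd, lo, hi)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
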