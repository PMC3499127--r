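# Internal numeric helpers shared across modules.

# Probability floor/ceiling that keeps log-likelihoods finite.
.PROB_EPS <- 1e-9

.clipProb <- function(p, eps = .PROB_EPS) pmin(pmax(p, eps), 1 - eps)

# Wrap an angle to [0, 2*pi).
.wrap2pi <- function(a) a %% (2 * pi)

# Wrap an angle to (-pi, pi].
.wrapPi <- function(a) {
  s <- a %% (2 * pi)
  ifelse(s > pi, s - 2 * pi, s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates in the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Expands one user-supplied seed into independent per-component seeds via a
#' small counter-based hash, so that adding a component to a pipeline does not
#' perturb the random draws of the others. The result is always a positive
#' integer below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stream Character label of the consuming component.
#' @param index Optional integer counter (e.g. replicate number).
#' @return A single integer seed.
#' @examples
#' deriveSeed(1, "ring")
#' deriveSeed(1, "ring", 2)
#' @export
deriveSeed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(1 + (h * 7919 + as.numeric(index)) %% (m - 1))
}

# Wilson score interval for a binomial proportion.
.wilsonCI <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
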