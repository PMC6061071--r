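#' Confluent hypergeometric function 1F1 (Kummer's M) for complex argument
#'
#' Evaluates \eqn{{}_1F_1(a; b; x) = \sum_k (a)_k / (b)_k \, x^k / k!} for real
#' parameters `a`, `b` and complex argument `x`, vectorised over `x`.
#'
#' For `Re(x) < 0` the Kummer transformation
#' \eqn{M(a,b,x) = e^x M(b-a, b, -x)} is applied first, so that the series is
#' summed at an argument with non-negative real part; this controls the
#' catastrophic cancellation that the raw series suffers for large negative
#' real parts.
#'
#' @param a,b numeric scalars; `b` must not be a non-positive integer.
#' @param x complex (or numeric) vector.
#' @param tol termination tolerance for the series, relative to the running sum.
#' @param max_terms maximum number of series terms.
#' @return complex vector of the same length as `x`.
#' @export
kummer_m <- function(a, b, x, tol = 1e-16, max_terms = 2000) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L)
    stop("'a' and 'b' must be numeric scalars")
  if (abs(b - round(b)) < .Machine$double.eps * 4 && round(b) <= 0)
    stop("1F1 undefined: denominator parameter b = ", b,
         " is a non-positive integer")
  x <- as.complex(x)
  out <- complex(length(x))
  neg <- Re(x) < 0
  if (any(neg)) out[neg] <- exp(x[neg]) * .kummer_series(b - a, b, -x[neg], tol, max_terms)
  if (any(!neg)) out[!neg] <- .kummer_series(a, b, x[!neg], tol, max_terms)
  out
}

.kummer_series <- function(a, b, x, tol, max_terms) {
  term <- rep(1 + 0i, length(x))
  s <- term
  for (j in 0:max_terms) {
    term <- term * ((a + j) / (b + j)) * x / (j + 1)
    s <- s + term
    if (all(abs(term) <= tol * (abs(s) + 1))) return(s)
  }
  warning("1F1 series did not converge to tolerance; returning partial sum")
  s
}

#' Complex dilogarithm
#'
#' Evaluates \eqn{\mathrm{Li}_2(z) = \sum_{k\ge1} z^k/k^2} (principal branch)
#' for complex `z`, vectorised. The argument is mapped into the unit disc by
#' the inversion and reflection identities; inside the disc either the direct
#' series (small \eqn{|z|}) or the Bernoulli-number (Debye) expansion in
#' \eqn{-\log(1-z)} is used.
#'
#' @param z complex (or numeric) vector.
#' @return complex vector.
#' @export
dilog_c <- local({
  nb <- 70L
  B <- numeric(nb + 1L); B[1L] <- 1
  for (n in 1:nb) {
    s <- 0
    for (k in 0:(n - 1L)) s <- s + choose(n + 1L, k) * B[k + 1L]
    B[n + 1L] <- -s / (n + 1L)
  }
  kpow <- 1:(nb + 1L)
  fct <- factorial(kpow)
  function(z) {
    one <- function(z) {
      if (abs(z) < 1e-300) return(0 + 0i)
      if (abs(z - 1) < 1e-14) return(pi^2 / 6 + 0i)
      extra <- 0 + 0i; sgn <- 1
      if (abs(z) > 1) {                       # inversion
        extra <- extra - pi^2 / 6 - 0.5 * log(-z)^2
        z <- 1 / z; sgn <- -1
      }
      if (Re(z) > 0.5) {                      # reflection
        extra <- extra + sgn * (pi^2 / 6 - log(z) * log(1 - z))
        sgn <- -sgn; z <- 1 - z
      }
      if (abs(z) <= 0.55) {
        k <- 1:60
        extra + sgn * sum(z^k / k^2)
      } else {
        w <- -log(1 - z)
        extra + sgn * sum(B * w^kpow / fct)
      }
    }
    vapply(as.complex(z), one, complex(1))
  }
})
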