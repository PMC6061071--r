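## Model A: autoregulated telegraph model.
##
## Along a characteristic with base point v0 (v = z - 1, v0 = v e^{-t}) the
## leading-order generating functions are combinations of Kummer functions of
## w = lambda * v0 * e^s. The two homogeneous solutions are
##   y1(w) = M(kf, 1+k, w),   y2(w) = w^{-k} M(-kb, 1-k, w),   k = kf + kb,
## and the product of the w^{-k} branch with the (lambda*v0)^k factor of the
## integration constant collapses to e^{-k s}, so no fractional powers of
## (z - 1) ever appear.

## Nudge kf when kf + kb sits (numerically) on a positive integer, where the
## 1 +/- k denominator parameters of the Kummer functions degenerate. The
## solution is continuous in the parameters, so a relative 1e-8 shift changes
## it far below the accuracy of the expansion while restoring well-posedness.
.nudge_a <- function(params, quiet = FALSE) {
  k <- params$kappa_f + params$kappa_b
  if (abs(k - round(k)) < 1e-6 && round(k) >= 1) {
    if (!quiet)
      message("kappa_f + kappa_b = ", format(k), " is within 1e-6 of an ",
              "integer; nudging kappa_f by a relative 1e-8 to avoid a ",
              "degenerate hypergeometric parameter")
    if (params$kappa_f > 0) params$kappa_f <- params$kappa_f * (1 + 1e-8)
    else params$kappa_b <- params$kappa_b * (1 + 1e-8)
  }
  params
}

## leading-order pair (F^(0)_0, F^(1)_0) as functions on the characteristic:
## s is a scalar "time along the characteristic", v0 a complex vector of base
## points. chi0 is the leading-order off-state probability.
.lead_a <- function(kf, kb, lam, chi0, n0, s, v0) {
  k <- kf + kb
  x0 <- lam * v0
  w <- x0 * exp(s)
  P <- kummer_m(-kb, 1 - k, x0) +
    chi0 * x0 / (1 - k) * kummer_m(1 - kb, 2 - k, x0)
  Q <- (chi0 * k - kb) * kummer_m(kf, 1 + k, x0) +
    kf * chi0 * x0 / (1 + k) * kummer_m(1 + kf, 2 + k, x0)
  pre <- (1 + v0)^n0 * exp(-x0)
  E <- exp(-k * s)
  list(F0 = pre * (kb * P * kummer_m(kf, 1 + k, w) +
                     E * Q * kummer_m(-kb, 1 - k, w)) / k,
       F1 = pre * (kf * P * kummer_m(1 + kf, 1 + k, w) -
                     E * Q * kummer_m(1 - kb, 1 - k, w)) / k)
}

## derivative of the leading order with respect to the base point v0, at
## fixed s. Both components are entire in v0, so the trapezoidal Cauchy-ring
## derivative on a small circle is spectrally accurate.
.dlead_a <- function(kf, kb, lam, chi0, n0, s, v0, radius = 0.05, nodes = 16L) {
  th <- 2 * pi * (seq_len(nodes) - 1) / nodes
  D0 <- D1 <- complex(length(v0))
  for (i in seq_len(nodes)) {
    e <- exp(1i * th[i])
    f <- .lead_a(kf, kb, lam, chi0, n0, s, v0 + radius * e)
    D0 <- D0 + f$F0 / e
    D1 <- D1 + f$F1 / e
  }
  list(D0 = D0 / (nodes * radius), D1 = D1 / (nodes * radius))
}

#' Leading-order generating functions of model A
#'
#' Evaluates the closed-form leading-order (zero autoregulation) generating
#' functions \eqn{F^{(0)}(z,t)} (gene off) and \eqn{F^{(1)}(z,t)} (gene on)
#' at complex `z` and time `t`, for initial protein count `n0` and initial
#' off-state probability `chi0`. With no regulation this is the exact
#' generating-function solution of the telegraph-model master equation.
#'
#' @param params a [model_a_params()] object.
#' @param n0 initial protein count (non-negative integer).
#' @param z complex vector of evaluation points.
#' @param t time (scalar, >= 0).
#' @param chi0 initial off-state probability; default the Markov value
#'   `kappa_b/(kappa_f + kappa_b)`.
#' @param quiet suppress the degenerate-parameter nudge message.
#' @return list with complex vectors `F0` and `F1`.
#' @export
eval_leading_a <- function(params, n0, z, t, chi0 = NULL, quiet = FALSE) {
  stopifnot(inherits(params, "model_a_params"), t >= 0, n0 >= 0)
  if (params$kappa_f + params$kappa_b <= 0)
    stop("kappa_f + kappa_b must be positive")
  params <- .nudge_a(params, quiet = quiet)
  if (is.null(chi0))
    chi0 <- params$kappa_b / (params$kappa_f + params$kappa_b)
  v0 <- (as.complex(z) - 1) * exp(-t)
  .lead_a(params$kappa_f, params$kappa_b, params$lam, chi0, n0, t, v0)
}

#' Integration constants of the model-A leading order
#'
#' Returns the homogeneous-solution constants `c1`, `c2` fixed by the initial
#' conditions on a characteristic with base point `v0`, their autorepression
#' analogues `hat_c1 = c1 * kappa_f/kappa_b`, `hat_c2 = c2`, and the lower
#' integration limits `c3 = c4 = lam * v0` of the first-order
#' variation-of-constants integrals (the particular solution is chosen to
#' vanish at s = 0).
#'
#' @inheritParams eval_leading_a
#' @param v0 complex vector of characteristic base points.
#' @return list with components `c1`, `c2`, `hat_c1`, `hat_c2`, `c3`, `c4`.
#' @export
leading_constants_a <- function(params, n0, v0, chi0 = NULL, quiet = FALSE) {
  stopifnot(inherits(params, "model_a_params"))
  params <- .nudge_a(params, quiet = quiet)
  kf <- params$kappa_f; kb <- params$kappa_b; lam <- params$lam
  k <- kf + kb
  if (is.null(chi0)) chi0 <- kb / k
  v0 <- as.complex(v0)
  x0 <- lam * v0
  pre <- (1 + v0)^n0 * exp(-x0)
  c1 <- pre * (kb / k) *
    (kummer_m(-kb, 1 - k, x0) +
       chi0 * x0 / (1 - k) * kummer_m(1 - kb, 2 - k, x0))
  c2 <- pre * (x0^k / k) *
    ((chi0 * k - kb) * kummer_m(kf, 1 + k, x0) +
       kf * chi0 * x0 / (1 + k) * kummer_m(1 + kf, 2 + k, x0))
  list(c1 = c1, c2 = c2, hat_c1 = c1 * kf / kb, hat_c2 = c2,
       c3 = x0, c4 = x0)
}

## source terms along the characteristic for the first-order equations.
## For autoactivation the non-homogeneity is alpha*(v0 + e^{-s}) d/dv0 F^(0)_0;
## for autorepression it is rho*(v0 + e^{-s}) d/dv0 F^(1)_0 (with signs per
## channel). Returned: the right-hand side R of the second-order form, on the
## path w(tau) = lam*v0*e^tau.
.first_a_rhs <- function(kf, kb, lam, reg, cf, chi0, n0, tau, v0) {
  d <- .dlead_a(kf, kb, lam, chi0, n0, tau, v0)
  wt <- lam * v0 * exp(tau)
  if (reg == "autoactivation") {
    Tt <- cf * (v0 + exp(-tau)) * d$D0
    ## R = w*T - dT/ds with dD0/ds = -kf D0 + kb D1
    wt * Tt + cf * exp(-tau) * d$D0 -
      cf * (v0 + exp(-tau)) * (-kf * d$D0 + kb * d$D1)
  } else {
    f <- .lead_a(kf, kb, lam, chi0, n0, tau, v0)
    ## R = -dT/ds with dD1/ds = kf D0 - kb D1 + lam e^s (F1 + v0 D1)
    -(-cf * exp(-tau) * d$D1 + cf * (v0 + exp(-tau)) *
        (kf * d$D0 - kb * d$D1 + lam * exp(tau) * (f$F1 + v0 * d$D1)))
  }
}

#' First-order autoregulation correction for model A
#'
#' Computes the order-`delta` coefficients \eqn{(F^{(0)}_1, F^{(1)}_1)} of the
#' generating-function expansion, either by variation of constants
#' (`method = "quadrature"`: Gauss-Legendre integration of the
#' hypergeometric-weighted source along the characteristic path, which is
#' branch-free because consecutive path points differ by real exponential
#' factors) or by direct integration of the characteristic ODE system
#' (`method = "ode"`, complex-capable solver). The two routes are independent
#' and agree to solver tolerance; the ODE route is the fallback if the
#' quadrature produces non-finite values.
#'
#' @inheritParams eval_leading_a
#' @param chi a [chi_spec()], a numeric fixed value, or `NULL` (Markov).
#' @param method `"quadrature"` (default, vectorised over `z`) or `"ode"`.
#' @param nq number of Gauss-Legendre nodes.
#' @return list with complex vectors `F0` and `F1` (the order-1 coefficients).
#' @export
first_order_a <- function(params, n0, z, t, chi = NULL,
                          method = c("quadrature", "ode"), nq = 64L,
                          quiet = FALSE) {
  stopifnot(inherits(params, "model_a_params"), t >= 0)
  method <- match.arg(method)
  if (params$regulation == "none")
    stop("first_order_a requires an autoregulated parameter set")
  params <- .nudge_a(params, quiet = quiet)
  kf <- params$kappa_f; kb <- params$kappa_b; lam <- params$lam
  reg <- params$regulation
  if (reg == "autoactivation" && kb <= 0)
    stop("autoactivation first order requires kappa_b > 0")
  if (reg == "autorepression" && kf <= 0)
    stop("autorepression first order requires kappa_f > 0")
  cc <- .chi_coefs(params, chi, n0 = n0, order = 1)
  chi0 <- cc[1]; chi1 <- cc[2]
  cf <- .reg_coeff(params)
  out <- if (method == "quadrature")
    .first_a_quad(kf, kb, lam, reg, cf, chi0, chi1, n0, as.complex(z), t, nq)
  else
    .first_a_ode(kf, kb, lam, reg, cf, chi0, chi1, n0, as.complex(z), t)
  if (method == "quadrature" && any(!is.finite(out$F0) | !is.finite(out$F1))) {
    warning("quadrature route produced non-finite values; falling back to ",
            "the ODE route")
    out <- .first_a_ode(kf, kb, lam, reg, cf, chi0, chi1, n0, as.complex(z), t)
  }
  out
}

.first_a_quad <- function(kf, kb, lam, reg, cf, chi0, chi1, n0, z, t, nq) {
  k <- kf + kb
  v0 <- (z - 1) * exp(-t)
  w <- lam * v0 * exp(t)
  w0 <- lam * v0
  Phi0 <- (1 + v0)^n0
  act <- reg == "autoactivation"
  ## homogeneous solutions for the relevant second-order operator
  Y1f <- function(x) if (act) kummer_m(kf, 1 + k, x) else kummer_m(1 + kf, 1 + k, x)
  Y2f <- function(x) if (act) kummer_m(-kb, 1 - k, x) else kummer_m(1 - kb, 1 - k, x)
  Y1p <- function(x) if (act) kf / (1 + k) * kummer_m(1 + kf, 2 + k, x)
  else (1 + kf) / (1 + k) * kummer_m(2 + kf, 2 + k, x)
  Y2p <- function(x) if (act) -kb / (1 - k) * kummer_m(1 - kb, 2 - k, x)
  else (1 - kb) / (1 - k) * kummer_m(2 - kb, 2 - k, x)
  A <- B <- complex(length(z))
  if (t > 0) {
    gl <- pracma::gaussLegendre(nq, 0, t)
    for (i in seq_len(nq)) {
      tau <- gl$x[i]
      wt <- lam * v0 * exp(tau)
      R <- .first_a_rhs(kf, kb, lam, reg, cf, chi0, n0, tau, v0)
      ew <- exp(-wt) * R
      A <- A + gl$w[i] * Y2f(wt) * ew
      B <- B + gl$w[i] * Y1f(wt) * ew * exp(k * tau)
    }
  }
  ## homogeneous constants from the order-1 initial conditions at s = 0
  d0 <- .dlead_a(kf, kb, lam, chi0, n0, 0, v0)
  if (act) {
    T0 <- cf * (v0 + 1) * d0$D0
    rhs1 <- chi1 * Phi0
    rhs2 <- -(kf + kb) * chi1 * Phi0 - T0
  } else {
    T0 <- cf * (v0 + 1) * d0$D1
    rhs1 <- -chi1 * Phi0
    ## [d/ds F^(1)_1]_{s=0} from the order-1 relation between the components
    rhs2 <- kf * chi1 * Phi0 + (kb - w0) * chi1 * Phi0 - T0
  }
  a11 <- Y1f(w0); a12 <- Y2f(w0)
  a21 <- w0 * Y1p(w0); a22 <- w0 * Y2p(w0) - k * Y2f(w0)
  det <- a11 * a22 - a12 * a21
  d1 <- (rhs1 * a22 - a12 * rhs2) / det
  d2 <- (a11 * rhs2 - rhs1 * a21) / det
  E <- exp(-k * t)
  Fsol <- (Y1f(w) * A - E * Y2f(w) * B) / k + d1 * Y1f(w) + d2 * E * Y2f(w)
  dsF <- (w * Y1p(w) * A - E * (w * Y2p(w) - k * Y2f(w)) * B) / k +
    d1 * w * Y1p(w) + d2 * E * (w * Y2p(w) - k * Y2f(w))
  dt1 <- .dlead_a(kf, kb, lam, chi0, n0, t, v0)
  if (act) {
    Tt <- cf * (v0 + exp(-t)) * dt1$D0
    list(F0 = Fsol, F1 = (dsF + kf * Fsol + Tt) / kb)
  } else {
    Tt <- cf * (v0 + exp(-t)) * dt1$D1
    list(F0 = (dsF + (kb - w) * Fsol + Tt) / kf, F1 = Fsol)
  }
}

.first_a_ode <- function(kf, kb, lam, reg, cf, chi0, chi1, n0, z, t) {
  v0s <- (z - 1) * exp(-t)
  F0 <- F1 <- complex(length(z))
  for (i in seq_along(z)) {
    v0 <- v0s[i]
    Phi0 <- (1 + v0)^n0
    rhs <- function(s, y, p) {
      d <- .dlead_a(kf, kb, lam, chi0, n0, s, v0)
      src <- if (reg == "autoactivation") cf * (v0 + exp(-s)) * d$D0
      else -cf * (v0 + exp(-s)) * d$D1
      list(c(-kf * y[1] + kb * y[2] - src,
             kf * y[1] - kb * y[2] + lam * v0 * exp(s) * y[2] + src))
    }
    y0 <- c(chi1 * Phi0, -chi1 * Phi0)
    if (t == 0) { F0[i] <- y0[1]; F1[i] <- y0[2]; next }
    sol <- deSolve::zvode(y0, c(0, t), rhs, NULL, rtol = 1e-11, atol = 1e-13,
                          maxsteps = 100000)
    F0[i] <- sol[2, 2]; F1[i] <- sol[2, 3]
  }
  list(F0 = F0, F1 = F1)
}

#' Generating functions of model A to a given autoregulation order
#'
#' Assembles \eqn{F^{(j)}(z,t) = \sum_m \delta^m F^{(j)}_m(z,t)} up to
#' `order` (0 or 1). With `order = 0` and no regulation this is the exact
#' solution; with `order = 1` the leading term uses the order-0 coefficient
#' of the off-state probability and the correction adds the first
#' autoregulation effect, leaving an O(delta^2) remainder.
#'
#' @inheritParams first_order_a
#' @param order 0 or 1 (orders above 1 are not implemented).
#' @return object of class `gf_a`: list with `total_F0`, `total_F1`,
#'   per-order terms `F0_terms`, `F1_terms`, `order` and `delta`.
#' @export
eval_gf_a <- function(params, n0, z, t, chi = NULL, order = NULL,
                      method = "quadrature", quiet = FALSE) {
  stopifnot(inherits(params, "model_a_params"))
  if (is.null(order)) order <- if (params$regulation == "none") 0L else 1L
  if (order > 1) stop("expansion orders above 1 are not implemented")
  if (order == 1 && params$regulation == "none")
    stop("order = 1 requires an autoregulated parameter set")
  cc <- .chi_coefs(params, chi, n0 = n0, order = 1)
  l0 <- eval_leading_a(params, n0 = n0, z = z, t = t, chi0 = cc[1],
                       quiet = quiet)
  F0_terms <- list(l0$F0); F1_terms <- list(l0$F1)
  tot0 <- l0$F0; tot1 <- l0$F1
  if (order == 1) {
    f1 <- first_order_a(params, n0 = n0, z = z, t = t, chi = chi,
                        method = method, quiet = TRUE)
    F0_terms[[2]] <- f1$F0; F1_terms[[2]] <- f1$F1
    tot0 <- tot0 + params$delta * f1$F0
    tot1 <- tot1 + params$delta * f1$F1
  }
  structure(list(order = order, delta = params$delta,
                 F0_terms = F0_terms, F1_terms = F1_terms,
                 total_F0 = tot0, total_F1 = tot1),
            class = "gf_a")
}
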