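## Model B: two-stage telegraph model (mRNA + protein), slow-fast expansion.
##
## Shifted variables u = w - 1, v = z - 1. On the characteristic ending at
## (u, v) at time t the protein coordinate flows exactly as v(s) = v e^{s-t};
## the mRNA coordinate is a fast variable with small parameter eps. All
## quantities below are expressed through
##   q  = 1 - mu*v,  q0 = 1 - mu*v0,  v0 = v e^{-t},
## and combinations of exponentials that are bounded on contours with
## |z| <= 1 (where Re(mu*v) <= 0). The fast-time series coefficients agree
## with the characteristic-ODE recursion order by order; secular slow-time
## monomials are resummed into closed-form integrals along the moving
## characteristic so that the evaluation stays bounded and accurate for
## sigma = t/eps >> 1 (see the methods vignette).

.pole_guard <- function(q, what = "z") {
  if (any(abs(q) < 1e-8))
    stop("contour point too close to the generating-function pole at ",
         "z = 1 + 1/mu: reduce the ", what, "-contour radius")
}

#' Exact characteristic flow of model B (oracle)
#'
#' Solves the characteristic system for the mRNA coordinate in closed form.
#' The incomplete-Gamma difference appearing in the solution is evaluated as
#' a branch-free integral over a real interval,
#' \eqn{x \int_1^{e^s} \xi^{-\gamma} e^{-x\xi} d\xi} with
#' \eqn{x = -\gamma\mu v_0}, so no complex-power branch choices arise.
#' Intended as an independent oracle: the production evaluation path never
#' calls it.
#'
#' @param u0,v0 complex base-point coordinates (scalars).
#' @param s flow time (>= 0).
#' @param gamma ratio of mRNA to protein decay rates (= 1/eps).
#' @param mu translation burst parameter.
#' @return list with complex scalars `u` and `v`.
#' @export
char_exact_b <- function(u0, v0, s, gamma, mu) {
  stopifnot(s >= 0, gamma > 0)
  u0 <- as.complex(u0); v0 <- as.complex(v0)
  v <- v0 * exp(s)
  x <- -gamma * mu * v0
  intg <- if (abs(x) < 1e-300 || s == 0) 0 + 0i else {
    f <- function(xi) xi^(-gamma) * exp(-x * xi)
    re <- stats::integrate(function(xi) Re(f(xi)), 1, exp(s),
                           rel.tol = 1e-12, abs.tol = 1e-14)$value
    im <- stats::integrate(function(xi) Im(f(xi)), 1, exp(s),
                           rel.tol = 1e-12, abs.tol = 1e-14)$value
    complex(real = re, imaginary = im)
  }
  u <- exp(gamma * (s - mu * v0 * (exp(s) - 1))) * u0 +
    exp(gamma * (s - mu * v0 * exp(s))) * x * intg
  list(u = u, v = v)
}

#' Exact inverse characteristic transform of model B (oracle)
#'
#' Flows `(u, v)` backward for time `t` in closed form; same branch-free
#' reduction of the incomplete-Gamma difference as in [char_exact_b()].
#'
#' @param u,v complex scalars.
#' @param t backward flow time (>= 0).
#' @inheritParams char_exact_b
#' @return list with complex scalars `u0` and `v0`.
#' @export
inverse_u0_exact <- function(u, v, t, gamma, mu) {
  stopifnot(t >= 0, gamma > 0)
  u <- as.complex(u); v <- as.complex(v)
  v0 <- v * exp(-t)
  x <- -gamma * mu * v
  intg <- if (abs(x) < 1e-300 || t == 0) 0 + 0i else {
    f <- function(xi) xi^(-gamma) * exp(-x * xi)
    re <- stats::integrate(function(xi) Re(f(xi)), exp(-t), 1,
                           rel.tol = 1e-12, abs.tol = 1e-14)$value
    im <- stats::integrate(function(xi) Im(f(xi)), exp(-t), 1,
                           rel.tol = 1e-12, abs.tol = 1e-14)$value
    complex(real = re, imaginary = im)
  }
  u0 <- exp(-gamma * (t - mu * v * (1 - exp(-t)))) * u -
    exp(-gamma * (t + mu * v * exp(-t))) * x * intg
  list(u0 = u0, v0 = v0)
}

#' Fast-time expansion of the mRNA characteristic coordinate
#'
#' Returns the first terms \eqn{\hat u_0(\sigma)}, \eqn{\hat u_1(\sigma)} of
#' the expansion of the mRNA characteristic in powers of `eps` at frozen base
#' point `(u0, v0)`.
#'
#' @param u0,v0 complex base-point coordinates.
#' @param sigma fast time.
#' @param eps time-scale ratio.
#' @param mu translation burst parameter.
#' @param order 0 or 1.
#' @return list with components `u_hat` (complex vector of length
#'   `order + 1`) and `total` (\eqn{\sum_n \varepsilon^n \hat u_n}).
#' @export
char_expansion_u <- function(u0, v0, sigma, eps, mu, order = 1L) {
  if (order > 1) stop("expansion orders above 1 are not implemented")
  q0 <- 1 - mu * v0
  .pole_guard(q0)
  h0 <- mu * v0 / q0
  A0 <- u0 - h0
  E <- exp(q0 * sigma)
  u_hat <- c(h0 + A0 * E)
  if (order >= 1)
    u_hat <- c(u_hat,
               mu * v0 / q0^2 * ((1 - E) / q0 + sigma) -
                 A0 * mu * v0 * sigma^2 / 2 * E)
  list(u_hat = u_hat, total = sum(eps^(seq_along(u_hat) - 1) * u_hat))
}

#' Perturbative inverse characteristic transform
#'
#' Expansion of the base-point coordinate `u0` as a function of the endpoint
#' `(u, v)` and fast time `sigma`, to first order in `eps`. Order 0 is the
#' frozen-manifold form; order 1 adds the `eps`-correction.
#'
#' @param u,v complex endpoint coordinates (vectors allowed).
#' @param t elapsed time; the fast time used is `sigma = t/eps`.
#' @inheritParams char_expansion_u
#' @return complex vector `u0`.
#' @export
inverse_u0 <- function(u, v, t, eps, mu, order = 1L) {
  if (order > 1) stop("expansion orders above 1 are not implemented")
  sig <- t / eps
  q <- 1 - mu * v
  .pole_guard(q)
  A <- u - mu * v / q
  E <- exp((mu * v - 1) * sig)
  u0 <- mu * v / q + E * A
  if (order >= 1)
    u0 <- u0 - eps * mu * v *
      ((E - 1) / q^3 + sig / q^2 + sig^2 / 2 * E * A)
  u0
}

#' Free constants of the fast-time solution from initial data
#'
#' Given the initial off-state probability `chi0` and initial counts
#' `(m0, n0)`, fixes the constants `f0, f1, f2, g1, g2` of the fast-time
#' solution on the characteristic with base point `(u0, v0)`.
#'
#' @param chi0 initial off-state probability.
#' @param params a [model_b_params()] object (`kappa_1 > 0` required).
#' @param m0,n0 initial mRNA and protein counts.
#' @param u0,v0 complex base-point coordinates.
#' @return list with complex components `f0`, `f1`, `f2`, `g1`, `g2`.
#' @export
coeffs_from_ics_b <- function(chi0, params, m0, n0, u0, v0) {
  stopifnot(inherits(params, "model_b_params"))
  if (params$kappa_1 <= 0)
    stop("kappa_1 must be positive: it divides the on-state fast-time ",
         "solution coefficients")
  k0 <- params$kappa_0; k1 <- params$kappa_1
  lam <- params$lam; mu <- params$mu
  q0 <- 1 - mu * v0
  .pole_guard(q0)
  Phi <- (1 + u0)^m0 * (1 + v0)^n0
  A0 <- u0 - mu * v0 / q0
  list(f0 = chi0 * Phi,
       f1 = 0 + 0i,
       f2 = -(1 - chi0) * Phi * lam * k1 / q0^2 * A0,
       g1 = (k1 * (1 - chi0) - k0 * chi0) * Phi,
       g2 = -(1 - chi0) * Phi * lam * k1 / q0 * A0)
}

## core evaluator, vectorised over (w, z) arrays of equal shape.
## eps_order 0: frozen leading-order closed form.
## eps_order 1: resummed first order (switching relaxation G exact, production
##              channel of F1 exponentially resummed with the exact integral
##              I1 of the mRNA coordinate along the moving characteristic).
## eps_order 2: additionally, the total GF is assembled through the exact
##              production identity F = Phi + lam * int u F1 ds (Gauss
##              quadrature on the smooth part, closed-form layer term), and
##              F0 := Ftot - F1.
.evalB_core <- function(k0, k1, lam, mu, eps, chi, m0, n0, w, z, t,
                        eps_order = 2L, nq = 24L) {
  u <- as.complex(w) - 1; v <- as.complex(z) - 1
  sig <- t / eps
  v0 <- v * exp(-t)
  q <- 1 - mu * v; q0 <- 1 - mu * v0
  .pole_guard(q)
  A <- u - mu * v / q
  if (eps_order == 0) {
    u0 <- mu * v / q + exp(-q * sig) * A
    Phi <- (1 + u0)^m0 * (1 + v0)^n0
    return(list(F0 = chi * Phi, F1 = (1 - chi) * Phi,
                total = Phi, u0 = u0, v0 = v0, Phi = Phi))
  }
  Eback <- exp((mu * v * (1 - exp(-t)) - t) / eps)
  Echar <- exp(-q * sig)
  hc <- eps * mu * v / q^3          # slow-manifold eps-correction at endpoint
  hc0 <- eps * mu * v0 / q0^3       # ... at the base point
  Abar <- A - hc                    # boundary-layer amplitude
  u0 <- mu * v0 / q0 + hc0 + Eback * Abar
  Phi <- (1 + u0)^m0 * (1 + v0)^n0
  f0 <- chi * Phi
  g1 <- (k1 * (1 - chi) - k0 * chi) * Phi
  F1_0 <- (f0 * k0 + g1) / k1
  ksw <- k0 + k1
  G <- g1 * (1 - exp(-ksw * t)) / ksw
  F1s <- function(s) {
    ## resummed on-state GF at intermediate slow time s on this characteristic
    vs <- v * exp(s - t); qs <- 1 - mu * vs
    Gs <- g1 * (1 - exp(-ksw * s)) / ksw
    Xs <- exp((mu * v * (1 - exp(s - t)) - (t - s)) / eps)
    I1s <- log(q0 / qs) / eps + 1 / (2 * qs^2) - 1 / (2 * q0^2) +
      Abar * (Xs - Eback) / qs
    (F1_0 - Gs) * exp(eps * lam * I1s)
  }
  F1 <- F1s(t)
  if (eps_order == 1L) {
    F0 <- f0 + G
    return(list(F0 = F0, F1 = F1, total = F0 + F1,
                u0 = u0, v0 = v0, Phi = Phi))
  }
  ## order 2: total from the production-integral identity
  intsm <- 0
  if (t > 0) {
    gl <- pracma::gaussLegendre(nq, 0, t)
    for (i in seq_len(nq)) {
      s <- gl$x[i]; vs <- v * exp(s - t); qs <- 1 - mu * vs
      usm <- mu * vs / qs + eps * mu * vs / qs^3
      intsm <- intsm + gl$w[i] * usm * F1s(s)
    }
  }
  Ftot <- Phi + lam * intsm + eps * lam * Abar * (1 - Echar) / q * F1
  list(F0 = Ftot - F1, F1 = F1, total = Ftot, u0 = u0, v0 = v0, Phi = Phi)
}

#' Generating functions of model B (no autoregulation)
#'
#' Evaluates the gene-state-resolved generating functions
#' \eqn{F^{(0)}(w,z,t)}, \eqn{F^{(1)}(w,z,t)} of the two-stage telegraph
#' model by the fast-time expansion in `eps`, composed with the inverse
#' characteristic transform. `eps_order = 0` reproduces the frozen
#' leading-order closed form exactly; higher orders use resummed slow-time
#' integrals so that the evaluation remains bounded and accurate for
#' `t/eps >> 1` (see the methods vignette for the assembly).
#'
#' @param params a [model_b_params()] object.
#' @param m0,n0 initial mRNA and protein counts.
#' @param w,z complex evaluation points (equal-shape vectors or matrices).
#' @param t time (scalar >= 0).
#' @param chi a [chi_spec()], numeric value, or `NULL` (Markov).
#' @param eps_order 0, 1 or 2 (default 2).
#' @param nq Gauss-Legendre nodes for the order-2 production integral.
#' @return object of class `gf_b`: list with `total_F0`, `total_F1`, `total`,
#'   `eps_order` and the resolved `chi`.
#' @export
eval_gf_b <- function(params, m0, n0, w, z, t, chi = NULL, eps_order = 2L,
                      nq = 24L) {
  stopifnot(inherits(params, "model_b_params"), t >= 0, m0 >= 0, n0 >= 0)
  if (eps_order > 2) stop("eps orders above 2 are not implemented")
  chiv <- .chi_value(params, chi, n0 = n0, m0 = m0)
  core <- .evalB_core(params$kappa_0, params$kappa_1, params$lam, params$mu,
                      params$eps, chiv, m0, n0, w, z, t, eps_order, nq)
  structure(list(eps_order = eps_order, delta_order = 0L, chi = chiv,
                 total_F0 = core$F0, total_F1 = core$F1, total = core$total),
            class = "gf_b")
}

#' Generating functions of model B with autoregulation
#'
#' Adds the first-order correction in the small autoregulation parameter
#' `delta` to [eval_gf_b()]. The order-`delta` coefficients are obtained from
#' the recursion for the doubly-indexed expansion (orders `delta^m eps^n`
#' with m <= 1, n <= 1): the fast-time-constant terms are proportional to the
#' first chi-series coefficient, and the order-(1,1) term integrates the
#' autoregulation source, whose leading fast-time coefficient is available in
#' closed form for all four feedback channels.
#'
#' @inheritParams eval_gf_b
#' @param delta_order 0 or 1.
#' @return object of class `gf_b` (totals include the delta-correction).
#' @export
autoreg_gf_b <- function(params, m0, n0, w, z, t, chi = NULL,
                         delta_order = 1L, eps_order = 2L, nq = 24L) {
  stopifnot(inherits(params, "model_b_params"), t >= 0)
  if (delta_order > 1) stop("delta orders above 1 are not implemented")
  if (eps_order > 2) stop("eps orders above 2 are not implemented")
  if (params$regulation == "none" || delta_order == 0L || params$delta == 0)
    return(eval_gf_b(params, m0, n0, w, z, t, chi = chi,
                     eps_order = eps_order, nq = nq))
  cc <- .chi_coefs(params, chi, n0 = n0, order = 1, m0 = m0)
  chi0 <- cc[1]; chi1 <- cc[2]
  k0 <- params$kappa_0; k1 <- params$kappa_1
  lam <- params$lam; mu <- params$mu; eps <- params$eps
  core <- .evalB_core(k0, k1, lam, mu, eps, chi0, m0, n0, w, z, t,
                      eps_order, nq)
  u0 <- core$u0; v0 <- core$v0; Phi <- core$Phi
  sig <- t / eps
  q0 <- 1 - mu * v0
  A0 <- u0 - mu * v0 / q0
  cf <- .reg_coeff(params)                  # scaled regulation coefficient
  ## Order-delta correction. On each characteristic the order-delta pair
  ## satisfies a constant-coefficient switching system driven by the
  ## autoregulation source in the antisymmetric direction (-1, +1); both the
  ## initial data chi1*Phi*(1, -1) and the source are annihilated by the
  ## stationary projector of the switching matrix, so the correction relaxes
  ## purely with rate kappa_0 + kappa_1 and conserves probability exactly:
  ##   dF0(t) = chi1*Phi*e^{-(k0+k1)t} - J,  dF1 = -dF0,
  ## with J the switching-weighted integral of the source. The leading
  ## fast-time source coefficient has the form c_e e^{-q0*sigma'} + c_0 +
  ## c_1*sigma' in all four feedback channels, so J is elementary. Expanding
  ## J and the relaxation factor in eps*sigma recovers the frozen double
  ## series term by term.
  ksw <- k0 + k1
  if (eps_order >= 1L) {
    cc0 <- switch(params$regulation,
                  mRNA_act = chi0, prot_act = chi0,
                  mRNA_rep = -(1 - chi0), prot_rep = -(1 - chi0))
    cc0 <- cc0 * cf
    if (params$regulation %in% c("mRNA_act", "mRNA_rep")) {
      K <- if (m0 == 0) 0 else cc0 * m0 * (1 + u0)^(m0 - 1) * (1 + v0)^n0
      c_e <- K / q0
      c_0 <- K * A0
      c_1 <- 0
    } else {
      P1 <- if (m0 == 0) 0 else m0 * (1 + u0)^(m0 - 1) * (1 + v0)^(n0 + 1)
      D <- mu / q0^2
      c_e <- -cc0 * D * P1
      c_0 <- cc0 * (D * P1 + n0 * Phi)
      c_1 <- cc0 * A0 * mu * P1
    }
    Erel <- exp(-ksw * t)
    ## int_0^t e^{-ksw (t-r)} [c_e e^{-q0 r/eps} + c_0 + c_1 r/eps] dr
    J <- c_e * Erel * (1 - exp((ksw - q0 / eps) * t)) / (q0 / eps - ksw) +
      c_0 * (1 - Erel) / ksw +
      (c_1 / eps) * (t / ksw - (1 - Erel) / ksw^2)
    dF0 <- chi1 * Phi * exp(-ksw * t) - J
  } else {
    dF0 <- chi1 * Phi
  }
  ## the on-state correction is additionally carried through the production
  ## channel (same resummed integral as the unperturbed on-state component);
  ## the factor is 1 on the z = w = 1 characteristic, so probability is
  ## still conserved exactly.
  dF1 <- -dF0
  if (eps_order >= 1L) {
    v <- as.complex(z) - 1
    q <- 1 - mu * v
    A <- (as.complex(w) - 1) - mu * v / q
    Eback <- exp((mu * v * (1 - exp(-t)) - t) / eps)
    hcq <- eps * mu * v / q^3
    I1 <- log(q0 / q) / eps + 1 / (2 * q^2) - 1 / (2 * q0^2) +
      (A - hcq) * (1 - Eback) / q
    dF1 <- dF1 * exp(eps * lam * I1)
  }
  delta <- params$delta
  tot0 <- core$F0 + delta * dF0
  tot1 <- core$F1 + delta * dF1
  structure(list(eps_order = eps_order, delta_order = 1L, chi = sum(cc * delta^(0:1)),
                 total_F0 = tot0, total_F1 = tot1, total = tot0 + tot1),
            class = "gf_b")
}
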