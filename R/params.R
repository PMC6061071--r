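#' Parameter set for the autoregulated telegraph model (model A)
#'
#' Dimensionless rates for a gene switching between an inactive state `D` and
#' an active state `D*`, producing protein only while active. Time is measured
#' in units of the protein lifetime, so all rates are ratios to the protein
#' decay rate. Autoregulation (protein promoting or repressing gene
#' activation) is treated perturbatively: its rate is written as
#' `delta * alpha` (activation) or `delta * rho` (repression) with `delta`
#' small.
#'
#' @param kappa_f dimensionless activation (on-switch) rate.
#' @param kappa_b dimensionless deactivation (off-switch) rate.
#' @param lam dimensionless protein production rate.
#' @param regulation one of `"none"`, `"autoactivation"`, `"autorepression"`.
#' @param delta small perturbation parameter (0 iff `regulation = "none"`).
#' @param alpha scaled autoactivation coefficient (used iff autoactivation).
#' @param rho scaled autorepression coefficient (used iff autorepression).
#' @return an object of class `model_a_params`.
#' @seealso [scale_model_a()] to build one from dimensional rates.
#' @export
model_a_params <- function(kappa_f, kappa_b, lam,
                           regulation = c("none", "autoactivation", "autorepression"),
                           delta = 0, alpha = 1, rho = 1) {
  regulation <- match.arg(regulation)
  rates <- c(kappa_f = kappa_f, kappa_b = kappa_b, lam = lam, delta = delta,
             alpha = alpha, rho = rho)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  if (regulation == "none" && delta != 0)
    stop("delta must be 0 when regulation = \"none\"")
  if (regulation != "none" && delta == 0)
    stop("delta must be positive when regulation is present")
  if (delta >= 1)
    warning("delta = ", delta, " >= 1: the small-autoregulation assumption is ",
            "violated and the perturbative expansion may be inaccurate")
  structure(list(model = "A", kappa_f = kappa_f, kappa_b = kappa_b, lam = lam,
                 regulation = regulation, delta = delta,
                 alpha = alpha, rho = rho),
            class = "model_a_params")
}

#' Nondimensionalise model-A rates
#'
#' Scales dimensional rates by the protein decay rate `p_d`:
#' `kappa_f = c_f/p_d`, `kappa_b = c_b/p_d`, `lam = p_b/p_d`. The
#' autoregulation rate is factorised as `reg_rate/p_d = delta * 1`, i.e. the
#' scaled Greek coefficient is fixed to 1 and `delta` carries the whole
#' magnitude (only the product is identifiable).
#'
#' @param c_f,c_b gene activation / deactivation rates.
#' @param p_b,p_d protein production / decay rates; `p_d > 0`.
#' @param regulation regulation type, as in [model_a_params()].
#' @param reg_rate dimensional autoregulation rate (`a` or `r`).
#' @return a `model_a_params` object.
#' @export
scale_model_a <- function(c_f, c_b, p_b, p_d,
                          regulation = c("none", "autoactivation", "autorepression"),
                          reg_rate = 0) {
  regulation <- match.arg(regulation)
  if (!is.finite(p_d) || p_d <= 0) stop("p_d must be positive")
  if (any(c(c_f, c_b, p_b, reg_rate) < 0)) stop("rates must be non-negative")
  model_a_params(kappa_f = c_f / p_d, kappa_b = c_b / p_d, lam = p_b / p_d,
                 regulation = regulation, delta = reg_rate / p_d,
                 alpha = 1, rho = 1)
}

#' Parameter set for the two-stage telegraph model (model B)
#'
#' Dimensionless rates for a switching gene transcribed to mRNA, which is
#' translated to protein; both species decay. Time is in units of the protein
#' lifetime; `eps = d_1/d_0` is the ratio of protein to mRNA decay rates,
#' assumed small (mRNA is short-lived relative to protein). `mu = nu_1/d_0`
#' is the mean translational burst size. Autoregulation acts through mRNA or
#' protein copy number on either switching channel, with scaled rate
#' `delta * reg_coeff`.
#'
#' @param kappa_0 dimensionless on-switch rate.
#' @param kappa_1 dimensionless off-switch rate.
#' @param lam dimensionless transcription rate.
#' @param mu translation burst parameter.
#' @param eps time-scale ratio `d_1/d_0`, in (0, 1).
#' @param regulation one of `"none"`, `"mRNA_act"`, `"mRNA_rep"`,
#'   `"prot_act"`, `"prot_rep"`.
#' @param delta small perturbation parameter (0 iff no regulation).
#' @param reg_coeff scaled autoregulation coefficient.
#' @return an object of class `model_b_params`.
#' @export
model_b_params <- function(kappa_0, kappa_1, lam, mu, eps,
                           regulation = c("none", "mRNA_act", "mRNA_rep",
                                          "prot_act", "prot_rep"),
                           delta = 0, reg_coeff = 1) {
  regulation <- match.arg(regulation)
  vals <- c(kappa_0, kappa_1, lam, mu, eps, delta, reg_coeff)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rates must be finite and non-negative")
  if (mu <= 0) stop("mu must be positive")
  if (eps <= 0) stop("eps must be positive")
  if (eps >= 1)
    warning("eps = ", eps, " >= 1: the time-scale separation assumption is ",
            "violated and the fast-time expansion may be inaccurate")
  if (regulation == "none" && delta != 0)
    stop("delta must be 0 when regulation = \"none\"")
  if (regulation != "none" && delta == 0)
    stop("delta must be positive when regulation is present")
  if (delta >= 1)
    warning("delta = ", delta, " >= 1: the small-autoregulation assumption is ",
            "violated")
  structure(list(model = "B", kappa_0 = kappa_0, kappa_1 = kappa_1, lam = lam,
                 mu = mu, eps = eps, regulation = regulation, delta = delta,
                 reg_coeff = reg_coeff),
            class = "model_b_params")
}

#' Nondimensionalise model-B rates
#'
#' Scales dimensional rates by the protein decay rate `d_1`:
#' `kappa_0 = k_0/d_1`, `kappa_1 = k_1/d_1`, `lam = nu_0/d_1`,
#' `mu = nu_1/d_0`, `eps = d_1/d_0`. The autoregulation rate is factorised as
#' `reg_rate/d_1 = delta * 1` (coefficient convention as in
#' [scale_model_a()]).
#'
#' @param k_0,k_1 gene switching rates.
#' @param nu_0 transcription rate; `nu_1` translation rate.
#' @param d_0,d_1 mRNA / protein decay rates (both positive).
#' @param regulation regulation type, as in [model_b_params()].
#' @param reg_rate dimensional autoregulation rate.
#' @return a `model_b_params` object.
#' @export
scale_model_b <- function(k_0, k_1, nu_0, nu_1, d_0, d_1,
                          regulation = c("none", "mRNA_act", "mRNA_rep",
                                         "prot_act", "prot_rep"),
                          reg_rate = 0) {
  regulation <- match.arg(regulation)
  if (d_0 <= 0 || d_1 <= 0) stop("decay rates must be positive")
  model_b_params(kappa_0 = k_0 / d_1, kappa_1 = k_1 / d_1, lam = nu_0 / d_1,
                 mu = nu_1 / d_0, eps = d_1 / d_0, regulation = regulation,
                 delta = reg_rate / d_1, reg_coeff = 1)
}

#' @export
print.model_a_params <- function(x, ...) {
  cat("Autoregulated telegraph model (model A), dimensionless rates:\n")
  cat(sprintf("  kappa_f = %g, kappa_b = %g, lambda = %g\n",
              x$kappa_f, x$kappa_b, x$lam))
  if (x$regulation == "none") cat("  no autoregulation\n")
  else cat(sprintf("  %s: delta = %g, coefficient = %g\n", x$regulation,
                   x$delta, if (x$regulation == "autoactivation") x$alpha else x$rho))
  invisible(x)
}

#' @export
print.model_b_params <- function(x, ...) {
  cat("Two-stage telegraph model (model B), dimensionless rates:\n")
  cat(sprintf("  kappa_0 = %g, kappa_1 = %g, lambda = %g, mu = %g, eps = %g\n",
              x$kappa_0, x$kappa_1, x$lam, x$mu, x$eps))
  if (x$regulation == "none") cat("  no autoregulation\n")
  else cat(sprintf("  %s: delta = %g, coefficient = %g\n", x$regulation,
                   x$delta, x$reg_coeff))
  invisible(x)
}

## effective scaled regulation coefficient (alpha, rho, alpha_M, ...) times 1
.reg_coeff <- function(params) {
  switch(params$model,
         A = if (params$regulation == "autoactivation") params$alpha else params$rho,
         B = params$reg_coeff)
}

#' Specification of the initial off-state probability chi
#'
#' `chi` is the probability that the gene is off at time zero, conditional on
#' the observed initial copy numbers. Three incorporation modes are supported:
#' `"markov"` derives it from the model's switching (and autoregulation)
#' rates; `"fixed"` uses a user-supplied value; `"series"` supplies the
#' coefficients of its expansion in the small autoregulation parameter
#' directly.
#'
#' @param mode one of `"markov"`, `"fixed"`, `"series"`.
#' @param value fixed value in \[0, 1\] (mode `"fixed"`).
#' @param coefficients numeric vector of series coefficients (mode `"series"`).
#' @return an object of class `chi_spec`.
#' @export
chi_spec <- function(mode = c("markov", "fixed", "series"), value = NULL,
                     coefficients = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(value) || value < 0 || value > 1)
      stop("fixed mode requires a value in [0, 1]")
  }
  if (mode == "series") {
    if (is.null(coefficients)) stop("series mode requires coefficients")
    if (coefficients[1] < 0 || coefficients[1] > 1)
      stop("leading series coefficient must lie in [0, 1]")
  }
  structure(list(mode = mode, value = value, coefficients = coefficients),
            class = "chi_spec")
}

#' Off-state probability from the Markov property of the model
#'
#' Computes `chi(n0)` (model A) or `chi(m0, n0)` (model B) as the stationary
#' off-state probability of the two-state switching process whose on- and
#' off-rates include the state-dependent autoregulation propensity evaluated
#' at the initial copy numbers. With no regulation this is
#' `kappa_b/(kappa_f + kappa_b)` resp. `kappa_1/(kappa_0 + kappa_1)`.
#'
#' @param params a `model_a_params` or `model_b_params` object.
#' @param n0 initial protein count.
#' @param m0 initial mRNA count (model B only).
#' @return a probability in \[0, 1\].
#' @export
chi_markov <- function(params, n0, m0 = NULL) {
  if (inherits(params, "model_a_params")) {
    reg <- params$delta * .reg_coeff(params) * n0
    on  <- params$kappa_f + if (params$regulation == "autoactivation") reg else 0
    off <- params$kappa_b + if (params$regulation == "autorepression") reg else 0
  } else if (inherits(params, "model_b_params")) {
    count <- switch(params$regulation,
                    none = 0,
                    mRNA_act = , mRNA_rep = {
                      if (is.null(m0)) stop("m0 required for mRNA-mediated regulation")
                      m0
                    },
                    prot_act = , prot_rep = n0)
    reg <- params$delta * .reg_coeff(params) * count
    on  <- params$kappa_0 + if (params$regulation %in% c("mRNA_act", "prot_act")) reg else 0
    off <- params$kappa_1 + if (params$regulation %in% c("mRNA_rep", "prot_rep")) reg else 0
  } else stop("params must be a model_a_params or model_b_params object")
  if (on + off == 0)
    stop("all switching and regulation rates are zero: the initial gene state ",
         "is undefined")
  off / (on + off)
}

#' Series coefficients of chi in the small autoregulation parameter
#'
#' Returns the coefficients `chi_0, ..., chi_order` of the expansion of the
#' Markov off-state probability in powers of the small parameter `delta`.
#' For autoactivation (gene-on channel perturbed) this is a geometric series
#' with leading term equal to the unregulated value; for autorepression the
#' leading term is unchanged and corrections carry the opposite overall sign.
#' A `"fixed"` [chi_spec()] yields `(value, 0, 0, ...)`; a `"series"` spec
#' returns its own (padded) coefficients.
#'
#' @param params model parameters.
#' @param n0 initial protein count; `m0` initial mRNA count (model B).
#' @param order highest coefficient order (>= 0).
#' @param spec optional [chi_spec()]; default Markov mode.
#' @return numeric vector of length `order + 1`.
#' @export
chi_series <- function(params, n0, order, m0 = NULL, spec = NULL) {
  if (order < 0) stop("order must be >= 0")
  if (!is.null(spec) && spec$mode == "fixed")
    return(c(spec$value, rep(0, order)))
  if (!is.null(spec) && spec$mode == "series") {
    co <- spec$coefficients
    length(co) <- order + 1
    co[is.na(co)] <- 0
    return(co)
  }
  if (inherits(params, "model_a_params")) {
    on <- params$kappa_f; off <- params$kappa_b
    count <- n0
    act <- params$regulation == "autoactivation"
  } else {
    on <- params$kappa_0; off <- params$kappa_1
    count <- switch(params$regulation,
                    none = 0, mRNA_act = , mRNA_rep = m0, prot_act = , prot_rep = n0)
    if (is.null(count)) stop("m0 required for mRNA-mediated regulation")
    act <- params$regulation %in% c("mRNA_act", "prot_act")
  }
  tot <- on + off
  if (tot == 0) stop("all switching rates are zero: chi series undefined")
  cf <- .reg_coeff(params)
  if (params$regulation == "none") return(c(off / tot, rep(0, order)))
  ratio <- -cf * count / tot
  m <- 0:order
  if (act) (off / tot) * ratio^m
  else c(off / tot, -(on / tot) * ratio^(m[-1]))
}

## resolve chi to (chi_0, ..., chi_order), honouring the spec mode
.chi_coefs <- function(params, chi, n0, order, m0 = NULL) {
  if (is.null(chi)) chi <- chi_spec("markov")
  if (is.numeric(chi)) chi <- chi_spec("fixed", value = chi)
  stopifnot(inherits(chi, "chi_spec"))
  chi_series(params, n0 = n0, order = order, m0 = m0, spec =
               if (chi$mode == "markov") NULL else chi)
}

## resolve chi to a single number (full, unexpanded value)
.chi_value <- function(params, chi, n0, m0 = NULL) {
  if (is.null(chi)) return(chi_markov(params, n0 = n0, m0 = m0))
  if (is.numeric(chi)) return(chi)
  stopifnot(inherits(chi, "chi_spec"))
  switch(chi$mode,
         markov = chi_markov(params, n0 = n0, m0 = m0),
         fixed = chi$value,
         series = {
           d <- params$delta
           sum(chi$coefficients * d^(seq_along(chi$coefficients) - 1))
         })
}
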