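## Shared fixtures: small parameter sets and contour samplers used across
## the test files. Everything is generated in code.

pa_plain <- function(kf = 0.5, kb = 1, lam = 2)
  model_a_params(kf, kb, lam)

pa_act <- function(delta = 0.05, kf = 0.8, kb = 1.1, lam = 3)
  model_a_params(kf, kb, lam, regulation = "autoactivation", delta = delta)

pa_rep <- function(delta = 0.05, kf = 0.8, kb = 1.1, lam = 3)
  model_a_params(kf, kb, lam, regulation = "autorepression", delta = delta)

pb_plain <- function(eps = 0.1, k0 = 1, k1 = 2, lam = 1, mu = 1.5)
  model_b_params(k0, k1, lam, mu, eps)

pb_reg <- function(reg, delta = 0.05, eps = 0.05, k0 = 0.3, k1 = 0.4,
                   lam = 0.5, mu = 1.5)
  model_b_params(k0, k1, lam, mu, eps, regulation = reg, delta = delta)

unit_circle <- function(M = 64) exp(2i * pi * (0:(M - 1)) / M)

## total model-A generating function on a vector of z values
gf_a_total <- function(params, n0, t, chi = NULL, order = NULL) {
  function(z) {
    g <- eval_gf_a(params, n0 = n0, z = z, t = t, chi = chi, order = order,
                   quiet = TRUE)
    g$total_F0 + g$total_F1
  }
}

## log-log slope of err against h by least squares
loglog_slope <- function(h, err) {
  -stats::coef(stats::lm(log(err) ~ log(h)))[2] * (-1)
}
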