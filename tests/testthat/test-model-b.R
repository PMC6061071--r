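test_that("exact characteristics: identity at s=0, v0=0 reduction, ODE oracle", {
  expect_equal(char_exact_b(0.3 + 0.2i, -0.1 + 0.1i, 0, gamma = 10, mu = 1.5),
               list(u = 0.3 + 0.2i, v = -0.1 + 0.1i))
  ## v0 = 0: pure exponential growth of u
  ce <- char_exact_b(0.2 + 0.1i, 0 + 0i, 1.2, gamma = 5, mu = 2)
  expect_equal(ce$u, (0.2 + 0.1i) * exp(5 * 1.2), tolerance = 1e-10)
  expect_equal(ce$v, 0 + 0i)
  ## against direct numerical integration of the characteristic system
  set.seed(11)
  for (i in 1:5) {
    u0 <- complex(real = stats::runif(1, -0.5, 0.5),
                  imaginary = stats::runif(1, -0.5, 0.5))
    v0 <- complex(real = stats::runif(1, -0.5, 0.5),
                  imaginary = stats::runif(1, -0.5, 0.5))
    s <- stats::runif(1, 0.1, 2)
    gam <- 8; mu <- 1.2
    sol <- deSolve::zvode(c(u0, v0), c(0, s), function(ss, y, p)
      list(c(gam * (y[1] - mu * y[2] * (y[1] + 1)), y[2])),
      NULL, rtol = 1e-12, atol = 1e-14, maxsteps = 1e5)
    ce <- char_exact_b(u0, v0, s, gamma = gam, mu = mu)
    expect_equal(ce$u, unname(sol[2, 2]), tolerance = 1e-8)
  }
})

test_that("exact forward and inverse characteristics are mutually inverse", {
  u0 <- 0.2 + 0.1i; v0 <- -0.1 + 0.05i
  ce <- char_exact_b(u0, v0, 1.5, gamma = 10, mu = 1.5)
  iv <- inverse_u0_exact(ce$u, ce$v, 1.5, gamma = 10, mu = 1.5)
  expect_equal(iv$u0, u0, tolerance = 1e-10)
  expect_equal(iv$v0, v0, tolerance = 1e-12)
})

test_that("fast-time expansion of the mRNA coordinate", {
  ## initial conditions
  ex <- char_expansion_u(0.3 + 0.1i, -0.2 + 0.1i, 0, eps = 0.1, mu = 1.5)
  expect_equal(ex$u_hat[1], 0.3 + 0.1i, tolerance = 1e-14)
  expect_equal(ex$u_hat[2], 0 + 0i, tolerance = 1e-14)
  ## starting on the critical manifold kills the exponential
  mu <- 1.2; v0 <- -0.15 + 0.2i
  h0 <- mu * v0 / (1 - mu * v0)
  for (sg in c(0.5, 2))
    expect_equal(char_expansion_u(h0, v0, sg, 0.1, mu)$u_hat[1], h0,
                 tolerance = 1e-13)
  ## second-order convergence to the exact characteristic
  u0 <- 0.25 - 0.1i
  errs <- vapply(c(0.1, 0.05, 0.025), function(eps) {
    ex <- char_expansion_u(u0, v0, sigma = 1.5, eps = eps, mu = mu)
    tr <- char_exact_b(u0, v0, s = eps * 1.5, gamma = 1 / eps, mu = mu)
    abs(ex$total - tr$u)
  }, 0)
  expect_gte(loglog_slope(c(0.1, 0.05, 0.025), errs), 1.8)
  expect_error(char_expansion_u(0.1, 1 / 1.5, 1, 0.1, mu = 1.5), "pole")
})

test_that("perturbative inverse transform: limits and round trip", {
  u <- 0.3 + 0.2i; v <- -0.25 + 0.15i; mu <- 1.3
  expect_equal(inverse_u0(u, v, t = 0, eps = 0.1, mu = mu), u,
               tolerance = 1e-13)
  ## v = 0: pure exponential contraction
  expect_equal(inverse_u0(u, 0 + 0i, t = 0.8, eps = 0.1, mu = mu),
               u * exp(-8), tolerance = 1e-12)
  ## composition with the forward expansion recovers u to O(eps^2)
  sg <- 1.2
  errs <- vapply(c(0.1, 0.05, 0.025), function(eps) {
    u0 <- inverse_u0(u, v, t = eps * sg, eps = eps, mu = mu)
    fw <- char_expansion_u(u0, v * exp(-eps * sg), sg, eps, mu)
    abs(fw$total - u)
  }, 0)
  expect_gte(loglog_slope(c(0.1, 0.05, 0.025), errs), 1.8)
})

test_that("fast-time constants from initial data", {
  pb <- pb_plain()
  co <- coeffs_from_ics_b(1, pb, m0 = 0, n0 = 0, u0 = 0 + 0i, v0 = 0 + 0i)
  expect_equal(co$f0, 1 + 0i)
  expect_equal(co$f1, 0 + 0i)
  expect_equal(co$f2, 0 + 0i)
  expect_equal(co$g1, -pb$kappa_0 + 0i)
  expect_equal(co$g2, 0 + 0i)
  ## reconstructed sigma = 0 values
  chi0 <- 0.4; u0 <- 0.2 + 0.1i; v0 <- -0.1 - 0.2i; m0 <- 2; n0 <- 3
  co <- coeffs_from_ics_b(chi0, pb, m0, n0, u0, v0)
  Phi <- (1 + u0)^m0 * (1 + v0)^n0
  expect_equal((co$f0 * pb$kappa_0 + co$g1) / pb$kappa_1, (1 - chi0) * Phi,
               tolerance = 1e-13)
  ## [F^(1)_1]_{sigma=0} = (f1 kappa_0 + g2)/kappa_1 + lam/(kappa_1 q0) *
  ##   (f0 kappa_0 + g1) * A0 must vanish
  q0 <- 1 - pb$mu * v0
  A0 <- u0 - pb$mu * v0 / q0
  F11_0 <- (co$f1 * pb$kappa_0 + co$g2) / pb$kappa_1 +
    pb$lam * (co$f0 * pb$kappa_0 + co$g1) / (pb$kappa_1 * q0) * A0
  expect_equal(F11_0, 0 + 0i, tolerance = 1e-12)
  pk <- model_b_params(1, 1e-12, 1, 1, 0.1)
  pk$kappa_1 <- 0
  expect_error(coeffs_from_ics_b(0.5, pk, 0, 0, 0 + 0i, 0 + 0i), "kappa_1")
})

test_that("eps_order = 0 equals the frozen leading-order closed form", {
  pb <- pb_plain()
  chi <- pb$kappa_1 / (pb$kappa_0 + pb$kappa_1)
  set.seed(3)
  th <- stats::runif(100, 0, 2 * pi); ph <- stats::runif(100, 0, 2 * pi)
  w <- exp(1i * th); z <- exp(1i * ph)
  t <- 0.8
  g <- eval_gf_b(pb, m0 = 2, n0 = 3, w = w, z = z, t = t, eps_order = 0)
  br <- 1 / (1 + pb$mu * (1 - z)) +
    exp(-(1 + pb$mu * (1 - z)) * t / pb$eps) *
    (w - 1 / (1 + pb$mu * (1 - z)))
  ref0 <- chi * (1 + (z - 1) * exp(-t))^3 * br^2
  expect_equal(g$total_F0, ref0, tolerance = 1e-12)
  expect_equal(g$total_F1, (1 - chi) / chi * ref0, tolerance = 1e-12)
})

test_that("t = 0 initial data and exact normalisation at all orders", {
  pb <- pb_plain()
  w <- exp(0.9i); z <- exp(2.2i)
  for (ord in 0:2) {
    g <- eval_gf_b(pb, m0 = 1, n0 = 2, w = w, z = z, t = 1e-12,
                   eps_order = ord, chi = 0.3)
    expect_equal(g$total_F0, 0.3 * w * z^2, tolerance = 1e-8)
    expect_equal(g$total, w * z^2, tolerance = 1e-8)
    gm <- eval_gf_b(pb, m0 = 2, n0 = 3, w = 1 + 0i, z = 1 + 0i, t = 1.3,
                    eps_order = ord, chi = 0.3)
    expect_equal(abs(gm$total - 1), 0, tolerance = 1e-12)
  }
})

test_that("pure-death protein marginal (m0 = 0, leading order)", {
  pb <- pb_plain()
  t <- 0.7
  tab <- protein_marginal(function(w, z)
    eval_gf_b(pb, m0 = 0, n0 = 6, w = w, z = z, t = t, eps_order = 0)$total,
    n_max = 12, t = t, n0 = 6)
  expect_equal(tab$P, closed_forms("binomial_decay", t = t, n0 = 6,
                                   n_max = 12), tolerance = 1e-10)
})

test_that("near-pole contour points are rejected with advice", {
  pb <- pb_plain(mu = 1.5)
  zpole <- 1 + 1 / pb$mu
  expect_error(eval_gf_b(pb, 0, 0, w = 1 + 0i, z = zpole + 1e-10, t = 1),
               "radius")
})

test_that("autoregulated evaluation reduces to the plain one at delta = 0", {
  pb <- pb_plain()
  w <- unit_circle(8); z <- unit_circle(8)
  g0 <- eval_gf_b(pb, 1, 2, w, z, t = 0.6)
  g1 <- autoreg_gf_b(pb, 1, 2, w, z, t = 0.6)
  expect_identical(g0$total_F0, g1$total_F0)
})

test_that("autoregulation correction: initial data, sign and mass", {
  for (reg in c("mRNA_act", "mRNA_rep", "prot_act", "prot_rep")) {
    pb <- pb_reg(reg)
    cc <- chi_series(pb, n0 = 2, order = 1, m0 = 2)
    w <- 0.6 + 0.5i; z <- 0.4 - 0.6i
    g <- autoreg_gf_b(pb, 2, 2, w, z, t = 1e-12)
    g0 <- eval_gf_b(pb, 2, 2, w, z, t = 1e-12, chi = cc[1])
    ## at t = 0 the delta-correction is chi1 * Phi * (1, -1)
    expect_equal(g$total_F0 - g0$total_F0, pb$delta * cc[2] * w^2 * z^2,
                 tolerance = 1e-7)
    expect_equal(g$total_F1 - g0$total_F1, -pb$delta * cc[2] * w^2 * z^2,
                 tolerance = 1e-7)
    ## probability conservation of the corrected series
    gm <- autoreg_gf_b(pb, 2, 2, 1 + 0i, 1 + 0i, t = 1.1)
    expect_equal(abs(gm$total - 1), 0, tolerance = 1e-12)
  }
})
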