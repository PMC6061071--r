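test_that("leading order satisfies the t=0 and z=1 identities", {
  p <- pa_plain(0.7, 1.4, 2.5)
  z <- c(0.3 + 0.8i, -0.9 + 0.1i, 1.2 + 0i)
  g0 <- eval_leading_a(p, n0 = 5, z = z, t = 0, chi0 = 0.4)
  expect_equal(g0$F0, 0.4 * z^5, tolerance = 1e-11)
  expect_equal(g0$F0 + g0$F1, z^5, tolerance = 1e-11)
  for (t in c(0.1, 1, 5)) {
    g1 <- eval_leading_a(p, n0 = 5, z = 1 + 0i, t = t, chi0 = 0.4)
    expect_equal(abs(g1$F0 + g1$F1 - 1), 0, tolerance = 1e-12)
  }
})

test_that("immigration-death limit reproduces the Poisson generating function", {
  p <- model_a_params(0.9, 0, 3)
  z <- unit_circle(16)
  t <- 0.8
  g <- eval_leading_a(p, n0 = 4, z = z, t = t, chi0 = 0)
  ref <- (1 + (z - 1) * exp(-t))^4 * exp(3 * (z - 1) * (1 - exp(-t)))
  expect_equal(g$F0, rep(0 + 0i, 16))
  expect_equal(g$F1, ref, tolerance = 1e-12)
})

test_that("integration constants reconstruct the s=0 data", {
  p <- pa_plain(0.8, 1.3, 2)
  kf <- p$kappa_f; kb <- p$kappa_b; k <- kf + kb
  set.seed(7)
  v0 <- complex(real = stats::runif(5, -0.7, 0.7),
                imaginary = stats::runif(5, -0.7, 0.7))
  chi0 <- 0.35; n0 <- 3
  cc <- leading_constants_a(p, n0 = n0, v0 = v0, chi0 = chi0)
  w0 <- p$lam * v0
  F0s0 <- cc$c1 * kummer_m(kf, 1 + k, w0) +
    cc$c2 * w0^(-k) * kummer_m(-kb, 1 - k, w0)
  expect_equal(F0s0, chi0 * (1 + v0)^n0, tolerance = 1e-10)
  ## second component at s = 0 via the first-order relation
  wdF <- cc$c1 * w0 * kf / (1 + k) * kummer_m(1 + kf, 2 + k, w0) +
    cc$c2 * w0^(-k) * (-k * kummer_m(-kb, 1 - k, w0) +
                         w0 * (-kb / (1 - k)) * kummer_m(1 - kb, 2 - k, w0))
  F1s0 <- (wdF + kf * F0s0) / kb
  expect_equal(F1s0, (1 - chi0) * (1 + v0)^n0, tolerance = 1e-9)
  ## autorepression analogues
  expect_equal(cc$hat_c1, cc$c1 * kf / kb)
  expect_equal(cc$hat_c2, cc$c2)
  ## v0 = 0 limit: value chi0, no blow-up from the w^{-k} branch
  cc0 <- leading_constants_a(p, n0 = n0, v0 = 1e-12 + 0i, chi0 = chi0)
  F000 <- cc0$c1 * kummer_m(kf, 1 + k, p$lam * 1e-12) +
    cc0$c2 * (p$lam * 1e-12)^(-k) * kummer_m(-kb, 1 - k, p$lam * 1e-12)
  expect_equal(F000, chi0 + 0i, tolerance = 1e-8)
})

test_that("leading order is continuous along the unit circle (branch safety)", {
  p <- pa_plain(0.6, 0.9, 4)
  z <- unit_circle(256)
  g <- eval_leading_a(p, n0 = 7, z = z, t = 0.9)
  tot <- g$F0 + g$F1
  jumps <- abs(diff(c(tot, tot[1])))
  expect_lt(max(jumps), 0.5)   # smooth sampling: no branch-cut jumps
})

test_that("first-order correction: quadrature and ODE routes agree", {
  zs <- exp(2i * pi * c(0.07, 0.23, 0.41, 0.66, 0.88))
  for (mk in list(pa_act(), pa_rep())) {
    for (t in c(0.4, 1.6)) {
      q <- first_order_a(mk, n0 = 3, z = zs, t = t, quiet = TRUE)
      o <- first_order_a(mk, n0 = 3, z = zs, t = t, method = "ode",
                         quiet = TRUE)
      expect_lt(max(abs(q$F0 - o$F0), abs(q$F1 - o$F1)), 1e-7)
    }
  }
})

test_that("first-order correction obeys its initial condition and vanishes at z=1", {
  for (mk in list(pa_act(), pa_rep())) {
    cc <- chi_series(mk, n0 = 4, order = 1)
    z <- c(0.4 + 0.6i, -0.2 - 0.5i)
    g <- first_order_a(mk, n0 = 4, z = z, t = 1e-12, quiet = TRUE)
    expect_equal(g$F0, cc[2] * z^4, tolerance = 1e-6)
    expect_equal(g$F1, -cc[2] * z^4, tolerance = 1e-6)
    g1 <- first_order_a(mk, n0 = 4, z = 1 + 0i, t = 1.1, quiet = TRUE)
    expect_equal(abs(g1$F0 + g1$F1), 0, tolerance = 1e-10)
  }
})

test_that("zero regulation coefficient and zero chi1 give a zero correction", {
  p <- model_a_params(0.8, 1.1, 3, regulation = "autoactivation",
                      delta = 0.05, alpha = 0)
  ch <- chi_spec("series", coefficients = c(0.5, 0))
  g <- first_order_a(p, n0 = 2, z = c(0.5 + 0.5i, 1.5 + 0i), t = 1,
                     chi = ch, quiet = TRUE)
  expect_equal(max(abs(g$F0), abs(g$F1)), 0, tolerance = 1e-12)
})

test_that("degenerate kappa sum is nudged, not fatal", {
  p <- model_a_params(1, 1, 2)
  expect_message(g <- eval_leading_a(p, n0 = 2, z = 0.5 + 0.5i, t = 1),
                 "nudging")
  expect_true(all(is.finite(c(g$F0, g$F1))))
})

test_that("eval_gf_a assembles the delta series and normalises", {
  p <- pa_act(0.05)
  g <- eval_gf_a(p, n0 = 3, z = 1 + 0i, t = 1.3, quiet = TRUE)
  expect_equal(g$order, 1L)
  expect_equal(abs(g$total_F0 + g$total_F1 - 1), 0, tolerance = 1e-9)
  expect_equal(g$total_F0,
               g$F0_terms[[1]] + p$delta * g$F0_terms[[2]])
  expect_error(eval_gf_a(p, n0 = 3, z = 1 + 0i, t = 1, order = 2), "order")
  ## order 0 on an unregulated set equals eval_leading_a
  p0 <- pa_plain()
  z <- unit_circle(8)
  expect_equal(eval_gf_a(p0, n0 = 2, z = z, t = 0.7)$total_F0,
               eval_leading_a(p0, n0 = 2, z = z, t = 0.7)$F0)
})
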