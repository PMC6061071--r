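test_that("FSP: point mass at t=0, probability conservation, Poisson limit", {
  p <- pa_plain()
  tab0 <- fsp_propagate("A", p, init = 4, t = 0)
  expect_equal(tab0$P[5], 1, tolerance = 1e-12)
  expect_equal(sum(tab0$P), 1, tolerance = 1e-12)
  for (t in c(0.5, 2)) {
    tab <- fsp_propagate("A", p, init = 4, t = t)
    expect_equal(sum(tab$P), 1, tolerance = 1e-9)
  }
  ## permanently active gene from zero: immigration-death Poisson
  pid <- model_a_params(0, 0, 3)
  tab <- fsp_propagate("A", pid, init = 0, t = 0.9, chi = 0)
  ref <- closed_forms("poisson_immigration_death", t = 0.9, lam = 3,
                      n_max = length(tab$P) - 1)
  expect_equal(tab$P, ref, tolerance = 1e-8)
})

test_that("FSP linearity in the chi split of the initial gene state", {
  p <- pa_plain()
  t <- 0.8
  mix <- fsp_propagate("A", p, 3, t, chi = 0.3)$P
  off <- fsp_propagate("A", p, 3, t, chi = 1)$P
  on <- fsp_propagate("A", p, 3, t, chi = 0)$P
  expect_equal(mix, 0.3 * off + 0.7 * on, tolerance = 1e-10)
})

test_that("model-B FSP conserves probability and respects moments", {
  pb <- pb_plain()
  tab <- fsp_propagate("B", pb, c(1, 2), t = 1)
  expect_equal(sum(tab$P), 1, tolerance = 1e-8)
  ## mean protein against the moment ODE system
  mom <- deSolve::ode(c(pon = 1 - 2 / 3, m = 1, n = 2), c(0, 1),
                      function(tt, y, p) list(c(
                        pb$kappa_0 * (1 - y[1]) - pb$kappa_1 * y[1],
                        pb$lam * y[1] - y[2] / pb$eps,
                        pb$mu * y[2] / pb$eps - y[3])),
                      NULL, rtol = 1e-10, atol = 1e-12)[2, -1]
  nmean <- sum(tab$P %*% (0:(ncol(tab$P) - 1)))
  mmean <- sum((0:(nrow(tab$P) - 1)) %*% tab$P)
  expect_equal(nmean, unname(mom[3]), tolerance = 1e-6)
  expect_equal(mmean, unname(mom[2]), tolerance = 1e-6)
})

test_that("SSA: determinism, constant trajectories, immigration-death mean", {
  p <- pa_plain()
  r1 <- ssa_simulate("A", p, 2, t_final = 1, record_times = c(0.5, 1),
                     n_paths = 50, seed = 99)
  r2 <- ssa_simulate("A", p, 2, t_final = 1, record_times = c(0.5, 1),
                     n_paths = 50, seed = 99)
  expect_identical(r1$counts, r2$counts)
  ## with zero switching/production rates and an empty initial state nothing
  ## can fire (decay is proportional to the count)
  pz <- model_a_params(0, 0, 0)
  rz <- ssa_simulate("A", pz, 0, t_final = 2, record_times = c(1, 2),
                     n_paths = 10, seed = 1, chi = 1)
  expect_true(all(rz$counts == 0))
  ## permanently active: mean protein within 3 standard errors
  pid <- model_a_params(0, 0, 3)
  run <- ssa_simulate("A", pid, 0, t_final = 1, record_times = 1,
                      n_paths = 4000, seed = 12, chi = 0)
  m <- 3 * (1 - exp(-1))
  se <- stats::sd(run$counts[, 1, 1]) / sqrt(4000)
  expect_lt(abs(mean(run$counts[, 1, 1]) - m), 3 * se + 1e-9)
})

test_that("empirical propagator: histogram basics and FSP agreement", {
  p <- pa_plain()
  run <- ssa_simulate("A", p, 3, t_final = 1, record_times = 1,
                      n_paths = 3000, seed = 5)
  emp <- empirical_propagator(run, 1)
  expect_equal(sum(emp$P), 1, tolerance = 1e-12)
  expect_error(empirical_propagator(run, 0.123), "not recorded")
  ref <- fsp_propagate("A", p, 3, t = 1)
  K <- length(emp$P)
  tv <- 0.5 * sum(abs(emp$P - ref$P[1:K])) + 0.5 * sum(ref$P[-(1:K)])
  expect_lt(tv, 3 * sqrt(K / 3000))
  ## single path gives an indicator histogram
  one <- ssa_simulate("A", p, 3, t_final = 0.4, record_times = 0.4,
                      n_paths = 1, seed = 2)
  e1 <- empirical_propagator(one, 0.4)
  expect_equal(sum(e1$P == 1), 1)
})

test_that("synthetic series: shape, determinism, serialisation round trip", {
  p <- pa_plain()
  s <- synth_series("A", p, n0 = 3, dt = 0.5, n_samples = 12, seed = 4)
  expect_equal(nrow(s$samples), 12)
  expect_equal(nrow(s$transitions), 11)
  expect_equal(s$dt, 0.5)
  s2 <- synth_series("A", p, n0 = 3, dt = 0.5, n_samples = 12, seed = 4)
  expect_identical(s$samples, s2$samples)
  s1 <- synth_series("A", p, n0 = 3, dt = 0.5, n_samples = 1, seed = 4)
  expect_equal(nrow(s1$transitions), 0)
  f <- tempfile(fileext = ".tsv")
  write_series(s, f)
  rs <- read_series(f)
  expect_equal(rs$dt, s$dt)
  expect_equal(rs$samples$count, s$samples$count)
  unlink(f)
})

test_that("closed forms: degenerate cases and normalisation", {
  expect_equal(closed_forms("binomial_decay", t = 1, n0 = 0, n_max = 3),
               c(1, 0, 0, 0))
  pmf <- closed_forms("poisson_immigration_death", t = 50, lam = 2.5,
                      n_max = 40)
  expect_equal(sum(pmf * (0:40)), 2.5, tolerance = 1e-10)
  expect_equal(sum(pmf), 1, tolerance = 1e-14)
})

test_that("SSA with each autoregulation channel stays within MC bounds of FSP", {
  ## model A channels
  for (mk in list(pa_act(0.2), pa_rep(0.2))) {
    run <- ssa_simulate("A", mk, 3, t_final = 0.8, record_times = 0.8,
                        n_paths = 2000, seed = 21)
    emp <- empirical_propagator(run, 0.8)
    ref <- fsp_propagate("A", mk, 3, t = 0.8)
    K <- length(emp$P)
    tv <- 0.5 * sum(abs(emp$P - ref$P[1:K])) + 0.5 * sum(ref$P[-(1:K)])
    expect_lt(tv, 3 * sqrt(K / 2000))
  }
  ## one model B channel here (all four are exercised in the acceptance suite)
  pb <- pb_reg("prot_rep", delta = 0.2, eps = 0.2)
  run <- ssa_simulate("B", pb, c(1, 2), t_final = 0.8, record_times = 0.8,
                      n_paths = 1500, seed = 22)
  emp <- empirical_propagator(run, 0.8)
  ref <- fsp_propagate("B", pb, c(1, 2), t = 0.8)
  K <- prod(dim(emp$P))
  tv <- 0.5 * sum(abs(emp$P - ref$P[1:nrow(emp$P), 1:ncol(emp$P)])) +
    0.5 * (1 - sum(ref$P[1:nrow(emp$P), 1:ncol(emp$P)]))
  expect_lt(tv, 3 * sqrt(K / 1500))
})
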