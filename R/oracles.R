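## Independent ground-truth generators: finite-state-projection (FSP)
## integration of the truncated master equation, Gillespie simulation of the
## full reaction schemes, closed-form reference distributions, and the
## synthetic time-series generator used by the likelihood front end.

#' FSP configuration
#'
#' @param n_trunc,m_trunc truncation bounds (inclusive); `NULL` for the
#'   default rule `init + ceil(10*rate + 10*sqrt(rate))` per species.
#' @param rtol,atol integrator tolerances.
#' @return object of class `fsp_config`.
#' @export
fsp_config <- function(n_trunc = NULL, m_trunc = NULL,
                       rtol = 1e-11, atol = 1e-13) {
  structure(list(n_trunc = n_trunc, m_trunc = m_trunc,
                 rtol = rtol, atol = atol), class = "fsp_config")
}

.default_trunc <- function(init, load) {
  init + ceiling(10 * load + 10 * sqrt(load) + 5)
}

## generator matrix for model A (states (gene j, protein n), n = 0..N)
.fsp_gen_a <- function(params, N) {
  kf <- params$kappa_f; kb <- params$kappa_b; lam <- params$lam
  d <- params$delta * .reg_coeff(params)
  areg <- if (params$regulation == "autoactivation") d else 0
  rreg <- if (params$regulation == "autorepression") d else 0
  idx <- function(j, n) j * (N + 1) + n + 1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (n in 0:N) {
    i0 <- idx(0, n); i1 <- idx(1, n)
    on <- kf + areg * n; off <- kb + rreg * n
    add(i0, i0, -on - n); add(i1, i0, on)
    add(i1, i1, -off - n - lam); add(i0, i1, off)
    if (n < N) {
      add(i0, idx(0, n + 1), n + 1); add(i1, idx(1, n + 1), n + 1)
      add(idx(1, n + 1), i1, lam)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(2 * (N + 1), 2 * (N + 1)))
}

## generator matrix for model B (states (gene j, mRNA m, protein n))
.fsp_gen_b <- function(params, Mx, Nx) {
  k0 <- params$kappa_0; k1 <- params$kappa_1
  lam <- params$lam; mu <- params$mu; gam <- 1 / params$eps
  d <- params$delta * .reg_coeff(params)
  nm <- Mx + 1; nn <- Nx + 1
  idx <- function(j, m, n) j * nm * nn + m * nn + n + 1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (m in 0:Mx) for (n in 0:Nx) {
    i0 <- idx(0, m, n); i1 <- idx(1, m, n)
    on <- k0 + switch(params$regulation, mRNA_act = d * m, prot_act = d * n, 0)
    off <- k1 + switch(params$regulation, mRNA_rep = d * m, prot_rep = d * n, 0)
    add(i0, i0, -on); add(i1, i0, on)
    add(i1, i1, -off); add(i0, i1, off)
    out_rate <- gam * m + n + gam * mu * m
    add(i0, i0, -out_rate); add(i1, i1, -out_rate)
    add(i1, i1, -lam)
    if (m < Mx) {
      add(i0, idx(0, m + 1, n), gam * (m + 1))
      add(i1, idx(1, m + 1, n), gam * (m + 1))
      add(idx(1, m + 1, n), i1, lam)
    }
    if (n < Nx) {
      add(i0, idx(0, m, n + 1), n + 1)
      add(i1, idx(1, m, n + 1), n + 1)
      add(idx(0, m, n + 1), i0, gam * mu * m)
      add(idx(1, m, n + 1), i1, gam * mu * m)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(2 * nm * nn, 2 * nm * nn))
}

#' Finite-state-projection propagator
#'
#' Integrates the truncated master equation from an initial point mass split
#' between the gene states (`chi` off, `1 - chi` on) and returns the
#' gene-marginal propagator at time `t`. Truncation validity is checked a
#' posteriori through the retained mass; on violation the truncation is
#' enlarged once before failing.
#'
#' @param model `"A"` or `"B"`.
#' @param params model parameter object.
#' @param init initial state: `n0` (model A) or `c(m0, n0)` (model B).
#' @param t output time.
#' @param chi off-state probability specification (value, [chi_spec()] or
#'   `NULL` for Markov).
#' @param config an [fsp_config()].
#' @return a `propagator_table` (vector over n for model A, matrix over
#'   (m, n) for model B).
#' @export
fsp_propagate <- function(model = c("A", "B"), params, init, t, chi = NULL,
                          config = fsp_config()) {
  model <- match.arg(model)
  tail_tol <- 1e-9
  for (attempt in 1:2) {
    if (model == "A") {
      n0 <- init[1]
      N <- config$n_trunc %||% .default_trunc(n0, params$lam)
      if (attempt == 2) N <- ceiling(N * 1.5)
      chiv <- .chi_value(params, chi, n0 = n0)
      A <- .fsp_gen_a(params, N)
      p0 <- numeric(2 * (N + 1))
      p0[n0 + 1] <- chiv; p0[(N + 1) + n0 + 1] <- 1 - chiv
      sol <- deSolve::ode(p0, c(0, t), function(tt, y, p)
        list(as.vector(A %*% y)), NULL, rtol = config$rtol, atol = config$atol)
      p <- sol[2, -1]
      P <- p[1:(N + 1)] + p[(N + 2):(2 * (N + 1))]
      ## truncation validity: occupancy of the boundary state must be tiny
      if (abs(P[N + 1]) < tail_tol)
        return(.new_propagator_table(P, t = t, n0 = n0, max_imag = 0))
    } else {
      m0 <- init[1]; n0 <- init[2]
      Mx <- config$m_trunc %||%
        .default_trunc(m0, params$lam * params$eps + 1)
      Nx <- config$n_trunc %||%
        .default_trunc(n0, params$lam * params$mu + 1)
      if (attempt == 2) { Mx <- ceiling(Mx * 1.5); Nx <- ceiling(Nx * 1.5) }
      chiv <- .chi_value(params, chi, n0 = n0, m0 = m0)
      A <- .fsp_gen_b(params, Mx, Nx)
      nm <- Mx + 1; nn <- Nx + 1
      p0 <- numeric(2 * nm * nn)
      p0[m0 * nn + n0 + 1] <- chiv
      p0[nm * nn + m0 * nn + n0 + 1] <- 1 - chiv
      sol <- deSolve::ode(p0, c(0, t), function(tt, y, p)
        list(as.vector(A %*% y)), NULL, rtol = config$rtol, atol = config$atol)
      p <- sol[2, -1]
      arr <- array(p, dim = c(nn, nm, 2))       # n fastest, then m, then gene
      Pmn <- t(arr[, , 1] + arr[, , 2])          # rows m, cols n
      tail_occ <- max(abs(Pmn[nrow(Pmn), ]), abs(Pmn[, ncol(Pmn)]))
      if (tail_occ < tail_tol)
        return(.new_propagator_table(Pmn, t = t, n0 = n0, m0 = m0,
                                     max_imag = 0))
    }
  }
  stop("FSP truncation insufficient even after enlargement; supply a larger ",
       "n_trunc/m_trunc in fsp_config()")
}

## reaction tables: each row: rate multiplier, state change. Propensities are
## computed per step; gene state g in {0 (off), 1 (on)}.
.ssa_step_a <- function(state, params) {
  g <- state[1]; n <- state[2]
  d <- params$delta * .reg_coeff(params)
  on <- if (g == 0) params$kappa_f +
      (if (params$regulation == "autoactivation") d * n else 0) else 0
  off <- if (g == 1) params$kappa_b +
      (if (params$regulation == "autorepression") d * n else 0) else 0
  prod <- if (g == 1) params$lam else 0
  props <- c(on, off, prod, n)
  changes <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  list(props = props, changes = changes)
}

.ssa_step_b <- function(state, params) {
  g <- state[1]; m <- state[2]; n <- state[3]
  d <- params$delta * .reg_coeff(params)
  gam <- 1 / params$eps
  on <- if (g == 0) params$kappa_0 + switch(params$regulation,
                                            mRNA_act = d * m,
                                            prot_act = d * n, 0) else 0
  off <- if (g == 1) params$kappa_1 + switch(params$regulation,
                                             mRNA_rep = d * m,
                                             prot_rep = d * n, 0) else 0
  props <- c(on, off,
             if (g == 1) params$lam else 0,   # transcription
             gam * m,                          # mRNA decay
             gam * params$mu * m,              # translation
             n)                                # protein decay
  changes <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  list(props = props, changes = changes)
}

#' Gillespie simulation of the full reaction schemes
#'
#' Exact stochastic simulation (direct method) of model A or B in
#' dimensionless time, including the selected autoregulation channel. The
#' initial gene state of each path is drawn Bernoulli with off-probability
#' `chi`. Per-path random streams are derived from the master seed, so runs
#' are reproducible and paths independent.
#'
#' @inheritParams fsp_propagate
#' @param t_final end time.
#' @param record_times times at which the state is recorded (must include
#'   only values in `[0, t_final]`).
#' @param n_paths number of trajectories.
#' @param seed integer master seed.
#' @return object of class `ssa_run`: list with `counts` (array paths x
#'   record_times x species, species = protein for A, (mRNA, protein) for B),
#'   `gene` (gene-state array), `record_times`, `seed`, `model`.
#' @export
ssa_simulate <- function(model = c("A", "B"), params, init, t_final,
                         record_times = t_final, n_paths = 1L, seed = 1L,
                         chi = NULL) {
  model <- match.arg(model)
  record_times <- sort(unique(record_times))
  stopifnot(all(record_times >= 0), all(record_times <= t_final))
  nspec <- if (model == "A") 1L else 2L
  counts <- array(NA_integer_, dim = c(n_paths, length(record_times), nspec))
  gene <- array(NA_integer_, dim = c(n_paths, length(record_times)))
  chiv <- if (model == "A") .chi_value(params, chi, n0 = init[1])
  else .chi_value(params, chi, n0 = init[2], m0 = init[1])
  stepfun <- if (model == "A") .ssa_step_a else .ssa_step_b
  set.seed(seed)
  path_seeds <- sample.int(.Machine$integer.max, n_paths)
  for (p in seq_len(n_paths)) {
    set.seed(path_seeds[p])
    g0 <- if (stats::runif(1) < chiv) 0L else 1L
    state <- c(g0, init)
    tt <- 0
    ri <- 1L
    while (ri <= length(record_times)) {
      sp <- stepfun(state, params)
      tot <- sum(sp$props)
      dt <- if (tot > 0) stats::rexp(1, tot) else Inf
      while (ri <= length(record_times) && tt + dt > record_times[ri]) {
        counts[p, ri, ] <- state[-1]
        gene[p, ri] <- state[1]
        ri <- ri + 1L
      }
      if (ri > length(record_times) || tot == 0) break
      tt <- tt + dt
      j <- sample.int(length(sp$props), 1, prob = sp$props)
      state <- state + sp$changes[[j]]
    }
    ## fill any remaining record times (absorbing/no-event case)
    while (ri <= length(record_times)) {
      counts[p, ri, ] <- state[-1]
      gene[p, ri] <- state[1]
      ri <- ri + 1L
    }
  }
  structure(list(counts = counts, gene = gene, record_times = record_times,
                 seed = seed, model = model, n_paths = n_paths),
            class = "ssa_run")
}

#' Empirical propagator from a simulation run
#'
#' Normalised histogram of the recorded counts at time `t`, with per-bin
#' Monte-Carlo standard errors.
#'
#' @param run an `ssa_run`.
#' @param t one of the run's record times.
#' @param n_max largest index of the histogram (default: observed maximum).
#' @return a `propagator_table` with an extra `se` component.
#' @export
empirical_propagator <- function(run, t, n_max = NULL) {
  ri <- match(TRUE, abs(run$record_times - t) < 1e-12)
  if (is.na(ri)) stop("time ", t, " was not recorded in this run")
  if (run$model == "A") {
    x <- run$counts[, ri, 1]
    n_max <- n_max %||% max(x)
    P <- tabulate(x + 1L, nbins = n_max + 1L) / length(x)
    se <- sqrt(P * (1 - P) / length(x))
    res <- .new_propagator_table(P, t = t, max_imag = 0)
    res$se <- se
    res
  } else {
    m <- run$counts[, ri, 1]; n <- run$counts[, ri, 2]
    m_max <- max(m); n_max <- n_max %||% max(n)
    P <- matrix(0, m_max + 1, n_max + 1)
    for (i in seq_along(m))
      if (n[i] <= n_max) P[m[i] + 1, n[i] + 1] <- P[m[i] + 1, n[i] + 1] + 1
    P <- P / length(m)
    res <- .new_propagator_table(P, t = t, max_imag = 0)
    res$se <- sqrt(P * (1 - P) / length(m))
    res
  }
}

#' Synthetic protein time series by stochastic simulation
#'
#' Simulates one trajectory and samples the protein count at the regular
#' grid `t_i = i * dt`, producing the fixed-interval transition list used by
#' the likelihood front end. For model B the mRNA count is marginalised
#' (protein only is observed).
#'
#' @inheritParams ssa_simulate
#' @param n0 initial protein count; `m0` initial mRNA count (model B).
#' @param dt sampling interval (> 0).
#' @param n_samples number of samples (series length).
#' @return object of class `transition_series`: list with `dt`, data frame
#'   `samples` (`time`, `count`) and data frame `transitions`
#'   (`from`, `to`).
#' @export
synth_series <- function(model = c("A", "B"), params, n0, dt, n_samples,
                         seed = 1L, chi = NULL, m0 = 0L) {
  model <- match.arg(model)
  stopifnot(dt > 0, n_samples >= 1)
  times <- (seq_len(n_samples) - 1) * dt
  init <- if (model == "A") n0 else c(m0, n0)
  run <- ssa_simulate(model, params, init, t_final = max(times),
                      record_times = times, n_paths = 1L, seed = seed,
                      chi = chi)
  prot <- if (model == "A") run$counts[1, , 1] else run$counts[1, , 2]
  transition_series(times, prot, dt = dt)
}

#' Construct a transition series from sampled counts
#'
#' @param time numeric vector of sampling times with fixed spacing.
#' @param count integer protein counts.
#' @param dt the sampling interval; checked against `time`.
#' @return a `transition_series`.
#' @export
transition_series <- function(time, count, dt = NULL) {
  stopifnot(length(time) == length(count))
  if (length(time) > 1) {
    spac <- diff(time)
    if (max(abs(spac - spac[1])) > 1e-9 * max(spac))
      stop("sampling interval is not fixed")
    dt <- dt %||% spac[1]
    if (abs(dt - spac[1]) > 1e-9 * dt) stop("dt does not match the time grid")
  } else dt <- dt %||% NA_real_
  trans <- if (length(count) > 1)
    data.frame(from = count[-length(count)], to = count[-1])
  else data.frame(from = integer(0), to = integer(0))
  structure(list(dt = dt,
                 samples = data.frame(time = time, count = count),
                 transitions = trans),
            class = "transition_series")
}

#' Write / read a transition series as tab-separated values
#'
#' Two columns (time, count) with a `# dt=` header line.
#'
#' @param x a `transition_series`.
#' @param path file path.
#' @return `path` (write) or a `transition_series` (read).
#' @export
write_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.15g", x$dt), con)
  writeLines("time\tcount", con)
  writeLines(paste(format(x$samples$time, digits = 15), x$samples$count,
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  first <- readLines(path, n = 1)
  dt <- if (grepl("^# dt=", first)) as.numeric(sub("^# dt=", "", first)) else NULL
  df <- utils::read.delim(path, comment.char = "#")
  transition_series(df$time, df$count, dt = dt)
}

#' Closed-form reference distributions
#'
#' `"poisson_immigration_death"`: protein distribution of a permanently
#' active gene starting from zero, Poisson with mean
#' `lam * (1 - exp(-t))`. `"binomial_decay"`: survival of `n0` initial
#' molecules under first-order decay, Binomial(`n0`, `exp(-t)`).
#'
#' @param kind distribution kind.
#' @param lam production rate (immigration-death case).
#' @param n0 initial count (binomial case).
#' @param t elapsed time.
#' @param n_max largest index of the returned pmf.
#' @return numeric pmf vector over `0..n_max`.
#' @export
closed_forms <- function(kind = c("poisson_immigration_death", "binomial_decay"),
                         t, lam = NULL, n0 = NULL, n_max = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         poisson_immigration_death = {
           stopifnot(!is.null(lam))
           mean <- lam * (1 - exp(-t))
           n_max <- n_max %||% .default_trunc(0, lam)
           stats::dpois(0:n_max, mean)
         },
         binomial_decay = {
           stopifnot(!is.null(n0))
           n_max <- n_max %||% n0
           stats::dbinom(0:n_max, n0, exp(-t))
         })
}
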