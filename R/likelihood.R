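## Transition log-likelihood over analytically computed propagators, with a
## propagator-row cache keyed by (model, parameters, dt, contour, engine).

.prop_cache <- new.env(parent = emptyenv())

.cache_key <- function(...) {
  paste(vapply(list(...), function(x) paste(format(unlist(x), digits = 15),
                                            collapse = ","), ""), collapse = "|")
}

#' Clear the propagator cache
#' @export
clear_propagator_cache <- function() {
  rm(list = ls(.prop_cache), envir = .prop_cache)
  invisible(NULL)
}

## one propagator row P_{. | n0}(dt) for either model and engine
.prop_row <- function(model, params, chi, n0, dt, n_max, engine,
                      contour = NULL, m0 = 0L, use_cache = TRUE) {
  key <- .cache_key(model, unclass(params), chi_tag <- if (is.null(chi)) "markov"
                    else unclass(chi), n0, dt, n_max, engine, m0,
                    if (is.null(contour)) "default" else unclass(contour))
  if (use_cache && !is.null(.prop_cache[[key]])) return(.prop_cache[[key]])
  row <- if (engine == "fsp") {
    init <- if (model == "A") n0 else c(m0, n0)
    tab <- fsp_propagate(model, params, init, t = dt, chi = chi)
    P <- if (model == "A") tab$P else colSums(tab$P)
    length(P) <- n_max + 1
    P[is.na(P)] <- 0
    P
  } else {
    if (model == "A") {
      contour <- contour %||% contour_spec()
      gfz <- function(z) {
        gfa <- eval_gf_a(params, n0 = n0, z = z, t = dt, chi = chi,
                         quiet = TRUE)
        gfa$total_F0 + gfa$total_F1
      }
      invert_1d(gfz, n_max, contour = contour, t = dt, n0 = n0)$P
    } else {
      contour <- contour %||%
        contour_spec(radius_z = .default_radius_b(params$mu))
      gfz <- function(z) {
        gfb <- autoreg_gf_b(params, m0 = m0, n0 = n0,
                            w = rep(1 + 0i, length(z)), z = z, t = dt,
                            chi = chi)
        gfb$total
      }
      invert_1d(gfz, n_max, contour = contour, t = dt, n0 = n0)$P
    }
  }
  if (use_cache) .prop_cache[[key]] <- row
  row
}

#' Library of propagator tables over a set of initial states
#'
#' Computes (and caches) one propagator row per initial protein count in
#' `n0_set`, all at the same sampling interval `dt`.
#'
#' @param model `"A"` or `"B"`.
#' @param params model parameters.
#' @param dt sampling interval.
#' @param n0_set integer vector of initial protein counts.
#' @param n_max largest final count reported.
#' @param chi off-state probability specification.
#' @param engine `"analytic"` (generating function + Cauchy inversion) or
#'   `"fsp"`.
#' @param m0 initial mRNA count used for model B (protein-only observation).
#' @param contour optional [contour_spec()].
#' @return named list of probability vectors (names = `n0_set`).
#' @export
propagator_grid <- function(model = c("A", "B"), params, dt, n0_set, n_max,
                            chi = NULL, engine = c("analytic", "fsp"),
                            m0 = 0L, contour = NULL) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  rows <- lapply(n0_set, function(n0)
    .prop_row(model, params, chi, n0, dt, n_max, engine, contour, m0))
  names(rows) <- as.character(n0_set)
  rows
}

#' Transition log-likelihood of a protein time series
#'
#' For a series sampled at fixed interval `dt`, sums the log transition
#' probabilities \eqn{\log P_{n_{i+1}|n_i}(\Delta t)} over consecutive
#' sample pairs. Propagator rows are computed once per distinct initial
#' count. Probabilities are floored at `1e-300` before taking logs; floored
#' transitions are counted in `n_underflow`. In Markov mode the off-state
#' probability is re-evaluated from each transition's initial count.
#'
#' @param series a `transition_series` (see [synth_series()], [read_series()]).
#' @inheritParams propagator_grid
#' @param n_max largest count in the propagator support; default: generous
#'   bound from the series maximum and the production load.
#' @return object of class `likelihood_result`: list with `loglik`,
#'   `per_transition` data frame, and `n_underflow`.
#' @export
log_likelihood <- function(series, model = c("A", "B"), params, chi = NULL,
                           engine = c("analytic", "fsp"), n_max = NULL,
                           m0 = 0L, contour = NULL) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  stopifnot(inherits(series, "transition_series"))
  tr <- series$transitions
  if (nrow(tr) == 0) stop("series contains no transitions")
  if (!is.finite(series$dt) || series$dt <= 0) stop("series dt must be positive")
  load <- if (model == "A") params$lam else params$lam * params$mu
  n_max <- n_max %||% .default_trunc(max(series$samples$count), load)
  floor_p <- 1e-300
  rows <- propagator_grid(model, params, dt = series$dt,
                          n0_set = sort(unique(tr$from)), n_max = n_max,
                          chi = chi, engine = engine, m0 = m0,
                          contour = contour)
  P <- vapply(seq_len(nrow(tr)), function(i) {
    row <- rows[[as.character(tr$from[i])]]
    if (tr$to[i] > n_max) 0 else row[tr$to[i] + 1]
  }, 0)
  if (any(P < -1e-6))
    stop("propagator row contains probabilities below -1e-6: the asymptotic ",
         "expansion is inaccurate here; reduce delta/eps or use the fsp engine")
  n_under <- sum(P < floor_p)
  logP <- log(pmax(P, floor_p))
  structure(list(loglik = sum(logP),
                 per_transition = data.frame(from = tr$from, to = tr$to,
                                             P = P, logP = logP),
                 n_underflow = n_under),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat("transition log-likelihood:", format(x$loglik, digits = 10), "over",
      nrow(x$per_transition), "transitions")
  if (x$n_underflow > 0) cat(" (", x$n_underflow, " floored)", sep = "")
  cat("\n")
  invisible(x)
}
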