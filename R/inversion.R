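#' Contour specification for Cauchy inversion
#'
#' Circular contours centred at the origin. Node counts default to the
#' smallest power of two that is at least `max(64, 4 * (index_max + 1))`,
#' giving spectral accuracy for generating functions holomorphic in a
#' neighbourhood of the closed disc. For model B the z-radius should not
#' exceed 1 (the generating function generically has a pole at
#' `z = 1 + 1/mu`).
#'
#' @param radius_z,radius_w contour radii (positive).
#' @param nodes_z,nodes_w node counts; `NULL` for the default rule.
#' @return object of class `contour_spec`.
#' @export
contour_spec <- function(radius_z = 1, radius_w = 1,
                         nodes_z = NULL, nodes_w = NULL) {
  if (radius_z <= 0 || radius_w <= 0) stop("contour radii must be positive")
  structure(list(radius_z = radius_z, radius_w = radius_w,
                 nodes_z = nodes_z, nodes_w = nodes_w),
            class = "contour_spec")
}

.default_nodes <- function(index_max) {
  2^ceiling(log2(max(64, 4 * (index_max + 1))))
}

## default z-radius for model B: stay clear of the pole at 1 + 1/mu while
## never exceeding 1
.default_radius_b <- function(mu) min(1, 0.75 * (1 + 1 / mu))

.new_propagator_table <- function(P, t = NA_real_, n0 = NA_integer_,
                                  m0 = NULL, max_imag = NA_real_) {
  P <- unname(P)
  structure(list(P = P, t = t, n0 = n0, m0 = m0,
                 mass = sum(P), max_imag = max_imag),
            class = "propagator_table")
}

#' @export
print.propagator_table <- function(x, ...) {
  dims <- if (is.matrix(x$P)) paste(dim(x$P), collapse = " x ") else length(x$P)
  cat("propagator table (", dims, " states), t = ", format(x$t),
      ", mass = ", format(x$mass, digits = 10),
      ", max residual imaginary part = ", format(x$max_imag, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Invert a one-variable generating function to probabilities
#'
#' Reconstructs \eqn{P_n} for `n = 0..n_max` from contour samples of the
#' generating function via the trapezoidal discretisation of the Cauchy
#' integral, which is exactly a discrete Fourier transform of the samples:
#' \eqn{P_n = r^{-n} M^{-1} \sum_k F(r e^{2\pi i k/M}) e^{-2\pi i k n/M}}.
#'
#' @param gf a function of a complex vector `z`, or a complex vector of
#'   samples already taken on the contour nodes.
#' @param n_max largest index to report; must satisfy `n_max < nodes/2`.
#' @param contour a [contour_spec()].
#' @param t,n0 metadata stored in the result (optional).
#' @param clip if `TRUE`, negative entries are set to zero and the table is
#'   renormalised; by default small negative values are reported as a
#'   diagnostic of expansion error.
#' @return a `propagator_table` with real probabilities `P`, total `mass` and
#'   the largest residual imaginary part `max_imag`.
#' @export
invert_1d <- function(gf, n_max, contour = contour_spec(),
                      t = NA_real_, n0 = NA_integer_, clip = FALSE) {
  M <- contour$nodes_z %||% .default_nodes(n_max)
  if (n_max >= M / 2)
    stop("aliasing: n_max = ", n_max, " requires more than ", M,
         " contour nodes")
  r <- contour$radius_z
  if (is.function(gf)) {
    zk <- r * exp(2i * pi * (0:(M - 1)) / M)
    samp <- gf(zk)
  } else {
    samp <- as.complex(gf)
    M <- length(samp)
    if (n_max >= M / 2) stop("aliasing: too few samples for n_max")
  }
  if (any(!is.finite(samp))) {
    bad <- which(!is.finite(samp))[1]
    stop("generating function returned a non-finite value at contour node ",
         bad, " of ", M)
  }
  co <- stats::fft(samp) / M
  Pn <- co[1:(n_max + 1)] / r^(0:n_max)
  res <- .new_propagator_table(Re(Pn), t = t, n0 = n0,
                               max_imag = max(abs(Im(Pn))))
  if (clip) {
    res$P <- pmax(res$P, 0)
    res$P <- res$P / sum(res$P)
    res$mass <- 1
  }
  res
}

#' Invert a two-variable generating function to joint probabilities
#'
#' Tensor-product trapezoidal Cauchy inversion: a two-dimensional discrete
#' Fourier transform of the samples on the product of circular contours.
#' Rows index the `w` (mRNA) exponent, columns the `z` (protein) exponent.
#'
#' @param gf a function of two equal-shape complex matrices `(w, z)`, or a
#'   complex matrix of samples on the node grid (w-nodes by z-nodes).
#' @param m_max,n_max largest indices to report.
#' @inheritParams invert_1d
#' @return a `propagator_table` with matrix `P`.
#' @export
invert_2d <- function(gf, m_max, n_max, contour = contour_spec(),
                      t = NA_real_, n0 = NA_integer_, m0 = NA_integer_,
                      clip = FALSE) {
  Mw <- contour$nodes_w %||% .default_nodes(m_max)
  Mz <- contour$nodes_z %||% .default_nodes(n_max)
  rw <- contour$radius_w; rz <- contour$radius_z
  if (is.function(gf)) {
    wk <- rw * exp(2i * pi * (0:(Mw - 1)) / Mw)
    zk <- rz * exp(2i * pi * (0:(Mz - 1)) / Mz)
    W <- matrix(wk, Mw, Mz)
    Z <- matrix(zk, Mw, Mz, byrow = TRUE)
    samp <- matrix(as.complex(gf(W, Z)), Mw, Mz)
  } else {
    samp <- gf
    Mw <- nrow(samp); Mz <- ncol(samp)
  }
  if (m_max >= Mw / 2 || n_max >= Mz / 2) stop("aliasing: too few nodes")
  if (any(!is.finite(samp)))
    stop("generating function returned non-finite contour samples")
  co <- stats::fft(samp) / (Mw * Mz)
  P <- co[1:(m_max + 1), 1:(n_max + 1), drop = FALSE]
  P <- P / outer(rw^(0:m_max), rz^(0:n_max))
  res <- .new_propagator_table(Re(P), t = t, n0 = n0, m0 = m0,
                               max_imag = max(abs(Im(P))))
  if (clip) {
    res$P <- pmax(res$P, 0)
    res$P <- res$P / sum(res$P)
    res$mass <- 1
  }
  res
}

#' Protein marginal by collapsing the mRNA variable
#'
#' Marginalising over the mRNA index amounts to evaluating the joint
#' generating function at `w = 1` and inverting in `z` only.
#'
#' @param gf2d function of `(w, z)` as in [invert_2d()].
#' @inheritParams invert_1d
#' @return a `propagator_table` over the protein index.
#' @export
protein_marginal <- function(gf2d, n_max, contour = contour_spec(),
                             t = NA_real_, n0 = NA_integer_, clip = FALSE) {
  invert_1d(function(z) gf2d(rep(1 + 0i, length(z)), z), n_max,
            contour = contour, t = t, n0 = n0, clip = clip)
}

#' Write a propagator table as tab-separated values
#'
#' Header lines (prefixed `#`) carry the metadata; the body is one row per
#' state index (1-D) or an `m` by `n` matrix with row/column labels.
#'
#' @param x a `propagator_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_propagator_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# propagator table: t=%s n0=%s m0=%s mass=%.12g max_imag=%.3g",
                     format(x$t), format(x$n0),
                     if (is.null(x$m0)) "NA" else format(x$m0),
                     x$mass, x$max_imag), con)
  if (is.matrix(x$P)) {
    writeLines(paste(c("m\\n", 0:(ncol(x$P) - 1)), collapse = "\t"), con)
    for (i in seq_len(nrow(x$P)))
      writeLines(paste(c(i - 1, format(x$P[i, ], digits = 15)), collapse = "\t"), con)
  } else {
    writeLines("n\tP", con)
    writeLines(paste(0:(length(x$P) - 1), format(x$P, digits = 15), sep = "\t"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
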