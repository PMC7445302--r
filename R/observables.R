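coords_of <- function(conf) {
  if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
}

#' Squared radius of gyration of one conformation
#'
#' \deqn{R_g^2 = \frac{1}{2M^2}\sum_{n,m} (r_n - r_m)^2,} identically the
#' mean squared deviation of the beads from their centroid. Both routes are
#' implemented: `"centroid"` (O(M), default) and the literal `"pairs"`
#' double sum (O(M^2), useful as a cross-check).
#'
#' @param conf a `"conformation"` or a numeric coordinate matrix (beads in
#'   rows).
#' @param method `"centroid"` or `"pairs"`.
#' @return \eqn{R_g^2} in squared length units.
#' @export
radius_of_gyration_sq <- function(conf, method = c("centroid", "pairs")) {
  x <- coords_of(conf)
  stopifnot(nrow(x) >= 2)
  method <- match.arg(method)
  if (method == "centroid") {
    xc <- sweep(x, 2L, colMeans(x))
    mean(rowSums(xc^2))
  } else {
    sum(dist(x)^2) / nrow(x)^2
  }
}

# Recover (row, col) bead indices from a position in the dist() vector.
dist_pair_index <- function(p, M) {
  ends <- cumsum((M - 1L):1L)
  i <- which(p <= ends)[1L]
  j <- i + p - c(0L, ends)[i]
  c(i, j)
}

#' Kirkwood reciprocal hydrodynamic radius of one conformation
#'
#' \deqn{R_H^{-1} = \frac{1}{M^2}\sum_{n \ne m} |r_n - r_m|^{-1}.}
#' The diagonal (divergent) terms are excluded while the `1/M^2`
#' normalisation is kept, matching standard Kirkwood practice; the O(1/M)
#' difference from a `1/(M(M-1))` normalisation is absorbed by the
#' finite-size extrapolation. With `pairs = K` an unbiased estimate from `K`
#' uniformly drawn ordered off-diagonal pairs is returned instead of the
#' exact sum.
#'
#' @inheritParams radius_of_gyration_sq
#' @param pairs `"exact"` for the full sum, or a positive integer `K` for
#'   the subsampled estimator.
#' @return \eqn{R_H^{-1}} in inverse length units.
#' @export
inverse_hydrodynamic_radius <- function(conf, pairs = "exact") {
  x <- coords_of(conf)
  M <- nrow(x)
  stopifnot(M >= 2)
  if (identical(pairs, "exact")) {
    dd <- dist(x)
    small <- dd < 1e-12
    if (any(small)) {
      ij <- dist_pair_index(which(small)[1L], M)
      stop(sprintf("coincident beads %d and %d (distance < 1e-12)",
                   ij[1L], ij[2L]))
    }
    2 * sum(1 / dd) / M^2
  } else {
    K <- as.integer(pairs)
    stopifnot(length(K) == 1L, K >= 1L)
    if (K >= M^2 - M) { # full coverage: fall back to the exact sum
      return(inverse_hydrodynamic_radius(x, pairs = "exact"))
    }
    i <- sample.int(M, K, replace = TRUE)
    j <- sample.int(M - 1L, K, replace = TRUE)
    j <- j + (j >= i)
    dd <- sqrt(rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2))
    if (any(dd < 1e-12)) {
      b <- which(dd < 1e-12)[1L]
      stop(sprintf("coincident beads %d and %d (distance < 1e-12)",
                   i[b], j[b]))
    }
    mean(1 / dd) * (M^2 - M) / M^2
  }
}

#' Exact finite-N observables of the discrete ideal chain
#'
#' Closed-form ensemble means for a linear Gaussian chain of `M` beads
#' (unit per-component step variance, `dim = 3`): pair separations are
#' Gaussian with per-component variance `|n - m|`, hence
#' `rg2 = (M^2 - 1)/(2 M)` and
#' \deqn{\langle R_H^{-1}\rangle = \frac{2}{M^2}\sqrt{2/\pi}
#'   \sum_{j=1}^{M-1}\frac{M-j}{\sqrt{j}}.}
#' Used as the independent oracle for the sampler and as an exact
#' finite-size series for the extrapolation fit.
#'
#' @param M number of beads (`>= 2`).
#' @return List with `rg2`, `rhinv`, `rho`.
#' @export
discrete_chain_reference <- function(M) {
  stopifnot(M >= 2, M == round(M))
  j <- seq_len(M - 1L)
  rg2 <- (M^2 - 1) / (2 * M)
  rhinv <- 2 / M^2 * sqrt(2 / pi) * sum((M - j) / sqrt(j))
  list(rg2 = rg2, rhinv = rhinv, rho = sqrt(rg2) * rhinv)
}

#' Exact finite-N observables of the discrete ideal ring
#'
#' Closed-form ensemble means for a Gaussian ring of `n` beads and `n` bonds
#' (unit per-component step variance, `dim = 3`): the separation of beads
#' `j` bonds apart along the cycle is Gaussian with per-component variance
#' `j (n - j) / n` (Brownian bridge), giving `rg2 = (n^2 - 1)/(4 n)` and
#' \deqn{\langle R_H^{-1}\rangle = \frac{\sqrt{2/\pi}}{n}
#'   \sum_{j=1}^{n-1}\sqrt{\frac{n}{j (n - j)}}.}
#'
#' @param n number of beads (= bonds) in the ring (`>= 2`).
#' @return List with `rg2`, `rhinv`, `rho`.
#' @export
discrete_ring_reference <- function(n) {
  stopifnot(n >= 2, n == round(n))
  j <- seq_len(n - 1L)
  rg2 <- (n^2 - 1) / (4 * n)
  rhinv <- sqrt(2 / pi) / n * sum(sqrt(n / (j * (n - j))))
  list(rg2 = rg2, rhinv = rhinv, rho = sqrt(rg2) * rhinv)
}

#' Ensemble estimate of gyration radius, Kirkwood radius and size ratio
#'
#' Averages [radius_of_gyration_sq()] and [inverse_hydrodynamic_radius()]
#' over conformations and combines the ensemble means into
#' \eqn{\rho = \sqrt{\langle R_g^2\rangle}\,\langle R_H^{-1}\rangle}
#' (means are taken before combining, matching the defining equations).
#' Standard errors come from a delete-one-block jackknife over
#' conformations, which propagates the within-conformation correlation of
#' the two observables into the error of \eqn{\rho}; for correlated series
#' (e.g. molecular-dynamics frames) set `block_size` to a decorrelation
#' length in frames.
#'
#' @param confs list of conformations sharing one topology.
#' @param pairs passed to [inverse_hydrodynamic_radius()].
#' @param block_size jackknife block length (default 1: independent
#'   conformations).
#' @return Object of class `"ensemble_estimate"` with fields `rg2`,
#'   `rg2_err`, `rhinv`, `rhinv_err`, `rho`, `rho_err`, `n_conf`,
#'   `n_blocks`, `pair_mode`, `topology`.
#' @export
ensemble_estimate <- function(confs, pairs = "exact", block_size = 1L) {
  stopifnot(is.list(confs), length(confs) >= 2, block_size >= 1)
  tops <- lapply(confs, function(cf) {
    if (inherits(cf, "conformation")) unclass(cf$topology) else NULL
  })
  if (!all(vapply(tops, identical, logical(1), tops[[1L]]))) {
    stop("conformations with mixed topologies cannot be pooled")
  }
  rg2 <- vapply(confs, radius_of_gyration_sq, numeric(1))
  rh <- vapply(confs, inverse_hydrodynamic_radius, numeric(1), pairs = pairs)
  n <- length(confs)
  blk <- ceiling(seq_len(n) / block_size)
  B <- max(blk)
  if (B < 2L) stop("need at least two jackknife blocks")
  s_rg2 <- sum(rg2); s_rh <- sum(rh)
  b_rg2 <- vapply(split(rg2, blk), sum, numeric(1))
  b_rh <- vapply(split(rh, blk), sum, numeric(1))
  b_n <- vapply(split(rg2, blk), length, numeric(1))
  jack <- function(vals) sqrt((B - 1) / B * sum((vals - mean(vals))^2))
  loo_rg2 <- (s_rg2 - b_rg2) / (n - b_n)
  loo_rh <- (s_rh - b_rh) / (n - b_n)
  structure(
    list(
      rg2 = s_rg2 / n, rg2_err = jack(loo_rg2),
      rhinv = s_rh / n, rhinv_err = jack(loo_rh),
      rho = sqrt(s_rg2 / n) * (s_rh / n),
      rho_err = jack(sqrt(loo_rg2) * loo_rh),
      n_conf = n, n_blocks = B,
      pair_mode = if (identical(pairs, "exact")) "exact"
                  else sprintf("subsampled(%d)", as.integer(pairs)),
      topology = if (inherits(confs[[1L]], "conformation"))
        confs[[1L]]$topology else NULL
    ),
    class = "ensemble_estimate"
  )
}

#' @export
print.ensemble_estimate <- function(x, ...) {
  cat(sprintf("Ensemble estimate over %d conformations (%s pairs, %d blocks)\n",
              x$n_conf, x$pair_mode, x$n_blocks))
  cat(sprintf("  <Rg^2>   = %.6g +/- %.2g\n", x$rg2, x$rg2_err))
  cat(sprintf("  <1/R_H>  = %.6g +/- %.2g\n", x$rhinv, x$rhinv_err))
  cat(sprintf("  rho      = %.6g +/- %.2g\n", x$rho, x$rho_err))
  invisible(x)
}
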