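#' Sample a free Gaussian arm
#'
#' Bead `k` of a linear arm rooted at the origin is the cumulative sum of
#' `k` i.i.d. centred Gaussian steps with per-component variance `step_var`,
#' so `<r_k^2> = dim * k * step_var`.
#'
#' @param n number of beads (bond steps) in the arm.
#' @param dim spatial dimension.
#' @param step_var per-component variance of one step.
#' @return `n x dim` matrix of bead coordinates (core excluded).
#' @export
sample_linear_arm <- function(n, dim = 3L, step_var = 1) {
  stopifnot(n >= 1, step_var >= 0)
  steps <- matrix(rnorm(n * dim, sd = sqrt(step_var)), n, dim)
  apply(steps, 2L, cumsum)
}

#' Sample a Gaussian ring arm (Brownian bridge)
#'
#' A ring arm is a random walk conditioned to return to the core after `n`
#' steps. It is constructed from a free walk `W` as the exact bridge
#' `r_k = W_k - (k/n) W_n`; the closure is exact by construction and bead `k`
#' has per-component variance `step_var * k (n - k) / n`. Only the `n - 1`
#' interior beads are returned (bead `n` is the core).
#'
#' @param n number of bond steps in the ring (`>= 2`).
#' @inheritParams sample_linear_arm
#' @return `(n - 1) x dim` matrix of interior bead coordinates.
#' @export
sample_ring_arm <- function(n, dim = 3L, step_var = 1) {
  stopifnot(n >= 2, step_var >= 0)
  w <- apply(matrix(rnorm(n * dim, sd = sqrt(step_var)), n, dim), 2L, cumsum)
  k <- seq_len(n - 1L)
  w[k, , drop = FALSE] - (k / n) %o% w[n, ]
}

#' Sample one rosette conformation from the exact Gaussian measure
#'
#' Arms are mutually independent (ideal polymer, no interactions) and rooted
#' at a common core placed at the origin. Linear arms are free cumulative
#' walks, ring arms Brownian bridges; no dynamics, equilibration or
#' integrator bias is involved — every conformation is an exact independent
#' draw.
#'
#' @param topology a [rosette_topology()].
#' @return An object of class `"conformation"`: list with `coords`
#'   (`M x dim` matrix, core in row 1), `topology`, and per-bead bookkeeping
#'   `arm` (0 for the core, else arm index) and `pos` (steps from the core
#'   along the arm).
#' @export
sample_rosette <- function(topology) {
  stopifnot(inherits(topology, "rosette_topology"))
  d <- topology$dim
  n <- topology$n
  coords <- matrix(0, topology$M, d)
  arm <- integer(topology$M)
  pos <- integer(topology$M)
  for (a in seq_len(topology$f)) {
    idx <- arm_bead_index(topology, a)
    coords[idx, ] <- if (a <= topology$fc) {
      sample_linear_arm(n, d, topology$step_var)
    } else {
      sample_ring_arm(n, d, topology$step_var)
    }
    arm[idx] <- a
    pos[idx] <- seq_along(idx)
  }
  structure(list(coords = coords, topology = topology, arm = arm, pos = pos),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d beads in %d dimensions (fc = %d, fr = %d)\n",
              nrow(x$coords), ncol(x$coords), x$topology$fc, x$topology$fr))
  invisible(x)
}

#' Simulate an ensemble of independent rosette conformations
#'
#' Draws `nsim` exact, independent conformations from the Gaussian measure of
#' the architecture. When `seed` is given, each conformation is generated
#' from its own L'Ecuyer-CMRG substream derived deterministically from the
#' root seed, so ensembles are reproducible and extensible; the caller's RNG
#' state is restored on exit.
#'
#' @param object a [rosette_topology()].
#' @param nsim number of conformations.
#' @param seed optional integer root seed.
#' @param ... unused.
#' @return A list of [sample_rosette()] conformations, with the seed stored
#'   in attribute `"seed"`.
#' @export
simulate.rosette_topology <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(nsim >= 1)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
    set.seed(as.integer(seed))
    stream <- get(".Random.seed", envir = globalenv())
    confs <- vector("list", nsim)
    for (i in seq_len(nsim)) {
      assign(".Random.seed", stream, envir = globalenv())
      confs[[i]] <- sample_rosette(object)
      stream <- parallel::nextRNGStream(stream)
    }
  } else {
    confs <- lapply(seq_len(nsim), function(i) sample_rosette(object))
  }
  attr(confs, "seed") <- seed
  confs
}
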