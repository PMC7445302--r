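#' Langevin bead-spring parameters
#'
#' Physical parameters of the bead-spring model in reduced units: energies in
#' `kT`, lengths in the equilibrium bond length `b`, masses in `m`, times in
#' `tau = sqrt(m b^2 / kT)`. Defaults are the standard stiff-bond protocol:
#' bond strength `k = 200 kT/b^2`, equilibrium bond `r0 = b`, friction
#' `zeta = 0.5 m/tau`, timestep `dt = 0.0025 tau`. Stability requires
#' `dt * sqrt(k/mass)` well below 1 (0.035 with defaults).
#'
#' @param k harmonic bond strength (energy/length^2).
#' @param r0 equilibrium bond length.
#' @param zeta friction coefficient (mass/time).
#' @param dt integration timestep.
#' @param kT thermal energy.
#' @param mass bead mass.
#' @param n_equil_steps,n_sample_steps,sample_interval optional protocol
#'   counts; when `NULL`, [run_md()] chooses them from the arm relaxation
#'   time.
#' @param seed optional RNG seed used by [run_md()].
#' @return Object of class `"md_params"`.
#' @export
md_params <- function(k = 200, r0 = 1, zeta = 0.5, dt = 0.0025, kT = 1,
                      mass = 1, n_equil_steps = NULL, n_sample_steps = NULL,
                      sample_interval = NULL, seed = NULL) {
  stopifnot(k > 0, r0 > 0, zeta > 0, dt > 0, kT >= 0, mass > 0)
  s <- dt * sqrt(k / mass)
  if (s >= 1) stop("unstable timestep: dt * sqrt(k/mass) = ", format(s))
  if (s > 0.2) warning("large timestep: dt * sqrt(k/mass) = ", format(s))
  structure(
    list(k = k, r0 = r0, zeta = zeta, dt = dt, kT = kT, mass = mass,
         n_equil_steps = n_equil_steps, n_sample_steps = n_sample_steps,
         sample_interval = sample_interval, seed = seed),
    class = "md_params"
  )
}

#' Harmonic bond forces
#'
#' Force on each bead from the harmonic potential `V(r) = k/2 (r - r0)^2`
#' summed over the bond list; Newton's third law holds pairwise and the
#' total internal force is zero.
#'
#' @param conf a `"conformation"` or coordinate matrix.
#' @param bonds integer bond matrix from [bond_list()] (1-based).
#' @param params an [md_params()].
#' @return Matrix of per-bead forces, same shape as the coordinates.
#' @export
bonded_forces <- function(conf, bonds, params = md_params()) {
  x <- coords_of(conf)
  stopifnot(is.matrix(bonds), ncol(bonds) == 2)
  bonded_forces_cpp(x, matrix(as.integer(bonds - 1L), ncol = 2),
                    params$k, params$r0)
}

#' One Langevin integration step
#'
#' Advances positions and velocities by one timestep of the velocity-Verlet
#' scheme with an analytically exact joint (x, v) Ornstein-Uhlenbeck
#' friction/noise substep, so the discretised noise obeys the
#' fluctuation-dissipation relation at any `dt` and the free particle
#' equilibrates to per-component velocity variance `kT/mass` exactly. In the
#' high-friction limit the per-step displacement variance tends to the
#' overdamped value `2 kT dt / zeta` per component.
#'
#' @param state list with `coords` and `vel` matrices.
#' @param bonds bond matrix from [bond_list()].
#' @param params an [md_params()].
#' @return Updated `state` list.
#' @export
langevin_step <- function(state, bonds, params = md_params()) {
  out <- langevin_run_cpp(state$coords, state$vel,
                          matrix(as.integer(bonds - 1L), ncol = 2),
                          params$k, params$r0, params$zeta, params$dt,
                          params$kT, params$mass, 1L, 0L)
  list(coords = out$x, vel = out$v)
}

# Arm relaxation time of the slowest Rouse mode, in integration steps.
relax_steps <- function(topology, params) {
  t_relax <- params$zeta * topology$n^2 * params$r0^2 /
    (3 * pi^2 * params$kT)
  max(100L, as.integer(ceiling(t_relax / params$dt)))
}

#' Run a Langevin molecular-dynamics trajectory
#'
#' Builds the bead-spring rosette, equilibrates, then samples frames at a
#' fixed interval. Defaults are scaled to the slowest arm relaxation time
#' `t_R = zeta n^2 r0^2 / (3 pi^2 kT)`: equilibration `4 t_R`, production
#' `40 t_R`, one frame every `t_R / 20` (about 800 frames). Stationarity is
#' checked on the production `Rg^2` series: the first-half and second-half
#' means, with standard errors from block means of `2 t_R` blocks, must
#' agree within 3 combined SE; residual equilibration drift would show up
#' here. A failure raises a warning, not an error. The trajectory is
#' deterministic given `seed`.
#'
#' Consecutive frames are correlated; analyse them with
#' [ensemble_estimate()] using the suggested `block_size` stored in the
#' result (frames per `2 t_R`).
#'
#' @param topology a [rosette_topology()] (its `step_var` is ignored; length
#'   scale is set by `params$r0`).
#' @param params an [md_params()].
#' @param n_equil,n_steps,sample_every optional overrides of the protocol
#'   defaults (integers, in integration steps).
#' @param seed RNG seed (falls back to `params$seed`).
#' @return Object of class `"md_trajectory"`: list with `frames` (list of
#'   `"conformation"` objects), `diagnostics` (data frame: `step`,
#'   `kinetic_T`, `bond_mean`, `bond_msd`, `rg2`), `block_size`,
#'   `stationary`, `topology`, `params`, `n_equil`, `sample_every`, `seed`.
#' @export
run_md <- function(topology, params = md_params(), n_equil = NULL,
                   n_steps = NULL, sample_every = NULL, seed = NULL) {
  stopifnot(inherits(topology, "rosette_topology"),
            inherits(params, "md_params"))
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- relax_steps(topology, params)
  if (is.null(n_equil)) n_equil <- params$n_equil_steps
  if (is.null(n_steps)) n_steps <- params$n_sample_steps
  if (is.null(sample_every)) sample_every <- params$sample_interval
  if (is.null(n_equil)) n_equil <- 4L * tr
  if (is.null(n_steps)) n_steps <- 40L * tr
  if (is.null(sample_every)) sample_every <- max(1L, tr %/% 20L)
  n_equil <- as.integer(n_equil); n_steps <- as.integer(n_steps)
  sample_every <- as.integer(sample_every)

  bonds <- matrix(as.integer(bond_list(topology) - 1L), ncol = 2)
  # start from an exact Gaussian draw at the bond length scale
  top0 <- rosette_topology(topology$fc, topology$fr, topology$n,
                           dim = topology$dim,
                           step_var = params$r0^2 / topology$dim)
  template <- sample_rosette(top0)
  x0 <- template$coords
  v0 <- matrix(rnorm(length(x0), sd = sqrt(params$kT / params$mass)),
               nrow(x0), ncol(x0))

  eq <- langevin_run_cpp(x0, v0, bonds, params$k, params$r0, params$zeta,
                         params$dt, params$kT, params$mass, n_equil, 0L)

  run <- langevin_run_cpp(eq$x, eq$v, bonds, params$k, params$r0,
                          params$zeta, params$dt, params$kT, params$mass,
                          n_steps, sample_every)
  frames <- lapply(run$frames, function(xx) {
    structure(list(coords = xx, topology = topology,
                   arm = template$arm, pos = template$pos),
              class = "conformation")
  })
  M <- topology$M
  diagnostics <- data.frame(
    step = run$frame_step,
    kinetic_T = 2 * run$ke / (topology$dim * M),
    bond_mean = run$bond_mean,
    bond_msd = run$bond_msd,
    rg2 = vapply(frames, radius_of_gyration_sq, numeric(1))
  )
  block_size <- max(1L, as.integer(ceiling(2 * tr / sample_every)))

  # stationarity: production halves compared through 2 t_R block means
  bm <- vapply(split(diagnostics$rg2,
                     ceiling(seq_along(diagnostics$rg2) / block_size)),
               mean, numeric(1))
  stationary <- NA
  if (length(bm) >= 4L) {
    h <- length(bm) %/% 2L
    a <- bm[seq_len(h)]
    b <- bm[seq.int(h + 1L, length(bm))]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    stationary <- is.finite(se) && abs(mean(a) - mean(b)) <= 3 * se
    if (!stationary) {
      warning("Rg^2 drift between production halves exceeds 3 SE; ",
              "consider a longer n_equil / n_steps")
    }
  }
  structure(
    list(frames = frames, diagnostics = diagnostics,
         block_size = block_size,
         stationary = stationary, topology = topology, params = params,
         n_equil = n_equil, sample_every = sample_every, seed = seed),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "Langevin MD trajectory: %d frames every %d steps (fc = %d, fr = %d, n = %d)\n",
    length(x$frames), x$sample_every, x$topology$fc, x$topology$fr,
    x$topology$n))
  cat(sprintf("  kinetic T = %.4f kT, <(l - r0)^2> = %.5g (kT/k = %.5g)\n",
              mean(x$diagnostics$kinetic_T), mean(x$diagnostics$bond_msd),
              x$params$kT / x$params$k))
  cat(sprintf("  equilibration %d steps, stationary: %s; suggested block_size = %d\n",
              x$n_equil, x$stationary, x$block_size))
  invisible(x)
}
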