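#' Rosette polymer architecture
#'
#' A rosette polymer consists of `fc` linear arms and `fr` ring arms, all
#' grafted to a single core bead. Each arm carries `n` bond steps of contour;
#' a ring arm closes back on the core, so its last bead coincides with the
#' core and is not stored twice. The total number of distinct beads is
#' therefore `M = 1 + fc * n + fr * (n - 1)`.
#'
#' Beads are indexed with the core first (index 1), then the linear arms in
#' declaration order, then the rings, each arm stored contiguously. `step_var`
#' is the per-component variance of a single bond step, so that a bond vector
#' has mean-square length `dim * step_var` and the discrete chain matches the
#' continuum normalisation `<(r(s2) - r(s1))^2> = dim * |s2 - s1|` when
#' `step_var = 1` (contour length per arm `L = n`).
#'
#' @param fc number of linear arms (non-negative integer).
#' @param fr number of ring arms (non-negative integer). `fc + fr >= 1`.
#' @param n bond steps per arm (integer `>= 2`).
#' @param dim spatial dimension (integer `>= 2`).
#' @param step_var per-component variance of one bond step (`>= 0`).
#' @return An object of class `"rosette_topology"`: a list with fields
#'   `fc`, `fr`, `n`, `dim`, `step_var`, and derived `f` (total
#'   functionality) and `M` (total beads).
#' @seealso [total_beads()], [bond_list()], [simulate.rosette_topology()]
#' @examples
#' top <- rosette_topology(fc = 2, fr = 1, n = 10)
#' total_beads(top) # 30
#' @export
rosette_topology <- function(fc, fr, n, dim = 3L, step_var = 1) {
  stopifnot(
    length(fc) == 1L, length(fr) == 1L, length(n) == 1L,
    fc >= 0, fr >= 0, fc == round(fc), fr == round(fr),
    n >= 2, n == round(n), dim >= 2, dim == round(dim),
    step_var >= 0
  )
  if (fc + fr < 1) {
    stop("a rosette needs at least one arm (fc + fr >= 1)")
  }
  fc <- as.integer(fc); fr <- as.integer(fr); n <- as.integer(n)
  structure(
    list(
      fc = fc, fr = fr, n = n, dim = as.integer(dim),
      step_var = as.numeric(step_var),
      f = fc + fr,
      M = 1L + fc * n + fr * (n - 1L)
    ),
    class = "rosette_topology"
  )
}

#' @export
print.rosette_topology <- function(x, ...) {
  cat(sprintf(
    "Rosette topology: %d linear arm(s) + %d ring arm(s), %d steps/arm\n",
    x$fc, x$fr, x$n
  ))
  cat(sprintf(
    "  beads M = %d, dim = %d, step_var = %g\n", x$M, x$dim, x$step_var
  ))
  invisible(x)
}

#' Total number of distinct beads
#'
#' @param topology a [rosette_topology()].
#' @return Integer bead count `M = 1 + fc * n + fr * (n - 1)`.
#' @export
total_beads <- function(topology) {
  stopifnot(inherits(topology, "rosette_topology"))
  topology$M
}

# Row indices of the beads belonging to arm `a` (1..f, linear arms first),
# excluding the core. Linear arm: n beads; ring arm: n - 1 interior beads.
arm_bead_index <- function(topology, a) {
  fc <- topology$fc
  n <- topology$n
  if (a <= fc) {
    1L + (a - 1L) * n + seq_len(n)
  } else {
    b <- a - fc
    1L + fc * n + (b - 1L) * (n - 1L) + seq_len(n - 1L)
  }
}

#' Bond connectivity of a rosette
#'
#' Builds the edge list of the bead-spring graph: each linear arm contributes
#' `n` bonds (including the graft to the core), each ring arm contributes `n`
#' bonds (graft, `n - 2` interior bonds, and the closing bond back to the
#' core). The core has degree `fc + 2 * fr` and the graph is connected.
#'
#' @param topology a [rosette_topology()].
#' @return Integer matrix with two columns (`from`, `to`), one row per bond,
#'   bead indices 1-based with the core at index 1.
#' @export
bond_list <- function(topology) {
  stopifnot(inherits(topology, "rosette_topology"))
  n <- topology$n
  edges <- vector("list", topology$f)
  for (a in seq_len(topology$f)) {
    idx <- arm_bead_index(topology, a)
    path <- c(1L, idx)
    e <- cbind(path[-length(path)], path[-1L])
    if (a > topology$fc) {
      e <- rbind(e, c(idx[length(idx)], 1L)) # ring closure through the core
    }
    edges[[a]] <- e
  }
  out <- do.call(rbind, edges)
  dimnames(out) <- list(NULL, c("from", "to"))
  out
}
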