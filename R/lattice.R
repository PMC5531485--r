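#' Hexagonal lattice configuration
#'
#' Defines the simulation domain: `I` columns by `J` rows of hexagonally
#' packed sites with spacing `delta` (the average cell diameter, in microns).
#' The site count `I * J` is the maximum possible population, i.e. 100%
#' confluence. Boundaries are zero-net-flux: a move or daughter placement
#' targeting a site outside the domain is aborted.
#'
#' The default dimensions correspond to a 75 cm^2 culture flask (10 cm x
#' 7.5 cm) discretised at `delta = 24` microns: `I = 4168`, `J = 3610`,
#' roughly 15 million sites. Routine exploration is usually done on
#' proportionally scaled-down lattices, since the passaging dynamics are
#' driven by density fractions rather than absolute counts.
#'
#' @param I Number of columns (integer >= 2).
#' @param J Number of rows (integer >= 2).
#' @param delta Lattice spacing in microns (> 0). Default 24.
#' @return An object of class `lattice_config`.
#' @examples
#' cfg <- lattice_config(80, 68)
#' n_sites(cfg)
#' @export
lattice_config <- function(I, J, delta = 24) {
  stopifnot(is.numeric(I), is.numeric(J), is.numeric(delta), length(I) == 1,
            length(J) == 1, length(delta) == 1)
  I <- as.integer(I); J <- as.integer(J)
  if (I < 2 || J < 2) stop("lattice dimensions must satisfy I >= 2, J >= 2")
  if (delta <= 0) stop("lattice spacing `delta` must be positive")
  structure(list(I = I, J = J, delta = as.numeric(delta)),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf("Hexagonal lattice: %d x %d sites (%s total), delta = %g um\n",
              x$I, x$J, format(n_sites(x), big.mark = ","), x$delta))
  invisible(x)
}

#' Total number of lattice sites
#'
#' @param config A [lattice_config()].
#' @return `I * J` as a double (the flask-scale lattice exceeds
#'   `.Machine$integer.max / 100`, so counts are kept numeric).
#' @export
n_sites <- function(config) {
  as.numeric(config$I) * as.numeric(config$J)
}

#' Cartesian position of a lattice site
#'
#' Rows are vertically spaced by `sqrt(3)/2 * delta` and odd rows are shifted
#' half a spacing to the right, so every site has six nearest neighbours at
#' distance `delta`:
#' \deqn{(x, y) = ((i - 1)\Delta,\; \sqrt{3}(j - 1)\Delta/2) \quad j \ \mathrm{even},}
#' \deqn{(x, y) = ((i - 1/2)\Delta,\; \sqrt{3}(j - 1)\Delta/2) \quad j \ \mathrm{odd}.}
#'
#' @param i,j Column and row indices (vectorised, 1-based).
#' @param config A [lattice_config()], or `delta` may be given directly.
#' @param delta Lattice spacing; ignored when `config` is supplied.
#' @return A data.frame with columns `x` and `y` in microns.
#' @examples
#' site_position(1, 1, delta = 24)  # x = 12, y = 0
#' @export
site_position <- function(i, j, config = NULL, delta = config$delta) {
  if (!is.null(config)) {
    if (any(i < 1 | i > config$I | j < 1 | j > config$J))
      stop("site index out of range for this lattice")
  }
  if (any(i < 1 | j < 1)) stop("site indices are 1-based and positive")
  odd <- j %% 2 == 1
  x <- ifelse(odd, (i - 0.5), (i - 1)) * delta
  y <- sqrt(3) * (j - 1) * delta / 2
  data.frame(x = x, y = y)
}

# neighbour offsets by row parity; row r of the matrix is direction r
.nb_even <- cbind(di = c(-1L, 1L, -1L, 0L, -1L, 0L),
                  dj = c(0L, 0L, -1L, -1L, 1L, 1L))
.nb_odd  <- cbind(di = c(-1L, 1L, 0L, 1L, 0L, 1L),
                  dj = c(0L, 0L, -1L, -1L, 1L, 1L))

#' Nearest neighbours of a lattice site
#'
#' Returns the in-domain subset of the six hexagonal nearest neighbours of
#' site `(i, j)`. Interior sites have exactly six; sites on the boundary have
#' fewer (off-domain candidates are dropped, realising the zero-net-flux
#' boundary).
#'
#' @param i,j Site index (scalars, 1-based).
#' @param config A [lattice_config()].
#' @return A two-column integer matrix with columns `i`, `j`, one row per
#'   in-domain neighbour.
#' @export
hex_neighbours <- function(i, j, config) {
  if (length(i) != 1 || length(j) != 1 || i < 1 || i > config$I ||
      j < 1 || j > config$J)
    stop("site index out of range for this lattice")
  off <- if (j %% 2 == 0) .nb_even else .nb_odd
  ii <- as.integer(i) + off[, "di"]
  jj <- as.integer(j) + off[, "dj"]
  keep <- ii >= 1 & ii <= config$I & jj >= 1 & jj <= config$J
  cbind(i = ii[keep], j = jj[keep])
}

new_lattice_state <- function(config, occ, pp, pm, tau, t = 0) {
  structure(list(config = config, occ = occ, pp = pp,
                 pm = as.numeric(pm), tau = as.numeric(tau),
                 t = as.numeric(t)),
            class = "hex_lattice_state")
}

#' Construct an empty lattice state
#'
#' @param config A [lattice_config()].
#' @param pm Per-step motility probability `Pm` in `[0, 1]`.
#' @param tau Step duration in hours (default 1/12 h, i.e. 5 minutes).
#' @return A `hex_lattice_state` with no cells: occupancy matrix `occ[i, j]`
#'   of 0/1 and proliferation-probability matrix `pp[i, j]` (`NA` at vacant
#'   sites), both of dimension `c(I, J)`.
#' @export
empty_state <- function(config, pm = 0.35, tau = 1 / 12) {
  stopifnot(pm >= 0, pm <= 1, tau > 0)
  occ <- matrix(0L, nrow = config$I, ncol = config$J)
  pp <- matrix(NA_real_, nrow = config$I, ncol = config$J)
  new_lattice_state(config, occ, pp, pm, tau)
}

#' @export
print.hex_lattice_state <- function(x, ...) {
  cat(sprintf(
    "hex_lattice_state: %d x %d lattice, %s cells (%.1f%% confluent), t = %g h\n",
    x$config$I, x$config$J, format(n_cells(x), big.mark = ","),
    100 * confluence(x), x$t))
  invisible(x)
}

#' Population size and confluence
#'
#' `n_cells()` counts occupied sites; `confluence()` is the occupied fraction
#' `N / (I * J)`.
#'
#' @param state A `hex_lattice_state`.
#' @return A scalar.
#' @export
n_cells <- function(state) sum(state$occ)

#' @rdname n_cells
#' @export
confluence <- function(state) n_cells(state) / n_sites(state$config)

#' Proliferation probabilities of the current population
#'
#' @param state A `hex_lattice_state`.
#' @return Numeric vector of the `Pp` values of all occupied sites (column
#'   -major site order).
#' @export
pp_values <- function(state) state$pp[state$occ == 1L]

check_state <- function(state) {
  stopifnot(inherits(state, "hex_lattice_state"))
  if (any(state$occ != 0L & state$occ != 1L))
    stop("occupancy must be 0/1: the exclusion property is violated")
  invisible(state)
}

#' Advance the simulation by whole time steps
#'
#' One step consists of `N(t)` motility attempts followed by `N(t)`
#' proliferation attempts, where `N(t)` is the population at the start of the
#' step. For each attempt a cell is selected uniformly at random with
#' replacement; it acts with probability `Pm` (or its own `Pp`), choosing one
#' of the six neighbour directions uniformly. Moves or daughter placements
#' onto occupied or off-domain sites are aborted. Elapsed time advances by
#' `tau` per step.
#'
#' @param state A `hex_lattice_state` with at least one cell.
#' @param n_steps Number of steps to take (default 1).
#' @param newborns_eligible If `TRUE` (default) each proliferation-sweep draw
#'   is uniform over the population at the moment of the draw, so daughters
#'   born earlier in the sweep can be selected; if `FALSE` the candidate pool
#'   is frozen at the sweep start. The number of attempts is `N(t)` either
#'   way.
#' @return The state at `t + n_steps * tau`.
#' @export
lattice_step <- function(state, n_steps = 1, newborns_eligible = TRUE) {
  check_state(state)
  if (n_cells(state) == 0 && n_steps > 0)
    stop("cannot advance an empty population: nothing to select")
  res <- cpp_run_steps(state$occ, state$pp, state$pm,
                       state$config$I, state$config$J,
                       as.integer(n_steps), isTRUE(newborns_eligible))
  state$occ <- matrix(res$occ, nrow = state$config$I)
  state$pp <- matrix(res$pp, nrow = state$config$I)
  state$t <- state$t + n_steps * state$tau
  state
}

#' Single motility / proliferation attempts (exposed for testing and
#' illustration)
#'
#' `attempt_move()` gives the cell at `site` one motility attempt: with
#' probability `Pm` a direction is drawn uniformly from the six geometric
#' neighbour directions; if the target is in-domain and vacant the cell
#' relocates there, carrying its `Pp` value, otherwise nothing changes.
#' `attempt_proliferation()` is analogous with probability `pp[site]`; on
#' success a daughter with exactly the mother's `Pp` is placed on the target.
#'
#' @param state A `hex_lattice_state`.
#' @param site Length-2 integer vector `c(i, j)`; must be occupied.
#' @return The updated state.
#' @export
attempt_move <- function(state, site) {
  check_state(state)
  i <- site[[1]]; j <- site[[2]]
  if (state$occ[i, j] != 1L)
    stop(sprintf("attempt_move: site (%d, %d) is vacant", i, j))
  res <- cpp_attempt_move(state$occ, state$pp, state$pm,
                          as.integer(i), as.integer(j),
                          state$config$I, state$config$J)
  state$occ <- matrix(res$occ, nrow = state$config$I)
  state$pp <- matrix(res$pp, nrow = state$config$I)
  state
}

#' @rdname attempt_move
#' @export
attempt_proliferation <- function(state, site) {
  check_state(state)
  i <- site[[1]]; j <- site[[2]]
  if (state$occ[i, j] != 1L)
    stop(sprintf("attempt_proliferation: site (%d, %d) is vacant", i, j))
  res <- cpp_attempt_proliferation(state$occ, state$pp,
                                   as.integer(i), as.integer(j),
                                   state$config$I, state$config$J)
  state$occ <- matrix(res$occ, nrow = state$config$I)
  state$pp <- matrix(res$pp, nrow = state$config$I)
  state
}

#' Mean-squared displacement of isolated agents
#'
#' Simulates `n_traj` independent single-agent trajectories of `n_steps`
#' steps each on an otherwise empty lattice (the lattice is sized so the
#' boundary is unreachable) and returns their squared displacements. On an
#' empty lattice every attempted move succeeds and displaces the agent by
#' `delta`, so `E[r^2] = n_steps * pm * delta^2` and the random-walk
#' diffusivity is `D = MSD / (4 t) = pm * delta^2 / (4 tau)`.
#'
#' @param n_traj Number of trajectories.
#' @param n_steps Steps per trajectory.
#' @param pm Motility probability.
#' @param delta Lattice spacing in microns.
#' @return Numeric vector of squared displacements in square microns.
#' @export
isolated_msd <- function(n_traj, n_steps, pm = 0.35, delta = 24) {
  side <- 2L * as.integer(n_steps) + 3L
  d2 <- cpp_isolated_sq_displacement(as.integer(n_traj), as.integer(n_steps),
                                     pm, side, side)
  d2 * delta^2
}
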