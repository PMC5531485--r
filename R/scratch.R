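#' Sources of proliferation probabilities for scratch assays
#'
#' A scratch assay can be seeded either with fresh normal draws
#' (`pp_normal()`) or by resampling, uniformly with replacement, from an
#' empirical table of `Pp` values harvested from a passaging run
#' (`pp_table()`). Resampling the raw values preserves the skewness that
#' passaging induces, which a re-fitted normal would destroy.
#'
#' @param mu_p,sigma Parameters of the normal source (clipped to `[0, 1]` on
#'   draw).
#' @param values Non-empty numeric vector of `Pp` values in `[0, 1]`.
#' @return A `pp_source` object.
#' @export
pp_normal <- function(mu_p = 0.004, sigma = 1e-4) {
  stopifnot(sigma >= 0)
  structure(list(kind = "normal", mu_p = mu_p, sigma = sigma),
            class = "pp_source")
}

#' @rdname pp_normal
#' @export
pp_table <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty Pp table")
  if (any(values < 0 | values > 1 | is.na(values)))
    stop("Pp table values must lie in [0, 1]")
  structure(list(kind = "table", values = values), class = "pp_source")
}

draw_pp_source <- function(source, n) {
  stopifnot(inherits(source, "pp_source"))
  if (n == 0) return(numeric(0))
  switch(source$kind,
         normal = draw_initial_pp(n, source$mu_p, source$sigma),
         table = source$values[sample.int(length(source$values), n,
                                          replace = TRUE)])
}

#' Scratch assay configuration
#'
#' The in silico analogue of an IncuCyte-style scratch (wound-healing) assay:
#' a small lattice representing the ~1900 x 1400 micron field of view is
#' seeded uniformly (each site independently occupied with probability
#' `seed_probability`), a vertical strip of columns is vacated at `t = 0`,
#' and re-colonisation is followed via column density profiles.
#'
#' Defaults: an 80 x 68 lattice at `delta = 24` um, 30% seeding, a centered
#' 23-column scratch (about 550 um wide), observation at 0, 24, 48 and 72 h,
#' 100-realisation ensembles.
#'
#' @param lattice A [lattice_config()].
#' @param seed_probability Independent per-site occupancy probability.
#' @param scratch_width Number of contiguous columns vacated.
#' @param scratch_position First vacated column; `NULL` centers the strip at
#'   `floor((I - width) / 2) + 1`.
#' @param record_times_h Non-negative, strictly increasing observation times
#'   (hours); each must be a whole number of steps.
#' @param n_realisations Ensemble size.
#' @param pp_source A [pp_normal()] or [pp_table()].
#' @param pm,tau Motility probability and step duration.
#' @return A `scratch_config` object.
#' @export
scratch_config <- function(lattice = lattice_config(80, 68),
                           seed_probability = 0.30,
                           scratch_width = 23,
                           scratch_position = NULL,
                           record_times_h = c(0, 24, 48, 72),
                           n_realisations = 100,
                           pp_source = pp_normal(),
                           pm = 0.35, tau = 1 / 12) {
  stopifnot(inherits(lattice, "lattice_config"),
            seed_probability >= 0, seed_probability <= 1,
            inherits(pp_source, "pp_source"))
  scratch_width <- as.integer(scratch_width)
  if (scratch_width < 0 || scratch_width >= lattice$I)
    stop("`scratch_width` must be in [0, I)")
  if (is.null(scratch_position))
    scratch_position <- floor((lattice$I - scratch_width) / 2) + 1L
  scratch_position <- as.integer(scratch_position)
  if (scratch_width > 0 &&
      (scratch_position < 1 || scratch_position + scratch_width - 1 > lattice$I))
    stop("scratch strip extends outside the lattice")
  if (any(record_times_h < 0) || is.unsorted(record_times_h, strictly = TRUE))
    stop("`record_times_h` must be non-negative and strictly increasing")
  steps <- record_times_h / tau
  if (any(abs(steps - round(steps)) > 1e-9))
    stop("each record time must be a whole number of steps of duration `tau`")
  structure(list(lattice = lattice, seed_probability = seed_probability,
                 scratch_width = scratch_width,
                 scratch_position = scratch_position,
                 record_times_h = as.numeric(record_times_h),
                 n_realisations = as.integer(n_realisations),
                 pp_source = pp_source, pm = pm, tau = tau),
            class = "scratch_config")
}

#' Columns occupied by the scratch
#'
#' @param config A [scratch_config()].
#' @return Integer vector of vacated column indices (empty if width 0).
#' @export
scratch_columns <- function(config) {
  if (config$scratch_width == 0) return(integer(0))
  seq(config$scratch_position,
      length.out = config$scratch_width)
}

#' Seed the scratch-assay monolayer
#'
#' Each lattice site is independently occupied with probability
#' `seed_probability` (so the cell count is Binomial, unlike the exact-count
#' seeding of [seed_random()]); each cell's `Pp` is drawn from the
#' configured source. No scratch is made here; see [make_scratch()].
#'
#' @param config A [scratch_config()].
#' @return A `hex_lattice_state` at `t = 0`.
#' @export
init_scratch_population <- function(config) {
  lat <- config$lattice
  state <- empty_state(lat, pm = config$pm, tau = config$tau)
  occ <- runif(n_sites(lat)) < config$seed_probability
  n <- sum(occ)
  state$occ[occ] <- 1L
  state$pp[occ] <- draw_pp_source(config$pp_source, n)
  state
}

#' Excise a vertical strip of cells
#'
#' Removes every cell in `width` contiguous columns starting at `position`
#' (their `Pp` values are discarded); all other sites are untouched.
#'
#' @param state A `hex_lattice_state`.
#' @param width Number of columns to vacate.
#' @param position First vacated column; `NULL` centers the strip.
#' @return The scratched state.
#' @export
make_scratch <- function(state, width = 23, position = NULL) {
  check_state(state)
  width <- as.integer(width)
  I <- state$config$I
  if (width == 0) return(state)
  if (width < 0 || width > I) stop("scratch width must be in [0, I]")
  if (is.null(position)) position <- floor((I - width) / 2) + 1L
  cols <- seq(as.integer(position), length.out = width)
  if (cols[1] < 1 || cols[width] > I)
    stop("scratch strip extends outside the lattice")
  state$occ[cols, ] <- 0L
  state$pp[cols, ] <- NA_real_
  state
}

#' Column density profile
#'
#' The occupancy of each lattice column averaged over its rows,
#' \deqn{\langle C_i \rangle = \frac{1}{J} \sum_{j=1}^{J} C_{i,j},}
#' the spatial summary used to track scratch closure.
#'
#' @param state A `hex_lattice_state`.
#' @return A data.frame with one row per column: `column`, `x_um` (the
#'   even-row x coordinate `(i-1) * delta`), `density` in `[0, 1]`.
#' @export
column_density <- function(state) {
  dens <- rowMeans(state$occ)
  data.frame(column = seq_len(state$config$I),
             x_um = (seq_len(state$config$I) - 1) * state$config$delta,
             density = dens)
}

#' Run an ensemble of scratch assays
#'
#' Performs `n_realisations` identically prepared, independently seeded
#' realisations (realisation `r` uses seed `base_seed + r`): seed the
#' monolayer, excise the scratch at `t = 0`, simulate to the last record time,
#' and record the column density profile at every record time. Profiles are
#' then averaged pointwise across the ensemble.
#'
#' @param config A [scratch_config()].
#' @param base_seed Integer; realisation seeds are `base_seed + 1, ...,
#'   base_seed + n_realisations`.
#' @param newborns_eligible Passed to [lattice_step()].
#' @return An object of class `scratch_ensemble`: list with
#'   `profiles` (data.frame: `time_h`, `column`, `x_um`, `mean_density`,
#'   `sd_density`), `density` (array `[realisation, time, column]`),
#'   `n_cells` (matrix `[realisation, time]`), `config`, `base_seed`.
#' @export
run_scratch_ensemble <- function(config, base_seed = 1,
                                 newborns_eligible = TRUE) {
  stopifnot(inherits(config, "scratch_config"))
  times <- config$record_times_h
  steps_at <- as.integer(round(times / config$tau))
  I <- config$lattice$I
  R <- config$n_realisations
  dens <- array(NA_real_, dim = c(R, length(times), I))
  ncell <- matrix(NA_real_, nrow = R, ncol = length(times))
  for (r in seq_len(R)) {
    set.seed(base_seed + r)
    state <- init_scratch_population(config)
    state <- make_scratch(state, config$scratch_width,
                          config$scratch_position)
    done <- 0L
    for (k in seq_along(times)) {
      d <- steps_at[k] - done
      if (d > 0) {
        state <- lattice_step(state, d, newborns_eligible)
        done <- steps_at[k]
      }
      dens[r, k, ] <- rowMeans(state$occ)
      ncell[r, k] <- n_cells(state)
    }
  }
  mean_d <- apply(dens, c(2, 3), mean)
  sd_d <- if (R > 1) apply(dens, c(2, 3), sd) else array(0, dim(mean_d))
  profiles <- data.frame(
    time_h = rep(times, each = I),
    column = rep(seq_len(I), times = length(times)),
    x_um = rep((seq_len(I) - 1) * config$lattice$delta, length(times)),
    mean_density = as.vector(t(mean_d)),
    sd_density = as.vector(t(sd_d)))
  structure(list(profiles = profiles, density = dens, n_cells = ncell,
                 config = config, base_seed = base_seed),
            class = "scratch_ensemble")
}

#' @export
print.scratch_ensemble <- function(x, ...) {
  cat(sprintf(
    "Scratch ensemble: %d realisations, %d x %d lattice, %d-column scratch at column %d\n",
    x$config$n_realisations, x$config$lattice$I, x$config$lattice$J,
    x$config$scratch_width, x$config$scratch_position))
  cat(sprintf("  recorded at t = %s h\n",
              paste(x$config$record_times_h, collapse = ", ")))
  invisible(x)
}

#' Scratch closure time
#'
#' Operationalises "the scratch has closed" as the first recorded time at
#' which the mean density inside the originally scratched columns reaches at
#' least `threshold` times the mean density outside them. The published
#' assays report closure only visually (by 48-72 h); the 0.9 relative
#' threshold makes that judgement reproducible.
#'
#' @param density Matrix of column densities, `length(times)` rows by `I`
#'   columns (one profile per recorded time), or a `scratch_ensemble` (whose
#'   per-realisation profiles are used, giving one closure time per
#'   realisation).
#' @param times Record times in hours (rows of `density`).
#' @param scratch_cols Integer vector: the originally vacated columns.
#' @param threshold Relative density defining closure (default 0.9).
#' @return The closure time in hours, or `NA_real_` if never closed within
#'   the recorded window. For a `scratch_ensemble`, a vector of closure
#'   times, one per realisation.
#' @export
closure_time <- function(density, times = NULL, scratch_cols = NULL,
                         threshold = 0.9) {
  if (inherits(density, "scratch_ensemble")) {
    ens <- density
    cols <- if (is.null(scratch_cols)) scratch_columns(ens$config) else scratch_cols
    return(vapply(seq_len(dim(ens$density)[1]), function(r) {
      closure_time(ens$density[r, , , drop = TRUE],
                   times = ens$config$record_times_h,
                   scratch_cols = cols, threshold = threshold)
    }, numeric(1)))
  }
  density <- rbind(density)
  if (is.null(times) || length(times) != nrow(density))
    stop("`times` must give one time per profile row")
  if (is.null(scratch_cols) || length(scratch_cols) == 0 ||
      any(scratch_cols < 1 | scratch_cols > ncol(density)))
    stop("`scratch_cols` must index columns of the profiles")
  inside <- rowMeans(density[, scratch_cols, drop = FALSE])
  outside <- rowMeans(density[, -scratch_cols, drop = FALSE])
  # an empty field has nothing to close into: require ambient cells
  closed <- outside > 0 & inside >= threshold * outside
  if (!any(closed)) return(NA_real_)
  times[which(closed)[1]]
}
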