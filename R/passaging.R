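#' Passage-induced damage model
#'
#' At every split each transferred cell's proliferation probability is
#' decremented by an independent draw `eps ~ N(mu_eps, sigma_eps)`, with
#' negative draws set to zero (damage can only reduce `Pp`, never raise it),
#' and the damaged `Pp` floored at zero. Presets:
#' \describe{
#'   \item{`none`}{`eps == 0`: `Pp` passes through unchanged.}
#'   \item{`small`}{`eps ~ N(2e-5, sd 2e-5)`.}
#'   \item{`large`}{`eps ~ N(1e-4, sd 1e-4)`.}
#' }
#'
#' @param preset One of `"none"`, `"small"`, `"large"`, or `"custom"` with
#'   `mu_eps` / `sigma_eps` given explicitly.
#' @param mu_eps,sigma_eps Mean and standard deviation of `eps` (per-step
#'   probability units); only used for `preset = "custom"`.
#' @return An object of class `damage_model`.
#' @examples
#' damage_model("large")
#' @export
damage_model <- function(preset = c("none", "small", "large", "custom"),
                         mu_eps = NULL, sigma_eps = NULL) {
  preset <- match.arg(preset)
  par <- switch(preset,
                none = c(0, 0),
                small = c(2e-5, 2e-5),
                large = c(1e-4, 1e-4),
                custom = c(mu_eps, sigma_eps))
  if (preset == "custom" && (is.null(mu_eps) || is.null(sigma_eps)))
    stop("custom damage requires `mu_eps` and `sigma_eps`")
  if (par[2] < 0) stop("`sigma_eps` must be non-negative")
  structure(list(preset = preset, mu_eps = par[1], sigma_eps = par[2]),
            class = "damage_model")
}

#' @export
print.damage_model <- function(x, ...) {
  if (x$preset == "none") cat("Damage model: none (eps = 0)\n")
  else cat(sprintf("Damage model: %s, eps ~ N(%g, sd %g), clipped at 0\n",
                   x$preset, x$mu_eps, x$sigma_eps))
  invisible(x)
}

#' Expected applied damage decrement
#'
#' Because negative draws are set to zero, the mean applied decrement is
#' `E[max(eps, 0)] = mu * pnorm(mu/sigma) + sigma * dnorm(mu/sigma)`, the mean
#' of a rectified normal.
#'
#' @param damage A [damage_model()].
#' @return The expected per-cell, per-passage decrement.
#' @export
expected_damage <- function(damage) {
  if (damage$sigma_eps == 0) return(max(damage$mu_eps, 0))
  z <- damage$mu_eps / damage$sigma_eps
  damage$mu_eps * pnorm(z) + damage$sigma_eps * dnorm(z)
}

#' Draw initial proliferation probabilities
#'
#' Independent draws from `N(mu_p, sd sigma)`, clipped to `[0, 1]` since `Pp`
#' is a per-step probability. At the default parameters clipping is a rare
#' event (probability ~3e-5 per cell for the heterogeneous line) that barely
#' perturbs the moments but matters at flask scale, where millions of cells
#' are drawn.
#'
#' @param n Number of cells.
#' @param mu_p,sigma Mean and standard deviation of the normal.
#' @return Numeric vector of `n` values in `[0, 1]`.
#' @export
draw_initial_pp <- function(n, mu_p = 0.004, sigma = 1e-4) {
  stopifnot(n >= 1)
  if (sigma < 0) stop("`sigma` must be non-negative")
  pmin(pmax(rnorm(n, mu_p, sigma), 0), 1)
}

#' Apply passage-induced damage to proliferation probabilities
#'
#' Each value receives an independent decrement `max(eps, 0)` with
#' `eps ~ N(mu_eps, sigma_eps)`; results are floored at zero. Output order
#' matches input order.
#'
#' @param pp Numeric vector of `Pp` values in `[0, 1]`.
#' @param damage A [damage_model()].
#' @return Damaged values, same length and order.
#' @export
apply_damage <- function(pp, damage) {
  stopifnot(inherits(damage, "damage_model"),
            all(pp >= 0), all(pp <= 1))
  if (damage$preset == "none") return(pp)
  eps <- rnorm(length(pp), damage$mu_eps, damage$sigma_eps)
  pmax(pp - pmax(eps, 0), 0)
}

#' Number of sites seeded at a given occupancy fraction
#'
#' @param config A [lattice_config()].
#' @param fraction Occupancy fraction in `(0, 1]`.
#' @return `round(fraction * I * J)`, as a double.
#' @examples
#' n_seeded_sites(lattice_config(4168, 3610), 0.15)  # 2256972
#' @export
n_seeded_sites <- function(config, fraction) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  round(fraction * n_sites(config))
}

#' Seed a lattice uniformly at random
#'
#' Occupies exactly `round(fraction * I * J)` distinct sites chosen uniformly
#' without replacement. `Pp` values are either supplied explicitly (e.g.
#' carried over from a split) or drawn fresh via [draw_initial_pp()].
#'
#' @param config A [lattice_config()].
#' @param fraction Occupancy fraction in `(0, 1]`.
#' @param pp Optional numeric vector of `Pp` values, one per seeded cell (its
#'   length must equal [n_seeded_sites()]); drawn from `model` when `NULL`.
#' @param model A [model_parameters()]; supplies `mu_p`, `sigma`, `pm`, `tau`.
#' @return A `hex_lattice_state` at `t = 0`.
#' @export
seed_random <- function(config, fraction, pp = NULL,
                        model = model_parameters()) {
  n_occ <- n_seeded_sites(config, fraction)
  if (is.null(pp)) {
    pp <- draw_initial_pp(n_occ, model$mu_p, model$sigma)
  } else if (length(pp) != n_occ) {
    stop(sprintf("`pp` has %d values but %s sites are being seeded",
                 length(pp), format(n_occ)))
  }
  state <- empty_state(config, pm = model$pm, tau = model$tau)
  sites <- sample.int(n_sites(config), n_occ)
  state$occ[sites] <- 1L
  state$pp[sites] <- pp
  state
}

#' Grow a population to a target confluence
#'
#' Repeats [lattice_step()] until `N / (I * J) >= confluence_fraction`,
#' checking after each completed step. Errors if `max_steps` is exhausted
#' first (e.g. when all `Pp` values have been damaged to zero).
#'
#' @param state A `hex_lattice_state`.
#' @param confluence_fraction Target occupied fraction (default 0.85).
#' @param max_steps Safety cap on the number of steps (default 20000, i.e.
#'   about 1667 h at `tau = 1/12` h).
#' @param newborns_eligible Passed to [lattice_step()].
#' @return A list with `state` (the first state at or above the target) and
#'   `duration_h` (simulated hours taken).
#' @export
grow_to_confluence <- function(state, confluence_fraction = 0.85,
                               max_steps = 20000, newborns_eligible = TRUE) {
  check_state(state)
  stopifnot(confluence_fraction > 0, confluence_fraction <= 1)
  if (confluence(state) >= confluence_fraction)
    return(list(state = state, duration_h = 0))
  target_n <- ceiling(confluence_fraction * n_sites(state$config) - 1e-9)
  res <- cpp_run_until(state$occ, state$pp, state$pm,
                       state$config$I, state$config$J,
                       as.integer(target_n), as.integer(max_steps),
                       isTRUE(newborns_eligible))
  if (!res$reached)
    stop(sprintf(
      "population did not reach %.0f%% confluence within %d steps (reached %.1f%%)",
      100 * confluence_fraction, as.integer(max_steps),
      100 * res$n / n_sites(state$config)))
  state$occ <- matrix(res$occ, nrow = state$config$I)
  state$pp <- matrix(res$pp, nrow = state$config$I)
  state$t <- state$t + res$steps * state$tau
  list(state = state, duration_h = res$steps * state$tau)
}

#' Passaging protocol
#'
#' The culture-split cycle: seed a fraction of the lattice, grow to the
#' confluence fraction, transfer a uniformly sampled subpopulation (enough to
#' cover `seed_fraction` of sites) onto an empty lattice, damaging each
#' transferred cell's `Pp` on the way, and repeat.
#'
#' @param seed_fraction Occupancy fraction after seeding/splitting
#'   (default 0.15).
#' @param confluence_fraction Growth-termination fraction (default 0.85).
#' @param n_passages Number of splits to perform (default 30; records run
#'   from passage 0, the first growth cycle, to `n_passages`).
#' @param damage A [damage_model()].
#' @param max_steps_per_passage Safety cap for each growth phase.
#' @return An object of class `passaging_protocol`.
#' @export
passaging_protocol <- function(seed_fraction = 0.15,
                               confluence_fraction = 0.85,
                               n_passages = 30,
                               damage = damage_model("none"),
                               max_steps_per_passage = 20000) {
  if (!(seed_fraction > 0 && seed_fraction < confluence_fraction &&
        confluence_fraction <= 1))
    stop("need 0 < seed_fraction < confluence_fraction <= 1")
  stopifnot(inherits(damage, "damage_model"), n_passages >= 0)
  structure(list(seed_fraction = seed_fraction,
                 confluence_fraction = confluence_fraction,
                 n_passages = as.integer(n_passages), damage = damage,
                 max_steps_per_passage = as.integer(max_steps_per_passage)),
            class = "passaging_protocol")
}

#' Split a confluent population onto a fresh lattice
#'
#' Samples `round(seed_fraction * I * J)` cells uniformly without replacement
#' from the population (splitting is blind to `Pp`), applies the damage model
#' to their `Pp` values, and reseeds them uniformly on an empty lattice.
#'
#' @param state A `hex_lattice_state` at (or above) the confluence fraction.
#' @param protocol A [passaging_protocol()].
#' @return The reseeded `hex_lattice_state` at `t = 0`.
#' @export
passage_once <- function(state, protocol) {
  check_state(state)
  n_keep <- n_seeded_sites(state$config, protocol$seed_fraction)
  pool <- pp_values(state)
  if (length(pool) < n_keep)
    stop(sprintf("population (%d) smaller than the split size (%s)",
                 length(pool), format(n_keep)))
  kept <- pool[sample.int(length(pool), n_keep)]
  kept <- apply_damage(kept, protocol$damage)
  out <- seed_random(state$config, protocol$seed_fraction, pp = kept,
                     model = model_parameters(pm = state$pm, tau = state$tau))
  out
}

#' Summary statistics of a proliferation-probability distribution
#'
#' Mean, standard deviation (sample convention, denominator `n - 1`), median
#' and quartiles (type-7 quantiles), plus a fixed-bin histogram for plotting
#' and for empirical resampling.
#'
#' @param values Non-empty numeric vector of `Pp` values.
#' @param breaks Histogram bin edges; values beyond the last edge fall in an
#'   overflow bin. Default: 80 bins of width 2.5e-4 spanning `[0, 0.02]`.
#' @return A list with `pp_mean`, `pp_sd`, `pp_median`, `pp_q1`, `pp_q3`,
#'   `n_cells` and `histogram` (list of `breaks`, `counts`).
#' @export
summarise_pp <- function(values, breaks = seq(0, 0.02, by = 2.5e-4)) {
  if (length(values) == 0) stop("cannot summarise an empty Pp distribution")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75)))
  counts <- tabulate(findInterval(values, breaks, left.open = FALSE),
                     nbins = length(breaks))
  list(pp_mean = mean(values),
       pp_sd = if (length(values) > 1) sd(values) else 0,
       pp_median = q[2], pp_q1 = q[1], pp_q3 = q[3],
       n_cells = length(values),
       histogram = list(breaks = breaks, counts = counts))
}

#' Run a full passaging experiment
#'
#' Seeds passage 0 with fresh `Pp` draws from `model`, grows each passage to
#' the confluence fraction, records the whole-population `Pp` distribution at
#' that moment, then splits with damage and repeats up to
#' `protocol$n_passages`.
#'
#' @param protocol A [passaging_protocol()].
#' @param model A [model_parameters()].
#' @param lattice A [lattice_config()]. The flask-scale default in
#'   [lattice_config()] is supported, but proportionally scaled lattices give
#'   the same fraction-driven dynamics at a fraction of the cost.
#' @param seed Optional integer seed (applied with [set.seed()] before any
#'   randomness).
#' @param keep_pp If `TRUE`, the full `Pp` vector at every recorded passage is
#'   retained in `$pp` (needed to seed scratch assays from passaged
#'   populations).
#' @param newborns_eligible Passed to [lattice_step()].
#' @return An object of class `passaging_experiment`: a list with
#'   `records` (data.frame with one row per passage: `passage`, `n_cells`,
#'   `duration_h`, `pp_mean`, `pp_sd`, `pp_median`, `pp_q1`, `pp_q3`),
#'   `pp` (list of per-passage `Pp` vectors if `keep_pp`), and the inputs.
#' @export
run_passaging_experiment <- function(protocol, model = model_parameters(),
                                     lattice = lattice_config(4168, 3610),
                                     seed = NULL, keep_pp = FALSE,
                                     newborns_eligible = TRUE) {
  stopifnot(inherits(protocol, "passaging_protocol"),
            inherits(model, "model_parameters"),
            inherits(lattice, "lattice_config"))
  if (!is.null(seed)) set.seed(seed)
  state <- seed_random(lattice, protocol$seed_fraction, model = model)
  records <- vector("list", protocol$n_passages + 1)
  pp_dumps <- if (keep_pp) vector("list", protocol$n_passages + 1) else NULL
  for (p in 0:protocol$n_passages) {
    grown <- grow_to_confluence(state, protocol$confluence_fraction,
                                max_steps = protocol$max_steps_per_passage,
                                newborns_eligible = newborns_eligible)
    vals <- pp_values(grown$state)
    s <- summarise_pp(vals)
    records[[p + 1]] <- data.frame(passage = p, n_cells = s$n_cells,
                                   duration_h = grown$duration_h,
                                   pp_mean = s$pp_mean, pp_sd = s$pp_sd,
                                   pp_median = s$pp_median,
                                   pp_q1 = s$pp_q1, pp_q3 = s$pp_q3)
    if (keep_pp) pp_dumps[[p + 1]] <- vals
    if (p < protocol$n_passages)
      state <- passage_once(grown$state, protocol)
  }
  structure(list(records = do.call(rbind, records), pp = pp_dumps,
                 protocol = protocol, model = model, lattice = lattice,
                 seed = seed),
            class = "passaging_experiment")
}

#' @export
print.passaging_experiment <- function(x, ...) {
  cat(sprintf("Passaging experiment: %d passages on a %d x %d lattice, damage = %s\n",
              x$protocol$n_passages, x$lattice$I, x$lattice$J,
              x$protocol$damage$preset))
  print(utils::head(x$records))
  if (nrow(x$records) > 6) cat(sprintf("... %d more rows\n", nrow(x$records) - 6))
  invisible(x)
}
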