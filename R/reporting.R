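scenario_defaults <- function(kind) {
  common <- list(kind = kind, seed = 1, out_dir = ".",
                 pm = 0.35, tau = 1 / 12, delta = 24)
  extra <- switch(kind,
    passage = list(
      I = 4168, J = 3610, mu_p = 0.004, sigma = 1e-4,
      seed_fraction = 0.15, confluence_fraction = 0.85, n_passages = 30,
      damage = "none", mu_eps = NULL, sigma_eps = NULL,
      max_steps_per_passage = 20000, keep_pp = FALSE,
      snapshot_fov_um = 2000),
    scratch = list(
      I = 80, J = 68, seed_probability = 0.30, scratch_width = 23,
      scratch_position = NULL, record_times_h = c(0, 24, 48, 72),
      n_realisations = 100, mu_p = 0.004, sigma = 1e-4, pp_table_file = NULL,
      closure_threshold = 0.9),
    msd_check = list(n_traj = 10000, n_steps = 100),
    stop(sprintf("unknown experiment kind '%s'", kind))
  )
  c(common, extra)
}

#' Scenario configuration
#'
#' A flat description of one experiment — a passaging run, a scratch-assay
#' ensemble, or a motility (mean-squared-displacement) calibration check —
#' suitable for serialisation to a YAML file and for driving [run_scenario()].
#' Missing fields take documented defaults; unknown fields are an error.
#'
#' @param kind `"passage"`, `"scratch"` or `"msd_check"`.
#' @param ... Field overrides; see `hexpassage:::scenario_defaults(kind)` for
#'   the full set per kind.
#' @return A `scenario_config` (named list).
#' @examples
#' scenario_config("scratch", n_realisations = 20, seed = 7)
#' @export
scenario_config <- function(kind = c("passage", "scratch", "msd_check"), ...) {
  kind <- match.arg(kind)
  defaults <- scenario_defaults(kind)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s) for kind '%s': %s",
                 kind, paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  structure(cfg, class = "scenario_config")
}

#' Read and write scenario configurations
#'
#' Configurations serialise to YAML. `load_config()` fills unspecified fields
#' with their defaults and rejects unrecognised keys with an error naming
#' them. A saved configuration loads back equal to the original (numeric
#' fields to at least 15 significant digits).
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `load_config()` returns a `scenario_config`; `save_config()`
#'   returns `path` invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$kind)) stop("configuration file lacks the `kind` field")
  do.call(scenario_config, c(list(kind = raw$kind),
                             raw[setdiff(names(raw), "kind")]))
}

#' Export per-passage boxplot statistics
#'
#' Writes one CSV row per passage with the population-level `Pp` statistics
#' (mean, sd, median, quartiles) recorded at the moment each passage reached
#' the confluence fraction — the data behind per-passage boxplots. Numbers are
#' written at full precision.
#'
#' @param records The `records` data.frame of a [run_passaging_experiment()]
#'   result (or the result itself).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_boxplot_table <- function(records, path) {
  if (inherits(records, "passaging_experiment")) records <- records$records
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("`records` must be a non-empty data.frame of passage records")
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export ensemble density profiles
#'
#' @param ensemble A `scratch_ensemble` from [run_scratch_ensemble()].
#' @param path Output CSV path (`time_h, column, x_um, mean_density,
#'   sd_density`).
#' @return `path`, invisibly.
#' @export
export_density_profiles <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "scratch_ensemble"))
  write.csv(ensemble$profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default field of view
#'
#' The central 2 mm x 2 mm window, clipped to the domain extent (small
#' lattices are smaller than 2 mm, in which case the whole domain is used).
#'
#' @param config A [lattice_config()].
#' @param size_um Window edge length in microns.
#' @return Numeric `c(x0, x1, y0, y1)` in microns.
#' @export
default_fov <- function(config, size_um = 2000) {
  xmax <- (config$I - 1) * config$delta
  ymax <- sqrt(3) * (config$J - 1) * config$delta / 2
  half <- size_um / 2
  c(max(0, xmax / 2 - half), min(xmax, xmax / 2 + half),
    max(0, ymax / 2 - half), min(ymax, ymax / 2 + half))
}

#' Lattice columns visible in a field of view
#'
#' Columns whose even-row x coordinate `(i - 1) * delta` lies inside the
#' window; a 2 mm window at `delta = 24` um spans about 83 columns.
#'
#' @param config A [lattice_config()].
#' @param fov Numeric `c(x0, x1, y0, y1)` in microns.
#' @return Integer vector of column indices.
#' @export
fov_columns <- function(config, fov = default_fov(config)) {
  x <- (seq_len(config$I) - 1) * config$delta
  which(x >= fov[1] & x <= fov[2])
}

#' Render a snapshot of a field of view
#'
#' Deterministic raster image of the cells inside a rectangular window:
#' each cell is drawn as a disc of diameter `delta` at its hexagonal lattice
#' position, coloured by its `Pp` value on a fixed scale (blue = slow,
#' red = fast); vacant space is white. Writing the same state twice produces
#' byte-identical files.
#'
#' @param state A `hex_lattice_state`.
#' @param fov Window `c(x0, x1, y0, y1)` in microns; default the central
#'   2 mm x 2 mm clipped to the domain.
#' @param pp_range Fixed colour-scale range `c(lo, hi)`. Use the same range
#'   across snapshots to make them comparable; defaults to the range of the
#'   current population (or `c(0, 1)` when empty).
#' @param px_per_um Raster resolution (default 0.25, i.e. a 2 mm window is
#'   500 px wide).
#' @param path Optional PNG output path.
#' @return Invisibly, the RGB raster array (height x width x 3, values in
#'   `[0, 1]`); also written to `path` if given.
#' @export
render_snapshot <- function(state, fov = default_fov(state$config),
                            pp_range = NULL, px_per_um = 0.25, path = NULL) {
  check_state(state)
  cfg <- state$config
  xmax <- (cfg$I - 1) * cfg$delta
  ymax <- sqrt(3) * (cfg$J - 1) * cfg$delta / 2
  if (fov[1] < 0 || fov[3] < 0 || fov[2] > xmax + cfg$delta ||
      fov[4] > ymax + cfg$delta || fov[1] >= fov[2] || fov[3] >= fov[4])
    stop("field of view lies outside the simulation domain")
  W <- max(2L, as.integer(ceiling((fov[2] - fov[1]) * px_per_um)))
  H <- max(2L, as.integer(ceiling((fov[4] - fov[3]) * px_per_um)))
  img <- array(1, dim = c(H, W, 3))  # white background
  occ_idx <- which(state$occ == 1L)
  if (length(occ_idx) > 0) {
    i <- (occ_idx - 1L) %% cfg$I + 1L
    j <- (occ_idx - 1L) %/% cfg$I + 1L
    pos <- site_position(i, j, delta = cfg$delta)
    margin <- cfg$delta / 2
    keep <- pos$x >= fov[1] - margin & pos$x <= fov[2] + margin &
            pos$y >= fov[3] - margin & pos$y <= fov[4] + margin
    if (any(keep)) {
      pp <- state$pp[occ_idx][keep]
      if (is.null(pp_range)) {
        pp_all <- pp_values(state)
        pp_range <- range(pp_all)
        if (diff(pp_range) == 0) pp_range <- pp_range + c(-1e-6, 1e-6)
      }
      pal <- grDevices::hcl.colors(256, "RdYlBu", rev = TRUE)
      idx <- pmin(pmax(1 + floor(255 * (pp - pp_range[1]) /
                                   (pp_range[2] - pp_range[1])), 1), 256)
      rgb <- grDevices::col2rgb(pal[idx]) / 255
      r_px <- max(1, margin * px_per_um)
      cx <- (pos$x[keep] - fov[1]) * px_per_um
      cy <- (fov[4] - pos$y[keep]) * px_per_um  # y up -> row down
      for (k in seq_along(cx)) {
        px <- seq(max(1, floor(cx[k] - r_px)), min(W, ceiling(cx[k] + r_px)))
        py <- seq(max(1, floor(cy[k] - r_px)), min(H, ceiling(cy[k] + r_px)))
        if (length(px) == 0 || length(py) == 0) next
        dx2 <- outer((py - cy[k])^2, (px - cx[k])^2, "+")
        hit <- dx2 <= r_px^2
        for (ch in 1:3) {
          layer <- img[py, px, ch, drop = FALSE]
          layer[hit] <- rgb[ch, k]
          img[py, px, ch] <- layer
        }
      }
    }
  }
  if (!is.null(path)) png::writePNG(img, target = path)
  invisible(img)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the full
#' configuration echo, the base seed, and the package version.
#'
#' @param config A [scenario_config()] (or any serialisable list).
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest (e.g. colour
#'   -scale ranges of emitted snapshots).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(package = "hexpassage",
                     version = as.character(utils::packageVersion("hexpassage")),
                     config = unclass(config)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Execute a scenario end-to-end
#'
#' Runs the experiment described by a [scenario_config()] and writes its
#' outputs (plus a manifest) into `config$out_dir`:
#' \describe{
#'   \item{passage}{`passage_records.csv` (one row per passage), optional
#'     `pp_values_p<k>.csv` dumps when `keep_pp`, `manifest.json`.}
#'   \item{scratch}{`density_profiles.csv`, `closure.json` (per-realisation
#'     and mean closure times), `manifest.json`.}
#'   \item{msd_check}{`msd.json` with the estimated and theoretical
#'     diffusivity, `manifest.json`.}
#' }
#'
#' @param config A [scenario_config()].
#' @param quiet Suppress progress messages.
#' @return The experiment object (invisible): a `passaging_experiment`,
#'   `scratch_ensemble`, or a list for `msd_check`.
#' @export
run_scenario <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- switch(config$kind,
    passage = {
      say("passaging: %d passages on %d x %d, damage = %s",
          config$n_passages, config$I, config$J, config$damage)
      dmg <- if (config$damage == "custom")
        damage_model("custom", config$mu_eps, config$sigma_eps)
      else damage_model(config$damage)
      exp <- run_passaging_experiment(
        protocol = passaging_protocol(config$seed_fraction,
                                      config$confluence_fraction,
                                      config$n_passages, dmg,
                                      config$max_steps_per_passage),
        model = model_parameters(pm = config$pm, mu_p = config$mu_p,
                                 sigma = config$sigma, delta = config$delta,
                                 tau = config$tau),
        lattice = lattice_config(config$I, config$J, config$delta),
        seed = config$seed, keep_pp = isTRUE(config$keep_pp))
      export_boxplot_table(exp, file.path(config$out_dir,
                                          "passage_records.csv"))
      if (isTRUE(config$keep_pp)) {
        for (p in seq_along(exp$pp)) {
          write.csv(data.frame(pp = exp$pp[[p]]),
                    file.path(config$out_dir,
                              sprintf("pp_values_p%d.csv", p - 1)),
                    row.names = FALSE)
        }
      }
      exp
    },
    scratch = {
      src <- if (!is.null(config$pp_table_file))
        pp_table(utils::read.csv(config$pp_table_file)$pp)
      else pp_normal(config$mu_p, config$sigma)
      say("scratch: %d realisations on %d x %d, %d-column scratch",
          config$n_realisations, config$I, config$J, config$scratch_width)
      sc <- scratch_config(
        lattice = lattice_config(config$I, config$J, config$delta),
        seed_probability = config$seed_probability,
        scratch_width = config$scratch_width,
        scratch_position = config$scratch_position,
        record_times_h = config$record_times_h,
        n_realisations = config$n_realisations,
        pp_source = src, pm = config$pm, tau = config$tau)
      ens <- run_scratch_ensemble(sc, base_seed = config$seed)
      export_density_profiles(ens, file.path(config$out_dir,
                                             "density_profiles.csv"))
      ct <- closure_time(ens, threshold = config$closure_threshold)
      jsonlite::write_json(
        list(threshold = config$closure_threshold,
             closure_times_h = ct,
             mean_closure_h = mean(ct),
             n_closed = sum(!is.na(ct))),
        file.path(config$out_dir, "closure.json"),
        auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
      ens
    },
    msd_check = {
      say("msd check: %d trajectories of %d steps", config$n_traj,
          config$n_steps)
      set.seed(config$seed)
      d2 <- isolated_msd(config$n_traj, config$n_steps, pm = config$pm,
                         delta = config$delta)
      t_h <- config$n_steps * config$tau
      res <- list(n_traj = config$n_traj, n_steps = config$n_steps,
                  msd_um2 = mean(d2),
                  diffusivity_um2_h = mean(d2) / (4 * t_h),
                  theoretical_um2_h = config$pm * config$delta^2 /
                    (4 * config$tau))
      jsonlite::write_json(res, file.path(config$out_dir, "msd.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      res
    })
  write_manifest(config, file.path(config$out_dir, "manifest.json"))
  invisible(out)
}

#' Plot ensemble density profiles
#'
#' Base-graphics line plot of the ensemble-mean column density versus
#' horizontal position, one curve per recorded time.
#'
#' @param ensemble A `scratch_ensemble`.
#' @param ... Passed to [graphics::matplot()].
#' @return The ensemble, invisibly.
#' @export
plot_density_profiles <- function(ensemble, ...) {
  stopifnot(inherits(ensemble, "scratch_ensemble"))
  pr <- ensemble$profiles
  times <- unique(pr$time_h)
  m <- sapply(times, function(tt) pr$mean_density[pr$time_h == tt])
  graphics::matplot(unique(pr$x_um), m, type = "l", lty = 1,
                    xlab = "x (um)", ylab = "<C_i>",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = paste0("t = ", times, " h"),
                   lty = 1, col = seq_along(times), bty = "n")
  invisible(ensemble)
}
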