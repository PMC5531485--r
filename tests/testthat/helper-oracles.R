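# Shared fixtures and independent oracles for the test suite.

# Cache for expensive simulation runs reused across test files. Every cached
# expression sets its own seed, so reuse does not couple tests.
.run_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache))
    assign(name, force(expr), envir = .run_cache)
  get(name, envir = .run_cache)
}

# Closed-form logistic time to grow from density c0 to c1 at rate lambda:
# solution of dC/dt = lambda C (1 - C).
logistic_time <- function(c0, c1, lambda) {
  log(c1 * (1 - c0) / (c0 * (1 - c1))) / lambda
}

# Mean of the rectified normal max(eps, 0), eps ~ N(mu, sigma).
rectified_normal_mean <- function(mu, sigma) {
  mu * pnorm(mu / sigma) + sigma * dnorm(mu / sigma)
}

# Geometric neighbour list derived from site positions only: all sites at
# Euclidean distance delta (independent of the package's offset tables).
geometric_neighbours <- function(i, j, cfg) {
  grid <- expand.grid(i = seq_len(cfg$I), j = seq_len(cfg$J))
  pos <- site_position(grid$i, grid$j, delta = cfg$delta)
  p0 <- site_position(i, j, delta = cfg$delta)
  d <- sqrt((pos$x - p0$x)^2 + (pos$y - p0$y)^2)
  grid[abs(d - cfg$delta) < 1e-9, ]
}

# Exhaustive one-step distribution over occupancy configurations, by direct
# enumeration of every selection / Bernoulli / direction outcome of the
# two-sweep update. Cells carry pp values; configurations are keyed by the
# occupancy vector. Neighbour targets come from geometric_neighbours(), and
# off-domain direction mass (each of the six directions has probability 1/6)
# is lumped into the abort branch.
enumerate_one_step <- function(occ, pp, pm, cfg, newborns_eligible = TRUE) {
  I <- cfg$I; J <- cfg$J
  nb_list <- lapply(seq_len(I * J), function(s) {
    i <- (s - 1) %% I + 1; j <- (s - 1) %/% I + 1
    nb <- geometric_neighbours(i, j, cfg)
    (nb$j - 1) * I + nb$i
  })
  acc <- new.env(parent = emptyenv())
  add <- function(key, p) {
    old <- if (exists(key, envir = acc)) get(key, envir = acc) else 0
    assign(key, old + p, envir = acc)
  }
  sites0 <- which(occ == 1L)
  pps0 <- pp[sites0]

  prolif <- function(cells, pps, occv, left, n0, prob) {
    if (left == 0) {
      add(paste(occv, collapse = ""), prob)
      return(invisible())
    }
    pool <- if (newborns_eligible) length(cells) else n0
    for (k in seq_len(pool)) {
      psel <- prob / pool
      p_act <- pps[k]
      # not acting (Bernoulli failure)
      if (p_act < 1)
        prolif(cells, pps, occv, left - 1, n0, psel * (1 - p_act))
      if (p_act > 0) {
        nbs <- nb_list[[cells[k]]]
        vac <- nbs[occv[nbs] == 0L]
        # aborted: off-domain directions + occupied neighbours
        p_abort <- p_act * (6 - length(vac)) / 6
        if (p_abort > 0)
          prolif(cells, pps, occv, left - 1, n0, psel * p_abort)
        for (tgt in vac) {
          o2 <- occv; o2[tgt] <- 1L
          prolif(c(cells, tgt), c(pps, pps[k]), o2, left - 1, n0,
                 psel * p_act / 6)
        }
      }
    }
  }

  motility <- function(cells, pps, occv, left, prob) {
    if (left == 0) {
      prolif(cells, pps, occv, length(cells), length(cells), prob)
      return(invisible())
    }
    n <- length(cells)
    for (k in seq_len(n)) {
      psel <- prob / n
      if (pm < 1) motility(cells, pps, occv, left - 1, psel * (1 - pm))
      if (pm > 0) {
        nbs <- nb_list[[cells[k]]]
        vac <- nbs[occv[nbs] == 0L]
        p_abort <- pm * (6 - length(vac)) / 6
        if (p_abort > 0) motility(cells, pps, occv, left - 1, psel * p_abort)
        for (tgt in vac) {
          o2 <- occv; o2[cells[k]] <- 0L; o2[tgt] <- 1L
          c2 <- cells; c2[k] <- tgt
          motility(c2, pps, o2, left - 1, psel * pm / 6)
        }
      }
    }
  }

  motility(sites0, pps0, occ, length(sites0), 1)
  probs <- unlist(as.list(acc))
  probs[order(names(probs))]
}

# Scaled-down 30-passage reference runs (the flask-scale experiment uses the
# same 15%/85% fractions; the dynamics are fraction-driven). Cached because
# several test files interrogate the same trajectories.
trend_run <- function(population, damage) {
  name <- paste("trend", population, damage, sep = "_")
  seed <- 3000 + match(paste(population, damage),
                       c("near_homogeneous none", "near_homogeneous small",
                         "near_homogeneous large", "heterogeneous none",
                         "heterogeneous small", "heterogeneous large"))
  cached(name, run_passaging_experiment(
    passaging_protocol(n_passages = 30, damage = damage_model(damage)),
    model = model_parameters(population = population),
    lattice = lattice_config(100, 87), seed = seed, keep_pp = TRUE))
}

# Small ready-made states -----------------------------------------------

# single cell at (i, j) on an I x J lattice
single_cell_state <- function(i, j, I, J, pm = 0.35, pp = 0, tau = 1 / 12) {
  st <- empty_state(lattice_config(I, J), pm = pm, tau = tau)
  st$occ[i, j] <- 1L
  st$pp[i, j] <- pp
  st
}
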