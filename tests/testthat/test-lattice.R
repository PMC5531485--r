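test_that("site positions follow the row-shifted hexagonal formula", {
  expect_equal(site_position(1, 1, delta = 24), data.frame(x = 12, y = 0))
  expect_equal(site_position(1, 2, delta = 24),
               data.frame(x = 0, y = sqrt(3) * 24 / 2))
  # first row lies on the x axis for any column
  p <- site_position(1:17, rep(1, 17), delta = 3.5)
  expect_true(all(p$y == 0))
  # vertical row spacing is sqrt(3)/2 * delta
  p2 <- site_position(rep(4, 5), 1:5, delta = 10)
  expect_equal(diff(p2$y), rep(sqrt(3) * 5, 4))
  expect_error(site_position(0, 1, delta = 24), "1-based")
  expect_error(site_position(11, 1, config = lattice_config(10, 10)),
               "out of range")
})

test_that("every interior site has six neighbours at distance delta", {
  cfg <- lattice_config(10, 10, delta = 24)
  for (i in 2:9) {
    for (j in 2:9) {
      nb <- hex_neighbours(i, j, cfg)
      expect_equal(nrow(nb), 6)
      geo <- geometric_neighbours(i, j, cfg)
      expect_setequal(paste(nb[, "i"], nb[, "j"]), paste(geo$i, geo$j))
    }
  }
})

test_that("boundary sites have truncated neighbourhoods", {
  cfg <- lattice_config(6, 7)
  expect_lt(nrow(hex_neighbours(1, 1, cfg)), 6)
  # all in-domain neighbours, even at boundaries, are at distance delta
  for (i in c(1, 6)) {
    for (j in c(1, 7)) {
      nb <- hex_neighbours(i, j, cfg)
      p0 <- site_position(i, j, delta = cfg$delta)
      p <- site_position(nb[, "i"], nb[, "j"], delta = cfg$delta)
      expect_equal(sqrt((p$x - p0$x)^2 + (p$y - p0$y)^2),
                   rep(cfg$delta, nrow(nb)))
    }
  }
  expect_error(hex_neighbours(0, 3, cfg), "out of range")
})

test_that("lattice_config validates its arguments", {
  expect_error(lattice_config(1, 5), "I >= 2")
  expect_error(lattice_config(5, 5, delta = 0), "positive")
  expect_equal(n_sites(lattice_config(4168, 3610)), 15046480)
})

test_that("attempt_move: zero motility and full crowding leave the state unchanged", {
  st <- single_cell_state(3, 3, 6, 6, pm = 0)
  set.seed(42)
  unchanged <- vapply(1:50, function(k) identical(attempt_move(st, c(3, 3))$occ,
                                                  st$occ), logical(1))
  expect_true(all(unchanged))
  # cell enclosed by its six occupied neighbours can never move
  cfg <- lattice_config(7, 7)
  st <- empty_state(cfg, pm = 1)
  st$occ[4, 4] <- 1L; st$pp[4, 4] <- 0.5
  nb <- hex_neighbours(4, 4, cfg)
  for (r in seq_len(nrow(nb))) {
    st$occ[nb[r, "i"], nb[r, "j"]] <- 1L
    st$pp[nb[r, "i"], nb[r, "j"]] <- 0.1
  }
  set.seed(43)
  unchanged <- vapply(1:100, function(k) identical(attempt_move(st, c(4, 4))$occ,
                                                   st$occ), logical(1))
  expect_true(all(unchanged))
  expect_error(attempt_move(st, c(1, 1)), "vacant")
})

test_that("attempt_move with Pm = 1 lands uniformly on the six neighbours", {
  st <- single_cell_state(4, 4, 8, 8, pm = 1, pp = 0.3)
  cfg <- st$config
  nb <- hex_neighbours(4, 4, cfg)
  keys <- paste(nb[, "i"], nb[, "j"])
  set.seed(7)
  n_rep <- 100000
  landed <- vapply(seq_len(n_rep), function(k) {
    which(attempt_move(st, c(4, 4))$occ == 1L)
  }, integer(1))
  i <- (landed - 1) %% cfg$I + 1; j <- (landed - 1) %/% cfg$I + 1
  counts <- table(factor(paste(i, j), levels = keys))
  expect_equal(sum(counts), n_rep)  # always moved to a neighbour
  chi <- chisq.test(as.vector(counts), p = rep(1 / 6, 6))
  expect_gt(chi$p.value, 1e-3)
})

test_that("attempt_proliferation inherits pp exactly and is uniform over directions", {
  mother_pp <- 0.123456789101112
  st <- single_cell_state(4, 4, 8, 8, pm = 0.35, pp = 1)
  st$pp[4, 4] <- mother_pp
  # pp = 0 never divides
  st0 <- single_cell_state(4, 4, 8, 8, pp = 0)
  set.seed(11)
  expect_true(all(vapply(1:50, function(k)
    n_cells(attempt_proliferation(st0, c(4, 4))), numeric(1)) == 1))
  # pp sub-unit: daughters carry the mother value bit-for-bit
  set.seed(12)
  daughter_pp <- unlist(lapply(1:2000, function(k) {
    st2 <- attempt_proliferation(st, c(4, 4))
    if (n_cells(st2) == 2) pp_values(st2) else NULL
  }))
  expect_gt(length(daughter_pp), 0)
  expect_identical(unique(daughter_pp), mother_pp)
  # pp = 1 divides with probability 1, uniformly over the six directions
  st1 <- single_cell_state(4, 4, 8, 8, pp = 1)
  nb <- hex_neighbours(4, 4, st1$config)
  keys <- paste(nb[, "i"], nb[, "j"])
  mother_site <- which(st1$occ == 1L)
  set.seed(13)
  n_rep <- 100000
  landed <- vapply(seq_len(n_rep), function(k) {
    s <- which(attempt_proliferation(st1, c(4, 4))$occ == 1L)
    s[s != mother_site]
  }, integer(1))  # errors if a division ever fails
  i <- (landed - 1) %% st1$config$I + 1; j <- (landed - 1) %/% st1$config$I + 1
  counts <- table(factor(paste(i, j), levels = keys))
  chi <- chisq.test(as.vector(counts), p = rep(1 / 6, 6))
  expect_gt(chi$p.value, 1e-3)
  expect_error(attempt_proliferation(st, c(1, 1)), "vacant")
})

test_that("isolated-agent MSD accrues Pm * delta^2 per step", {
  set.seed(21)
  n_steps <- 40
  d2 <- isolated_msd(8000, n_steps, pm = 0.35, delta = 24)
  expect_equal(mean(d2), n_steps * 0.35 * 24^2, tolerance = 0.03)
})

test_that("a fully confluent lattice is frozen (all events aborted)", {
  cfg <- lattice_config(6, 5)
  st <- empty_state(cfg, pm = 1)
  st$occ[] <- 1L
  st$pp[] <- 1
  set.seed(31)
  st2 <- lattice_step(st, 5)
  expect_identical(st2$occ, st$occ)
  expect_identical(st2$pp, st$pp)
  expect_equal(st2$t, 5 / 12)
})

test_that("stepping an empty lattice errors", {
  st <- empty_state(lattice_config(5, 5))
  expect_error(lattice_step(st), "empty population")
})

test_that("per-capita division probability matches pp at low density", {
  set.seed(41)
  cfg <- lattice_config(200, 200)
  p <- 0.02
  st <- seed_random(cfg, 0.005,
                    model = model_parameters(mu_p = p, sigma = 0))
  n_traj <- numeric(101)
  n_traj[1] <- n_cells(st)
  for (k in 1:100) {
    st <- lattice_step(st)
    n_traj[k + 1] <- n_cells(st)
  }
  births <- n_traj[101] - n_traj[1]
  cell_steps <- sum(n_traj[1:100])
  expect_gt(cell_steps, 1e4)
  expect_equal(births / cell_steps, p, tolerance = 0.06)
})

test_that("one lattice step matches the exhaustive one-step distribution", {
  cfg <- lattice_config(4, 4)
  st <- empty_state(cfg, pm = 0.5)
  st$occ[2, 2] <- 1L; st$pp[2, 2] <- 0.3
  st$occ[3, 3] <- 1L; st$pp[3, 3] <- 0.7
  exact <- enumerate_one_step(as.vector(st$occ), as.vector(st$pp),
                              pm = 0.5, cfg)
  expect_equal(sum(exact), 1, tolerance = 1e-12)

  set.seed(51)
  n_rep <- 100000
  keys <- character(n_rep)
  for (k in seq_len(n_rep)) {
    st2 <- lattice_step(st)
    keys[k] <- paste(as.vector(st2$occ), collapse = "")
  }
  obs <- table(keys)
  # every observed configuration must be possible
  expect_true(all(names(obs) %in% names(exact)))
  # chi-square against the exact law, pooling low-expectation configurations
  expected <- exact * n_rep
  pool <- expected < 10
  counts <- c(as.vector(obs[names(exact)[!pool]]),
              sum(obs[names(exact)[pool]], na.rm = TRUE))
  counts[is.na(counts)] <- 0
  probs <- c(exact[!pool], sum(exact[pool]))
  chi <- chisq.test(counts, p = probs / sum(probs))
  expect_gt(chi$p.value, 1e-3)
})

test_that("motility conserves N and the pp multiset; proliferation only duplicates", {
  set.seed(61)
  cfg <- lattice_config(15, 15)
  st <- seed_random(cfg, 0.4,
                    model = model_parameters(mu_p = 0.05, sigma = 0.01))
  pp0 <- sort(pp_values(st))
  for (k in 1:30) {
    st <- lattice_step(st)
    expect_true(all(st$occ %in% c(0L, 1L)))  # exclusion, every step
    ppk <- pp_values(st)
    expect_gte(length(ppk), length(pp0))
    # every pp value now present was present at t = 0 (inheritance only)
    expect_true(all(ppk %in% pp0))
    # the original multiset survives (no value ever lost: no death)
    expect_true(all(table(pp0) <= table(factor(ppk, levels = unique(sort(pp0))))))
  }
})

test_that("frozen-pool proliferation sweep is available and behaves sanely", {
  set.seed(71)
  cfg <- lattice_config(12, 12)
  st <- seed_random(cfg, 0.2, model = model_parameters(mu_p = 0.5, sigma = 0))
  n0 <- n_cells(st)
  st_frozen <- lattice_step(st, newborns_eligible = FALSE)
  expect_true(all(st_frozen$occ %in% c(0L, 1L)))
  expect_gte(n_cells(st_frozen), n0)
  # at most one daughter per attempt either way
  expect_lte(n_cells(st_frozen), 2 * n0)
})
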