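test_that("spherical geometries match brute-force lattice enumeration", {
  # only the origin lattice point fits a 0.1-um sphere
  g <- build_spherical_biofilm(0.1, spacing = 1.5, jitter = 0)
  expect_identical(nrow(g$positions), 1L)
  expect_equal(as.numeric(g$positions), c(0, 0, 0))
  # radius 3, spacing 1.5: independent enumeration of lattice points
  g3 <- build_spherical_biofilm(3, spacing = 1.5, jitter = 0)
  grid <- as.matrix(expand.grid(-2:2, -2:2, -2:2)) * 1.5
  expect_identical(nrow(g3$positions), sum(rowSums(grid^2) <= 9))
  # determinism and jitter bounds
  a <- build_spherical_biofilm(6, seed = 11)
  b <- build_spherical_biofilm(6, seed = 11)
  expect_identical(a$positions, b$positions)
  expect_true(all(sqrt(rowSums(a$positions^2)) <= 6 + 1e-9))
  expect_error(build_spherical_biofilm(15, spacing = 0.3), "max_agents")
  expect_error(build_spherical_biofilm(3, jitter = 0.7), "jitter")
})

test_that("diffusion conserves mass in a closed box and decays pointwise", {
  f <- potassium_field(6, 1, boundary = "reflective")
  ctr <- (dim(f$grid) + 1) / 2
  f$grid[ctr[1], ctr[2], ctr[3]] <- 100
  m0 <- sum(f$grid)
  for (i in 1:40) f <- diffuse_step(f, D = 1, k_decay = 0, dt = 0.1)
  expect_equal(sum(f$grid), m0, tolerance = 1e-9)
  expect_true(all(f$grid >= 0))
  # pure decay: every voxel shrinks by exactly (1 - r dt)
  f2 <- potassium_field(3, 1)
  f2$grid[] <- runif(length(f2$grid))
  g_before <- f2$grid
  f2 <- diffuse_step(f2, D = 0, k_decay = 0.5, dt = 0.1)
  expect_equal(f2$grid, g_before * (1 - 0.5 * 0.1), tolerance = 1e-12)
  expect_error(diffuse_step(f2, D = 100, k_decay = 0, dt = 0.1), "stability")
})

test_that("a point release spreads with the heat-kernel variance 2 D t", {
  D <- 1; dt <- 0.05
  f <- potassium_field(10, 1, boundary = "reflective")
  ctr <- (dim(f$grid) + 1) / 2
  f$grid[ctr[1], ctr[2], ctr[3]] <- 1
  x <- (seq_len(dim(f$grid)[1]) - ctr[1])  # voxel coordinates, dx = 1
  times <- seq(0.5, 3, by = 0.5)
  vars <- numeric(length(times))
  t_now <- 0
  for (j in seq_along(times)) {
    while (t_now < times[j] - 1e-9) {
      f <- diffuse_step(f, D, 0, dt); t_now <- t_now + dt
    }
    marg <- apply(f$grid, 1, sum)
    vars[j] <- sum(marg * x^2) / sum(marg)
  }
  slope <- coef(lm(vars ~ times))[["times"]]
  expect_equal(slope, 2 * D, tolerance = 0.05)  # within 5% of 2D
})

test_that("the firing rule is an inclusive-threshold state machine", {
  p <- fdf_params(core_source = 0)
  geom <- build_spherical_biofilm(0.1, jitter = 0)
  field <- potassium_field(6, p$grid_dx)
  stencil <- biofilmwave:::trilinear_stencil(geom$positions, field)
  agents <- list(state = 0L, t_state = -Inf, fired = 0L, t_fired = NA_real_,
                 tht_spike = 0, released = 0, trigger = integer(0))
  # below threshold: nothing happens except flash decay
  agents$tht_spike <- 0.5
  upd <- fire_update(agents, field, p, t = 0, stencil)
  expect_identical(upd$agents$state, 0L)
  expect_equal(upd$agents$tht_spike, 0.5 * exp(-p$tht_decay * p$dt))
  # exactly at threshold: fires (threshold is inclusive)
  ctr <- (dim(field$grid) + 1) / 2
  field$grid[ctr[1], ctr[2], ctr[3]] <- p$c_thresh
  upd <- fire_update(agents, field, p, t = 0, stencil)
  expect_identical(upd$agents$state, 1L)
  expect_identical(upd$agents$fired, 1L)
  expect_equal(upd$agents$tht_spike, 1 * exp(-p$tht_decay * p$dt))
})

test_that("a neighbour fires after the first-passage delay of the pulse", {
  # two cells 1.5 um apart; the first is seeded to fire. Oracle: direct
  # finite-difference integration of the same diffusion-decay PDE, written
  # independently of the package's field machinery. The release is set high
  # enough that a single cell's pulse can ignite its neighbour.
  p <- fdf_params(core_source = 0, k_decay = 0.4, k_matrix = 0.4,
                  sigma_release = 60)
  geom <- structure(list(
    positions = rbind(c(0, 0, 0), c(1.5, 0, 0)),
    lattice_r = c(0, 1.5), radius = 1.5, spacing = 1.5, jitter = 0, seed = 1,
    bounding_box = c(-1.5, 1.5)), class = "biofilm_geometry")
  sim <- run_simulation(p, geom, duration = 2, trigger_radius = 0.5)
  expect_identical(length(sim$trigger), 1L)
  fire_frame <- which(sim$state[, 2] > 0)[1]
  t_pkg <- sim$times[fire_frame]

  # independent oracle on the same grid geometry
  dx <- p$grid_dx; dt <- p$dt
  hw <- max(p$domain_factor * 1.5, 4 * dx); m <- ceiling(hw / dx); n <- 2 * m + 1
  conc <- array(0, c(n, n, n))
  src <- c(m + 1, m + 1, m + 1)            # voxel of cell 1 (origin)
  tgt <- c(m + 1 + round(1.5 / dx), m + 1, m + 1)  # voxel of cell 2
  t_oracle <- NA
  conc_rate <- p$sigma_release / p$t_fire / dx^3
  for (step in 1:200) {
    t_now <- (step - 1) * dt
    if (t_now < p$t_fire) conc[src[1], src[2], src[3]] <-
        conc[src[1], src[2], src[3]] + conc_rate * min(dt, p$t_fire - t_now)
    new <- conc
    for (ax in 1:3) {
      up <- array(0, dim(conc)); dn <- array(0, dim(conc))
      if (ax == 1) { up[1:(n-1),,] <- conc[2:n,,]; dn[2:n,,] <- conc[1:(n-1),,] }
      if (ax == 2) { up[,1:(n-1),] <- conc[,2:n,]; dn[,2:n,] <- conc[,1:(n-1),] }
      if (ax == 3) { up[,,1:(n-1)] <- conc[,,2:n]; dn[,,2:n] <- conc[,,1:(n-1)] }
      new <- new + p$D * dt / dx^2 * (up + dn - 2 * conc)
    }
    conc <- pmax(new - dt * 0.4 * conc, 0)
    if (conc[tgt[1], tgt[2], tgt[3]] >= p$c_thresh) { t_oracle <- step * dt; break }
  }
  expect_false(is.na(t_oracle))
  expect_lt(abs(t_pkg - t_oracle), 3 * p$dt + p$frame_dt)
})

test_that("simulations are reproducible, refractory-limited and mass-balanced", {
  p <- fdf_params(k_decay = 0, k_matrix = 0, core_source = 0)
  geom <- build_spherical_biofilm(5, seed = 3)
  s1 <- run_simulation(p, geom, duration = 4, boundary = "reflective")
  s2 <- run_simulation(p, geom, duration = 4, boundary = "reflective")
  expect_identical(s1$tht, s2$tht)
  expect_identical(s1$state, s2$state)
  # frames strictly ordered
  expect_true(all(diff(s1$times) > 0))
  # each cell fires at most once during the first-peak phase
  expect_true(all(s1$fired <= 1L))
  # mass balance: closed box, no clearance -> field holds all released K
  expect_gt(s1$released, 0)
  expect_equal(s1$field_mass[length(s1$field_mass)], s1$released,
               tolerance = 0.005)
})

test_that("the global trace shows the peak / quiescence / plateau sequence", {
  sim <- memoize("global_trace_run", {
    run_simulation(fdf_params(), build_spherical_biofilm(10, seed = 3),
                   duration = 26)
  })
  g <- global_tht_trace(sim)
  expect_s3_class(g, "tht_trace")
  peak1 <- max(g$intensity[g$times < 5])
  trough <- min(g$intensity[g$times > 5 & g$times < 17])
  plateau <- mean(g$intensity[g$times > 22])
  expect_gt(peak1, 5 * trough)
  expect_gt(plateau, 5 * trough)
  # plateau persists (habituation): late values stay high
  expect_true(all(g$intensity[g$times > 22] > 0.5 * plateau))
})

test_that("a geometry with no cells near the origin rejects the default trigger", {
  p <- fdf_params(core_source = 0)
  geom <- build_spherical_biofilm(4, seed = 2)
  # hollow shell: strip the core cells so the trigger region is empty
  keep <- geom$lattice_r > 2
  geom$positions <- geom$positions[keep, , drop = FALSE]
  geom$lattice_r <- geom$lattice_r[keep]
  expect_error(run_simulation(p, geom), "empty trigger")
  # a single-cell biofilm still runs
  expect_error(run_simulation(p, build_spherical_biofilm(0, jitter = 0),
                              duration = 1), NA)
})

test_that("wave propagation fails below and succeeds above the critical size", {
  p <- fdf_params()
  small <- run_simulation(p, build_spherical_biofilm(1.6, seed = 1), duration = 6)
  big <- run_simulation(p, build_spherical_biofilm(8, seed = 1), duration = 6)
  expect_false(propagation_success(small))
  expect_true(propagation_success(big))
  expect_gt(mean(big$fired > 0), 0.9)
})

test_that("with a vanishing threshold the critical radius collapses to the ignition zone", {
  p <- fdf_params(c_thresh = 1e-6)
  cr <- find_critical_radius(p, radius_lo = 0.4, radius_hi = 4, n_seeds = 2,
                             duration = 3, tol = 0.5)
  # everything fires instantly; the only floor left is the direct-ignition
  # zone (trigger + one spacing) that the relayed-success tally excludes
  expect_lte(cr$mean, 2 * 1.5 + 0.5)
  # a violated bracket is reported with advice
  expect_error(find_critical_radius(fdf_params(), radius_lo = 8, radius_hi = 12,
                                    n_seeds = 1, duration = 4),
               "widen")
})
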