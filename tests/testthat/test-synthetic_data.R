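test_that("trace ensembles are reproducible and sized as requested", {
  tpl <- trace_template("wildtype")
  e1 <- generate_trace_ensemble(tpl, 5, seed = 9)
  e2 <- generate_trace_ensemble(tpl, 5, seed = 9)
  expect_identical(length(e1), 5L)
  expect_identical(e1[[3]]$intensity, e2[[3]]$intensity)
  expect_identical(length(generate_trace_ensemble(tpl, 0)), 0L)
  expect_error(trace_template("mystery"), "invalid phenotype")
})

test_that("ensemble first-peak latencies recover the target moments", {
  # sparse single cells: mean 7.34 min, SD 10.89 min; traces long enough to
  # observe the heavy lognormal tail
  tpl <- trace_template("wildtype", latency_mean = 7.34, latency_sd = 10.89,
                        duration = 180)
  ens <- generate_trace_ensemble(tpl, 500, seed = 2)
  lat <- vapply(ens, function(tr) {
    tryCatch(time_to_first_peak(normalize_trace(tr)), error = function(e) NA_real_)
  }, numeric(1))
  lat <- lat[!is.na(lat)]
  st <- latency_statistics(lat)
  se_target <- 10.89 / sqrt(st$n)
  expect_lt(abs(st$mean - 7.34), 2 * se_target)
  # microclusters have a far tighter latency spread than sparse cells
  tpl_mc <- trace_template("wildtype", latency_mean = 3.24, latency_sd = 1.77)
  ens_mc <- generate_trace_ensemble(tpl_mc, 200, seed = 3)
  lat_mc <- vapply(ens_mc, function(tr) {
    tryCatch(time_to_first_peak(normalize_trace(tr)), error = function(e) NA_real_)
  }, numeric(1))
  expect_lt(sd(lat_mc, na.rm = TRUE), 0.5 * st$sd)
})

test_that("phenotype peak-count contracts hold for at least 95% of traces", {
  counts <- function(phen, expected) {
    tpl <- trace_template(phen)
    ens <- generate_trace_ensemble(tpl, 60, seed = 5)
    mean(vapply(ens, function(tr) {
      n_peaks(detect_peaks(normalize_trace(tr)))
    }, numeric(1)) == expected)
  }
  expect_gte(counts("wildtype", 2), 0.95)
  expect_gte(counts("delta_kch", 1), 0.95)
  expect_gte(counts("catalase", 1), 0.95)
  # knockouts are non-responsive: flagged via raw dynamic range
  tpl <- trace_template("ms_knockout")
  ens <- generate_trace_ensemble(tpl, 60, seed = 6)
  frac0 <- mean(vapply(ens, function(tr) {
    n_peaks(detect_peaks(normalize_trace(tr)))
  }, numeric(1)) == 0)
  expect_gte(frac0, 0.95)
})

test_that("power-law tracks are exact when noiseless and seeded when noisy", {
  tr <- generate_power_law_track(5, 3, 2, n_points = 30, noise_sd = 0)
  expect_equal(tr$R^2, 5^2 + 3 * tr$times^2, tolerance = 1e-12)
  a <- generate_power_law_track(5, 3, 2, noise_sd = 0.1, seed = 8)
  b <- generate_power_law_track(5, 3, 2, noise_sd = 0.1, seed = 8)
  expect_identical(a$R, b$R)
  expect_error(generate_power_law_track(5, 3, -1), "gamma")
})

test_that("rendering places a PSF-shaped blob at a bright cell's position", {
  p <- fdf_params()
  geom <- build_spherical_biofilm(0.1, jitter = 0)
  sim <- run_simulation(p, geom, duration = 0.4)
  sim$tht[] <- 0
  spec <- image_stack_spec(voxel_size = 1, half_width = 6, psf_sigma = 1,
                           photon_scale = 5000, background = 0.01)
  # background-only stack
  dark <- render_image_stack(sim, spec, seed = 2)
  expect_equal(mean(dark) / spec$photon_scale, spec$background, tolerance = 0.02)
  # one bright cell at the origin
  sim$tht[, 1] <- 1
  img <- render_image_stack(sim, spec, seed = 2)
  frame <- img[, , , 1] / spec$photon_scale - spec$background
  n <- dim(frame)[1]; ctr <- (n + 1) / 2
  expect_identical(which.max(frame),
                   which.max(array(seq_along(frame) ==
                     (ctr + (ctr - 1) * n + (ctr - 1) * n^2), dim(frame))))
  # radial profile matches a direct Gaussian evaluation
  ax <- seq_len(n) - ctr
  direct <- exp(-ax^2 / 2) / sum(exp(-ax^2 / 2))  # 1D kernel, sigma 1 voxel
  prof <- frame[, ctr, ctr] / frame[ctr, ctr, ctr]
  expect_equal(prof[ctr + 2] , (direct[ctr + 2] / direct[ctr]), tolerance = 0.15)
})

test_that("cells outside the stack bounds are reported", {
  p <- fdf_params()
  geom <- build_spherical_biofilm(6, seed = 1)
  sim <- run_simulation(p, geom, duration = 0.4)
  spec <- image_stack_spec(half_width = 2)
  expect_error(render_image_stack(sim, spec), "outside the stack bounds")
})

test_that("image stacks survive the TIFF round trip", {
  p <- fdf_params()
  geom <- build_spherical_biofilm(3, seed = 1)
  sim <- run_simulation(p, geom, duration = 1)
  stack <- render_image_stack(sim, image_stack_spec(), seed = 3)
  path <- tempfile(fileext = ".tif")
  write_image_stack(stack, path)
  back <- read_image_stack(path)
  expect_equal(dim(back), dim(stack))
  expect_lt(max(abs(back - stack)) / max(stack), 1e-6)
  expect_equal(attr(back, "times"), as.numeric(attr(stack, "times")))
  unlink(c(path, paste0(path, ".json")))
})

test_that("image-based tracking reproduces the agent-space transport class", {
  sim <- memoize("render_roundtrip_sim", {
    run_simulation(fdf_params(), build_spherical_biofilm(15, seed = 1),
                   duration = 8)
  })
  agent_tracks <- track_wavefront_radius(sim)
  agent_fit <- fit_power_law(agent_tracks$centrifugal)
  stack <- render_image_stack(sim, image_stack_spec(voxel_size = 1),
                              seed = 7)
  img_tracks <- track_wavefront_radius(stack, voxel_size = 1,
                                       times = attr(stack, "times"))
  img_fit <- fit_power_law(img_tracks$centrifugal)
  expect_identical(classify_transport(img_fit$gamma),
                   classify_transport(agent_fit$gamma))
  comb_sd <- sqrt(img_fit$gamma_sd^2 + agent_fit$gamma_sd^2)
  expect_lt(abs(img_fit$gamma - agent_fit$gamma), max(1 * comb_sd, 0.3))
})
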