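test_that("gating steady state is a logistic with the expected anchor points", {
  expect_equal(gate_steady_state(-50, V_half = -50, slope = 10), 0.5)
  expect_equal(gate_steady_state(1e6, V_half = 0, slope = 10), 1.0, tolerance = 1e-12)
  # one slope unit above the midpoint: 1 / (1 + exp(-1))
  expect_equal(gate_steady_state(-40, V_half = -50, slope = 10),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  # monotone in V for positive slope
  v <- seq(-120, 0, by = 5)
  expect_true(all(diff(gate_steady_state(v, -60, 8)) > 0))
  expect_error(gate_steady_state(NaN, -50, 10), "finite")
  expect_error(gate_steady_state(-50, -50, 0), "nonzero")
})

test_that("parameter constructor enforces the channel-kinetics invariants", {
  p <- hh_params()
  expect_s3_class(p, "hh_params")
  expect_lt(p$tau_act_Q, p$tau_act_K)   # Q activates faster than Kch
  expect_gt(p$tau_inact_Q, p$tau_deact_K)
  expect_lt(p$E_K, p$E_L)               # potassium efflux hyperpolarizes
  expect_error(hh_params(tau_act_Q = 5), "faster")
  expect_error(hh_params(E_K = -10), "resting")
  expect_error(hh_params(C_m = -1), "positive")
  expect_error(hh_params(not_a_field = 1), "unknown")
})

test_that("variants modify exactly the intended parameter", {
  p <- hh_params()
  expect_identical(make_variant(p, "wildtype"), p)
  expect_identical(make_variant(p, "delta_kch")$g_K, 0)
  expect_identical(make_variant(p, "catalase")$alpha_ROS, 0)
  expect_identical(make_variant(p, "ms_knockout")$g_Q, 0)
  expect_identical(make_variant(p, "delta_kch")[names(p) != "g_K"],
                   unclass(p)[names(p) != "g_K"])
  expect_error(make_variant(p, "nonsense"), "wildtype, delta_kch")
})

test_that("the four phenotypes show their characteristic peak structure", {
  wt <- hh_variant_sim("wildtype")
  expect_identical(hh_peak_count(wt), 2L)
  # second maximum persists to the end of the experiment
  pk <- detect_peaks(wt$trace)
  expect_true(pk$plateau_peak)

  kch <- hh_variant_sim("delta_kch")
  pk_kch <- detect_peaks(kch$trace)
  expect_identical(n_peaks(pk_kch), 1L)
  expect_true(pk_kch$plateau_peak)  # single rise to plateau, no repolarization
  # no repolarization: potential never recovers towards rest after the dive
  V <- kch$trajectory$V
  expect_lt(max(V[kch$trajectory$t > 20]), min(V) + 5)

  expect_identical(hh_peak_count(hh_variant_sim("catalase")), 1L)
  expect_identical(hh_peak_count(hh_variant_sim("ms_knockout")), 0L)
})

test_that("irradiance controls the second event and first-peak latency", {
  # below threshold: at most one peak; at/above threshold: two
  expect_lte(hh_peak_count(hh_variant_sim("wildtype", irradiance = 12)), 1L)
  expect_lte(hh_peak_count(hh_variant_sim("wildtype", irradiance = 15)), 1L)
  expect_identical(hh_peak_count(hh_variant_sim("wildtype", irradiance = 15.99)), 2L)
  expect_identical(hh_peak_count(hh_variant_sim("wildtype", irradiance = 24)), 2L)
  # time to first peak is non-increasing in irradiance
  lat <- vapply(c(6, 9, 13, 15.99, 22, 32), function(I) {
    time_to_first_peak(hh_variant_sim("wildtype", irradiance = I)$trace)
  }, numeric(1))
  expect_true(all(diff(lat) <= 1e-9))
})

test_that("gate variables stay in [0,1] across a randomized parameter sweep", {
  set.seed(41)
  for (i in 1:6) {
    p <- hh_params(g_Q = runif(1, 0.5, 4), g_K = runif(1, 2, 12),
                   g_L = runif(1, 0.2, 1), alpha_ROS = runif(1, 0.05, 0.2),
                   irradiance = runif(1, 5, 40))
    sim <- simulate_membrane(p, constant_light(p$irradiance, 30), dt = 0.01)
    gates <- as.matrix(sim$trajectory[, c("m_Q", "h_Q", "n_K")])
    expect_true(all(gates >= 0 & gates <= 1))
    expect_true(all(sim$trajectory$S >= 0))
    expect_true(all(is.finite(sim$trajectory$V)))
  }
})

test_that("with all conductances zero the potential stays exactly constant", {
  p <- hh_params(g_Q = 0, g_K = 0, g_L = 0)
  sim <- simulate_membrane(p, constant_light(20, 10), dt = 0.01)
  expect_equal(sim$trajectory$V, rep(p$E_L, nrow(sim$trajectory)))
})

test_that("integration converges: halving dt changes the trace by < 0.1%", {
  p <- hh_params()
  s1 <- simulate_membrane(p, dt = 0.01)
  s2 <- simulate_membrane(p, dt = 0.005)
  rel <- max(abs(s1$trajectory$V - s2$trajectory$V)) / diff(range(s1$trajectory$V))
  expect_lt(rel, 0.001)
})

test_that("adaptive and fixed-step integrators agree", {
  p <- hh_params()
  s1 <- simulate_membrane(p, dt = 0.01)
  s2 <- simulate_membrane(p, method = "adaptive")
  expect_lt(max(abs(s1$trajectory$V - s2$trajectory$V)), 0.05)
})

test_that("ROS coupling shifts the second event as expected", {
  # reduced ROS production delays the second peak; increased ROS brings it
  # forward and raises the late plateau
  t2_of <- function(alpha) {
    sim <- hh_variant_sim("wildtype")
    p <- hh_params(alpha_ROS = alpha)
    sim <- simulate_membrane(p)
    pk <- detect_peaks(sim$trace)
    if (n_peaks(pk) < 2) Inf else pk$peak_times[2]
  }
  expect_gt(t2_of(0.085), t2_of(0.1))
  expect_gt(t2_of(0.1), t2_of(0.15))
})

test_that("oversized step sizes and degenerate schedules are rejected", {
  p <- hh_params()
  expect_error(simulate_membrane(p, dt = 1), "dt")
  empty <- stimulus_program(data.frame(start = numeric(0), stop = numeric(0),
                                       irradiance = numeric(0)), 10)
  expect_warning(sim <- simulate_membrane(p, empty), "empty")
  expect_identical(nrow(sim$trajectory), 1L)
  expect_error(stimulus_program(data.frame(start = 0, stop = 20, irradiance = 1), 10),
               "within")
  expect_error(stimulus_program(data.frame(start = c(0, 3), stop = c(5, 8),
                                           irradiance = c(1, 1)), 10),
               "overlap")
})

test_that("ThT readout is Nernstian and flags non-responsive traces", {
  # constant V gives constant intensity
  tr <- tht_readout(rep(-80, 10), normalize = FALSE)
  expect_equal(diff(range(tr$intensity)), 0)
  # intensity is monotone decreasing in V
  tr <- tht_readout(seq(-140, -80, by = 5), normalize = FALSE)
  expect_true(all(diff(tr$intensity) < 0))
  # a -26 mV step at V_T = 26 mV brightens by a factor e before normalization
  tr <- tht_readout(c(-80, -106), V_T = 26, normalize = FALSE)
  expect_equal(tr$intensity[2] / tr$intensity[1], exp(1), tolerance = 1e-12)
  expect_error(tht_readout(numeric(0)), "empty")
  # the raw dynamic range is preserved for flat-trace screening
  tr <- tht_readout(c(-80, -80.01, -80), normalize = TRUE)
  expect_lt(tr$dynamic_range - 1, 0.05)
})

test_that("irradiance from power follows the field-of-view geometry", {
  expect_identical(irradiance_from_power(0, 26.5, 60), 0)
  # the working measurement: 2.43 uW through the 60x objective (FN 26.5 mm)
  I <- irradiance_from_power(2.43, 26.5, 60)
  expect_equal(I, 2.43 / (pi * (26.5 / 120)^2), tolerance = 1e-12)
  expect_equal(I, 15.9, tolerance = 0.01)
  # linear in power
  expect_equal(irradiance_from_power(4.86, 26.5, 60), 2 * I)
  expect_error(irradiance_from_power(1, 26.5, 0), "positive")
})
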