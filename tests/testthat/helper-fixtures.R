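# Shared fixtures. Heavy simulations are memoized in this environment so the
# acceptance ensemble is computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# ensemble of default-parameter FDF runs on 15-um biofilms with per-run
# power-law fits of both wave phases
fdf_ensemble_fits <- function(n_seeds = 10, radius = 15, duration = 10) {
  memoize(sprintf("fdf_ens_%d_%g", n_seeds, radius), {
    p <- fdf_params()
    out <- list()
    s <- 0L
    while (length(out) < n_seeds && s < 2L * n_seeds) {
      s <- s + 1L
      geom <- build_spherical_biofilm(radius, seed = s)
      sim <- run_simulation(p, geom, duration = duration)
      if (mean(sim$fired > 0) < 0.9) next
      tr <- track_wavefront_radius(sim)
      cf <- tryCatch(fit_power_law(tr$centrifugal), error = function(e) NULL)
      cp <- if (!is.null(tr$centripetal)) {
        tryCatch(fit_power_law(tr$centripetal), error = function(e) NULL)
      } else NULL
      if (is.null(cf) || is.null(cp)) next
      out[[length(out) + 1L]] <- list(seed = s, cf = cf, cp = cp, sim = NULL)
    }
    out
  })
}

# a small default HH simulation per variant
hh_variant_sim <- function(variant, irradiance = NULL, duration = 60) {
  p <- make_variant(hh_params(), variant)
  stim <- constant_light(irradiance %||% p$irradiance, duration)
  simulate_membrane(p, stim)
}

hh_peak_count <- function(sim, ...) n_peaks(detect_peaks(sim$trace, ...))

`%||%` <- function(a, b) if (is.null(a)) b else a
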