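# Synthetic-data generators: parametric ThT trace ensembles for the four
# phenotypes, power-law wavefront tracks for fitter validation, and rendered
# 3D fluorescence image stacks bridging the FDF simulator to the image-based
# wavefront analysis.

#' Parametric template for a two-peak ThT trace
#'
#' The wildtype trace is modelled as a Gaussian first pulse at a random
#' latency plus a logistic second rise to a persistent plateau; phenotypes switch components off: \code{delta_kch} has a single
#' rise to plateau with no repolarization, \code{catalase} has the first
#' pulse only, \code{ms_knockout} is flat. First-peak latencies are drawn
#' from a lognormal matched to the target mean/SD (the sparse-cell latency
#' SD exceeds its mean, which rules out a Gaussian).
#'
#' @param phenotype one of \code{"wildtype"}, \code{"delta_kch"},
#'   \code{"catalase"}, \code{"ms_knockout"}.
#' @param latency_mean,latency_sd target first-peak latency moments (min).
#'   Defaults 7.34 and 10.89 (sparse single cells); microclusters use
#'   3.24 and 1.77.
#' @param peak_width relative width of the first pulse as a fraction of its
#'   latency (default 0.15), with an absolute floor of
#'   \code{min_peak_width} minutes so that early peaks remain resolvable at
#'   the one-frame-per-minute cadence.
#' @param min_peak_width minimum absolute pulse width (min, default 1.2).
#' @param peak_amp first-pulse amplitude (fluorescence units above baseline).
#' @param quiescence quiescent interval between the first peak and the
#'   midpoint of the second rise (min).
#' @param rise_slope logistic slope of the second rise (min).
#' @param plateau_level plateau amplitude (fluorescence units above baseline).
#' @param baseline background fluorescence level (units; keeps the raw
#'   dynamic range meaningful).
#' @param noise_add additive Gaussian noise SD (units).
#' @param noise_mult multiplicative noise SD (fraction; the default keeps
#'   plateau ripples safely below the default peak-calling prominence).
#' @param duration trace duration (min, default 60, the standard light-stress
#'   protocol).
#' @param dt sampling cadence (min, default 1, one frame per minute).
#' @return object of class \code{trace_template}.
#' @export
trace_template <- function(phenotype = c("wildtype", "delta_kch", "catalase",
                                         "ms_knockout"),
                           latency_mean = 7.34, latency_sd = 10.89,
                           peak_width = 0.15, min_peak_width = 1.2,
                           peak_amp = 1,
                           quiescence = 18, rise_slope = 3,
                           plateau_level = 0.95, baseline = 1,
                           noise_add = 0.01, noise_mult = 0.01,
                           duration = 60, dt = 1) {
  if (!is.character(phenotype) ||
      !phenotype[1] %in% c("wildtype", "delta_kch", "catalase", "ms_knockout")) {
    stopf("trace_template(): invalid phenotype '%s'", paste(phenotype[1]))
  }
  phenotype <- phenotype[1]
  for (f in c("latency_mean", "latency_sd", "peak_width", "min_peak_width",
              "peak_amp",
              "quiescence", "rise_slope", "plateau_level", "baseline",
              "duration", "dt")) check_positive(get(f), f)
  check_nonneg(noise_add, "noise_add"); check_nonneg(noise_mult, "noise_mult")
  structure(list(phenotype = phenotype, latency_mean = latency_mean,
                 latency_sd = latency_sd, peak_width = peak_width,
                 min_peak_width = min_peak_width,
                 peak_amp = peak_amp, quiescence = quiescence,
                 rise_slope = rise_slope, plateau_level = plateau_level,
                 baseline = baseline, noise_add = noise_add,
                 noise_mult = noise_mult, duration = duration, dt = dt),
            class = "trace_template")
}

#' @export
print.trace_template <- function(x, ...) {
  cat(sprintf("Trace template (%s): latency %g +/- %g min, %g min @ %g min cadence\n",
              x$phenotype, x$latency_mean, x$latency_sd, x$duration, x$dt))
  invisible(x)
}

# lognormal parameters matched to a target mean and SD
lognormal_moments <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# deterministic trace shape for a given first-peak latency
template_shape <- function(tpl, t, latency) {
  y <- rep(0, length(t))
  # first pulse: Gaussian in time; the width scales with the latency but has
  # an absolute floor so short-latency spikes survive the sampling cadence
  w <- max(tpl$peak_width * latency, tpl$min_peak_width)
  pulse <- function(tt) exp(-(tt - latency)^2 / (2 * w^2))
  rise_mid <- latency + tpl$quiescence
  if (tpl$phenotype == "wildtype") {
    y <- tpl$peak_amp * pulse(t) +
      tpl$plateau_level * sigmoid((t - rise_mid) / tpl$rise_slope)
  } else if (tpl$phenotype == "delta_kch") {
    # single hyperpolarization that never repolarizes: saturating rise
    y <- tpl$plateau_level *
      sigmoid((t - latency) / max(latency * tpl$peak_width, tpl$min_peak_width))
  } else if (tpl$phenotype == "catalase") {
    y <- tpl$peak_amp * pulse(t)
  }
  # ms_knockout: flat
  # stimulus-onset ramp: fluorescence rises from the pre-stimulus baseline,
  # so even the shortest-latency responses start dark at t = 0
  tpl$baseline + y * (1 - exp(-(t / 0.5)^2))
}

#' Generate an ensemble of synthetic ThT traces
#'
#' Draws a first-peak latency per trace from the moment-matched lognormal,
#' evaluates the phenotype's trace shape, and applies multiplicative and
#' additive Gaussian noise. Deterministic per seed. The drawn latencies are
#' returned as an attribute for round-trip checks.
#'
#' @param template a \code{\link{trace_template}}.
#' @param n number of traces (0 gives an empty list).
#' @param seed RNG seed.
#' @return list of \code{\link{tht_trace}} (raw, unnormalized), with
#'   attribute \code{latencies}.
#' @export
generate_trace_ensemble <- function(template, n, seed = 1L) {
  stopifnot(inherits(template, "trace_template"))
  check_nonneg(n, "n")
  if (n == 0) return(structure(list(), latencies = numeric(0)))
  set.seed(derive_seed(seed, "trace_ensemble"))
  lp <- lognormal_moments(template$latency_mean, template$latency_sd)
  lat <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
  t <- seq(0, template$duration, by = template$dt)
  traces <- lapply(seq_len(n), function(i) {
    y <- template_shape(template, t, lat[i])
    y <- y * (1 + stats::rnorm(length(y), 0, template$noise_mult)) +
      stats::rnorm(length(y), 0, template$noise_add)
    y <- pmax(y, 0)
    tht_trace(t, y, label = sprintf("%s_%03d", template$phenotype, i),
              dynamic_range = max(y) / max(min(y), .Machine$double.eps))
  })
  structure(traces, latencies = lat)
}

#' Generate a wavefront track from the anomalous power law
#'
#' Forward model for validating \code{\link{fit_power_law}}:
#' \eqn{R(t) = \sqrt{Rc^2 + b t^\gamma}} sampled at \code{n_points} with
#' optional Gaussian noise on R. Exact when \code{noise_sd = 0}.
#'
#' @param Rc critical radius (um), >= 0.
#' @param b prefactor (um^2/min^gamma), > 0.
#' @param gamma anomalous exponent, > 0.
#' @param n_points number of samples (default 30).
#' @param noise_sd Gaussian noise SD on R (um); may also be given as a
#'   fraction of R via \code{noise_frac}.
#' @param noise_frac relative noise (fraction of R), applied in addition to
#'   \code{noise_sd}; default 0.
#' @param t_max track duration (min, default 10).
#' @param seed RNG seed.
#' @param phase track phase label.
#' @return a \code{\link{wavefront_track}}.
#' @export
generate_power_law_track <- function(Rc, b, gamma, n_points = 30,
                                     noise_sd = 0, noise_frac = 0,
                                     t_max = 10, seed = 1L,
                                     phase = "centrifugal") {
  check_nonneg(Rc, "Rc"); check_positive(b, "b")
  if (!is.numeric(gamma) || gamma <= 0) stopf("generate_power_law_track(): gamma must be > 0")
  check_positive(t_max, "t_max")
  if (n_points < 4) stopf("generate_power_law_track(): need n_points >= 4")
  t <- seq(0, t_max, length.out = n_points)
  R <- sqrt(Rc^2 + b * t^gamma)
  if (noise_sd > 0 || noise_frac > 0) {
    set.seed(derive_seed(seed, "power_law_track"))
    R <- R + stats::rnorm(n_points, 0, noise_sd) +
      R * stats::rnorm(n_points, 0, noise_frac)
    R <- pmax(R, 0)
  }
  wavefront_track(t, R, phase = phase, source = "synthetic")
}

#' Specification of a rendered fluorescence image stack
#'
#' @param voxel_size voxel edge (um, default 1.5).
#' @param half_width half-width of the imaged cube (um); defaults to the
#'   biofilm radius plus 4 voxels when rendering a simulation.
#' @param frame_every render every k-th simulation frame (default 1).
#' @param psf_sigma Gaussian PSF standard deviation (um, default 1).
#' @param photon_scale expected photon count at unit fluorescence (shot-noise
#'   scale, default 100).
#' @param background background fluorescence level (default 0.05).
#' @return object of class \code{image_stack_spec}.
#' @export
image_stack_spec <- function(voxel_size = 1.5, half_width = NULL,
                             frame_every = 1, psf_sigma = 1,
                             photon_scale = 100, background = 0.05) {
  check_positive(voxel_size, "voxel_size")
  check_positive(frame_every, "frame_every")
  check_nonneg(psf_sigma, "psf_sigma")
  check_positive(photon_scale, "photon_scale")
  check_nonneg(background, "background")
  if (!is.null(half_width)) check_positive(half_width, "half_width")
  structure(list(voxel_size = voxel_size, half_width = half_width,
                 frame_every = frame_every, psf_sigma = psf_sigma,
                 photon_scale = photon_scale, background = background),
            class = "image_stack_spec")
}

# separable 3D Gaussian blur, zero-padded
gaussian_blur3 <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2)); k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(d[axis]) + off
      ok <- src >= 1L & src <= d[axis]
      if (!any(ok)) next
      dst <- which(ok); src <- src[ok]
      switch(axis,
             out[dst, , ] <- out[dst, , , drop = FALSE] + k[j] * a[src, , , drop = FALSE],
             out[, dst, ] <- out[, dst, , drop = FALSE] + k[j] * a[, src, , drop = FALSE],
             out[, , dst] <- out[, , dst, drop = FALSE] + k[j] * a[, , src, drop = FALSE])
    }
    out
  }
  conv_axis(conv_axis(conv_axis(a, 1L), 2L), 3L)
}

#' Render an FDF simulation as a synthetic confocal image stack
#'
#' Per rendered frame each cell's fluorescence proxy is deposited into its
#' voxel (trilinear weights), convolved with a Gaussian PSF, scaled to an
#' expected photon count, and replaced by a Poisson draw plus background
#' (shot noise). Deterministic per seed.
#'
#' @param sim an \code{fdf_sim}.
#' @param spec an \code{\link{image_stack_spec}}.
#' @param seed RNG seed.
#' @return 4D array (x, y, z, t) of noisy intensities in photon units, with
#'   attributes \code{times} (min) and \code{voxel_size} (um).
#' @export
render_image_stack <- function(sim, spec = image_stack_spec(), seed = 1L) {
  stopifnot(inherits(sim, "fdf_sim"), inherits(spec, "image_stack_spec"))
  hw <- spec$half_width %||% (sim$geometry$radius + 4 * spec$voxel_size)
  m <- ceiling(hw / spec$voxel_size)
  n <- 2L * m + 1L
  pos <- sim$geometry$positions
  if (any(abs(pos) > hw + spec$voxel_size / 2)) {
    off <- which(apply(abs(pos) > hw + spec$voxel_size / 2, 1, any))
    stopf("render_image_stack(): %d cell(s) outside the stack bounds (first: #%d)",
          length(off), off[1])
  }
  pseudo_field <- list(grid = array(0, c(n, n, n)), dx = spec$voxel_size,
                       origin = rep(-m * spec$voxel_size, 3))
  class(pseudo_field) <- "potassium_field"
  stencil <- trilinear_stencil(pos, pseudo_field)
  frames <- seq(1L, length(sim$times), by = spec$frame_every)
  out <- array(0, c(n, n, n, length(frames)))
  set.seed(derive_seed(seed, "render_stack"))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    vol <- array(0, c(n, n, n))
    idx <- as.vector(stencil$idx)
    val <- as.vector(stencil$w * sim$tht[f, ])
    agg <- rowsum(val, idx)
    vol[as.integer(rownames(agg))] <- agg[, 1]
    vol <- gaussian_blur3(vol, spec$psf_sigma / spec$voxel_size)
    lambda <- spec$photon_scale * (vol + spec$background)
    out[, , , fi] <- array(stats::rpois(length(lambda), lambda), dim(lambda))
  }
  attr(out, "times") <- sim$times[frames]
  attr(out, "voxel_size") <- spec$voxel_size
  out
}

#' Write / read a multi-page TIFF image stack
#'
#' Pages are z-slices ordered within frames (frame-major). Intensities are
#' stored as 32-bit floats scaled to [0, 1] by the recorded \code{scale};
#' dimensions, times, voxel size and scale go to a JSON sidecar
#' (\code{<path>.json}) so the round trip is lossless in structure.
#'
#' @param stack 4D array from \code{\link{render_image_stack}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 4L)
  d <- dim(stack)
  mx <- max(stack, 1e-12)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (fi in seq_len(d[4])) for (z in seq_len(d[3])) {
    pages[[k]] <- stack[, , z, fi] / mx
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(dims = d, scale = mx,
               times = as.numeric(attr(stack, "times") %||% (seq_len(d[4]) - 1)),
               voxel_size = as.numeric(attr(stack, "voxel_size") %||% 1))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  stack <- array(0, d)
  k <- 1L
  for (fi in seq_len(d[4])) for (z in seq_len(d[3])) {
    stack[, , z, fi] <- pages[[k]] * meta$scale
    k <- k + 1L
  }
  attr(stack, "times") <- meta$times
  attr(stack, "voxel_size") <- meta$voxel_size
  stack
}
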