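# Wavefront radius tracking, anomalous power-law fitting and
# velocity-curvature analysis.
#
# The wavefront radius-time relation is fitted with the anomalous transport
# law
#     R(t)^2 = Rc^2 + b t^gamma ,
# where Rc is the critical biofilm size for wavefront initiation, b a
# prefactor and gamma the anomalous exponent that classifies the transport
# (subdiffusive gamma < 1, diffusive gamma = 1, superdiffusive subballistic
# 1 < gamma < 2, ballistic gamma = 2, super-ballistic gamma > 2).

#' Wavefront track: radius of the bright region versus time
#'
#' @param times times (min), increasing.
#' @param R wavefront radial distance (um), >= 0.
#' @param phase \code{"centrifugal"} (outward) or \code{"centripetal"}
#'   (inward collapse).
#' @param source provenance tag.
#' @param exclude_below radii below this (um) are excluded from power-law
#'   fits (grid discretization artifacts); default 0.
#' @return object of class \code{wavefront_track}.
#' @export
wavefront_track <- function(times, R, phase = c("centrifugal", "centripetal"),
                            source = "", exclude_below = 0) {
  phase <- match.arg(phase)
  times <- as.numeric(times); R <- as.numeric(R)
  stopifnot(length(times) == length(R))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stopf("wavefront_track(): times must be increasing")
  }
  if (any(R < 0)) stopf("wavefront_track(): negative radius")
  structure(list(times = times, R = R, phase = phase, source = source,
                 exclude_below = exclude_below), class = "wavefront_track")
}

#' @export
print.wavefront_track <- function(x, ...) {
  cat(sprintf("%s wavefront track (%s): %d frames, R in [%.3g, %.3g] um\n",
              x$phase, x$source, length(x$times), min(x$R), max(x$R)))
  invisible(x)
}

rolling_mean <- function(x, w) {
  if (w <= 1L || length(x) < w) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) -> s
  s[is.na(s)] <- x[is.na(s)]
  s
}

#' Track the wavefront radius through a simulation or image stack
#'
#' Per frame, the bright-region radius R is the centre of the outermost
#' radial shell whose mean intensity is at least \code{threshold} times the
#' frame maximum (shell width = lattice spacing for simulations, voxel size
#' for image stacks). The track is split at the global maximum of R into a
#' centrifugal (outward) phase and a centripetal (collapse) phase.
#'
#' @param x an \code{fdf_sim}, or a 4D numeric array (x, y, z, t) image
#'   stack.
#' @param threshold half-max fraction (default 0.5).
#' @param smooth_frames temporal smoothing window on the radius series
#'   (frames, default 3).
#' @param voxel_size voxel edge (um), for image stacks.
#' @param times frame times (min), for image stacks.
#' @param ... unused.
#' @return list with elements \code{centrifugal} and \code{centripetal}
#'   (\code{\link{wavefront_track}} objects; centripetal may be absent when
#'   the movie ends at the maximum), plus \code{R}, \code{times}.
#' @export
track_wavefront_radius <- function(x, threshold = 0.5, smooth_frames = 3,
                                   threshold_ref = c("stack", "frame"), ...) {
  UseMethod("track_wavefront_radius")
}

#' @rdname track_wavefront_radius
#' @export
track_wavefront_radius.fdf_sim <- function(x, threshold = 0.5,
                                           smooth_frames = 3,
                                           threshold_ref = c("stack", "frame"),
                                           ...) {
  shell_w <- x$geometry$spacing
  radial_track(radii = x$radii, intensity = x$tht, times = x$times,
               shell_w = shell_w, threshold = threshold,
               smooth_frames = smooth_frames, source = "fdf_sim",
               threshold_ref = match.arg(threshold_ref))
}

#' @rdname track_wavefront_radius
#' @export
track_wavefront_radius.array <- function(x, threshold = 0.5, smooth_frames = 3,
                                         threshold_ref = c("stack", "frame"),
                                         voxel_size = 1, times = NULL, ...) {
  if (length(dim(x)) != 4L) stopf("track_wavefront_radius(): expected a 4D (x,y,z,t) array")
  d <- dim(x)
  times <- times %||% (seq_len(d[4]) - 1)
  ctr <- (d[1:3] + 1) / 2
  ax <- function(n, c) (seq_len(n) - c) * voxel_size
  rr <- sqrt(outer(outer(ax(d[1], ctr[1])^2, ax(d[2], ctr[2])^2, `+`),
                   ax(d[3], ctr[3])^2, `+`))
  nt <- d[4]
  inten <- matrix(x, ncol = nt)  # voxels x frames
  radial_track(radii = as.vector(rr), intensity = t(inten), times = times,
               shell_w = voxel_size, threshold = threshold,
               smooth_frames = smooth_frames, source = "image_stack",
               threshold_ref = match.arg(threshold_ref))
}

# shared radius extraction: intensity is frames x elements
radial_track <- function(radii, intensity, times, shell_w, threshold,
                         smooth_frames, source, threshold_ref = "stack") {
  if (max(intensity) <= 0) stopf("no wavefront detected: stack is dark")
  shell <- floor(radii / shell_w)
  shell_ids <- sort(unique(shell))
  shell_f <- factor(shell, levels = shell_ids)
  counts <- as.integer(table(shell_f))
  stack_mx <- max(intensity)
  R_of_frame <- function(v) {
    mx <- if (threshold_ref == "stack") stack_mx else max(v)
    if (max(v) <= 0) return(NA_real_)
    means <- rowsum(v, shell_f)[, 1] / counts
    ok <- which(means >= threshold * mx)
    if (!length(ok)) return(NA_real_)
    (shell_ids[max(ok)] + 0.5) * shell_w  # shell centre radius
  }
  R <- apply(intensity, 1L, R_of_frame)
  if (all(is.na(R))) stopf("no wavefront detected")
  R <- rolling_mean(ifelse(is.na(R), 0, R), smooth_frames)
  imax <- which.max(R)
  # the biofilm can stay fully illuminated for a stretch at peak extent;
  # those frames belong to neither phase: the outward phase ends when R
  # first attains its maximum, the collapse starts when R departs from it
  ipin <- imax
  while (ipin < length(R) && R[ipin + 1L] >= R[imax] - 1e-9) ipin <- ipin + 1L
  out <- list(
    centrifugal = wavefront_track(times[1:imax], R[1:imax],
                                  phase = "centrifugal", source = source,
                                  exclude_below = shell_w),
    R = R, times = times)
  if (ipin < length(R)) {
    # the collapse ends where R attains its minimum after the maximum;
    # later frames belong to the quiescent / plateau phases
    rest <- R[ipin:length(R)]
    iend <- ipin + which.min(rest) - 1L
    if (iend > ipin) {
      idx <- ipin:iend
      out$centripetal <- wavefront_track(times[idx], R[idx],
                                         phase = "centripetal", source = source,
                                         exclude_below = shell_w)
    }
  }
  out
}

#' Fit the anomalous power law R(t)^2 = Rc^2 + b t^gamma
#'
#' Nonlinear least squares (Levenberg-Marquardt via \pkg{minpack.lm}) on
#' R^2 versus time, with \eqn{Rc^2} constrained non-negative. Times are
#' shifted so the phase starts at t = 0. Multi-start over gamma in
#' \{0.5, 1, 1.5, 2, 2.5\} guards against local minima; the lowest-residual
#' fit wins, ties broken towards the smaller gamma.
#'
#' For a centripetal track the law is fitted in the collapse frame: t is time
#' since collapse onset and R is the distance the front has travelled inward
#' from the periphery (so R grows from 0), which makes the power law
#' well-posed for the inward phase.
#'
#' @param track a \code{\link{wavefront_track}}.
#' @return object of class \code{power_law_fit}: \code{Rc}, \code{b},
#'   \code{gamma}, \code{Rc_sd}, \code{b_sd}, \code{gamma_sd},
#'   \code{residual_norm}, \code{n_points}, \code{phase}.
#' @export
fit_power_law <- function(track) {
  stopifnot(inherits(track, "wavefront_track"))
  t <- track$times - track$times[1L]
  if (track$phase == "centripetal") {
    R <- track$R[1L] - track$R     # inward distance travelled
  } else {
    R <- track$R
  }
  keep <- rep(TRUE, length(R))
  if (track$exclude_below > 0) {
    keep <- if (track$phase == "centripetal") {
      # drop the tail where the remaining bright core is below one shell
      track$R >= track$exclude_below
    } else {
      R >= track$exclude_below
    }
  }
  t <- t[keep]; R <- R[keep]
  if (length(t) < 4L) stopf("fit_power_law(): need at least 4 points, have %d", length(t))
  t <- t - t[1L]
  y <- R^2
  df <- data.frame(t = t, y = y)
  # the collapse distance grows from zero by construction, so the inward
  # phase is fitted without an intercept (the critical size Rc belongs to
  # the outward, initiation phase)
  free_Rc <- track$phase != "centripetal"
  fits <- lapply(c(0.5, 1, 1.5, 2, 2.5), function(g0) {
    b0 <- max((max(y) - min(y)) / max(max(t)^g0, 1e-12), 1e-8)
    tryCatch(
      if (free_Rc) {
        minpack.lm::nlsLM(y ~ Rc2 + b * t^gamma, data = df,
                          start = list(Rc2 = max(min(y), 0), b = b0, gamma = g0),
                          lower = c(Rc2 = 0, b = 1e-12, gamma = 1e-3),
                          upper = c(Rc2 = Inf, b = Inf, gamma = 10),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ b * t^gamma, data = df,
                          start = list(b = b0, gamma = g0),
                          lower = c(b = 1e-12, gamma = 1e-3),
                          upper = c(b = Inf, gamma = 10),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      },
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stopf("fit_power_law(): did not converge from any start")
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  gam <- vapply(fits, function(f) coef(f)[["gamma"]], numeric(1))
  best <- order(round(rss, 12), gam)[1L]
  fit <- fits[[best]]
  cf <- coef(fit)
  if (!free_Rc) cf <- c(Rc2 = 0, cf)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(coef(fit))), names(coef(fit))))
  if (!free_Rc) se <- c(Rc2 = 0, se)
  names(se) <- names(cf)
  Rc <- sqrt(max(cf[["Rc2"]], 0))
  # delta method: sd(Rc) = sd(Rc2) / (2 Rc)
  Rc_sd <- if (is.finite(se[["Rc2"]]) && Rc > 1e-8) se[["Rc2"]] / (2 * Rc) else NA_real_
  structure(list(Rc = Rc, b = cf[["b"]], gamma = cf[["gamma"]],
                 Rc_sd = Rc_sd, b_sd = se[["b"]], gamma_sd = se[["gamma"]],
                 residual_norm = sqrt(rss[best]), n_points = length(t),
                 phase = track$phase), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): Rc = %.4g um, b = %.4g, gamma = %.4g +/- %.2g (n = %d)\n",
              x$phase, x$Rc, x$b, x$gamma,
              if (is.finite(x$gamma_sd)) x$gamma_sd else NA, x$n_points))
  cat(sprintf("  transport class: %s\n", classify_transport(x$gamma)))
  invisible(x)
}

#' Classify wavefront transport from the anomalous exponent
#'
#' Partition of gamma in (0, Inf): subdiffusive (gamma < 1), diffusive
#' (gamma = 1), superdiffusive subballistic (1 < gamma < 2), ballistic
#' (gamma = 2), super-ballistic (gamma > 2).
#'
#' @param gamma anomalous exponent, > 0.
#' @return character class name.
#' @export
classify_transport <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stopf("classify_transport(): gamma must be a single positive number")
  }
  if (gamma < 1) "subdiffusive"
  else if (gamma == 1) "diffusive"
  else if (gamma < 2) "superdiffusive subballistic"
  else if (gamma == 2) "ballistic"
  else "super-ballistic"
}

#' Wavefront velocity and curvature profile
#'
#' Velocity via central differences on the (rolling-mean smoothed) radius
#' series; front curvature kappa = 2/R (mean curvature of a sphere; use
#' \code{convention = "1/R"} for comparison with 2D work). Frames with R = 0
#' are excluded with a warning, since curvature diverges there.
#'
#' @param track a \code{\link{wavefront_track}}.
#' @param smoothing_window rolling-mean window (points, default 3).
#' @param convention \code{"2/R"} (default) or \code{"1/R"}.
#' @return object of class \code{velocity_profile}: \code{times}, \code{v}
#'   (um/min, signed dR/dt), \code{kappa} (1/um), \code{R}, \code{phase}.
#' @export
velocity_curvature <- function(track, smoothing_window = 3,
                               convention = c("2/R", "1/R")) {
  stopifnot(inherits(track, "wavefront_track"))
  convention <- match.arg(convention)
  if (length(track$times) < smoothing_window + 2) {
    stopf("velocity_curvature(): need at least smoothing_window + 2 = %d points",
          smoothing_window + 2)
  }
  keep <- track$R > 0
  if (!all(keep)) warnf("velocity_curvature(): excluding %d frame(s) with R = 0",
                        sum(!keep))
  t <- track$times[keep]; R <- rolling_mean(track$R[keep], smoothing_window)
  n <- length(R)
  if (n < 3L) stopf("velocity_curvature(): too few usable frames")
  v <- numeric(n)
  v[2:(n - 1)] <- (R[3:n] - R[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (R[2] - R[1]) / (t[2] - t[1])
  v[n] <- (R[n] - R[n - 1]) / (t[n] - t[n - 1])
  fac <- if (convention == "2/R") 2 else 1
  structure(list(times = t, v = v, kappa = fac / R, R = R,
                 phase = track$phase, convention = convention),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("Velocity profile (%s, kappa = %s): %d frames, v in [%.3g, %.3g] um/min\n",
              x$phase, x$convention, length(x$v), min(x$v), max(x$v)))
  invisible(x)
}
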