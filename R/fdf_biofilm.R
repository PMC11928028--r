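# 3D agent-based fire-diffuse-fire (FDF) simulator.
#
# Cells sit on a jittered cubic lattice clipped to a sphere. A firing cell
# releases potassium into its voxel of a 3D extracellular concentration grid;
# the ion diffuses and decays in the surrounding fluid; a quiescent cell fires
# when the local concentration reaches the threshold (inclusive), then passes
# through a refractory period. The domain boundary is absorbing (flow-fed
# fluid), which together with bulk clearance sets a critical biofilm radius
# below which the wavefront dies before reaching the periphery. A per-cell
# ThT-like fluorescence proxy combines a firing flash with a component
# sustained by the local potassium level; the latter is what makes brightness
# collapse from the periphery (where the ion drains fastest) back to the core
# after the outward wave has passed. A global stress clock converts cells
# leaving the refractory state into a habituated, persistently bright state,
# producing the second plateau.

#' Parameters for the fire-diffuse-fire biofilm simulator
#'
#' Canonical defaults are pinned so that default-parameter runs of
#' \code{\link{run_simulation}} on a 15 um biofilm reproduce the anomalous
#' wavefront exponents (superdiffusive-subballistic centrifugal phase,
#' super-ballistic centripetal collapse) and a critical radius of ~6 um
#' (see \code{\link{find_critical_radius}}).
#'
#' @param ... named overrides of the defaults.
#' @section Fields:
#' \describe{
#'   \item{D}{extracellular K+ diffusion coefficient (um^2/min). This is an
#'     effective coefficient inside the biofilm matrix, far below the
#'     free-water value.}
#'   \item{k_decay}{clearance rate of K+ in the open, flow-fed fluid
#'     outside the biofilm (1/min). Fast: ions escaping the matrix are washed
#'     away within ~sqrt(D/k_decay) um of the surface.}
#'   \item{k_matrix}{clearance rate inside the biofilm matrix (1/min). Slow:
#'     the extracellular polymeric matrix retains potassium, so the interior
#'     reservoir persists for ~1/k_matrix minutes. The contrast between
#'     k_decay and k_matrix is what makes small biofilms (high
#'     surface-to-volume ratio) unable to sustain the wave, slows the front
#'     as it nears the periphery, and drives the edge-to-core collapse.}
#'   \item{k_uptake}{potassium re-uptake rate by repolarizing (refractory)
#'     cells (1/min at one cell per voxel); this consumes the extracellular
#'     reservoir behind the wavefront, decelerating the front and driving the
#'     edge-to-core brightness collapse.}
#'   \item{c_thresh}{firing threshold concentration (inclusive).}
#'   \item{sigma_release}{K+ released per firing event (conc. um^3).}
#'   \item{t_fire}{release duration (min).}
#'   \item{t_refract}{refractory period (min).}
#'   \item{tht_decay}{decay constant of the firing flash (1/min).}
#'   \item{c_bright}{local concentration at which the sustained brightness
#'     component saturates (conc. units).}
#'   \item{repol_rate}{rate at which a fired cell's sustained brightness
#'     fades as its membrane repolarizes (1/min); cells that fired earliest
#'     (the core) dim first, grading the collapse profile.}
#'   \item{core_source}{sustained K+ efflux rate (conc. um^3/min) of the
#'     stimulus-driven trigger cells during the first-peak episode; keeps the
#'     core concentration profile peaked so the collapse sweeps smoothly
#'     towards the centre.}
#'   \item{core_delay}{time after stimulus onset at which the core's
#'     sustained efflux begins (min); the sustained phase follows the
#'     core's initial spike, so it does not assist wave initiation.}
#'   \item{habituation_delay}{global stress-clock time after which cells
#'     leaving the refractory state become habituated (min).}
#'   \item{tht_plateau}{brightness of habituated cells.}
#'   \item{grid_dx}{diffusion grid spacing (um); must not exceed the cell
#'     spacing.}
#'   \item{dt}{time step (min); the explicit scheme needs
#'     \code{D * dt / grid_dx^2 <= 1/6}.}
#'   \item{frame_dt}{frame recording cadence (min).}
#'   \item{domain_factor}{domain half-width as a multiple of the biofilm
#'     radius (>= 3; absorbing boundary sits this far out).}
#'   \item{max_agents}{guard against accidentally huge geometries.}
#'   \item{seed}{default RNG seed.}
#' }
#' @return object of class \code{fdf_params}.
#' @export
fdf_params <- function(...) {
  p <- list(
    D = 5, k_decay = 6, k_matrix = 0.55, k_uptake = 0, c_thresh = 1,
    sigma_release = 27,
    t_fire = 0.1, t_refract = 18, tht_decay = 1.5, c_bright = 3,
    repol_rate = 0, core_source = 40, core_delay = 1.5,
    habituation_delay = 10, tht_plateau = 0.9,
    grid_dx = 1.5, dt = 0.04, frame_dt = 0.2,
    domain_factor = 3, max_agents = 20000, seed = 1L)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stopf("fdf_params(): unknown field(s): %s",
                           paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  for (f in c("D", "c_thresh", "sigma_release", "t_fire", "t_refract",
              "grid_dx", "dt", "frame_dt", "c_bright")) check_positive(p[[f]], f)
  for (f in c("k_decay", "k_matrix", "k_uptake", "tht_decay",
              "repol_rate", "core_source", "core_delay",
              "habituation_delay")) check_nonneg(p[[f]], f)
  if (p$domain_factor < 3) stopf("fdf_params(): domain_factor must be >= 3")
  check_stability(p$D, p$grid_dx, p$dt)
  structure(p, class = "fdf_params")
}

check_stability <- function(D, dx, dt) {
  cfl <- D * dt / dx^2
  if (cfl > 1 / 6 + 1e-12) {
    stopf("diffusion stability violated: D*dt/dx^2 = %.4g > 1/6; reduce dt below %.4g",
          cfl, dx^2 / (6 * D))
  }
  invisible(cfl)
}

#' @export
print.fdf_params <- function(x, ...) {
  cat(sprintf("FDF parameters: D=%g um^2/min, k_fluid=%g, k_matrix=%g, c_thresh=%g, sigma=%g\n",
              x$D, x$k_decay, x$k_matrix, x$c_thresh, x$sigma_release))
  cat(sprintf("  t_fire=%g t_refract=%g habituation_delay=%g min; dx=%g um dt=%g min\n",
              x$t_fire, x$t_refract, x$habituation_delay, x$grid_dx, x$dt))
  invisible(x)
}

#' Build a spherical biofilm of cell agents
#'
#' Cells are placed on a cubic lattice of the given spacing, jittered
#' uniformly by up to \code{jitter * spacing} per axis (breaking lattice
#' anisotropy), and clipped to the sphere. Deterministic per seed.
#'
#' @param radius biofilm radius (um), >= 0.
#' @param spacing nearest-neighbour lattice spacing (um), default 1.5 (one
#'   cell diameter).
#' @param jitter jitter amplitude as a fraction of spacing, in [0, 0.5).
#' @param seed RNG seed.
#' @param max_agents error if the geometry would exceed this count.
#' @return object of class \code{biofilm_geometry}: \code{positions}
#'   (n x 3 matrix, um), \code{radius}, \code{spacing}, \code{jitter},
#'   \code{bounding_box}.
#' @export
build_spherical_biofilm <- function(radius, spacing = 1.5, jitter = 0.2,
                                    seed = 1L, max_agents = 20000) {
  check_nonneg(radius, "radius")
  check_positive(spacing, "spacing")
  if (jitter < 0 || jitter >= 0.5) stopf("jitter must be in [0, 0.5)")
  m <- floor(radius / spacing)
  g <- expand.grid(x = -m:m, y = -m:m, z = -m:m)
  pos <- as.matrix(g) * spacing
  keep <- rowSums(pos^2) <= radius^2 + 1e-9
  pos <- pos[keep, , drop = FALSE]
  lattice_r <- sqrt(rowSums(pos^2))
  if (nrow(pos) > max_agents) {
    stopf("build_spherical_biofilm(): %d agents exceed max_agents = %d",
          nrow(pos), max_agents)
  }
  if (jitter > 0 && nrow(pos)) {
    set.seed(derive_seed(seed, "geometry"))
    pos <- pos + matrix(stats::runif(3 * nrow(pos), -jitter, jitter) * spacing,
                        ncol = 3)
    # clip jittered cells back onto the sphere surface
    r <- sqrt(rowSums(pos^2))
    out <- r > radius & r > 0
    if (any(out)) pos[out, ] <- pos[out, , drop = FALSE] * (radius / r[out])
  }
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = pos, lattice_r = lattice_r, radius = radius,
                 spacing = spacing, jitter = jitter, seed = seed,
                 bounding_box = c(-1, 1) * max(radius, spacing)),
            class = "biofilm_geometry")
}

#' @export
print.biofilm_geometry <- function(x, ...) {
  cat(sprintf("Spherical biofilm: %d cells, radius %g um, spacing %g um, jitter %g\n",
              nrow(x$positions), x$radius, x$spacing, x$jitter))
  invisible(x)
}

#' Create an empty potassium concentration field
#'
#' A cubic grid centred on the origin with the absorbing (or reflective)
#' boundary at half-width \code{half_width}.
#'
#' @param half_width domain half-width (um).
#' @param dx voxel size (um).
#' @param boundary \code{"absorbing"} (default; open, flow-fed fluid) or
#'   \code{"reflective"} (closed test box used by conservation checks).
#' @return object of class \code{potassium_field}: \code{grid} (3D array),
#'   \code{dx}, \code{origin} (coordinate of the first voxel centre),
#'   \code{boundary}.
#' @export
potassium_field <- function(half_width, dx, boundary = c("absorbing", "reflective")) {
  boundary <- match.arg(boundary)
  check_positive(half_width, "half_width"); check_positive(dx, "dx")
  m <- max(1L, ceiling(half_width / dx))
  n <- 2L * m + 1L
  structure(list(grid = array(0, dim = c(n, n, n)), dx = dx,
                 origin = rep(-m * dx, 3), boundary = boundary),
            class = "potassium_field")
}

# shift a 3D array by one voxel along an axis; out-of-domain neighbours are 0
# (absorbing) or mirror the edge value (reflective / zero flux)
shift3 <- function(a, axis, by, boundary) {
  n <- dim(a)[axis]
  idx <- seq_len(n) + by
  if (boundary == "reflective") {
    idx[idx < 1L] <- 1L; idx[idx > n] <- n
    pad <- NULL
  } else {
    pad <- which(idx < 1L | idx > n)
    idx[pad] <- 1L  # placeholder, zeroed after
  }
  out <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
  if (length(pad)) {
    switch(axis, out[pad, , ] <- 0, out[, pad, ] <- 0, out[, , pad] <- 0)
  }
  out
}

#' One explicit finite-difference diffusion-decay step
#'
#' Updates the field by \eqn{\partial c/\partial t = D \nabla^2 c - k c}
#' with a 7-point Laplacian. Checks the stability condition
#' \eqn{D dt / dx^2 \le 1/6} before stepping; non-negativity is preserved.
#'
#' @param field a \code{\link{potassium_field}}.
#' @param D diffusion coefficient (um^2/min).
#' @param k_decay clearance rate (1/min); either a scalar or an array of the
#'   field's dimensions (spatially varying clearance, e.g. matrix vs fluid).
#' @param dt time step (min).
#' @return the updated field.
#' @export
diffuse_step <- function(field, D, k_decay, dt) {
  stopifnot(inherits(field, "potassium_field"))
  check_stability(D, field$dx, dt)
  c0 <- field$grid
  lap <- shift3(c0, 1L, 1L, field$boundary) + shift3(c0, 1L, -1L, field$boundary) +
         shift3(c0, 2L, 1L, field$boundary) + shift3(c0, 2L, -1L, field$boundary) +
         shift3(c0, 3L, 1L, field$boundary) + shift3(c0, 3L, -1L, field$boundary) -
         6 * c0
  g <- c0 + dt * (D * lap / field$dx^2 - k_decay * c0)
  field$grid <- pmax(g, 0)
  field
}

# trilinear interpolation stencil for a set of positions: 8 linear indices
# and weights per cell
trilinear_stencil <- function(positions, field) {
  dims <- dim(field$grid)
  u <- sweep(positions, 2, field$origin) / field$dx + 1  # fractional voxel coords
  i0 <- pmin(pmax(floor(u), 1), matrix(rep(dims - 1L, each = nrow(u)), ncol = 3))
  f <- u - i0
  f <- pmin(pmax(f, 0), 1)
  idx <- matrix(0L, nrow(u), 8L); w <- matrix(0, nrow(u), 8L)
  k <- 1L
  for (dz in 0:1) for (dy in 0:1) for (dx_ in 0:1) {
    ii <- i0[, 1] + dx_; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    idx[, k] <- ii + (jj - 1L) * dims[1] + (kk - 1L) * dims[1] * dims[2]
    w[, k] <- (if (dx_) f[, 1] else 1 - f[, 1]) *
              (if (dy)  f[, 2] else 1 - f[, 2]) *
              (if (dz)  f[, 3] else 1 - f[, 3])
    k <- k + 1L
  }
  list(idx = idx, w = w)
}

sample_field <- function(field, stencil, cells = NULL) {
  idx <- stencil$idx; w <- stencil$w
  if (!is.null(cells)) { idx <- idx[cells, , drop = FALSE]; w <- w[cells, , drop = FALSE] }
  rowSums(matrix(field$grid[idx], nrow = nrow(idx)) * w)
}

deposit_field <- function(field, stencil, cells, amounts) {
  if (!length(cells)) return(field)
  idx <- as.vector(stencil$idx[cells, , drop = FALSE])
  val <- as.vector(stencil$w[cells, , drop = FALSE] * amounts)  # recycled by column
  agg <- rowsum(val, idx)
  at <- as.integer(rownames(agg))
  field$grid[at] <- field$grid[at] + agg[, 1] / field$dx^3  # amount -> concentration
  field
}

#' Fire-diffuse-fire state update for one time step
#'
#' Pure state machine applied between diffusion steps: a quiescent cell whose
#' local (trilinearly sampled) concentration reaches \code{c_thresh}
#' (inclusive) starts firing and will deposit its release over \code{t_fire};
#' a firing cell past \code{t_fire} becomes refractory; a refractory cell past
#' \code{t_refract} returns to quiescence, or becomes habituated (persistently
#' bright) once the global stress clock exceeds \code{habituation_delay}.
#'
#' @param agents internal agent state list (see \code{\link{run_simulation}}).
#' @param field a \code{\link{potassium_field}}.
#' @param params \code{\link{fdf_params}}.
#' @param t current time (min).
#' @param stencil trilinear stencil for the agent positions.
#' @return list with updated \code{agents} and \code{field} (release deposited).
#' @keywords internal
#' @export
fire_update <- function(agents, field, params, t, stencil) {
  st <- agents$state
  q <- which(st == 0L)
  if (length(q)) {
    c_loc <- sample_field(field, stencil, q)
    ignite <- q[c_loc >= params$c_thresh]
    if (length(ignite)) {
      agents$state[ignite] <- 1L
      agents$t_state[ignite] <- t
      agents$fired[ignite] <- agents$fired[ignite] + 1L
      agents$t_fired[ignite] <- t
      agents$tht_spike[ignite] <- 1
    }
  }
  firing <- which(agents$state == 1L)
  if (length(firing)) {
    # release at constant rate over t_fire, clipped at the interval end
    dt_active <- pmin(params$dt, agents$t_state[firing] + params$t_fire - t)
    dt_active <- pmax(dt_active, 0)
    rel <- params$sigma_release / params$t_fire * dt_active
    field <- deposit_field(field, stencil, firing, rel)
    agents$released <- agents$released + sum(rel)
    done <- firing[t + params$dt - agents$t_state[firing] >= params$t_fire - 1e-12]
    if (length(done)) {
      agents$state[done] <- 2L
      agents$t_state[done] <- t + params$dt
    }
  }
  if (params$core_source > 0 && t >= params$core_delay && t < params$t_refract) {
    rel <- rep(params$core_source * params$dt, length(agents$trigger))
    field <- deposit_field(field, stencil, agents$trigger, rel)
    agents$released <- agents$released + sum(rel)
  }
  refr <- which(agents$state == 2L)
  if (length(refr)) {
    out <- refr[t - agents$t_state[refr] >= params$t_refract]
    if (length(out)) {
      if (t > params$habituation_delay) {
        agents$state[out] <- 3L
      } else {
        agents$state[out] <- 0L
      }
      agents$t_state[out] <- t
    }
  }
  agents$tht_spike <- agents$tht_spike * exp(-params$tht_decay * params$dt)
  list(agents = agents, field = field)
}

#' Run a fire-diffuse-fire biofilm simulation
#'
#' Cells within \code{trigger_radius} spacings of the origin fire at t = 0
#' (the core-triggered ignition). Membership is decided on the pre-jitter
#' lattice positions, so the default of one lattice spacing always selects
#' the origin cell plus its six nearest lattice neighbours, independent of
#' the jitter draw. Frames are recorded at
#' \code{params$frame_dt} cadence with each cell's state and fluorescence
#' proxy. Fully reproducible given the geometry and parameters (the dynamics
#' itself is deterministic; randomness enters only through the jittered
#' geometry seed).
#'
#' @param params \code{\link{fdf_params}}.
#' @param geometry \code{\link{build_spherical_biofilm}} output.
#' @param duration simulated time (min).
#' @param trigger_radius trigger region radius in units of the lattice
#'   spacing (default 1), applied to pre-jitter lattice positions.
#' @param boundary field boundary condition, default absorbing.
#' @return object of class \code{fdf_sim}: \code{times}, \code{tht}
#'   (frames x cells), \code{state} (frames x cells, integer codes
#'   0 quiescent / 1 firing / 2 refractory / 3 habituated), \code{global_tht},
#'   \code{geometry}, \code{params}, \code{released} (total K+ released),
#'   \code{field_mass} (total field content per frame, amount units),
#'   \code{fired} (per-cell cumulative fire counts at the end).
#' @export
run_simulation <- function(params, geometry, duration = 10,
                           trigger_radius = 1,
                           boundary = c("absorbing", "reflective")) {
  stopifnot(inherits(params, "fdf_params"), inherits(geometry, "biofilm_geometry"))
  boundary <- match.arg(boundary)
  check_positive(duration, "duration")
  if (params$grid_dx > geometry$spacing + 1e-9) {
    stopf("run_simulation(): grid_dx (%g) must not exceed the cell spacing (%g)",
          params$grid_dx, geometry$spacing)
  }
  pos <- geometry$positions
  n_cells <- nrow(pos)
  if (n_cells == 0L) stopf("run_simulation(): geometry has no cells")
  if (n_cells > params$max_agents) {
    stopf("run_simulation(): %d agents exceed max_agents = %d", n_cells, params$max_agents)
  }
  half_width <- max(params$domain_factor * geometry$radius, 4 * params$grid_dx)
  field <- potassium_field(half_width, params$grid_dx, boundary)
  stencil <- trilinear_stencil(pos, field)
  # two-zone clearance: voxels occupied by the biofilm matrix retain K+
  # (k_matrix), open fluid clears it fast (k_decay)
  occ <- array(0, dim(field$grid))
  agg0 <- rowsum(as.vector(stencil$w), as.vector(stencil$idx))
  occ[as.integer(rownames(agg0))] <- pmin(agg0[, 1], 1)
  decay_field <- params$k_decay + (params$k_matrix - params$k_decay) * occ
  r <- sqrt(rowSums(pos^2))
  agents <- list(state = integer(n_cells), t_state = rep(-Inf, n_cells),
                 fired = integer(n_cells), t_fired = rep(NA_real_, n_cells),
                 tht_spike = numeric(n_cells), released = 0)
  r_trig <- geometry$lattice_r %||% r
  trig <- which(r_trig <= trigger_radius * geometry$spacing + 1e-9)
  if (!length(trig)) stopf("run_simulation(): empty trigger region")
  agents$trigger <- trig
  agents$state[trig] <- 1L; agents$t_state[trig] <- 0
  agents$fired[trig] <- 1L; agents$t_fired[trig] <- 0
  agents$tht_spike[trig] <- 1

  nstep <- ceiling(duration / params$dt - 1e-9)
  every <- max(1L, round(params$frame_dt / params$dt))
  frame_steps <- seq(0L, nstep, by = every)
  nf <- length(frame_steps)
  tht_mat <- matrix(0, nf, n_cells)
  state_mat <- matrix(0L, nf, n_cells)
  mass <- numeric(nf)
  times <- frame_steps * params$dt

  record <- function(row, agents, field, t_now) {
    c_loc <- sample_field(field, stencil)
    tht <- agents$tht_spike
    fired_mask <- agents$fired > 0L & agents$state != 3L
    # sustained hyperpolarization: local K+ keeps the cell bright, fading as
    # the membrane repolarizes after its firing time
    repol <- exp(-params$repol_rate * pmax(t_now - agents$t_fired, 0))
    repol[is.na(repol)] <- 0
    sustained <- pmin(c_loc / params$c_bright, 1) * repol
    tht[fired_mask] <- pmax(tht[fired_mask], sustained[fired_mask])
    tht[agents$state == 3L] <- params$tht_plateau
    tht_mat[row, ] <<- tht
    state_mat[row, ] <<- agents$state
    mass[row] <<- sum(field$grid) * field$dx^3
  }
  row <- 1L
  record(row, agents, field, 0)
  for (i in seq_len(nstep)) {
    t <- (i - 1L) * params$dt
    upd <- fire_update(agents, field, params, t, stencil)
    agents <- upd$agents
    field <- diffuse_step(upd$field, params$D, decay_field, params$dt)
    if (params$k_uptake > 0) {
      refr <- which(agents$state == 2L)
      if (length(refr)) {
        idx <- as.vector(stencil$idx[refr, , drop = FALSE])
        agg <- rowsum(as.vector(stencil$w[refr, , drop = FALSE]), idx)
        at <- as.integer(rownames(agg))
        field$grid[at] <- field$grid[at] *
          pmax(1 - params$dt * params$k_uptake * agg[, 1], 0)
      }
    }
    if (i %in% frame_steps) { row <- row + 1L; record(row, agents, field, i * params$dt) }
  }
  structure(list(times = times, tht = tht_mat, state = state_mat,
                 global_tht = rowMeans(tht_mat), radii = r,
                 geometry = geometry, params = params,
                 released = agents$released, field_mass = mass,
                 fired = agents$fired, trigger = trig,
                 trigger_span = trigger_radius * geometry$spacing,
                 boundary = boundary),
            class = "fdf_sim")
}

#' @export
print.fdf_sim <- function(x, ...) {
  cat(sprintf("FDF simulation: %d cells, %d frames over %.3g min; %.0f%% of cells fired\n",
              ncol(x$tht), length(x$times), max(x$times),
              100 * mean(x$fired > 0)))
  invisible(x)
}

#' Globally averaged fluorescence trace of an FDF simulation
#'
#' Mean per-cell fluorescence proxy per frame, the simulated analogue of the
#' biofilm-wide ThT intensity profile.
#'
#' @param sim an \code{fdf_sim} (or a frames matrix with a \code{times}
#'   attribute).
#' @return a \code{\link{tht_trace}} (raw, not normalized).
#' @export
global_tht_trace <- function(sim) {
  stopifnot(inherits(sim, "fdf_sim"))
  if (length(sim$times) == 0L) stopf("global_tht_trace(): no frames")
  tht_trace(sim$times, sim$global_tht, label = "fdf_global")
}

#' Did the wavefront reach the biofilm periphery?
#'
#' Success means at least \code{frac} of the outer-shell cells (radial
#' distance within one spacing of the biofilm radius) fired. The tally
#' measures the relayed wavefront, so cells inside the direct-ignition zone
#' -- the trigger region plus one lattice spacing, which the stimulus pulse
#' lights up without any relay -- are excluded; a biofilm so small that its
#' whole periphery sits in that zone has not propagated anything and counts
#' as failure.
#'
#' @param sim an \code{fdf_sim}.
#' @param frac required outer-shell firing fraction (default 0.9).
#' @return logical.
#' @export
propagation_success <- function(sim, frac = 0.9) {
  outer <- sim$radii >= sim$geometry$radius - sim$geometry$spacing
  if (!any(outer)) outer <- sim$radii >= max(sim$radii) - 1e-9
  if (!is.null(sim$trigger)) outer[sim$trigger] <- FALSE
  span <- sim$trigger_span %||% sim$geometry$spacing
  outer[sim$radii <= span + sim$geometry$spacing] <- FALSE
  if (!any(outer)) return(FALSE)
  mean(sim$fired[outer] > 0) >= frac
}

#' Critical biofilm radius for wavefront propagation
#'
#' Bisection on the propagation-success indicator: for each seed the geometry
#' is rebuilt at the candidate radius, the simulation is run, and success is
#' judged by \code{\link{propagation_success}}. The bracket must fail at
#' \code{radius_lo} and succeed at \code{radius_hi} for every seed. The
#' per-seed bisection estimates are summarized as mean +/- SD.
#'
#' @param params \code{\link{fdf_params}}.
#' @param radius_lo,radius_hi bracketing radii (um).
#' @param trigger_radius passed to \code{\link{run_simulation}}.
#' @param n_seeds number of independent seeds (jittered geometries).
#' @param tol bisection tolerance (um, default 0.25).
#' @param duration simulated minutes per trial run (default 8; long enough
#'   for the first-peak wave to cross or die at these radii).
#' @param frac outer-shell firing fraction defining success.
#' @param seed master seed.
#' @return object of class \code{critical_radius}: \code{mean}, \code{sd},
#'   \code{estimates} (per seed), \code{n_seeds}.
#' @export
find_critical_radius <- function(params, radius_lo = 1.2, radius_hi = 12,
                                 n_seeds = 10, tol = 0.25, duration = 8,
                                 frac = 0.9, seed = 1L, trigger_radius = 1) {
  stopifnot(inherits(params, "fdf_params"))
  if (radius_lo >= radius_hi) stopf("find_critical_radius(): radius_lo must be < radius_hi")
  trial <- function(radius, s) {
    geom <- build_spherical_biofilm(radius, seed = derive_seed(seed, s))
    sim <- run_simulation(params, geom, duration = duration,
                          trigger_radius = trigger_radius)
    propagation_success(sim, frac = frac)
  }
  est <- vapply(seq_len(n_seeds), function(s) {
    if (trial(radius_lo, s)) {
      stopf("find_critical_radius(): propagation already succeeds at radius_lo = %g (seed %d); widen the bracket downward",
            radius_lo, s)
    }
    if (!trial(radius_hi, s)) {
      stopf("find_critical_radius(): propagation still fails at radius_hi = %g (seed %d); widen the bracket upward",
            radius_hi, s)
    }
    lo <- radius_lo; hi <- radius_hi
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (trial(mid, s)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  structure(list(mean = mean(est), sd = stats::sd(est), estimates = est,
                 n_seeds = as.integer(n_seeds)), class = "critical_radius")
}

#' @export
print.critical_radius <- function(x, ...) {
  cat(sprintf("Critical radius: %.3g +/- %.3g um (mean +/- SD over %d seeds)\n",
              x$mean, x$sd, x$n_seeds))
  invisible(x)
}
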