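#' @title Pennes bioheat finite-difference solver
#' @description Explicit forward-Euler integration of
#'   `rho c dT/dt = div(k grad T) + rho_b c_b w (T_a - T) + Q_met + Q_laser`
#'   on the voxel grid of a [material_field()], with a 7-point conduction
#'   stencil, harmonic-mean interface conductivities, radiative top-surface
#'   loss `eps sigma_SB (T^4 - T_amb^4)` and either insulated or
#'   frozen-far-field ("open") lateral/bottom boundaries.
#' @name bioheat-solver
NULL

# harmonic-mean face conductivities along one dimension
face_k <- function(k, dim) {
  d <- dim(k)
  idx1 <- switch(dim,
                 k[-d[1], , , drop = FALSE],
                 k[, -d[2], , drop = FALSE],
                 k[, , -d[3], drop = FALSE])
  idx2 <- switch(dim,
                 k[-1, , , drop = FALSE],
                 k[, -1, , drop = FALSE],
                 k[, , -1, drop = FALSE])
  s <- idx1 + idx2
  out <- array(0, dim = dim(idx1))
  pos <- s > 0
  out[pos] <- 2 * idx1[pos] * idx2[pos] / s[pos]
  out
}

solver_coeffs <- function(mf) {
  list(kx = face_k(mf$k, 1L), ky = face_k(mf$k, 2L), kz = face_k(mf$k, 3L),
       rhoc = mf$rho * mf$cp, perf_a = mf$rho_b_c_b * mf$w_perf)
}

#' Explicit-scheme stability bound on the solver time step
#'
#' Largest `dt` for which every voxel keeps a non-negative self-coefficient
#' in the update, `dt <= rho c / (sum_faces k_face / delta^2 + a)`; for a
#' homogeneous medium this reduces to the familiar `rho c delta^2 / (6 k)`
#' bound.  Time steps above the bound are rejected by [step_heat()].
#'
#' @param mf a [material_field()].
#' @return maximum stable time step (s).
#' @export
stability_dt <- function(mf) {
  cf <- solver_coeffs(mf)
  d <- mf$dims; s2 <- mf$spacing^2
  csum <- array(0, dim = d)
  add <- function(csum, f, dim, side, s2d) {
    # spread each face's conductivity to the two voxels it couples
    pad <- array(0, dim = d)
    if (dim == 1L) {
      if (side == 1L) pad[-d[1], , ] <- f else pad[-1, , ] <- f
    } else if (dim == 2L) {
      if (side == 1L) pad[, -d[2], ] <- f else pad[, -1, ] <- f
    } else {
      if (side == 1L) pad[, , -d[3]] <- f else pad[, , -1] <- f
    }
    csum + pad / s2d
  }
  csum <- add(csum, cf$kx, 1L, 1L, s2[1]); csum <- add(csum, cf$kx, 1L, 2L, s2[1])
  csum <- add(csum, cf$ky, 2L, 1L, s2[2]); csum <- add(csum, cf$ky, 2L, 2L, s2[2])
  csum <- add(csum, cf$kz, 3L, 1L, s2[3]); csum <- add(csum, cf$kz, 3L, 2L, s2[3])
  csum <- csum + cf$perf_a
  min(cf$rhoc / pmax(csum, .Machine$double.xmin))
}

#' Advance the temperature field
#'
#' Steps the bioheat equation forward by `nsteps` explicit steps of size
#' `dt`.  See [bioheat-solver] for the discretization.
#'
#' @param T_field numeric array of `mf$dims`, temperatures (K).
#' @param mf a [material_field()].
#' @param Q_laser volumetric heat source array (W/m^3) or `NULL` for none.
#' @param dt time step (s); must not exceed [stability_dt()].
#' @param nsteps number of steps.
#' @param boundary `"open"` (lateral/bottom clamped one voxel outside the
#'   domain to the entry field, emulating equilibrated far-field tissue) or
#'   `"insulated"`.
#' @param radiative apply the radiative top-surface loss (set `FALSE` for
#'   idealized closed-box tests).
#' @param h_conv optional convective surface coefficient (W/(m^2 K)).
#' @param record_steps integer step indices at which to snapshot the top
#'   surface.
#' @param ghost reference field for the open boundary; defaults to the
#'   entry `T_field`.
#' @return list with `T` (final field), `surface` (array
#'   `nx x ny x length(record_steps)`), and `max_dT` of the final step.
#' @export
step_heat <- function(T_field, mf, Q_laser = NULL, dt, nsteps = 1L,
                      boundary = c("open", "insulated"), radiative = TRUE,
                      h_conv = 0, record_steps = integer(0), ghost = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(identical(dim(T_field), mf$dims))
  if (!all(is.finite(T_field))) stop("temperature field contains non-finite values")
  dt_max <- stability_dt(mf)
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf(paste0("dt = %g s violates the explicit stability bound ",
                        "min(rho c delta^2 / (6 k)) = %g s"), dt, dt_max))
  cf <- solver_coeffs(mf)
  src <- mf$q_met
  if (!is.null(Q_laser)) src <- src + Q_laser
  if (is.null(ghost)) ghost <- T_field
  rec <- as.integer(sort(record_steps))
  out <- cpp_run_solver(
    as.numeric(T_field), mf$dims, mf$spacing,
    as.numeric(cf$kx), as.numeric(cf$ky), as.numeric(cf$kz),
    as.numeric(mf$k), as.numeric(cf$rhoc), as.numeric(cf$perf_a),
    as.numeric(src), mf$T_a,
    if (radiative) mf$emissivity else 0, mf$T_amb, h_conv,
    if (boundary == "open") 1L else 0L, as.numeric(ghost),
    dt, as.integer(nsteps), rec)
  Tn <- array(out$T, dim = mf$dims)
  if (!all(is.finite(Tn))) stop("temperature field became non-finite")
  surf <- if (length(rec))
    array(out$surface, dim = c(mf$dims[1], mf$dims[2], length(rec)))
  list(T = Tn, surface = surf, max_dT = out$max_dT)
}

# TRUE when every property map is constant within each depth layer, so the
# equilibration problem collapses to a single depth column
laterally_homogeneous <- function(mf) {
  if (!is.null(mf$T_init_map)) {
    rng <- apply(mf$T_init_map, 3, function(m) diff(range(m)))
    if (any(rng > 1e-12)) return(FALSE)
  }
  for (p in list(mf$rho, mf$cp, mf$k, mf$mu_a, mf$w_perf, mf$q_met,
                 mf$rho_b_c_b)) {
    rng <- apply(p, 3, function(m) diff(range(m)))
    if (any(rng > 1e-12 * max(abs(p), 1))) return(FALSE)
  }
  TRUE
}

# 1D depth-column equilibration for laterally homogeneous fields; exact for
# insulated lateral boundaries by symmetry.  Returns the broadcast 3D field.
equilibrate_column <- function(mf, duration, dt) {
  d <- mf$dims; dz <- mf$spacing[3]
  k <- mf$k[1, 1, ]; rhoc <- (mf$rho * mf$cp)[1, 1, ]
  a <- (mf$rho_b_c_b * mf$w_perf)[1, 1, ]; qm <- mf$q_met[1, 1, ]
  kf <- if (d[3] > 1) 2 * k[-d[3]] * k[-1] / pmax(k[-d[3]] + k[-1], 1e-300) else numeric(0)
  Tz <- if (!is.null(mf$T_init_map)) mf$T_init_map[1, 1, ] else rep(mf$T_init, d[3])
  nsteps <- max(0L, as.integer(round(duration / dt)))
  Tamb4 <- mf$T_amb^4
  nz <- d[3]
  max_dT <- 0
  for (s in seq_len(nsteps)) {
    flux <- numeric(nz)
    if (nz > 1) {
      df <- kf * (Tz[-1] - Tz[-nz]) / dz^2
      flux[-nz] <- flux[-nz] + df
      flux[-1] <- flux[-1] - df
    }
    flux[1] <- flux[1] - mf$emissivity * SIGMA_SB * (Tz[1]^4 - Tamb4) / dz
    dT <- dt * (flux + a * (mf$T_a - Tz) + qm) / rhoc
    Tz <- Tz + dT
    max_dT <- max(abs(dT))
    if (!all(is.finite(Tz))) stop("equilibration diverged (non-finite field)")
  }
  list(T = array(rep(Tz, each = d[1] * d[2]), dim = d),
       max_dT = max_dT)
}

#' Equilibrate a material field without laser
#'
#' Lets the tissue self-regulate (perfusion, metabolism, radiative surface
#' loss) for the protocol's equilibration duration, starting from the
#' initial temperature.  For laterally homogeneous fields the computation
#' collapses to a single depth column (exact by symmetry) and is broadcast;
#' heterogeneous fields are stepped in 3D with insulated lateral/bottom
#' boundaries.
#'
#' @param mf a [material_field()].
#' @param duration equilibration time (s).
#' @param dt time step (s) or `NULL` for 90% of the stability bound.
#' @return list with `T` (equilibrated field), `residual` (max |dT/dt| of
#'   the final step, K/s) and `dt`.
#' @export
equilibrate <- function(mf, duration = 120, dt = NULL) {
  if (is.null(dt)) dt <- 0.9 * stability_dt(mf)
  if (duration <= 0)
    return(list(T = initial_temperature(mf), residual = 0, dt = dt))
  if (laterally_homogeneous(mf)) {
    out <- equilibrate_column(mf, duration, dt)
  } else {
    nsteps <- as.integer(round(duration / dt))
    out <- step_heat(initial_temperature(mf), mf, NULL, dt = dt,
                     nsteps = nsteps, boundary = "insulated")
  }
  list(T = out$T, residual = out$max_dT / dt, dt = dt)
}

#' Resample simulated surface frames through a thermal camera
#'
#' Area-averages simulation surface cells into camera pixels (the camera
#' pitch must be an integer multiple of the grid pitch) and adds zero-mean
#' Gaussian read noise.  Deterministic given `seed`.
#'
#' @param surface array `nx x ny x nframes` of surface temperatures (K) on
#'   the simulation grid.
#' @param timestamps frame times (s).
#' @param grid_pitch simulation surface cell size (m); scalar or `c(dx, dy)`.
#' @param camera a [camera_model()].
#' @param seed integer seed for the noise stream.
#' @param laser_on,meta passed through to [thermal_video()].
#' @return a [thermal_video()].
#' @export
sample_camera <- function(surface, timestamps, grid_pitch, camera,
                          seed = 1L, laser_on = NULL, meta = list()) {
  stopifnot(inherits(camera, "camera_model"))
  if (length(grid_pitch) == 1L) grid_pitch <- rep(grid_pitch, 2L)
  d <- dim(surface)
  m <- camera$pitch / grid_pitch
  if (any(abs(m - round(m)) > 1e-9))
    stop("camera pitch must be an integer multiple of the grid pitch")
  m <- as.integer(round(m))
  np <- if (!is.null(camera$fov)) camera$fov else d[1:2] %/% m
  if (any(np * m > d[1:2]))
    stop("camera pixel grid is larger than the simulated surface")
  # centre the pixel block on the surface
  off <- (d[1:2] - np * m) %/% 2L
  ix <- off[1] + seq_len(np[1] * m[1])
  iy <- off[2] + seq_len(np[2] * m[2])
  nt <- d[3]
  frames <- array(0, dim = c(np[1], np[2], nt))
  gx <- rep(seq_len(np[1]), each = m[1])
  gy <- rep(seq_len(np[2]), each = m[2])
  for (t in seq_len(nt)) {
    sub <- surface[ix, iy, t]
    # block mean over m x m cells
    acc <- rowsum(sub, gx, reorder = TRUE)
    acc <- t(rowsum(t(acc), gy, reorder = TRUE))
    frames[, , t] <- acc / (m[1] * m[2])
  }
  if (camera$noise_sd > 0) {
    set.seed(seed)
    frames <- frames + array(rnorm(length(frames), sd = camera$noise_sd),
                             dim = dim(frames))
  }
  meta$seed <- seed
  thermal_video(frames, timestamps, camera$pitch, laser_on = laser_on,
                meta = meta)
}

#' Run a full FDTI acquisition protocol
#'
#' Equilibrates the sample, then records pre-laser, laser-on and post-laser
#' phases at the camera frame rate with open (frozen far-field) boundaries,
#' and resamples the surface through the camera model.
#'
#' @param mf a [material_field()].
#' @param beam a [laser_beam()] (or a precomputed volumetric source array
#'   via `Q_laser`).
#' @param camera a [camera_model()]; its field of view must cover the beam
#'   position.
#' @param protocol a [sim_protocol()].
#' @param eq_field optional precomputed equilibrated field (from
#'   [equilibrate()]); when supplied, equilibration is skipped, which is
#'   exact for laser-free re-equilibration between repeated measurements.
#' @param Q_laser optional precomputed source array overriding `beam`.
#' @return a [thermal_video()]; metadata records the phantom id, beam
#'   centre and FWHM (mm), seed, and solver step.
#' @export
run_fdti_protocol <- function(mf, beam, camera, protocol,
                              eq_field = NULL, Q_laser = NULL) {
  stopifnot(inherits(protocol, "sim_protocol"))
  dt <- if (!is.null(protocol$dt)) protocol$dt else 0.9 * stability_dt(mf)
  Teq <- if (!is.null(eq_field)) eq_field
         else equilibrate(mf, protocol$equilibration, dt = dt)$T
  if (is.null(Q_laser)) Q_laser <- build_laser_source(mf, beam)

  total <- protocol$pre + protocol$exposure + protocol$post
  n_frames <- max(1L, floor(total * camera$fps) + 1L)
  frame_t <- (seq_len(n_frames) - 1L) / camera$fps
  # frames snap to the nearest solver step; at most one frame per step
  frame_steps <- unique(as.integer(round(frame_t / dt)))
  # map global steps into the three phases
  phase_end <- cumsum(c(protocol$pre, protocol$exposure, protocol$post))
  phase_steps <- as.integer(round(phase_end / dt))
  n_steps <- c(phase_steps[1], diff(phase_steps))

  Tcur <- Teq
  surf_list <- list(); t_list <- list()
  step0 <- 0L
  for (ph in 1:3) {
    if (n_steps[ph] <= 0L) { next }
    sel <- frame_steps > step0 & frame_steps <= step0 + n_steps[ph]
    rec <- frame_steps[sel] - step0
    out <- step_heat(Tcur, mf,
                     Q_laser = if (ph == 2L) Q_laser else NULL,
                     dt = dt, nsteps = n_steps[ph], boundary = "open",
                     radiative = TRUE, record_steps = rec, ghost = Teq)
    Tcur <- out$T
    if (length(rec)) {
      surf_list[[length(surf_list) + 1L]] <- out$surface
      t_list[[length(t_list) + 1L]] <- (step0 + sort(unique(rec))) * dt
    }
    step0 <- step0 + n_steps[ph]
  }
  # frame at t = 0 is the equilibrated field itself
  pre_frame <- NULL
  if (any(frame_steps == 0L)) {
    pre_frame <- array(Teq[, , 1], dim = c(mf$dims[1], mf$dims[2], 1L))
  }
  surf <- c(if (!is.null(pre_frame)) list(pre_frame), surf_list)
  times <- c(if (!is.null(pre_frame)) list(0), t_list)
  surface <- array(unlist(surf), dim = c(mf$dims[1], mf$dims[2],
                                         sum(vapply(surf, function(s) dim(s)[3], 1L))))
  if (!is.null(mf$surface_gain)) {
    # radiometric surface mottle scales the apparent contrast above ambient
    surface <- mf$T_amb + (surface - mf$T_amb) * as.numeric(mf$surface_gain)
  }
  timestamps <- unlist(times)
  laser_on <- c(protocol$pre, protocol$pre + protocol$exposure)
  meta <- list(phantom_id = mf$id,
               beam_center_mm = if (inherits(beam, "laser_beam")) beam$center * 1e3,
               beam_fwhm_mm = if (inherits(beam, "laser_beam")) beam$fwhm * 1e3,
               dt = dt)
  sample_camera(surface, timestamps, mf$spacing[1:2], camera,
                seed = protocol$seed, laser_on = laser_on, meta = meta)
}
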