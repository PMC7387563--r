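#' Voxelized material field for bioheat simulation
#'
#' A `material_field` holds the per-voxel thermal and optical properties of a
#' simulated sample on a regular grid, plus the scalar boundary/ambient
#' parameters the Pennes bioheat solver needs.  Voxel index `[ix, iy, iz]`
#' maps to physical position with `iz = 1` at the imaged top surface; the
#' lateral origin is at the grid centre.
#'
#' Properties may be given as scalars (expanded to the full grid) or as
#' arrays of dimension `dims`.  Units are SI throughout: densities in
#' kg/m^3, specific heats in J/(kg K), conductivities in W/(m K), optical
#' coefficients in 1/m, perfusion in 1/s, metabolic heat in W/m^3,
#' temperatures in K, spacing in m.
#'
#' @param dims integer grid shape `c(nx, ny, nz)`.
#' @param spacing voxel spacing in m; scalar or length-3 `c(dx, dy, dz)`.
#' @param rho tissue density (kg/m^3).
#' @param cp tissue specific heat (J/(kg K)).
#' @param k thermal conductivity (W/(m K)).
#' @param mu_a optical absorption coefficient (1/m).
#' @param mu_s optical scattering coefficient (1/m).
#' @param g scattering anisotropy, in `[0, 1)`.
#' @param w_perf blood perfusion rate (1/s).
#' @param q_met metabolic heat generation (W/m^3).
#' @param emissivity surface thermal emissivity, in `(0, 1]`.
#' @param n_refr refractive index (metadata only; no Fresnel loss applied).
#' @param T_a arterial blood temperature (K).  Defaults to `T_init`.
#' @param T_init initial tissue temperature (K).
#' @param T_amb ambient temperature (K).
#' @param rho_b_c_b blood volumetric heat capacity (J/(m^3 K)); defaults to
#'   the tissue `rho * cp` field.
#' @param T_init_map optional per-voxel initial temperature array (K),
#'   overriding the scalar `T_init`.
#' @param surface_gain optional `nx x ny` radiometric gain map: the
#'   apparent (camera-observed) surface temperature is
#'   `T_amb + gain * (T - T_amb)`, modelling spatially varying surface
#'   emissivity/texture of the sample.  Static offsets it induces are
#'   removed by background subtraction, but it multiplies the
#'   laser-induced excess, so it roughens the observed peak.  `NULL`
#'   means uniform gain 1.
#' @param id free-form phantom identifier carried into video metadata.
#'
#' @return An object of class `material_field`.
#' @export
material_field <- function(dims, spacing,
                           rho = 1000, cp = 3000, k = 0.35,
                           mu_a = 900, mu_s = 2500, g = 0.90,
                           w_perf = 0.001, q_met = 200,
                           emissivity = 0.98, n_refr = 1.40,
                           T_a = NULL, T_init = 303.45, T_amb = 296.45,
                           rho_b_c_b = NULL, T_init_map = NULL,
                           surface_gain = NULL, id = "phantom") {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be three positive integers")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("grid spacing must be positive on every axis")

  expand <- function(x, name) {
    if (length(x) == 1L) x <- array(x, dim = dims)
    if (!identical(dim(x), dims))
      stop(sprintf("property '%s' does not match the grid shape", name))
    storage.mode(x) <- "double"
    x
  }
  mf <- list(
    dims = dims, spacing = as.numeric(spacing),
    rho = expand(rho, "rho"), cp = expand(cp, "cp"), k = expand(k, "k"),
    mu_a = expand(mu_a, "mu_a"), mu_s = expand(mu_s, "mu_s"),
    g = expand(g, "g"),
    w_perf = expand(w_perf, "w_perf"), q_met = expand(q_met, "q_met"),
    emissivity = as.numeric(emissivity), n_refr = as.numeric(n_refr),
    T_init = as.numeric(T_init), T_amb = as.numeric(T_amb),
    id = as.character(id)
  )
  mf$T_a <- if (is.null(T_a)) mf$T_init else as.numeric(T_a)
  mf$rho_b_c_b <- if (is.null(rho_b_c_b)) mf$rho * mf$cp
                  else expand(rho_b_c_b, "rho_b_c_b")
  if (!is.null(T_init_map)) mf$T_init_map <- expand(T_init_map, "T_init_map")
  if (!is.null(surface_gain)) {
    if (!identical(dim(surface_gain), dims[1:2]))
      stop("surface_gain must be an nx x ny matrix")
    if (any(surface_gain <= 0)) stop("surface_gain must be positive")
    mf$surface_gain <- surface_gain
  }
  class(mf) <- "material_field"
  validate_material_field(mf)
  mf
}

validate_material_field <- function(mf) {
  stopifnot(inherits(mf, "material_field"))
  if (any(mf$rho <= 0) || any(mf$cp <= 0) || any(mf$k <= 0))
    stop("rho, cp and k must be strictly positive everywhere")
  if (any(mf$mu_a < 0) || any(mf$mu_s < 0) || any(mf$w_perf < 0) ||
      any(mf$q_met < 0))
    stop("mu_a, mu_s, w_perf and q_met must be non-negative")
  if (any(mf$g < 0) || any(mf$g >= 1))
    stop("anisotropy g must lie in [0, 1)")
  if (mf$emissivity <= 0 || mf$emissivity > 1)
    stop("emissivity must lie in (0, 1]")
  if (any(mf$spacing <= 0)) stop("grid spacing must be positive")
  invisible(mf)
}

#' Physical voxel-centre coordinates of a material field
#'
#' Lateral axes are centred on the grid; depth starts at `dz/2` below the
#' surface.
#'
#' @param mf a [material_field()].
#' @return list with numeric vectors `x`, `y` (m, centred) and `z` (m, depth).
#' @export
grid_coords <- function(mf) {
  d <- mf$dims; s <- mf$spacing
  list(x = (seq_len(d[1]) - (d[1] + 1) / 2) * s[1],
       y = (seq_len(d[2]) - (d[2] + 1) / 2) * s[2],
       z = (seq_len(d[3]) - 0.5) * s[3])
}

initial_temperature <- function(mf) {
  if (!is.null(mf$T_init_map)) mf$T_init_map
  else array(mf$T_init, dim = mf$dims)
}

#' Laser beam description
#'
#' An elliptical-Gaussian beam normal to the tissue surface, described by its
#' optical power and the full width at half maximum of the irradiance
#' profile along each lateral axis.
#'
#' @param power optical power at the surface (W).
#' @param fwhm lateral FWHM in m; scalar (circular) or `c(fwhm_x, fwhm_y)`.
#'   For a top-hat beam this is the disc diameter.
#' @param center beam centre `c(x0, y0)` in m relative to the grid centre.
#' @param shape `"gaussian"` for the free-running elliptical-Gaussian
#'   diode profile, `"tophat"` for a pinhole-conditioned flat circular
#'   beam (uniform irradiance inside the disc, no tails).
#' @param wavelength_nm wavelength (metadata only).
#' @return An object of class `laser_beam` with `sigma = fwhm / (2 sqrt(2 ln 2))`.
#' @export
laser_beam <- function(power = 5e-3, fwhm = c(0.69e-3, 1.35e-3),
                       center = c(0, 0), shape = c("gaussian", "tophat"),
                       wavelength_nm = 405) {
  shape <- match.arg(shape)
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, 2L)
  if (power < 0) stop("beam power must be non-negative")
  if (any(fwhm <= 0)) stop("beam FWHM must be positive")
  structure(list(power = power, fwhm = as.numeric(fwhm),
                 sigma = as.numeric(fwhm) / (2 * sqrt(2 * log(2))),
                 center = as.numeric(center), shape = shape,
                 wavelength_nm = wavelength_nm),
            class = "laser_beam")
}

#' Thermal camera description
#'
#' @param pitch pixel pitch on the sample (m).
#' @param fps frame rate (Hz).
#' @param noise_sd additive zero-mean Gaussian noise per pixel per frame (K).
#' @param fov field of view in pixels, `c(npx, npy)`, or `NULL` to cover the
#'   whole simulated surface.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pitch = 100e-6, fps = 30, noise_sd = 0.02,
                         fov = NULL) {
  if (pitch <= 0) stop("pixel pitch must be positive")
  if (fps <= 0) stop("frame rate must be positive")
  if (noise_sd < 0) stop("noise sd must be non-negative")
  structure(list(pitch = pitch, fps = fps, noise_sd = noise_sd,
                 fov = if (!is.null(fov)) as.integer(fov)),
            class = "camera_model")
}

#' Simulation protocol: equilibration, recording phases and solver step
#'
#' @param equilibration laser-free self-regulation time before recording (s).
#' @param pre pre-laser recording (s).
#' @param exposure laser-on duration (s).
#' @param post post-laser recording (s).
#' @param dt solver time step (s), or `NULL` to use 90% of the explicit
#'   stability bound of the material field.
#' @param seed random seed for camera noise.
#' @return An object of class `sim_protocol`.
#' @export
sim_protocol <- function(equilibration = 120, pre = 1, exposure = 10,
                         post = 10, dt = NULL, seed = 1L) {
  durs <- c(equilibration, pre, exposure, post)
  if (any(durs < 0)) stop("all protocol durations must be non-negative")
  if (!is.null(dt) && dt <= 0) stop("dt must be positive")
  structure(list(equilibration = equilibration, pre = pre,
                 exposure = exposure, post = post, dt = dt,
                 seed = as.integer(seed)),
            class = "sim_protocol")
}

#' Thermal video container
#'
#' @param frames numeric array `[x, y, time]` of surface temperatures (K).
#' @param timestamps frame times (s), strictly increasing.
#' @param pixel_pitch pixel pitch (m).
#' @param laser_on `c(t_on, t_off)` of the laser interval (s), or `NULL`.
#' @param meta list of provenance metadata (phantom id, beam, seed, ...).
#' @return An object of class `thermal_video`.
#' @export
thermal_video <- function(frames, timestamps, pixel_pitch,
                          laser_on = NULL, meta = list()) {
  if (length(dim(frames)) != 3L)
    stop("frames must be a 3D array [x, y, time]")
  if (dim(frames)[3] != length(timestamps))
    stop("number of frames must match timestamps")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!all(is.finite(frames))) stop("temperatures must be finite")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 pixel_pitch = pixel_pitch,
                 laser_on = if (!is.null(laser_on)) as.numeric(laser_on),
                 meta = meta),
            class = "thermal_video")
}

#' @export
print.thermal_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("thermal_video: %d x %d px, %d frames, %.3g-%.3g s, pitch %.3g mm\n",
              d[1], d[2], d[3], min(x$timestamps), max(x$timestamps),
              x$pixel_pitch * 1e3))
  if (!is.null(x$laser_on))
    cat(sprintf("  laser on: %.3g-%.3g s\n", x$laser_on[1], x$laser_on[2]))
  invisible(x)
}

#' @export
print.material_field <- function(x, ...) {
  cat(sprintf("material_field '%s': %d x %d x %d voxels, spacing %s mm\n",
              x$id, x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$spacing * 1e3, 3), collapse = " x ")))
  invisible(x)
}
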