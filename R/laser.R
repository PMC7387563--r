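#' Volumetric laser heat source from an attenuated Gaussian beam
#'
#' The collimated beam enters the tissue normal to the top surface and is
#' attenuated in depth with the effective transport coefficient
#' `mu_t' = mu_a + mu_s (1 - g)` (Beer-Lambert with reduced scattering).
#' The local volumetric heat source is the absorbed fraction of the local
#' fluence, `Q = mu_a * Phi`.  Lateral irradiance is integrated exactly over
#' each pixel (error-function differences), and depth absorption exactly
#' over each voxel, so the volume integral of the returned source never
#' exceeds the beam power.
#'
#' Surface specular reflection is ignored: all incident power enters the
#' tissue and the refractive index is metadata only.
#'
#' @param mf a [material_field()].
#' @param beam a [laser_beam()].
#' @return numeric array of `mf$dims` with the heat source in W/m^3.
#' @export
build_laser_source <- function(mf, beam) {
  stopifnot(inherits(mf, "material_field"), inherits(beam, "laser_beam"))
  co <- grid_coords(mf)
  half_x <- (max(co$x) - min(co$x)) / 2 + mf$spacing[1] / 2
  half_y <- (max(co$y) - min(co$y)) / 2 + mf$spacing[2] / 2
  if (abs(beam$center[1]) > half_x || abs(beam$center[2]) > half_y)
    stop("beam centre lies outside the lateral grid extent")

  if (is.null(beam$shape) || beam$shape == "gaussian") {
    # per-pixel integrated Gaussian power fraction along each lateral axis
    ex <- c(co$x - mf$spacing[1] / 2, max(co$x) + mf$spacing[1] / 2)
    ey <- c(co$y - mf$spacing[2] / 2, max(co$y) + mf$spacing[2] / 2)
    fx <- diff(pnorm(ex, mean = beam$center[1], sd = beam$sigma[1]))
    fy <- diff(pnorm(ey, mean = beam$center[2], sd = beam$sigma[2]))
    irr <- beam$power * outer(fx, fy) / (mf$spacing[1] * mf$spacing[2])
  } else {
    # pinhole-conditioned flat-top ellipse (axes = fwhm), no tails
    inside <- outer(((co$x - beam$center[1]) / (beam$fwhm[1] / 2))^2,
                    ((co$y - beam$center[2]) / (beam$fwhm[2] / 2))^2,
                    `+`) <= 1
    if (!any(inside)) stop("top-hat beam covers no pixels")
    irr <- matrix(0, mf$dims[1], mf$dims[2])
    irr[inside] <- beam$power / (sum(inside) * mf$spacing[1] * mf$spacing[2])
  }
  attenuate_depth(mf, irr)
}

#' Depth-attenuate a surface irradiance map into a volumetric source
#'
#' Shared by the focal laser and the widefield LED source: given the
#' irradiance (W/m^2) arriving at each surface pixel, distributes absorbed
#' power in depth with per-voxel exact Beer-Lambert integration using
#' `mu_t' = mu_a + mu_s (1 - g)`.
#'
#' @param mf a [material_field()].
#' @param irradiance `nx x ny` matrix of incident irradiance (W/m^2).
#' @return numeric array of `mf$dims`, W/m^3.
#' @export
attenuate_depth <- function(mf, irradiance) {
  d <- mf$dims; dz <- mf$spacing[3]
  Q <- array(0, dim = d)
  tau_top <- matrix(0, d[1], d[2])
  for (iz in seq_len(d[3])) {
    mt <- mf$mu_a[, , iz] + mf$mu_s[, , iz] * (1 - mf$g[, , iz])
    tau_bot <- tau_top + mt * dz
    frac <- matrix(0, d[1], d[2])
    pos <- mt > 0
    # absorbed fraction of the incident beam within this voxel layer
    frac[pos] <- (mf$mu_a[, , iz][pos] / mt[pos]) *
      (exp(-tau_top[pos]) - exp(-tau_bot[pos]))
    Q[, , iz] <- irradiance * frac / dz
    tau_top <- tau_bot
  }
  Q
}

#' Widefield flat-top illumination source
#'
#' Emulates a large-spot LED stimulus: uniform irradiance over a circular
#' disc, depth-attenuated identically to the focal beam.
#'
#' @param mf a [material_field()].
#' @param diameter spot diameter (m).
#' @param power total optical power (W).
#' @param center disc centre `c(x0, y0)` in m relative to the grid centre.
#' @return numeric array of `mf$dims`, W/m^3; the surface irradiance map is
#'   attached as attribute `"irradiance"`.
#' @export
make_widefield_source <- function(mf, diameter = 1e-2, power = 0.5,
                                  center = c(0, 0)) {
  stopifnot(inherits(mf, "material_field"))
  co <- grid_coords(mf)
  r <- diameter / 2
  if (abs(center[1]) + r > max(co$x) + mf$spacing[1] / 2 + 1e-12 ||
      abs(center[2]) + r > max(co$y) + mf$spacing[2] / 2 + 1e-12)
    stop("widefield spot exceeds the lateral grid extent")
  inside <- outer(co$x - center[1], co$y - center[2],
                  function(a, b) a^2 + b^2 <= r^2)
  n_in <- sum(inside)
  if (n_in == 0) stop("widefield spot covers no pixels")
  irr <- matrix(0, mf$dims[1], mf$dims[2])
  irr[inside] <- power / (n_in * mf$spacing[1] * mf$spacing[2])
  Q <- attenuate_depth(mf, irr)
  attr(Q, "irradiance") <- irr
  Q
}
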