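#' Homogeneous baseline tissue phantom
#'
#' Literature-typical soft-tissue parameters for the simulated parameter
#' sweep: absorption 900 1/m, conductivity 0.35 W/(m K), density 1000
#' kg/m^3, specific heat 3000 J/(kg K), metabolic heat 200 W/m^3, perfusion
#' 0.001 1/s, emissivity 0.98, scattering 2500 1/m, anisotropy 0.90,
#' initial/arterial temperature 303.45 K, ambient 296.45 K.  Any of these
#' may be overridden (e.g. `k = 0.21` or `mu_a = 1075` for the sweep's low
#' and high members).
#'
#' @param overrides named list of property overrides; unknown names error.
#' @param dims,spacing grid shape and spacing (m); the default 80 x 80 x 40
#'   voxels at 100 um spans 8 x 8 x 4 mm.
#' @return a [material_field()].
#' @export
make_baseline <- function(overrides = list(), dims = c(80, 80, 40),
                          spacing = 100e-6) {
  pars <- list(rho = 1000, cp = 3000, k = 0.35, mu_a = 900, mu_s = 2500,
               g = 0.90, w_perf = 0.001, q_met = 200, emissivity = 0.98,
               n_refr = 1.40, T_init = 303.45, T_amb = 296.45,
               T_a = NULL, rho_b_c_b = NULL, T_init_map = NULL,
               surface_gain = NULL, id = "baseline")
  unknown <- setdiff(names(overrides), names(pars))
  if (length(unknown))
    stop("unknown override key(s): ", paste(unknown, collapse = ", "))
  pars[names(overrides)] <- overrides
  do.call(material_field, c(list(dims = dims, spacing = spacing), pars))
}

#' Ex vivo porcine tissue phantoms
#'
#' Homogeneous fat or muscle blocks with literature optical/thermal
#' parameters at 405 nm; perfusion and metabolism are zero (ex vivo).
#'
#' @param tissue `"fat"` or `"muscle"`.
#' @param dims,spacing grid geometry as in [make_baseline()].
#' @return a [material_field()].
#' @export
make_porcine <- function(tissue = c("fat", "muscle"), dims = c(80, 80, 40),
                         spacing = 100e-6) {
  tissue <- match.arg(tissue)
  p <- switch(tissue,
    fat    = list(mu_a = 150, mu_s = 7750, k = 0.24, rho = 911, cp = 2348,
                  T_init = 294.99),
    muscle = list(mu_a = 950, mu_s = 7000, k = 0.56, rho = 1090, cp = 3421,
                  T_init = 293.34))
  material_field(dims = dims, spacing = spacing,
                 rho = p$rho, cp = p$cp, k = p$k, mu_a = p$mu_a,
                 mu_s = p$mu_s, g = 0.90, w_perf = 0, q_met = 0,
                 emissivity = 0.98, n_refr = 1.40,
                 T_init = p$T_init, T_amb = 296.45,
                 id = paste0("porcine_", tissue))
}

#' 3D-printed pillar resolution phantom
#'
#' Alternating stripes of solid polymer pillars (low conductivity, opaque)
#' and ink-filled water channels (higher conductivity, weakly absorbing)
#' over a solid polymer base.  The channels are filled above the pillar
#' tops, leaving a thin ink film (`cover`) that obscures the structure, as
#' in the physical target: the beam then heats the same absorbing film
#' everywhere, and the contrast comes from what lies beneath - insulating
#' polymer under a pillar traps the heat (wide, tall spot), the water
#' column under a channel drains it (narrow, short spot).  Stripes run
#' along y; the scan axis is x.  Stripe boundaries are aligned to voxel
#' edges, so `pillar_width` and `gap` must be integer multiples of the
#' lateral spacing.
#'
#' Material defaults (config-exposed; the resolution analysis is geometric,
#' not absolute): polymer k = 0.13 W/(m K), rho = 1240, cp = 1800,
#' mu_a = 5000 1/m; ink solution k = 0.60, rho = 1000, cp = 4180,
#' mu_a = 400 1/m, low scattering.  The phantom is passive (no perfusion or
#' metabolism) and starts at ambient temperature, so it is already in
#' thermal equilibrium.
#'
#' @param n_pillars number of polymer pillars (>= 1).
#' @param pillar_width,gap stripe widths (m).
#' @param margin ink-filled margin on each side of the pillar block (m).
#' @param depth_y lateral extent along the stripes (m).
#' @param cover ink fill height above the pillar tops (m); 0 leaves the
#'   pillar tops flush with the imaged surface.
#' @param depth pillar/channel depth below the cover film (m).
#' @param base thickness of the polymer base (m).
#' @param spacing voxel spacing (m).
#' @param pla_props,ink_props named lists overriding the polymer / ink
#'   properties (`k`, `rho`, `cp`, `mu_a`, `mu_s`, `g`).
#' @return a [material_field()]; `$geometry` holds the pillar centre
#'   x-positions (m, grid-centred) and the stripe period.
#' @export
make_pillar_phantom <- function(n_pillars = 3, pillar_width = 1e-3,
                                gap = 1e-3, margin = 2.5e-3, depth_y = 12e-3,
                                cover = 0.8e-3, depth = 2e-3, base = 1.2e-3,
                                spacing = 100e-6,
                                pla_props = list(), ink_props = list()) {
  if (n_pillars < 1) stop("n_pillars must be >= 1")
  pla <- modifyList(list(k = 0.13, rho = 1240, cp = 1800, mu_a = 5000,
                         mu_s = 100, g = 0.90), pla_props)
  ink <- modifyList(list(k = 0.60, rho = 1000, cp = 4180, mu_a = 400,
                         mu_s = 100, g = 0.90), ink_props)
  wpx <- pillar_width / spacing
  gpx <- gap / spacing
  if (wpx < 1 - 1e-9 || gpx < 1 - 1e-9)
    stop("stripe narrower than one voxel")
  if (abs(wpx - round(wpx)) > 1e-9 || abs(gpx - round(gpx)) > 1e-9)
    stop("pillar_width and gap must be integer multiples of the spacing")
  wpx <- as.integer(round(wpx)); gpx <- as.integer(round(gpx))
  mpx <- as.integer(round(margin / spacing))
  nx <- 2L * mpx + n_pillars * wpx + (n_pillars - 1L) * gpx
  ny <- as.integer(round(depth_y / spacing))
  nzc <- as.integer(round(cover / spacing))
  nzd <- as.integer(round(depth / spacing))
  nz <- nzc + nzd + as.integer(round(base / spacing))

  # TRUE where polymer, along x, in the structured layer
  pillar_x <- rep(FALSE, nx)
  pos <- mpx
  for (p in seq_len(n_pillars)) {
    pillar_x[pos + seq_len(wpx)] <- TRUE
    pos <- pos + wpx + gpx
  }
  dims <- c(nx, ny, nz)
  pick <- function(pv, iv) {
    a <- array(iv, dim = dims)                    # ink everywhere
    a[pillar_x, , nzc + seq_len(nzd)] <- pv       # pillars under the film
    if (nzc + nzd < nz) a[, , (nzc + nzd + 1L):nz] <- pv  # polymer base
    a
  }
  mf <- material_field(
    dims = dims, spacing = spacing,
    rho = pick(pla$rho, ink$rho), cp = pick(pla$cp, ink$cp),
    k = pick(pla$k, ink$k), mu_a = pick(pla$mu_a, ink$mu_a),
    mu_s = pick(pla$mu_s, ink$mu_s), g = pick(pla$g, ink$g),
    w_perf = 0, q_met = 0, emissivity = 0.98, n_refr = 1.40,
    T_init = 296.45, T_amb = 296.45, id = "pillar")
  # grid-centred x positions of pillar centres
  x0 <- -(nx / 2) * spacing
  centers <- x0 + (mpx + wpx / 2 + (seq_len(n_pillars) - 1) * (wpx + gpx)) * spacing
  mf$geometry <- list(pillar_centers = centers,
                      period = (pillar_width + gap),
                      pillar_width = pillar_width, gap = gap)
  mf
}

# spatially correlated standard-normal field via circular FFT smoothing of
# white noise with a Gaussian kernel (correlation length in m)
gaussian_random_field <- function(dims, spacing, corr_len) {
  if (corr_len <= 0) stop("heterogeneity correlation length must be positive")
  noise <- array(rnorm(prod(dims)), dim = dims)
  k1 <- function(n, d) {
    if (n == 1L) return(1)
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * d
    k <- exp(-x^2 / (2 * corr_len^2))
    k / sqrt(sum(k^2))
  }
  kern <- outer(outer(k1(dims[1], spacing[1]), k1(dims[2], spacing[2])),
                k1(dims[3], spacing[3]))
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / prod(dims)
  sm / sd(sm)
}

#' Synthetic tumor/healthy cohort generator
#'
#' Emulates the contrast the in vivo studies exploit: tumors have elevated
#' thermal conductivity and more heterogeneous thermal/optical properties
#' than healthy tissue.  Healthy samples are baseline tissue with a small
#' per-sample multiplicative jitter of `k` and `mu_a`; tumor samples
#' additionally carry a subsurface spherical inclusion with conductivity
#' raised by `tumor_effect` and a spatially correlated log-normal
#' perturbation of `k` and `mu_a` (amplitude `heterogeneity` on the log
#' scale).  Deterministic given `seed`.
#'
#' @param n_per_arm samples per arm (>= 1).
#' @param tumor_effect fractional conductivity elevation inside the
#'   inclusion (default +40%).
#' @param tumor_mu_a_effect fractional absorption elevation inside the
#'   inclusion (default +70%): the hemoglobin of the recruited
#'   vasculature absorbs strongly at 405 nm.
#' @param heterogeneity log-sd of the multiplicative random field on
#'   absorption in the tumor arm (0 disables it).
#' @param heterogeneity_k log-sd of the random field on conductivity;
#'   defaults to a quarter of `heterogeneity` (optical mottle from
#'   vasculature is the dominant heterogeneity at 405 nm, and conductivity
#'   mottle mostly injects variance into the width readout).
#' @param seed integer seed.
#' @param corr_len correlation length of the heterogeneity field (m).
#' @param incl_radius,incl_depth radius and centre depth (m) of each
#'   lesion focus.
#' @param n_foci number of overlapping lesion foci per tumor; real tumors
#'   are multifocal and irregular rather than spherical, and the lobed
#'   union is what breaks the radial symmetry of the thermal peak.
#' @param focus_spread lateral sd of the focus centres around the beam
#'   axis (m).
#' @param jitter per-sample log-sd of the scalar property jitter (both arms).
#' @param surface_texture log-sd of the static correlated radiometric
#'   surface-gain mottle on tumor sites (scabby, vascular, irregular lesion
#'   skin); healthy sites get `surface_texture / 5` (mild normal-skin
#'   mottle).  This is the dominant contributor to the steady-state
#'   dispersion and Lorentzian misfit contrast: bulk property texture is
#'   smoothed out by 10 s of lateral conduction, surface texture is not.
#' @param texture_corr_len correlation length of the surface texture (m);
#'   sub-millimetre, the scale of scabs, follicles and surface vessels.
#'   Coarser mottle is largely absorbed by the surface fit and does not
#'   register as misfit.
#' @param t_offset baseline temperature offset of tumor samples (K);
#'   default 0 so thermal-property contrast alone drives classification.
#' @param dims,spacing grid geometry; the default 40 x 40 x 20 voxels at
#'   200 um spans 8 x 8 x 4 mm.
#' @return list of elements `list(mf = material_field, label = "healthy" |
#'   "tumor")`, tumor and healthy interleaved.
#' @export
make_cohort <- function(n_per_arm = 20, tumor_effect = 0.4,
                        tumor_mu_a_effect = 0.7,
                        heterogeneity = 0.08, heterogeneity_k = NULL,
                        seed = 1L, corr_len = 1.5e-3,
                        incl_radius = 4e-3, incl_depth = 2.5e-3,
                        n_foci = 1, focus_spread = 0,
                        jitter = 0.03, surface_texture = 0.05,
                        texture_corr_len = 0.5e-3, t_offset = 0,
                        dims = c(40, 40, 20), spacing = 200e-6) {
  if (n_per_arm < 1) stop("n_per_arm must be >= 1")
  if (corr_len <= 0) stop("heterogeneity correlation length must be positive")
  if (is.null(heterogeneity_k)) heterogeneity_k <- heterogeneity / 4
  set.seed(seed)
  base <- make_baseline(dims = dims, spacing = spacing)
  co <- grid_coords(base)

  lesion_mask <- function() {
    mask <- array(FALSE, dim = dims)
    for (f in seq_len(n_foci)) {
      ctr <- c(rnorm(2, sd = focus_spread), incl_depth)
      r2 <- outer(outer((co$x - ctr[1])^2, (co$y - ctr[2])^2, `+`),
                  (co$z - ctr[3])^2, `+`)
      mask <- mask | (r2 <= incl_radius^2)
    }
    mask
  }

  gain_map <- function(log_sd) {
    if (log_sd <= 0) return(NULL)
    g <- exp(log_sd * gaussian_random_field(c(dims[1:2], 1L), base$spacing,
                                            texture_corr_len)[, , 1])
    g / mean(g)
  }

  one_sample <- function(label, i) {
    jk <- exp(rnorm(1, sd = jitter)); ja <- exp(rnorm(1, sd = jitter))
    k <- base$k * jk; mu_a <- base$mu_a * ja
    Tmap <- NULL
    gain <- gain_map(if (label == "tumor") surface_texture
                     else surface_texture / 5)
    if (label == "tumor") {
      inclusion <- lesion_mask()
      k[inclusion] <- k[inclusion] * (1 + tumor_effect)
      mu_a[inclusion] <- mu_a[inclusion] * (1 + tumor_mu_a_effect)
      if (heterogeneity > 0 || heterogeneity_k > 0) {
        # each realized field is normalized by its own spatial mean, so the
        # heterogeneity knob controls within-sample texture only and the
        # between-sample spread stays with `jitter`
        gk <- exp(heterogeneity_k *
                    gaussian_random_field(dims, base$spacing, corr_len))
        ga <- exp(heterogeneity *
                    gaussian_random_field(dims, base$spacing, corr_len))
        k <- k * gk / mean(gk)
        mu_a <- mu_a * ga / mean(ga)
      }
      if (t_offset != 0)
        Tmap <- array(base$T_init + t_offset, dim = dims)
    }
    make_baseline(overrides = list(k = k, mu_a = mu_a, T_init_map = Tmap,
                                   surface_gain = gain,
                                   id = sprintf("%s_%02d", label, i)),
                  dims = dims, spacing = spacing)
  }
  out <- vector("list", 2L * n_per_arm)
  for (i in seq_len(n_per_arm)) {
    out[[2L * i - 1L]] <- list(mf = one_sample("healthy", i), label = "healthy")
    out[[2L * i]] <- list(mf = one_sample("tumor", i), label = "tumor")
  }
  out
}
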