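#' Region of interest around the heated spot
#'
#' Generates the analysis window: the hottest pixel within a small
#' neighbourhood of the seed point (on the last laser-on frame) becomes the
#' ROI centre; the window is square with side
#' `max(min_mm, fwhm_multiple * beam FWHM)` and is clipped to the frame.
#' All pre-laser frames become the background reference.
#'
#' @param video a [thermal_video()] with a recorded laser interval.
#' @param seed_point `c(row, col)` pixel near the irradiation point;
#'   defaults to the frame centre.
#' @param min_mm minimum window side (mm).
#' @param fwhm_multiple window side as a multiple of the mean beam FWHM
#'   (used when beam metadata is present).
#' @param snap_mm radius of the neighbourhood searched for the hottest
#'   pixel (mm).
#' @return an object of class `fdti_roi`: inclusive pixel bounds `rows`,
#'   `cols`, the peak `seed` pixel, and `background_frames` indices.
#' @export
make_roi <- function(video, seed_point = NULL, min_mm = 5,
                     fwhm_multiple = 4, snap_mm = 1) {
  stopifnot(inherits(video, "thermal_video"))
  d <- dim(video$frames)
  if (is.null(seed_point)) seed_point <- round(d[1:2] / 2)
  if (any(seed_point < 1) || any(seed_point > d[1:2]))
    stop("seed point lies outside the frame")
  if (is.null(video$laser_on)) stop("video has no recorded laser interval")
  bg <- which(video$timestamps < video$laser_on[1])
  if (!length(bg)) stop("video has no pre-laser frames")

  pitch_mm <- video$pixel_pitch * 1e3
  iref <- last_on_frame(video)
  rs <- max(1L, as.integer(round(snap_mm / pitch_mm)))
  rr <- max(1, seed_point[1] - rs):min(d[1], seed_point[1] + rs)
  cc <- max(1, seed_point[2] - rs):min(d[2], seed_point[2] + rs)
  # centre on the hottest pixel of the lightly smoothed laser-induced
  # excess, so neither baseline structure nor a single bright speckle
  # (noise, surface texture) can displace the ROI off the heated spot
  bg_mean <- apply(video$frames[, , bg, drop = FALSE], c(1, 2), mean)
  ref <- box3(video$frames[, , iref] - bg_mean)
  sub <- ref[rr, cc, drop = FALSE]
  w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  peak <- c(rr[w[1]], cc[w[2]])

  side_mm <- min_mm
  if (!is.null(video$meta$beam_fwhm_mm))
    side_mm <- max(min_mm, fwhm_multiple * mean(video$meta$beam_fwhm_mm))
  half <- max(2L, as.integer(round(side_mm / pitch_mm / 2)))
  structure(list(
    rows = c(max(1L, peak[1] - half), min(d[1], peak[1] + half)),
    cols = c(max(1L, peak[2] - half), min(d[2], peak[2] + half)),
    seed = peak, background_frames = bg), class = "fdti_roi")
}

# index of the last frame within the laser-on interval (the analysis frame)
last_on_frame <- function(video) {
  on <- which(video$timestamps >= video$laser_on[1] - 1e-9 &
              video$timestamps <= video$laser_on[2] + 1e-9)
  if (!length(on)) stop("video has no laser-on frames")
  on[length(on)]
}

roi_slice <- function(roi) {
  list(r = roi$rows[1]:roi$rows[2], c = roi$cols[1]:roi$cols[2])
}

# mean pre-laser frame over the ROI
background_frame <- function(video, roi) {
  s <- roi_slice(roi)
  bg <- video$frames[s$r, s$c, roi$background_frames, drop = FALSE]
  apply(bg, c(1, 2), mean)
}

#' Background-subtracted (excess) frame over the ROI
#'
#' Frame nearest to time `t` minus the mean of the background reference
#' frames, restricted to the ROI, so features measure laser-induced excess
#' temperature rather than baseline.
#'
#' @param video a [thermal_video()].
#' @param roi an `fdti_roi` from [make_roi()].
#' @param t time (s); the nearest frame is used.  Defaults to the end of
#'   the laser exposure.
#' @return excess-temperature matrix (K) with attribute `pitch_mm`.
#' @export
excess_frame <- function(video, roi, t = NULL) {
  if (is.null(t)) t <- video$timestamps[last_on_frame(video)]
  if (t < min(video$timestamps) - 1e-9 || t > max(video$timestamps) + 1e-9)
    stop("t outside the recorded video")
  i <- which.min(abs(video$timestamps - t))
  s <- roi_slice(roi)
  ex <- video$frames[s$r, s$c, i] - background_frame(video, roi)
  attr(ex, "pitch_mm") <- video$pixel_pitch * 1e3
  attr(ex, "peak") <- c(roi$seed[1] - roi$rows[1] + 1L,
                        roi$seed[2] - roi$cols[1] + 1L)
  ex
}

# 3x3 box mean with edge replication
box3 <- function(m) {
  d <- dim(m)
  acc <- m * 0
  for (dr in -1:1) for (dc in -1:1) {
    r <- pmin(pmax(seq_len(d[1]) + dr, 1), d[1])
    c <- pmin(pmax(seq_len(d[2]) + dc, 1), d[2])
    acc <- acc + m[r, c]
  }
  acc / 9
}

# linear-interpolated half-max crossing along one profile through the peak
half_crossings <- function(profile, ipk) {
  half <- profile[ipk] / 2
  left <- NA_real_
  for (i in seq(ipk, 2)) {
    if (profile[i - 1] < half && profile[i] >= half) {
      left <- (i - 1) + (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk, length(profile) - 1)) {
    if (profile[i + 1] < half && profile[i] >= half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  c(left, right)
}

#' Full width at half maximum of the excess-temperature peak
#'
#' Along each lateral axis through the peak pixel, the half-maximum
#' crossings on both sides are located by linear interpolation between
#' samples; the scalar FWHM is the mean of the two axis values.
#'
#' @param ex excess frame from [excess_frame()].
#' @param pitch_mm pixel pitch in mm (taken from `ex` if absent).
#' @param peak `c(row, col)` of the peak pixel (taken from `ex`, else the
#'   maximum).
#' @return list with `fwhm_x`, `fwhm_y`, `fwhm` (mm).
#' @export
measure_fwhm <- function(ex, pitch_mm = NULL, peak = NULL) {
  if (is.null(pitch_mm)) pitch_mm <- attr(ex, "pitch_mm")
  if (is.null(peak)) peak <- attr(ex, "peak")
  if (is.null(peak))
    peak <- which(ex == max(ex), arr.ind = TRUE)[1, ]
  if (ex[peak[1], peak[2]] <= 0) stop("no positive peak excess in the ROI")
  cx <- half_crossings(ex[, peak[2]], peak[1])
  cy <- half_crossings(ex[peak[1], ], peak[2])
  if (any(is.na(c(cx, cy))))
    stop("half-maximum not crossed inside the ROI (ROI too small)")
  fx <- diff(cx) * pitch_mm
  fy <- diff(cy) * pitch_mm
  list(fwhm_x = fx, fwhm_y = fy, fwhm = (fx + fy) / 2)
}

#' Peak metrics of an excess frame
#'
#' Amplitude is the maximum excess; area is the half-max support (pixel
#' area times the count of pixels at or above half the amplitude); volume
#' is the integral of the positive excess.
#'
#' @param ex excess frame (K).
#' @param raw_max maximum raw temperature over the ROI (K), reported as
#'   `t_max`; `NA` if not supplied.
#' @param pitch_mm pixel pitch (mm).
#' @return list with `t_max` (K), `amplitude` (K), `area` (mm^2),
#'   `volume` (K mm^2).
#' @export
peak_metrics <- function(ex, raw_max = NA_real_, pitch_mm = NULL) {
  if (is.null(pitch_mm)) pitch_mm <- attr(ex, "pitch_mm")
  dA <- pitch_mm^2
  amp <- max(ex)
  if (amp <= 0)
    return(list(t_max = raw_max, amplitude = max(0, amp), area = 0, volume = 0))
  list(t_max = raw_max, amplitude = amp,
       area = dA * sum(ex >= amp / 2),
       volume = dA * sum(ex[ex > 0]))
}

#' Fit a 2D Gaussian or Lorentzian surface to the excess peak
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `z0 + A exp(-(x-x0)^2/(2 sx^2) - (y-y0)^2/(2 sy^2))` or
#' `z0 + A / (1 + ((x-x0)/gx)^2 + ((y-y0)/gy)^2)` over the ROI, initialized
#' from [peak_metrics()] and [measure_fwhm()].  Width parameters are
#' bounded in (0.1 px, ROI extent) and centres within the ROI.
#' Non-convergence is flagged, not raised.
#'
#' @param ex excess frame (K) with pitch attribute.
#' @param model `"gaussian"` or `"lorentzian"`.
#' @param pitch_mm pixel pitch (mm).
#' @return object of class `surface_fit`: `model`, `pars` (named:
#'   amplitude `A` (K), centre `x0`,`y0` (mm), widths (mm), offset `z0`
#'   (K)), `sse` (K^2), `mse` per pixel, `converged`.
#' @export
fit_surface <- function(ex, model = c("gaussian", "lorentzian"),
                        pitch_mm = NULL) {
  model <- match.arg(model)
  if (is.null(pitch_mm)) pitch_mm <- attr(ex, "pitch_mm")
  if (max(ex) <= 0) stop("no positive peak excess to fit")
  d <- dim(ex)
  peak <- which(ex == max(ex), arr.ind = TRUE)[1, ]
  x <- (seq_len(d[1]) - peak[1]) * pitch_mm
  y <- (seq_len(d[2]) - peak[2]) * pitch_mm
  dat <- data.frame(x = rep(x, times = d[2]), y = rep(y, each = d[1]),
                    z = as.numeric(ex))
  fw <- tryCatch(measure_fwhm(ex, pitch_mm), error = function(e) NULL)
  w0x <- if (!is.null(fw)) fw$fwhm_x else 2 * pitch_mm
  w0y <- if (!is.null(fw)) fw$fwhm_y else 2 * pitch_mm
  amp <- max(ex)
  ext <- max(d) * pitch_mm
  if (model == "gaussian") {
    form <- z ~ z0 + A * exp(-(x - x0)^2 / (2 * sx^2) - (y - y0)^2 / (2 * sy^2))
    start <- list(A = amp, x0 = 0, y0 = 0,
                  sx = w0x / 2.3548, sy = w0y / 2.3548, z0 = 0)
    lower <- c(A = 0, x0 = min(x), y0 = min(y),
               sx = 0.1 * pitch_mm, sy = 0.1 * pitch_mm, z0 = -Inf)
    upper <- c(A = Inf, x0 = max(x), y0 = max(y), sx = ext, sy = ext, z0 = Inf)
  } else {
    form <- z ~ z0 + A / (1 + ((x - x0) / gx)^2 + ((y - y0) / gy)^2)
    start <- list(A = amp, x0 = 0, y0 = 0, gx = w0x / 2, gy = w0y / 2, z0 = 0)
    lower <- c(A = 0, x0 = min(x), y0 = min(y),
               gx = 0.1 * pitch_mm, gy = 0.1 * pitch_mm, z0 = -Inf)
    upper <- c(A = Inf, x0 = max(x), y0 = max(y), gx = ext, gy = ext, z0 = Inf)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300)
  attempt <- function(st, bounded = TRUE) tryCatch(
    if (bounded)
      minpack.lm::nlsLM(form, data = dat, start = st, lower = lower,
                        upper = upper, control = ctrl)
    else
      minpack.lm::nlsLM(form, data = dat, start = st, control = ctrl),
    error = function(e) NULL)
  within_bounds <- function(fit) {
    p <- stats::coef(fit)
    all(p >= lower[names(p)] - 1e-9) && all(p <= upper[names(p)] + 1e-9)
  }
  # a near-optimal start can abort the bounded optimizer with a singular
  # gradient; fall back to a perturbed start and then to an unbounded fit
  # (accepted only if it lands inside the bounds anyway)
  start2 <- start
  wn <- intersect(names(start2), c("sx", "sy", "gx", "gy"))
  start2[wn] <- lapply(start2[wn], function(v) v * 1.25)
  start2$x0 <- start2$x0 + 0.5 * pitch_mm
  start2$y0 <- start2$y0 + 0.5 * pitch_mm
  fit <- attempt(start)
  if (is.null(fit)) fit <- attempt(start2)
  if (is.null(fit)) {
    fit <- attempt(start, bounded = FALSE)
    if (is.null(fit)) fit <- attempt(start2, bounded = FALSE)
    if (!is.null(fit) && !within_bounds(fit)) fit <- NULL
  }
  if (is.null(fit)) {
    p <- unlist(start)
    pred <- if (model == "gaussian")
      p["z0"] + p["A"] * exp(-(dat$x - p["x0"])^2 / (2 * p["sx"]^2) -
                             (dat$y - p["y0"])^2 / (2 * p["sy"]^2))
    else
      p["z0"] + p["A"] / (1 + ((dat$x - p["x0"]) / p["gx"])^2 +
                          ((dat$y - p["y0"]) / p["gy"])^2)
    sse <- sum((dat$z - pred)^2)
    # a zero-residual start is already the least-squares optimum; the
    # optimizer rejecting it is not a convergence failure
    return(structure(list(model = model, pars = p, sse = sse,
                          mse = sse / nrow(dat),
                          converged = sse / nrow(dat) < 1e-10),
                     class = "surface_fit"))
  }
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  structure(list(model = model, pars = stats::coef(fit), sse = sse,
                 mse = sse / nrow(dat), converged = TRUE),
            class = "surface_fit")
}

#' Spatial dispersion of the excess frame at the heating plateau
#'
#' Frames in the last `window` seconds of the laser-on interval are
#' averaged (suppressing camera noise) and the standard deviation of the
#' resulting excess frame is taken across ROI pixels: a measure of how far
#' the plateau peak departs from a smooth surface.  A per-pixel temporal
#' version over the same frames is also returned.
#'
#' @param video a [thermal_video()] with laser interval.
#' @param roi an `fdti_roi`.
#' @param window plateau window before laser-off (s).
#' @return list with `spatial` (K; the primary statistic) and `temporal`
#'   (K; mean per-pixel std over plateau frames).
#' @export
steady_state_std <- function(video, roi, window = 1) {
  if (is.null(video$laser_on)) stop("video has no recorded laser interval")
  if (diff(video$laser_on) < window - 1e-9)
    stop("laser exposure shorter than the plateau window")
  sel <- which(video$timestamps >= video$laser_on[2] - window - 1e-9 &
               video$timestamps <= video$laser_on[2] + 1e-9)
  s <- roi_slice(roi)
  bg <- background_frame(video, roi)
  stack <- video$frames[s$r, s$c, sel, drop = FALSE]
  mean_ex <- apply(stack, c(1, 2), mean) - bg
  temporal <- if (length(sel) > 1) mean(apply(stack, c(1, 2), sd)) else NA_real_
  list(spatial = sd(mean_ex), temporal = temporal)
}

#' Exponential rise and decay constants of the peak-pixel time course
#'
#' The excess temperature of the ROI peak pixel is fitted to
#' `A (1 - exp(-t/tau))` over the laser-on window (t zeroed at laser-on)
#' and to `B exp(-t/tau)` over the post-laser window (t zeroed at
#' laser-off), by Levenberg-Marquardt least squares.
#'
#' @param video a [thermal_video()].
#' @param roi an `fdti_roi`.
#' @return list with `tau_rise`, `tau_decay` (s), `r2_rise`, `r2_decay`,
#'   and `flagged` (TRUE when a fit failed or returned a non-positive tau).
#' @export
fit_kinetics <- function(video, roi) {
  if (is.null(video$laser_on)) stop("video has no recorded laser interval")
  ts <- video$timestamps
  on <- which(ts >= video$laser_on[1] - 1e-9 & ts <= video$laser_on[2] + 1e-9)
  post <- which(ts > video$laser_on[2] + 1e-9)
  if (!length(on) || !length(post))
    stop("video must contain both laser-on and post-laser frames")
  bg <- mean(video$frames[roi$seed[1], roi$seed[2], roi$background_frames])
  y_on <- video$frames[roi$seed[1], roi$seed[2], on] - bg
  t_on <- ts[on] - video$laser_on[1]
  y_po <- video$frames[roi$seed[1], roi$seed[2], post] - bg
  t_po <- ts[post] - video$laser_on[2]

  fit_one <- function(form, dat, start) {
    tryCatch(minpack.lm::nlsLM(form, data = dat, start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 300,
                                                           ftol = 1e-12,
                                                           ptol = 1e-12)),
             error = function(e) NULL)
  }
  r2 <- function(fit, y) {
    if (is.null(fit)) return(NA_real_)
    1 - sum(stats::residuals(fit)^2) / max(sum((y - mean(y))^2),
                                           .Machine$double.eps)
  }
  amp <- max(y_on)
  i63 <- which(y_on >= 0.63 * amp)[1]
  tau0 <- max(t_on[i63], diff(range(t_on)) / 10, 1e-3)
  f_r <- fit_one(y ~ A * (1 - exp(-t / tau)), data.frame(t = t_on, y = y_on),
                 list(A = amp, tau = tau0))
  i37 <- which(y_po <= 0.37 * max(y_po[1], 1e-12))[1]
  tau0d <- if (!is.na(i37)) max(t_po[i37], 1e-3) else diff(range(t_po)) / 2
  f_d <- fit_one(y ~ B * exp(-t / tau), data.frame(t = t_po, y = y_po),
                 list(B = max(y_po[1], 1e-6), tau = tau0d))
  tr <- if (!is.null(f_r)) stats::coef(f_r)[["tau"]] else NA_real_
  td <- if (!is.null(f_d)) stats::coef(f_d)[["tau"]] else NA_real_
  list(tau_rise = tr, tau_decay = td,
       r2_rise = r2(f_r, y_on), r2_decay = r2(f_d, y_po),
       flagged = is.null(f_r) || is.null(f_d) ||
         isTRUE(tr <= 0) || isTRUE(td <= 0))
}

#' Extract the full FDTI feature battery from a thermal video
#'
#' Composes ROI generation, peak metrics, FWHM, 2D Gaussian and Lorentzian
#' surface fits, plateau dispersion, and rise/decay kinetics at the
#' end-of-exposure analysis frame.
#'
#' @param video a [thermal_video()] with pre, exposure and post segments.
#' @param seed_point optional `c(row, col)` seed pixel for the ROI.
#' @param roi optional precomputed `fdti_roi`.
#' @return one-row `data.frame` with columns `t_max`, `amplitude`,
#'   `fwhm_x`, `fwhm_y`, `fwhm`, `area`, `volume`, `gauss_sse`,
#'   `gauss_mse`, `gauss_converged`, `lor_sse`, `lor_mse`,
#'   `lor_converged`, `ss_std`, `ss_std_temporal`, `tau_rise`,
#'   `tau_decay`, `r2_rise`, `r2_decay`.
#' @export
extract_features <- function(video, seed_point = NULL, roi = NULL) {
  if (is.null(roi)) roi <- make_roi(video, seed_point)
  ex <- excess_frame(video, roi)
  s <- roi_slice(roi)
  raw_max <- max(video$frames[s$r, s$c, last_on_frame(video)])
  pm <- peak_metrics(ex, raw_max = raw_max)
  fw <- tryCatch(measure_fwhm(ex), error = function(e) NULL)
  if (is.null(fw)) {
    # wide or edge-clipped peak: retry over the whole frame before giving up
    d <- dim(video$frames)
    roi_full <- structure(list(rows = c(1L, d[1]), cols = c(1L, d[2]),
                               seed = roi$seed,
                               background_frames = roi$background_frames),
                          class = "fdti_roi")
    fw <- measure_fwhm(excess_frame(video, roi_full))
  }
  fg <- fit_surface(ex, "gaussian")
  fl <- fit_surface(ex, "lorentzian")
  ss <- steady_state_std(video, roi)
  kin <- fit_kinetics(video, roi)
  data.frame(t_max = pm$t_max, amplitude = pm$amplitude,
             fwhm_x = fw$fwhm_x, fwhm_y = fw$fwhm_y, fwhm = fw$fwhm,
             area = pm$area, volume = pm$volume,
             gauss_sse = fg$sse, gauss_mse = fg$mse,
             gauss_converged = fg$converged,
             lor_sse = fl$sse, lor_mse = fl$mse, lor_converged = fl$converged,
             ss_std = ss$spatial, ss_std_temporal = ss$temporal,
             tau_rise = kin$tau_rise, tau_decay = kin$tau_decay,
             r2_rise = kin$r2_rise, r2_decay = kin$r2_decay)
}
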