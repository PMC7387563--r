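#' Stepped-beam FDTI scan across a phantom
#'
#' Translates the focal beam along x in fixed steps; at each position runs
#' the full acquisition protocol (the sample is reset to the laser-free
#' equilibrated field between measurements, which is exact re-equilibration
#' for a deterministic laser-free relaxation) and extracts the feature
#' battery.  The FWHM-versus-position profile is the scan's resolution
#' readout.
#'
#' @param mf a [material_field()].
#' @param beam a [laser_beam()]; its centre y is kept, x is scanned.
#' @param camera a [camera_model()].
#' @param protocol a [sim_protocol()]; per-position noise seeds are derived
#'   from `protocol$seed`.
#' @param start,stop scan extent along x (m, grid-centred coordinates).
#' @param step step size (m), default 125 um.
#' @return a `data.frame` of class `scan_profile`: `position_mm` plus all
#'   [extract_features()] columns, one row per beam position.
#' @export
scan_fdti <- function(mf, beam, camera, protocol, start, stop,
                      step = 125e-6) {
  co <- grid_coords(mf)
  if (start > stop) stop("start must be <= stop")
  if (start < min(co$x) || stop > max(co$x))
    stop("scan segment lies outside the phantom")
  positions <- seq(start, stop, by = step)
  dt <- if (!is.null(protocol$dt)) protocol$dt else 0.9 * stability_dt(mf)
  eq <- equilibrate(mf, protocol$equilibration, dt = dt)
  rows <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    b <- laser_beam(power = beam$power, fwhm = beam$fwhm,
                    center = c(positions[i], beam$center[2]),
                    shape = if (is.null(beam$shape)) "gaussian" else beam$shape,
                    wavelength_nm = beam$wavelength_nm)
    pr <- protocol
    pr$dt <- dt
    pr$seed <- protocol$seed + i
    video <- run_fdti_protocol(mf, b, camera, pr, eq_field = eq$T)
    # seed the ROI at the beam position
    seed_px <- round(c(
      (positions[i] - min(co$x)) / video$pixel_pitch + 0.5,
      (beam$center[2] - min(co$y)) / video$pixel_pitch + 0.5))
    d <- dim(video$frames)
    seed_px <- pmin(pmax(seed_px, 1), d[1:2])
    rows[[i]] <- cbind(position_mm = positions[i] * 1e3,
                       extract_features(video, seed_point = seed_px))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_profile", class(out))
  attr(out, "step_mm") <- step * 1e3
  out
}

#' Per-pixel thermal decay-constant map (widefield DTI)
#'
#' For every pixel inside the illumination footprint, fits the post-
#' illumination excess temperature to `B exp(-t/tau)` by least squares on
#' the log-linearized decay, the standard per-pixel recovery analysis of
#' widefield dynamic thermal imaging.  Pixels whose plateau excess falls
#' below `noise_floor` are flagged invalid rather than fitted.
#'
#' @param video a [thermal_video()] with post-illumination frames.
#' @param footprint logical matrix of illuminated pixels; defaults to
#'   pixels whose end-of-exposure excess exceeds `noise_floor`.
#' @param noise_floor minimum excess amplitude (K) for a valid fit.
#' @return list of class `decay_map`: `tau` (s) and `r2` matrices (NA
#'   where invalid), `valid` mask, `footprint`.
#' @export
decay_map <- function(video, footprint = NULL, noise_floor = 0.1) {
  if (is.null(video$laser_on)) stop("video has no recorded laser interval")
  ts <- video$timestamps
  post <- which(ts > video$laser_on[2] + 1e-9)
  if (length(post) < 3) stop("video has no post-illumination frames to fit")
  pre <- which(ts < video$laser_on[1])
  if (!length(pre)) stop("video has no pre-illumination frames")
  d <- dim(video$frames)
  bg <- apply(video$frames[, , pre, drop = FALSE], c(1, 2), mean)
  iend <- which(ts <= video$laser_on[2] + 1e-9)
  amp <- video$frames[, , iend[length(iend)]] - bg
  if (is.null(footprint)) footprint <- amp > noise_floor
  t <- ts[post] - video$laser_on[2]

  nt <- length(post)
  np <- d[1] * d[2]
  ex <- matrix(video$frames[, , post], nrow = np, ncol = nt) - as.numeric(bg)
  cand <- as.numeric(footprint) > 0 & rowSums(ex <= noise_floor / 4) == 0
  tauv <- r2v <- rep(NA_real_, np)
  validv <- rep(FALSE, np)
  if (any(cand)) {
    idx <- which(cand)
    L <- log(ex[idx, , drop = FALSE])
    tc <- t - mean(t)
    slope <- as.numeric(L %*% tc) / sum(tc^2)
    mu <- rowMeans(L)
    fitted <- outer(slope, tc) + mu
    ssr <- rowSums((L - fitted)^2)
    sst <- rowSums((L - mu)^2)
    tv <- -1 / slope
    ok <- is.finite(tv) & tv > 0
    validv[idx[ok]] <- TRUE
    tauv[idx[ok]] <- tv[ok]
    r2v[idx[ok]] <- (1 - ssr / pmax(sst, .Machine$double.eps))[ok]
  }
  structure(list(tau = matrix(tauv, d[1], d[2]),
                 r2 = matrix(r2v, d[1], d[2]),
                 valid = matrix(validv, d[1], d[2]), footprint = footprint),
            class = "decay_map")
}

#' Count resolved peaks in a 1D profile
#'
#' A sample is a resolved peak when it is a local maximum whose topographic
#' prominence is at least `prominence_frac` of the profile's dynamic range
#' and which is separated from any taller accepted peak by at least
#' `min_separation`.  The profile is lightly smoothed first (`smooth`-point
#' moving average, default 3) so single-sample noise spikes are not counted
#' as structure; set `smooth = 1` to count on the raw profile.
#'
#' @param values profile values (>= 5 samples).
#' @param positions sample positions (same units as `min_separation`).
#' @param prominence_frac prominence threshold as a fraction of
#'   `max(values) - min(values)`.
#' @param min_separation minimum distance between accepted peaks; default
#'   half of `expected_pitch` when given, else 0.
#' @param expected_pitch expected peak spacing (optional convenience).
#' @param smooth odd moving-average window applied before counting.
#' @return integer number of resolved peaks; accepted positions are
#'   attached as attribute `"peaks"`.
#' @export
count_resolved_peaks <- function(values, positions = seq_along(values),
                                 prominence_frac = 0.2,
                                 min_separation = NULL,
                                 expected_pitch = NULL, smooth = 3) {
  n <- length(values)
  if (n < 5) stop("need at least 5 samples")
  if (length(positions) != n) stop("positions must match values")
  if (smooth > 1) {
    sm <- stats::filter(values, rep(1 / smooth, smooth), sides = 2)
    values <- ifelse(is.na(sm), values, as.numeric(sm))
  }
  if (is.null(min_separation))
    min_separation <- if (!is.null(expected_pitch)) expected_pitch / 2 else 0
  rng <- diff(range(values))
  if (rng <= 0) return(structure(0L, peaks = numeric(0)))

  is_max <- which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && values[i] > values[i - 1] && values[i] >= values[i + 1]
  }, logical(1)))
  if (!length(is_max)) return(structure(0L, peaks = numeric(0)))

  prominence <- vapply(is_max, function(i) {
    v <- values[i]
    lmin <- v; j <- i
    while (j > 1) { j <- j - 1
      if (values[j] > v) break
      lmin <- min(lmin, values[j]) }
    lb <- if (values[j] > v) lmin else min(values[1:i])
    rmin <- v; j <- i
    while (j < n) { j <- j + 1
      if (values[j] > v) break
      rmin <- min(rmin, values[j]) }
    rb <- if (values[j] > v) rmin else min(values[i:n])
    v - max(lb, rb)
  }, numeric(1))

  keep <- is_max[prominence >= prominence_frac * rng]
  if (!length(keep)) return(structure(0L, peaks = numeric(0)))
  # enforce separation, tallest first
  keep <- keep[order(values[keep], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in keep) {
    if (!length(accepted) ||
        all(abs(positions[i] - positions[accepted]) >= min_separation))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  structure(length(accepted), peaks = positions[accepted])
}
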