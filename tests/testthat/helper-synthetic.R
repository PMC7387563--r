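# builders for small fixtures used across the suite; everything is
# generated in code at test time

# small homogeneous field with sources switched off unless asked for
tiny_field <- function(n = c(20, 20, 10), dx = 2e-4, ...) {
  defaults <- list(dims = n, spacing = dx, rho = 1000, cp = 3000, k = 0.35,
                   mu_a = 900, mu_s = 2500, g = 0.9, w_perf = 0, q_met = 0,
                   T_init = 300, T_amb = 300)
  args <- utils::modifyList(defaults, list(...))
  do.call(material_field, args)
}

# analytic radial surfaces on a pixel grid (pitch in mm)
lorentz_surface <- function(n = 61, pitch_mm = 0.1, A = 1, gamma_mm = 1,
                            center = c((n + 1) / 2, (n + 1) / 2)) {
  x <- (seq_len(n) - center[1]) * pitch_mm
  y <- (seq_len(n) - center[2]) * pitch_mm
  z <- A / (1 + outer(x^2, y^2, `+`) / gamma_mm^2)
  attr(z, "pitch_mm") <- pitch_mm
  z
}

gauss_surface <- function(n = 61, pitch_mm = 0.1, A = 1, sigma_mm = 1,
                          center = c((n + 1) / 2, (n + 1) / 2)) {
  x <- (seq_len(n) - center[1]) * pitch_mm
  y <- (seq_len(n) - center[2]) * pitch_mm
  z <- A * exp(-outer(x^2, y^2, `+`) / (2 * sigma_mm^2))
  attr(z, "pitch_mm") <- pitch_mm
  z
}

# synthetic thermal video: flat baseline, exponential-ramp heating of a
# given spatial shape, exponential decay; optional noise
synthetic_video <- function(shape, fps = 30, pre = 1, on = 10, post = 10,
                            tau_rise = 2, tau_decay = 3, T0 = 300,
                            noise_sd = 0, pitch = 1e-4, seed = 1) {
  times <- seq(0, pre + on + post, by = 1 / fps)
  d <- dim(shape)
  frames <- array(T0, dim = c(d[1], d[2], length(times)))
  for (i in seq_along(times)) {
    t <- times[i]
    f <- if (t <= pre) 0
    else if (t <= pre + on) 1 - exp(-(t - pre) / tau_rise)
    else (1 - exp(-on / tau_rise)) * exp(-(t - pre - on) / tau_decay)
    frames[, , i] <- T0 + shape * f
  }
  if (noise_sd > 0) {
    set.seed(seed)
    frames <- frames + array(rnorm(length(frames), sd = noise_sd), dim(frames))
  }
  thermal_video(frames, times, pitch, laser_on = c(pre, pre + on),
                meta = list(beam_fwhm_mm = c(1, 1)))
}

# labelled two-class feature table with controllable separation
synthetic_cohort_table <- function(n_per_arm = 30, shift = c(f1 = 2, f2 = 0),
                                   seed = 1) {
  set.seed(seed)
  lab <- rep(c("healthy", "tumor"), each = n_per_arm)
  tab <- data.frame(label = lab)
  for (f in names(shift))
    tab[[f]] <- rnorm(2 * n_per_arm) + ifelse(lab == "tumor", shift[[f]], 0)
  tab$id <- sprintf("m%03d", seq_len(nrow(tab)))
  tab$subject <- tab$id
  tab
}
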