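#' Parameter sweep over thermal conductivity and optical absorption
#'
#' Simulates the single-spot FDTI protocol on homogeneous baseline tissue
#' for every combination of the supplied conductivity and absorption
#' values, and reports end-of-exposure amplitude and FWHM.  The camera is
#' noise-free here: the sweep emulates a deterministic forward model, and
#' trends are read from the clean surface.
#'
#' @param k_values thermal conductivities (W/(m K)).
#' @param mu_a_values absorption coefficients (1/m).
#' @param dims,spacing grid geometry (see [make_baseline()]).
#' @param protocol a [sim_protocol()]; `NULL` for the default 2 min
#'   equilibration, 1 s pre, 10 s exposure, 10 s decay.
#' @param power beam power (W).
#' @return `data.frame` with one row per (k, mu_a) pair and the feature
#'   battery columns.
#' @export
run_sweep <- function(k_values = c(0.21, 0.35, 0.48),
                      mu_a_values = c(700, 900, 1075),
                      dims = c(80, 80, 40), spacing = 100e-6,
                      protocol = NULL, power = 5e-3) {
  if (is.null(protocol)) protocol <- sim_protocol()
  beam <- laser_beam(power = power)
  camera <- camera_model(pitch = spacing, noise_sd = 0)
  grid <- expand.grid(k = k_values, mu_a = mu_a_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mf <- make_baseline(overrides = list(k = grid$k[i], mu_a = grid$mu_a[i],
                                         id = sprintf("sweep_k%g_mua%g",
                                                      grid$k[i], grid$mu_a[i])),
                        dims = dims, spacing = spacing)
    video <- run_fdti_protocol(mf, beam, camera, protocol)
    cbind(grid[i, , drop = FALSE], extract_features(video))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulated porcine fat/muscle comparison
#'
#' Runs the FDTI protocol on homogeneous ex vivo fat and muscle blocks
#' with identical beam and camera settings and extracts the feature
#' battery for each.
#'
#' @inheritParams run_sweep
#' @return `data.frame` with a `tissue` column and the feature battery.
#' @export
run_porcine <- function(dims = c(80, 80, 40), spacing = 100e-6,
                        protocol = NULL, power = 5e-3) {
  if (is.null(protocol)) protocol <- sim_protocol()
  beam <- laser_beam(power = power)
  camera <- camera_model(pitch = spacing, noise_sd = 0)
  rows <- lapply(c("fat", "muscle"), function(tt) {
    mf <- make_porcine(tt, dims = dims, spacing = spacing)
    video <- run_fdti_protocol(mf, beam, camera, protocol)
    cbind(data.frame(tissue = tt), extract_features(video))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pillar-phantom resolution experiment: scanned FDTI vs widefield DTI
#'
#' Builds the pillar resolution phantom, scans the focal beam across the
#' pillars in 125 um steps collecting the FWHM-versus-position profile,
#' then illuminates the same phantom with a widefield flat-top source and
#' computes the per-pixel decay-constant map.  Both readouts are reduced
#' to a transect across the pillars and passed through the identical
#' resolved-peak criterion.
#'
#' @param n_pillars number of pillars.
#' @param step scan step (m).
#' @param seed noise seed.
#' @param scan_margin scan extent beyond the outer pillar centres (m).
#' @param beam_fwhm scanning beam diameter (m); the pinhole-conditioned
#'   beam is modeled as a flat-top disc.
#' @param power focal beam power (W).
#' @param wf_power,wf_diameter widefield source power (W) and spot size (m).
#' @param spacing voxel spacing (m).
#' @param protocol a [sim_protocol()]; defaults to a passive-phantom
#'   protocol (the phantom starts at ambient temperature, so equilibration
#'   is instantaneous).
#' @param prominence_frac resolved-peak prominence criterion.
#' @return list with `scan` (the [scan_fdti()] profile), `fdti_peaks`,
#'   `decay` (the [decay_map()]), `transect` (`data.frame` of position vs
#'   decay constant), `widefield_peaks`, and the phantom geometry.
#' @export
run_pillar_experiment <- function(n_pillars = 3, step = 125e-6, seed = 1L,
                                  scan_margin = 1e-3, beam_fwhm = 1e-3,
                                  power = 5e-3, wf_power = 0.5,
                                  wf_diameter = 1e-2, spacing = 100e-6,
                                  protocol = NULL,
                                  prominence_frac = 0.2) {
  mf <- make_pillar_phantom(n_pillars = n_pillars, spacing = spacing)
  if (is.null(protocol))
    protocol <- sim_protocol(equilibration = 0, pre = 1, exposure = 10,
                             post = 5, seed = seed)
  camera <- camera_model(pitch = spacing, noise_sd = 0.02, fps = 30)
  beam <- laser_beam(power = power, fwhm = beam_fwhm, shape = "tophat")
  ctr <- mf$geometry$pillar_centers
  start <- min(ctr) - scan_margin
  stop <- max(ctr) + scan_margin
  scan <- scan_fdti(mf, beam, camera, protocol, start, stop, step = step)
  fdti_peaks <- count_resolved_peaks(scan$fwhm, scan$position_mm,
                                     prominence_frac = prominence_frac,
                                     expected_pitch = mf$geometry$period * 1e3)

  # widefield arm: same phantom, 10 s flat-top illumination, 10 s decay
  wf_protocol <- sim_protocol(equilibration = 0, pre = 1, exposure = 10,
                              post = 10, seed = seed + 1000L)
  Q_wf <- make_widefield_source(mf, diameter = wf_diameter, power = wf_power)
  video <- run_fdti_protocol(mf, beam = NULL, camera, wf_protocol,
                             Q_laser = Q_wf)
  dm <- decay_map(video)
  # transect across the pillars at the scan's y position, averaged over a
  # few adjacent camera rows
  co <- grid_coords(mf)
  jmid <- which.min(abs(co$y - 0))
  jrows <- max(1, jmid - 2):min(mf$dims[2], jmid + 2)
  xs <- co$x * 1e3
  sel <- xs >= start * 1e3 & xs <= stop * 1e3
  tau_line <- rowMeans(dm$tau[sel, jrows, drop = FALSE], na.rm = TRUE)
  transect <- data.frame(position_mm = xs[sel], tau = tau_line)
  transect <- transect[is.finite(transect$tau), , drop = FALSE]
  wf_peaks <- if (nrow(transect) >= 5)
    count_resolved_peaks(transect$tau, transect$position_mm,
                         prominence_frac = prominence_frac,
                         expected_pitch = mf$geometry$period * 1e3)
  else structure(0L, peaks = numeric(0))

  list(scan = scan, fdti_peaks = fdti_peaks,
       decay = dm, transect = transect, widefield_peaks = wf_peaks,
       geometry = mf$geometry)
}

#' Simulate a tumor/healthy cohort and extract its feature table
#'
#' Generates a synthetic cohort with [make_cohort()], runs the FDTI
#' protocol on every sample and assembles the labeled feature table used
#' by the classification stage.
#'
#' @param n_per_arm samples per arm.
#' @param seed cohort and camera seed.
#' @param tumor_effect,heterogeneity generator knobs (see [make_cohort()]).
#' @param dims,spacing grid geometry (reduced-scale default).
#' @param protocol acquisition protocol; default 2 min equilibration,
#'   1 s pre, 10 s exposure, 10 s decay.
#' @param ... further arguments forwarded to [make_cohort()]
#'   (e.g. `corr_len`, `incl_radius`).
#' @return a `data.frame` with `id`, `subject`, `label` and the feature
#'   battery, one row per sample.
#' @export
run_cohort_experiment <- function(n_per_arm = 20, seed = 1L,
                                  tumor_effect = 0.4, heterogeneity = 0.08,
                                  dims = c(40, 40, 20), spacing = 200e-6,
                                  protocol = NULL, ...) {
  cohort <- make_cohort(n_per_arm = n_per_arm, tumor_effect = tumor_effect,
                        heterogeneity = heterogeneity, seed = seed,
                        dims = dims, spacing = spacing, ...)
  if (is.null(protocol)) protocol <- sim_protocol()
  beam <- laser_beam()
  camera <- camera_model(pitch = spacing, noise_sd = 0.02, fps = 30)
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    pr <- protocol
    pr$seed <- protocol$seed + seed * 10000L + i
    video <- run_fdti_protocol(s$mf, beam, camera, pr)
    cbind(data.frame(id = s$mf$id, subject = s$mf$id, label = s$label),
          extract_features(video))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a named end-to-end experiment recipe and write its artifacts
#'
#' Executes one of the packaged recipes (`sweep`, `porcine`, `pillar`,
#' `cohort`), writes its result tables as CSV under `out_dir`, and records
#' a provenance log (`provenance.json`: recipe, parameters, seed, package
#' version).  Outputs are never silently overwritten.
#'
#' @param recipe one of `"sweep"`, `"porcine"`, `"pillar"`, `"cohort"`.
#' @param out_dir output directory.
#' @param seed global seed.
#' @param params named list of recipe parameters forwarded to the
#'   corresponding `run_*` function.
#' @param overwrite allow replacing existing outputs.
#' @return list of written file paths, invisibly; the computed result is
#'   attached as attribute `"result"`.
#' @export
run_experiment <- function(recipe = c("sweep", "porcine", "pillar", "cohort"),
                           out_dir, seed = 1L, params = list(),
                           overwrite = FALSE) {
  recipe <- match.arg(recipe)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    if (!overwrite && file.exists(p))
      stop("output exists; pass overwrite = TRUE to replace: ", p)
    write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  result <- switch(recipe,
    sweep = {
      r <- do.call(run_sweep, params)
      emit(r, "sweep_features.csv"); r
    },
    porcine = {
      r <- do.call(run_porcine, params)
      emit(r, "porcine_features.csv"); r
    },
    pillar = {
      r <- do.call(run_pillar_experiment, c(list(seed = seed), params))
      emit(as.data.frame(r$scan), "pillar_scan_profile.csv")
      emit(r$transect, "pillar_widefield_transect.csv")
      emit(data.frame(method = c("fdti_scan", "widefield_dti"),
                      resolved_peaks = c(as.integer(r$fdti_peaks),
                                         as.integer(r$widefield_peaks))),
           "pillar_peak_counts.csv")
      r
    },
    cohort = {
      r <- do.call(run_cohort_experiment, c(list(seed = seed), params))
      emit(r, "cohort_features.csv"); r
    })
  prov <- file.path(out_dir, "provenance.json")
  if (overwrite || !file.exists(prov))
    jsonlite::write_json(
      list(recipe = recipe, seed = seed, params = params,
           package_version = as.character(utils::packageVersion("fdti")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      prov, auto_unbox = TRUE, digits = NA, force = TRUE)
  written <- c(written, prov)
  structure(invisible(written), result = result)
}
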