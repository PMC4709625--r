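#' Wavenumber grid
#'
#' Defines the evenly spaced wavenumber axis of an FT-NIR instrument.
#' The default covers 4000--12000 cm\eqn{^{-1}} at 8 cm\eqn{^{-1}}
#' resolution (1001 channels), the full range of a process spectrometer
#' fitted with a transmission flow cell.
#'
#' @param start lowest wavenumber, cm^-1.
#' @param stop highest wavenumber, cm^-1.
#' @param step channel spacing, cm^-1.
#' @return An object of class `"wn_grid"` with elements `start`, `stop`,
#'   `step` and `points` (strictly increasing channel positions,
#'   `floor((stop - start)/step) + 1` of them).
#' @examples
#' g <- wn_grid()
#' length(g$points)  # 1001
#' @export
wn_grid <- function(start = 4000, stop = 12000, step = 8) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step))
    stop("grid parameters must be numeric")
  if (start >= stop) stop("invalid grid: start must be < stop")
  if (step <= 0) stop("invalid grid: step must be > 0")
  n <- floor((stop - start) / step) + 1
  structure(
    list(start = start, stop = stop, step = step,
         points = start + step * (seq_len(n) - 1)),
    class = "wn_grid")
}

#' Analyte specification for the process simulator
#'
#' Describes one monitored analyte: its synthetic pure-component NIR
#' signature (a sum of Gaussian absorption bands) and its concentration
#' trajectory through the two process phases (water addition, then the
#' thermostatic precipitation stage).
#'
#' @param name analyte label, e.g. `"DSS"`.
#' @param bands data frame (or 3-column matrix) with columns `center`
#'   (cm^-1), `width` (Gaussian sigma, cm^-1) and `amplitude`
#'   (AU mL/mg) -- absorptivity per unit concentration at the band peak.
#' @param plateau_conc asymptotic concentration in the thermostatic
#'   phase, mg/mL.
#' @param start_conc concentration at the start of water addition, mg/mL.
#' @param decay_rate first-order relaxation rate toward the plateau
#'   during the thermostatic phase, 1/min.
#' @return An object of class `"analyte_spec"`.
#' @export
analyte_spec <- function(name, bands, plateau_conc, start_conc,
                         decay_rate) {
  bands <- as.data.frame(bands)
  if (nrow(bands) == 0) stop("no bands")
  names(bands) <- c("center", "width", "amplitude")
  if (any(bands$width <= 0)) stop("band widths must be > 0")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be >= 0")
  if (plateau_conc <= 0) stop("plateau_conc must be > 0")
  if (start_conc <= 0) stop("start_conc must be > 0")
  structure(
    list(name = name, bands = bands, plateau_conc = plateau_conc,
         start_conc = start_conc, decay_rate = decay_rate),
    class = "analyte_spec")
}

#' Default analyte panel
#'
#' Four phenolic-acid analytes (DSS, PA, RA, SAB) with plateau
#' concentrations set to the end-of-process batch averages of the study
#' system (1.28, 0.260, 0.564 and 2.07 mg/mL) and Gaussian bands placed
#' inside the two modeling windows (5450--6100 and 7700--8700 cm^-1) so
#' that the windows carry quantitative signal. Band positions partially
#' overlap between analytes, as real O-H/C-H overtone bands do.
#'
#' @return Named list of [analyte_spec()] objects.
#' @export
default_analytes <- function() {
  band <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center", "width", "amplitude")
    m
  }
  # start_conc chosen so that dilution over the default water-adding
  # phase (100 L + 1 L/min * 30 min, factor 1.3) leaves c(0-) at the
  # stated multiple of the plateau; each analyte precipitates with its
  # own loss fraction and first-order rate, so the four trajectories
  # are linearly independent.
  mk <- function(name, bands, plateau, loss_ratio, decay) {
    analyte_spec(name, bands,
                 plateau_conc = plateau,
                 start_conc = plateau * loss_ratio * 1.3,
                 decay_rate = decay)
  }
  list(
    DSS = mk("DSS", band(5600, 60, 0.20,
                         8000, 90, 0.16,
                         8450, 120, 0.06), 1.28, 1.18, 0.040),
    PA  = mk("PA",  band(5820, 55, 0.90,
                         8280, 80, 0.85), 0.260, 1.30, 0.060),
    RA  = mk("RA",  band(5950, 65, 0.45,
                         7850, 85, 0.40,
                         5600, 80, 0.12), 0.564, 1.22, 0.035),
    SAB = mk("SAB", band(5720, 70, 0.11,
                         8550, 95, 0.13,
                         8000, 110, 0.05), 2.07, 1.35, 0.080))
}

#' Instrumental noise model
#'
#' Parameters of the measurement-error model applied to each synthetic
#' spectrum: multiplicative scatter (lognormal path-length factor),
#' additive baseline offset and tilt, and white noise whose standard
#' deviation is inflated inside the strong water-absorption bands, where
#' a flowing sample degrades the signal-to-noise ratio.
#'
#' @param scatter_sigma sdlog of the lognormal multiplicative factor.
#' @param baseline_offset_sigma sd of the per-spectrum baseline offset, AU.
#' @param baseline_slope_sigma sd of the per-spectrum baseline slope,
#'   AU per cm^-1.
#' @param noise_floor sd of the white noise outside water bands, AU.
#' @param waterband_noise_factor multiplicative noise inflation at the
#'   water-band maxima (>= 1).
#' @param saturation_level absorbance above which a detector channel is
#'   considered saturated, AU.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(scatter_sigma = 0.01,
                        baseline_offset_sigma = 0.01,
                        baseline_slope_sigma = 2e-6,
                        noise_floor = 1e-3,
                        waterband_noise_factor = 5,
                        saturation_level = 1.5) {
  sig <- c(scatter_sigma, baseline_offset_sigma, baseline_slope_sigma,
           noise_floor)
  if (any(sig < 0)) stop("noise sigmas must be >= 0")
  if (waterband_noise_factor < 1)
    stop("waterband_noise_factor must be >= 1")
  structure(
    list(scatter_sigma = scatter_sigma,
         baseline_offset_sigma = baseline_offset_sigma,
         baseline_slope_sigma = baseline_slope_sigma,
         noise_floor = noise_floor,
         waterband_noise_factor = waterband_noise_factor,
         saturation_level = saturation_level),
    class = "noise_model")
}

#' Study configuration for the synthetic water-precipitation process
#'
#' Bundles everything the simulator needs to emulate an on-line NIR
#' campaign: the wavenumber grid, the analyte panel, the water
#' absorption bands (which saturate the detector and concentrate the
#' noise), the noise model, and the process schedule. Spectra are taken
#' every `spectra_cadence` minutes; reference (off-line assay) samples
#' are drawn every `reference_cadence` minutes. Time zero is the
#' boundary between the water-adding phase (negative minutes) and the
#' thermostatic phase.
#'
#' @param grid a [wn_grid()].
#' @param analytes list of [analyte_spec()] objects.
#' @param water_bands data frame/matrix with columns `center`, `width`,
#'   `amplitude` (AU): the background water/solvent absorption.
#' @param noise a [noise_model()].
#' @param n_batches number of process batches (>= 2).
#' @param spectra_cadence minutes between consecutive spectra.
#' @param reference_cadence minutes between reference samples; must be
#'   an integer multiple of `spectra_cadence`.
#' @param water_add_duration length of the water-adding phase, min.
#' @param thermostat_duration length of the thermostatic phase, min.
#' @param initial_volume reactor volume at the start of water
#'   addition, L.
#' @param water_flow water addition rate, L/min.
#' @param batch_scale_sigma sdlog of the per-batch lognormal
#'   concentration scale factor (batch-to-batch variability).
#' @param reference_noise_sigma sd of optional additive error on the
#'   reference assay, mg/mL (0 = reference treated as ground truth).
#' @param base_seed integer; batch `i` is generated with seed
#'   `base_seed + i` so batches are independently reproducible.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(grid = wn_grid(),
                         analytes = default_analytes(),
                         water_bands = default_water_bands(),
                         noise = noise_model(),
                         n_batches = 5,
                         spectra_cadence = 0.5,
                         reference_cadence = 2,
                         water_add_duration = 30,
                         thermostat_duration = 100,
                         initial_volume = 100,
                         water_flow = 1,
                         batch_scale_sigma = 0.03,
                         reference_noise_sigma = 0,
                         base_seed = 42) {
  cfg <- structure(
    list(grid = grid, analytes = analytes,
         water_bands = {
           wb <- as.data.frame(water_bands)
           names(wb) <- c("center", "width", "amplitude")
           wb
         },
         noise = noise, n_batches = n_batches,
         spectra_cadence = spectra_cadence,
         reference_cadence = reference_cadence,
         water_add_duration = water_add_duration,
         thermostat_duration = thermostat_duration,
         initial_volume = initial_volume, water_flow = water_flow,
         batch_scale_sigma = batch_scale_sigma,
         reference_noise_sigma = reference_noise_sigma,
         base_seed = as.integer(base_seed)),
    class = "study_config")
  validate_config(cfg)
  cfg
}

#' @export
default_water_bands <- function() {
  data.frame(center = c(4400, 5200, 6900),
             width = c(250, 150, 300),
             amplitude = c(3.0, 2.5, 2.6))
}

validate_config <- function(cfg) {
  bad <- character(0)
  if (!inherits(cfg$grid, "wn_grid")) bad <- c(bad, "grid is not a wn_grid")
  if (cfg$spectra_cadence <= 0) bad <- c(bad, "spectra_cadence must be > 0")
  if (cfg$reference_cadence <= 0) bad <- c(bad, "reference_cadence must be > 0")
  ratio <- cfg$reference_cadence / cfg$spectra_cadence
  if (abs(ratio - round(ratio)) > 1e-9)
    bad <- c(bad, "reference_cadence must be an integer multiple of spectra_cadence")
  if (cfg$water_add_duration <= 0) bad <- c(bad, "water_add_duration must be > 0")
  if (cfg$thermostat_duration <= 0) bad <- c(bad, "thermostat_duration must be > 0")
  if (cfg$initial_volume <= 0) bad <- c(bad, "initial_volume must be > 0")
  if (cfg$water_flow < 0) bad <- c(bad, "water_flow must be >= 0")
  if (length(cfg$analytes) == 0) bad <- c(bad, "at least one analyte required")
  if (length(bad)) stop("invalid study config: ", paste(bad, collapse = "; "))
  invisible(cfg)
}

#' Pure-component spectrum
#'
#' Evaluates an analyte's synthetic absorptivity signature -- a sum of
#' Gaussian bands -- on a wavenumber grid:
#' \deqn{\epsilon(\nu) = \sum_j a_j \exp\{-(\nu - c_j)^2 / (2 w_j^2)\}.}
#'
#' @param analyte an [analyte_spec()].
#' @param grid a [wn_grid()].
#' @return Numeric vector of absorptivities (AU mL/mg), one per channel.
#' @export
pure_spectrum <- function(analyte, grid) {
  if (nrow(analyte$bands) == 0) stop("no bands")
  gaussian_profile(analyte$bands, grid$points)
}

gaussian_profile <- function(bands, nu) {
  out <- numeric(length(nu))
  for (j in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[j] *
      exp(-(nu - bands$center[j])^2 / (2 * bands$width[j]^2))
  }
  out
}

#' Concentration trajectory
#'
#' Two-phase concentration course of one analyte. During water addition
#' (t < 0) the analyte is diluted:
#' \deqn{c(t) = c_{start} V_0 / (V_0 + q (t + D_w)),}
#' with \eqn{D_w} the water-adding duration. During the thermostatic
#' phase (t >= 0) precipitation relaxes the concentration first-order
#' toward its plateau:
#' \deqn{c(t) = c_\infty + (c(0^-) - c_\infty) e^{-k t}.}
#' The trajectory is continuous at t = 0 and positive throughout.
#'
#' @param analyte an [analyte_spec()].
#' @param cfg a [study_config()] (supplies volumes, flow and phase
#'   durations).
#' @param times numeric vector of minutes relative to the phase
#'   boundary, sorted ascending, within
#'   `[-water_add_duration, thermostat_duration]`.
#' @param scale optional multiplicative factor (batch-to-batch scale).
#' @return Concentrations in mg/mL, one per time point.
#' @export
trajectory <- function(analyte, cfg, times, scale = 1) {
  if (is.unsorted(times)) stop("times must be sorted ascending")
  if (any(times < -cfg$water_add_duration - 1e-9) ||
      any(times > cfg$thermostat_duration + 1e-9))
    stop("times outside [-water_add_duration, thermostat_duration]")
  v0 <- cfg$initial_volume
  q <- cfg$water_flow
  dw <- cfg$water_add_duration
  c0 <- analyte$start_conc * v0 / (v0 + q * dw)   # c(0-)
  conc <- ifelse(times < 0,
                 analyte$start_conc * v0 / (v0 + q * (times + dw)),
                 analyte$plateau_conc +
                   (c0 - analyte$plateau_conc) *
                   exp(-analyte$decay_rate * pmax(times, 0)))
  conc * scale
}

#' Synthesize one process batch
#'
#' Generates the on-line spectra and the reference-assay table of a
#' single water-precipitation batch. The measurement model for each
#' spectrum is
#' \deqn{A(\nu) = m [\textstyle\sum_a c_a \epsilon_a(\nu) + A_{water}(\nu)]
#'   + \alpha + \beta \nu + e(\nu)}
#' with a lognormal multiplicative scatter factor m, per-spectrum
#' baseline offset/slope draws, and heteroscedastic white noise inflated
#' where the water absorption is strong. Reference concentrations equal
#' the trajectory values exactly unless `reference_noise_sigma > 0`.
#' The batch is generated under seed `base_seed + batch_index`, so
#' repeated calls are bit-reproducible.
#'
#' @param cfg a [study_config()].
#' @param batch_index 1-based batch number (`<= n_batches`).
#' @return List with elements `spectra` (a `"spectra_set"`: `wavenumber`,
#'   matrix `A` of spectra in rows, `t_min`, `batch`) and `reference`
#'   (data frame: `sample_id`, `batch`, `t_min`, one column per analyte,
#'   mg/mL).
#' @export
synthesize_batch <- function(cfg, batch_index) {
  validate_config(cfg)
  if (batch_index < 1 || batch_index > cfg$n_batches)
    stop("batch_index must be in 1..n_batches")

  nu <- cfg$grid$points
  t_spec <- seq(-cfg$water_add_duration, cfg$thermostat_duration,
                by = cfg$spectra_cadence)
  t_ref <- seq(-cfg$water_add_duration, cfg$thermostat_duration,
               by = cfg$reference_cadence)
  n_sp <- length(t_spec)
  n_ch <- length(nu)
  n_an <- length(cfg$analytes)

  set.seed(cfg$base_seed + batch_index)

  # per-batch concentration scale (batch-to-batch variability)
  scales <- stats::rlnorm(n_an, 0, cfg$batch_scale_sigma)

  eps <- vapply(cfg$analytes, pure_spectrum, numeric(n_ch), grid = cfg$grid)
  conc <- vapply(seq_len(n_an), function(a)
    trajectory(cfg$analytes[[a]], cfg, t_spec, scale = scales[a]),
    numeric(n_sp))                                   # n_sp x n_an
  water <- gaussian_profile(cfg$water_bands, nu)

  nm <- cfg$noise
  m <- stats::rlnorm(n_sp, 0, nm$scatter_sigma)
  alpha <- stats::rnorm(n_sp, 0, nm$baseline_offset_sigma)
  beta <- stats::rnorm(n_sp, 0, nm$baseline_slope_sigma)
  wprof <- if (max(water) > 0) water / max(water) else water
  noise_sd <- nm$noise_floor * (1 + (nm$waterband_noise_factor - 1) * wprof)
  e <- matrix(stats::rnorm(n_sp * n_ch, 0, rep(noise_sd, each = n_sp)),
              n_sp, n_ch)

  chem <- conc %*% t(eps)                            # n_sp x n_ch
  A <- m * sweep(chem, 2, water, "+") +
    alpha + outer(beta, nu) + e
  colnames(A) <- NULL

  ref_idx <- match(round(t_ref / cfg$spectra_cadence),
                   round(t_spec / cfg$spectra_cadence))
  ref_conc <- conc[ref_idx, , drop = FALSE]
  if (cfg$reference_noise_sigma > 0)
    ref_conc <- ref_conc +
      matrix(stats::rnorm(length(ref_conc), 0, cfg$reference_noise_sigma),
             nrow(ref_conc))
  ref <- data.frame(
    sample_id = sprintf("b%d_s%03d", batch_index, seq_along(t_ref)),
    batch = batch_index, t_min = t_ref,
    stringsAsFactors = FALSE)
  for (a in seq_len(n_an)) ref[[names(cfg$analytes)[a]]] <- ref_conc[, a]

  spectra <- structure(
    list(wavenumber = nu, A = A, t_min = t_spec, batch = batch_index),
    class = "spectra_set")
  list(spectra = spectra, reference = ref)
}

#' Simulate a complete monitoring study
#'
#' Generates all batches of the campaign and assigns their roles: the
#' first batch is the pre-experiment, the last batch is the validation
#' (prediction) set, and intermediate batches form the calibration set.
#'
#' @param cfg a [study_config()].
#' @return An object of class `"nir_study"`: list with `config`,
#'   `batches` (each a `synthesize_batch()` result plus `role`), and
#'   `roles` (character vector `"pre"/"cal"/"val"`).
#' @export
simulate_study <- function(cfg) {
  validate_config(cfg)
  if (cfg$n_batches < 2) stop("n_batches must be >= 2")
  roles <- rep("cal", cfg$n_batches)
  roles[1] <- "pre"
  roles[cfg$n_batches] <- "val"
  if (cfg$n_batches == 2)
    warning("only 2 batches: calibration set is empty")
  batches <- lapply(seq_len(cfg$n_batches), function(i) {
    b <- synthesize_batch(cfg, i)
    b$role <- roles[i]
    b$reference$role <- roles[i]
    b$index <- i
    b
  })
  structure(list(config = cfg, batches = batches, roles = roles),
            class = "nir_study")
}

#' @export
print.nir_study <- function(x, ...) {
  cat("Synthetic on-line NIR study:", length(x$batches), "batches\n")
  cat("  roles:", paste(x$roles, collapse = ", "), "\n")
  cat("  channels:", length(x$config$grid$points),
      sprintf("(%g-%g cm-1, step %g)", x$config$grid$start,
              x$config$grid$stop, x$config$grid$step), "\n")
  n_sp <- nrow(x$batches[[1]]$spectra$A)
  cat("  spectra/batch:", n_sp,
      " reference samples/batch:", nrow(x$batches[[1]]$reference), "\n")
  cat("  analytes:", paste(names(x$config$analytes), collapse = ", "), "\n")
  invisible(x)
}

#' Calibration/validation design matrices of a study
#'
#' Pairs each reference sample of the requested batches with the raw
#' spectrum acquired at the same time stamp.
#'
#' @param study a `"nir_study"`.
#' @param role one of `"cal"`, `"val"`, `"pre"`.
#' @return List with `X` (raw spectra at reference time stamps, samples
#'   in rows), `reference` (stacked reference table) and `t_min`.
#' @export
study_design <- function(study, role = c("cal", "val", "pre")) {
  role <- match.arg(role)
  sel <- which(study$roles == role)
  if (length(sel) == 0) stop("no batches with role '", role, "'")
  Xs <- list(); refs <- list()
  for (i in sel) {
    b <- study$batches[[i]]
    idx <- match(round(b$reference$t_min / study$config$spectra_cadence),
                 round(b$spectra$t_min / study$config$spectra_cadence))
    Xs[[length(Xs) + 1]] <- b$spectra$A[idx, , drop = FALSE]
    refs[[length(refs) + 1]] <- b$reference
  }
  list(X = do.call(rbind, Xs), reference = do.call(rbind, refs))
}
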