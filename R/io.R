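#' Read and write spectra CSV files
#'
#' The spectra exchange format is a plain CSV whose first column is
#' `wavenumber_cm-1` (strictly monotonic) and whose remaining columns
#' are one spectrum each, named `<batch>_<t_min>` (e.g. `5_-12.5`,
#' `5_0.5`). UTF-8, `.` decimal point, no thousands separators.
#'
#' @param x a `"spectra_set"` (see [synthesize_batch()]).
#' @param path file path.
#' @return `read_spectra()` returns a `"spectra_set"`;
#'   `write_spectra()` returns `path` invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(x$wavenumber, t(x$A), check.names = FALSE)
  names(df) <- c("wavenumber_cm-1",
                 paste(x$batch, format_t(x$t_min), sep = "_"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

format_t <- function(t) {
  # minimal decimal representation so that round-trips are exact for
  # cadence-aligned time stamps
  sub("\\.?0+$", "", sprintf("%.6f", t))
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("spectra file needs a wavenumber column plus ",
                         "at least one spectrum")
  if (names(df)[1] != "wavenumber_cm-1")
    stop("first column must be 'wavenumber_cm-1', found '",
         names(df)[1], "'")
  nu <- df[[1]]
  if (any(diff(nu) <= 0))
    stop("wavenumber column non-monotonic at line ",
         which(diff(nu) <= 0)[1] + 1)
  A <- t(as.matrix(df[, -1, drop = FALSE]))
  if (anyNA(A)) {
    bad <- which(is.na(A), arr.ind = TRUE)[1, ]
    stop("NaN cell at spectrum ", bad[1], ", channel ", bad[2])
  }
  ids <- names(df)[-1]
  batch <- sub("_.*$", "", ids)
  t_min <- as.numeric(sub("^[^_]*_", "", ids))
  dimnames(A) <- NULL
  structure(list(wavenumber = nu, A = A, t_min = t_min,
                 batch = unique(batch)[1]),
            class = "spectra_set")
}

#' Read and write reference-assay tables
#'
#' Reference CSVs carry the columns `sample_id`, `batch`, `t_min`,
#' `role` (one of `pre`/`cal`/`val`) and one concentration column per
#' analyte (mg/mL).
#'
#' @param x reference data frame.
#' @param path file path.
#' @param analytes analyte column names expected on read (optional).
#' @return `read_references()` returns the data frame.
#' @export
write_references <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_references
#' @export
read_references <- function(path, analytes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  needed <- c("sample_id", "batch", "t_min", "role", analytes)
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("reference table missing column(s): ",
         paste(missing, collapse = ", "))
  num <- df[, setdiff(names(df), c("sample_id", "role", "batch")),
            drop = FALSE]
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("NaN cell at row ", bad[1], ", column '",
         names(num)[bad[2]], "'")
  }
  df
}

#' Persist a calibrated model as JSON
#'
#' Serializes a `"nir_model"` (or every model of a
#' `"nir_calibration"`) to a JSON file holding the analyte name, the
#' modeling regions, the pretreatment pipeline and its fitted state,
#' the centring vectors, the NIPALS factors (W, P, q), the regression
#' vector, the latent-variable count, the grid and the selected
#' channels -- everything needed to predict from raw spectra. Numbers
#' are written at full double precision, so a load/save cycle is
#' bit-identical.
#'
#' @param model a `"nir_model"` or `"nir_calibration"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- if (inherits(model, "nir_calibration"))
    list(models = lapply(model$models, model_payload))
  else list(models = list(model_payload(model)))
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

model_payload <- function(m) {
  stopifnot(inherits(m, "nir_model"))
  list(
    analyte = m$analyte,
    grid = list(start = m$grid$start, stop = m$grid$stop,
                step = m$grid$step),
    regions = unclass(m$regions)[, , drop = FALSE],
    channels = list(index = m$channels$index,
                    segment = m$channels$segment),
    preprocess = list(
      steps = lapply(m$pretreat$spec$steps, function(s)
        list(method = s$method, params = s$params)),
      state = m$pretreat$state),
    x_mean = m$pls$x_mean, y_mean = m$pls$y_mean,
    W = m$pls$weights, P = m$pls$loadings, q = m$pls$y_loadings,
    b = m$pls$coefficients, intercept = m$pls$intercept,
    n_lv = m$pls$n_lv)
}

#' @rdname save_model
#' @return `load_model()` returns a `"nir_calibration"`-like list of
#'   `"nir_model"` objects (a single model file yields a list of one).
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  models <- lapply(obj$models, function(p) {
    grid <- wn_grid(p$grid$start, p$grid$stop, p$grid$step)
    regions <- region_set(matrix(p$regions, ncol = 2))
    idx <- as.integer(p$channels$index)
    chan <- list(index = idx, wavenumber = grid$points[idx],
                 segment = as.integer(p$channels$segment))
    steps <- lapply(p$preprocess$steps, function(s)
      do.call(pp_step, c(list(method = s$method), s$params)))
    state <- lapply(p$preprocess$state, as.numeric)
    fitted_pp <- structure(
      list(spec = pp_spec(steps), state = state,
           nu = chan$wavenumber, segments = chan$segment,
           n_channels = length(idx), train = NULL),
      class = "pp_fitted")
    k <- as.integer(p$n_lv)
    pls <- structure(
      list(x_mean = as.numeric(p$x_mean), y_mean = as.numeric(p$y_mean),
           weights = matrix(p$W, ncol = k),
           loadings = matrix(p$P, ncol = k),
           y_loadings = as.numeric(p$q),
           coefficients = as.numeric(p$b),
           intercept = as.numeric(p$intercept), n_lv = k),
      class = "plsr_nipals")
    structure(list(analyte = p$analyte, grid = grid, regions = regions,
                   channels = chan, pretreat = fitted_pp, pls = pls),
              class = "nir_model")
  })
  names(models) <- vapply(models, function(m) m$analyte, character(1))
  models
}

#' Read and write a study configuration as YAML
#'
#' The YAML file mirrors [study_config()] field-for-field (grid,
#' analytes with their bands and trajectory parameters, water bands,
#' noise model, schedule and seed).
#'
#' @param path YAML file path.
#' @param cfg a [study_config()].
#' @return `read_study_config()` returns a `"study_config"`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_band_df <- function(b) {
    m <- do.call(rbind, lapply(b, function(r)
      c(r$center, r$width, r$amplitude)))
    data.frame(center = m[, 1], width = m[, 2], amplitude = m[, 3])
  }
  analytes <- lapply(y$analytes, function(a)
    analyte_spec(a$name, as_band_df(a$bands), a$plateau_conc,
                 a$start_conc, a$decay_rate))
  names(analytes) <- vapply(analytes, function(a) a$name, character(1))
  study_config(
    grid = wn_grid(y$grid$start, y$grid$stop, y$grid$step),
    analytes = analytes,
    water_bands = as_band_df(y$water_bands),
    noise = do.call(noise_model, y$noise),
    n_batches = y$n_batches,
    spectra_cadence = y$spectra_cadence,
    reference_cadence = y$reference_cadence,
    water_add_duration = y$water_add_duration,
    thermostat_duration = y$thermostat_duration,
    initial_volume = y$initial_volume,
    water_flow = y$water_flow,
    batch_scale_sigma = y$batch_scale_sigma %||% 0.03,
    reference_noise_sigma = y$reference_noise_sigma %||% 0,
    base_seed = y$base_seed)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(cfg, path) {
  band_list <- function(df) lapply(seq_len(nrow(df)), function(i)
    list(center = df$center[i], width = df$width[i],
         amplitude = df$amplitude[i]))
  y <- list(
    grid = list(start = cfg$grid$start, stop = cfg$grid$stop,
                step = cfg$grid$step),
    analytes = lapply(unname(cfg$analytes), function(a)
      list(name = a$name, bands = band_list(a$bands),
           plateau_conc = a$plateau_conc, start_conc = a$start_conc,
           decay_rate = a$decay_rate)),
    water_bands = band_list(cfg$water_bands),
    noise = unclass(cfg$noise),
    n_batches = cfg$n_batches,
    spectra_cadence = cfg$spectra_cadence,
    reference_cadence = cfg$reference_cadence,
    water_add_duration = cfg$water_add_duration,
    thermostat_duration = cfg$thermostat_duration,
    initial_volume = cfg$initial_volume,
    water_flow = cfg$water_flow,
    batch_scale_sigma = cfg$batch_scale_sigma,
    reference_noise_sigma = cfg$reference_noise_sigma,
    base_seed = cfg$base_seed)
  yaml::write_yaml(y, path, precision = 17)
  invisible(path)
}

#' Write a study to a directory of CSV files
#'
#' One spectra CSV per batch (`spectra_batch<i>.csv`) plus a single
#' stacked reference table (`references.csv`).
#'
#' @param study a `"nir_study"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in study$batches)
    write_spectra(b$spectra,
                  file.path(dir, sprintf("spectra_batch%d.csv", b$index)))
  refs <- do.call(rbind, lapply(study$batches, function(b) b$reference))
  write_references(refs, file.path(dir, "references.csv"))
  invisible(dir)
}
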