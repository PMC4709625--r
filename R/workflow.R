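#' Calibrate on-line NIR models for every analyte
#'
#' The end-to-end model-building step: raw calibration spectra are
#' masked for saturation, restricted to the modeling windows,
#' pretreated, and regressed on the reference concentrations with a
#' NIPALS PLS model whose latent-variable count is chosen by
#' leave-one-out cross-validation. Each model is then evaluated on the
#' held-out validation batch (RMSEP, RSEP, RPD of prediction) and run
#' through the on-line acceptance rule (RSEP < 20%, RPD > 3).
#'
#' @param study a `"nir_study"` from [simulate_study()] (or any object
#'   with the same structure, e.g. read from disk).
#' @param regions modeling windows, a [region_set()].
#' @param pretreat a [pp_spec()]; default 17-point quadratic
#'   Savitzky-Golay first derivative.
#' @param max_lv largest latent-variable count screened by LOO CV.
#' @param analytes names of analytes to model (default: all in the
#'   study's reference table).
#' @return An object of class `"nir_calibration"`: named list `models`
#'   of `"nir_model"` objects, a `metrics` data frame (one row per
#'   analyte: `n_lv`, `r2`, `rmsec`, `rmsecv`, `rsec`, `rpd_cal`,
#'   `rmsep`, `rsep`, `rpd_pred`, `accepted`), and the acceptance
#'   outcome in `accepted`.
#' @export
nir_calibrate <- function(study, regions = default_regions(),
                          pretreat = pp_spec(pp_step("sg_deriv")),
                          max_lv = 10, analytes = NULL) {
  cal <- study_design(study, "cal")
  val <- study_design(study, "val")
  if (is.null(analytes)) analytes <- names(study$config$analytes)
  grid <- study$config$grid

  # saturation judged on every calibration-batch spectrum, not only the
  # reference-matched subset
  all_cal <- do.call(rbind, lapply(
    study$batches[study$roles == "cal"], function(b) b$spectra$A))
  mask <- saturation_mask(all_cal, study$config$noise$saturation_level)
  chan <- extract_channels(regions, grid, mask)

  Xc_raw <- cal$X[, chan$index, drop = FALSE]
  Xv_raw <- val$X[, chan$index, drop = FALSE]

  models <- list()
  rows <- list()
  preds <- list()
  for (an in analytes) {
    y_cal <- cal$reference[[an]]
    y_val <- val$reference[[an]]
    if (is.null(y_cal)) stop("analyte '", an, "' not in reference table")

    curve <- loo_rmsecv(Xc_raw, y_cal, max_lv, pretreat = pretreat,
                        nu = chan$wavenumber, segments = chan$segment)
    k <- select_lv(curve, cap = max_lv)
    fitted_pp <- pp_fit(pretreat, Xc_raw, chan$wavenumber, chan$segment)
    pls <- plsr_nipals(fitted_pp$train, y_cal, k)

    model <- structure(
      list(analyte = an, grid = grid, regions = regions,
           channels = chan, pretreat = fitted_pp, pls = pls,
           rmsecv = curve),
      class = "nir_model")

    yhat_c <- predict(pls, fitted_pp$train)
    yhat_v <- predict(model, val$X)
    rmsec <- rmse(y_cal, yhat_c)
    rmsep <- rmse(y_val, yhat_v)
    acc <- acceptance_check(rse(y_val, yhat_v), rpd(y_val, rmsep))
    rows[[an]] <- data.frame(
      analyte = an, n_lv = k,
      r2 = r_squared(y_cal, yhat_c),
      rmsec = rmsec, rmsecv = curve[k],
      rsec = rse(y_cal, yhat_c),
      rpd_cal = rpd(y_cal, rmsec),
      rmsep = rmsep, rsep = rse(y_val, yhat_v),
      rpd_pred = rpd(y_val, rmsep),
      accepted = acc$pass,
      stringsAsFactors = FALSE)
    models[[an]] <- model
    preds[[an]] <- yhat_v
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  structure(
    list(models = models, metrics = metrics,
         accepted = all(metrics$accepted),
         n_cal = nrow(Xc_raw), n_val = nrow(Xv_raw),
         pretreat_label = pp_label(pretreat),
         validation = list(reference = val$reference,
                           predicted = do.call(cbind, preds))),
    class = "nir_calibration")
}

#' Predict concentrations from raw spectra
#'
#' Applies a calibrated model's stored channel selection, pretreatment
#' state and regression vector to new raw spectra on the model's grid.
#'
#' @param object a `"nir_model"`.
#' @param newdata raw spectra: a matrix with one spectrum per row on the
#'   full wavenumber grid, or a `"spectra_set"`.
#' @param ... unused.
#' @return Numeric vector of concentrations, mg/mL.
#' @export
predict.nir_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_set")) newdata$A
       else if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
       else as.matrix(newdata)
  n_grid <- length(object$grid$points)
  if (ncol(X) != n_grid)
    stop("expected ", n_grid, " channels on the model grid, got ",
         ncol(X))
  Xp <- pp_apply(object$pretreat, X[, object$channels$index,
                                    drop = FALSE])
  predict(object$pls, Xp)
}

#' @export
print.nir_model <- function(x, ...) {
  cat(sprintf("NIR calibration model for %s: %d LV, %d channels, %s\n",
              x$analyte, x$pls$n_lv, length(x$channels$index),
              pp_label(x$pretreat$spec)))
  invisible(x)
}

#' @rdname predict.nir_model
#' @export
predict.nir_calibration <- function(object, newdata, ...) {
  vapply(object$models, predict, numeric(spectra_count(newdata)),
         newdata = newdata)
}

spectra_count <- function(newdata) {
  if (inherits(newdata, "spectra_set")) nrow(newdata$A)
  else if (is.null(dim(newdata))) 1L
  else nrow(newdata)
}

#' @export
print.nir_calibration <- function(x, ...) {
  cat("On-line NIR calibration (", x$pretreat_label, "), ",
      x$n_cal, " calibration / ", x$n_val, " validation samples\n",
      sep = "")
  m <- x$metrics
  fmt <- data.frame(analyte = m$analyte, LV = m$n_lv,
                    R2 = sprintf("%.4f", m$r2),
                    RMSEC = signif(m$rmsec, 3),
                    RMSECV = signif(m$rmsecv, 3),
                    `RSEC(%)` = sprintf("%.2f", m$rsec),
                    RPDcal = sprintf("%.2f", m$rpd_cal),
                    RMSEP = signif(m$rmsep, 3),
                    `RSEP(%)` = sprintf("%.2f", m$rsep),
                    RPDpred = sprintf("%.2f", m$rpd_pred),
                    accepted = m$accepted, check.names = FALSE)
  print(fmt, row.names = FALSE)
  cat(if (x$accepted) "All models meet the on-line acceptance rule (RSEP < 20%, RPD > 3).\n"
      else "WARNING: some models fail the on-line acceptance rule.\n")
  invisible(x)
}

#' @export
summary.nir_calibration <- function(object, ...) {
  print(object)
  invisible(object$metrics)
}

#' Measured-vs-predicted plot for a calibration
#'
#' One panel per analyte showing validation-set reference
#' concentrations against model predictions, with the identity line.
#'
#' @param x a `"nir_calibration"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nir_calibration <- function(x, ...) {
  m <- names(x$models)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(m)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  ref <- x$validation$reference
  for (an in m) {
    y <- ref[[an]]
    row <- x$metrics[x$metrics$analyte == an, ]
    yhat <- x$validation$predicted[, an]
    graphics::plot(y, yhat, xlab = "reference (mg/mL)",
                   ylab = "predicted (mg/mL)", main = an, ...)
    graphics::abline(0, 1, lty = 2)
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("RSEP %.2f%%  RPD %.2f",
                                      row$rsep, row$rpd_pred))
  }
  invisible(x)
}

#' Compare pretreatment pipelines
#'
#' Screens a list of pretreatment pipelines: for every pipeline and
#' analyte a PLS model with LOO-selected latent variables is built on
#' the calibration set, and R2 (in percent), RMSEC and RMSECV are
#' tabulated. The winner per analyte is the pipeline with the smallest
#' RMSECV (ties go to the pipeline listed first, i.e. the simpler one);
#' a shared winner across analytes is chosen by lowest mean RMSECV
#' rank.
#'
#' @param study a `"nir_study"`.
#' @param regions modeling windows, a [region_set()].
#' @param pretreats named list of [pp_spec()] pipelines, simplest first
#'   (default [standard_pretreatments()]).
#' @param max_lv largest latent-variable count screened.
#' @return An object of class `"pp_comparison"`: data frame with columns
#'   `pretreatment`, `analyte`, `n_lv`, `r2_pct`, `rmsec`, `rmsecv`,
#'   `chosen`, `failed`, `reason`; attribute `shared_winner`.
#' @export
compare_pretreatments <- function(study, regions = default_regions(),
                                  pretreats = standard_pretreatments(),
                                  max_lv = 10) {
  cal <- study_design(study, "cal")
  if (nrow(cal$X) == 0) stop("calibration set is empty")
  grid <- study$config$grid
  all_cal <- do.call(rbind, lapply(
    study$batches[study$roles == "cal"], function(b) b$spectra$A))
  mask <- saturation_mask(all_cal, study$config$noise$saturation_level)
  chan <- extract_channels(regions, grid, mask)
  Xc <- cal$X[, chan$index, drop = FALSE]
  analytes <- names(study$config$analytes)

  rows <- list()
  for (pn in names(pretreats)) {
    for (an in analytes) {
      y <- cal$reference[[an]]
      res <- tryCatch({
        curve <- loo_rmsecv(Xc, y, max_lv, pretreat = pretreats[[pn]],
                            nu = chan$wavenumber,
                            segments = chan$segment)
        k <- select_lv(curve, cap = max_lv)
        fp <- pp_fit(pretreats[[pn]], Xc, chan$wavenumber, chan$segment)
        fit <- plsr_nipals(fp$train, y, k)
        data.frame(pretreatment = pn, analyte = an, n_lv = k,
                   r2_pct = 100 * r_squared(y, fitted(fit)),
                   rmsec = rmse(y, fitted(fit)), rmsecv = curve[k],
                   failed = FALSE, reason = "",
                   stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(pretreatment = pn, analyte = an, n_lv = NA_integer_,
                   r2_pct = NA_real_, rmsec = NA_real_,
                   rmsecv = NA_real_, failed = TRUE,
                   reason = conditionMessage(e),
                   stringsAsFactors = FALSE))
      rows[[length(rows) + 1]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  tab$chosen <- FALSE
  for (an in analytes) {
    sub <- which(tab$analyte == an & !tab$failed)
    if (length(sub))
      tab$chosen[sub[which.min(tab$rmsecv[sub])]] <- TRUE
  }
  # shared winner: lowest mean rank of RMSECV across analytes
  ranks <- sapply(names(pretreats), function(pn) {
    mean(sapply(analytes, function(an) {
      sub <- tab[tab$analyte == an & !tab$failed, ]
      rank(sub$rmsecv)[match(pn, sub$pretreatment)]
    }), na.rm = TRUE)
  })
  attr(tab, "shared_winner") <- names(pretreats)[which.min(ranks)]
  class(tab) <- c("pp_comparison", "data.frame")
  tab
}

#' @export
print.pp_comparison <- function(x, ...) {
  cat("Pretreatment comparison (winner per analyte by RMSECV)\n")
  df <- as.data.frame(x)
  df$r2_pct <- round(df$r2_pct, 2)
  df$rmsec <- signif(df$rmsec, 3)
  df$rmsecv <- signif(df$rmsecv, 3)
  print(df[, c("pretreatment", "analyte", "n_lv", "r2_pct", "rmsec",
               "rmsecv", "chosen", "failed")], row.names = FALSE)
  cat("Shared winner:", attr(x, "shared_winner"), "\n")
  invisible(x)
}

#' Streaming on-line prediction
#'
#' Consumes spectra one at a time, as an on-line monitor would, emitting
#' one record per spectrum with the predicted concentration of every
#' analyte and an out-of-control flag per analyte when a prediction
#' leaves its control limits. Spectra whose channel count does not match
#' the model grid produce a record-level error entry and the stream
#' continues. If a reference table is supplied, the summary compares
#' predictions at the reference time stamps (RMSEP, RSEP, RPD per
#' analyte).
#'
#' @param calibration a `"nir_calibration"` (or named list of
#'   `"nir_model"` objects sharing one grid).
#' @param source spectra to stream: a `"spectra_set"`, a raw matrix
#'   (one spectrum per row), or the path of a spectra CSV file.
#' @param reference optional reference data frame with `t_min` and one
#'   column per analyte.
#' @param control_limits optional named list `analyte -> c(lo, hi)`
#'   (mg/mL); predictions outside are flagged.
#' @param t_min optional time stamps when `source` is a bare matrix.
#' @return An object of class `"nir_monitor"`: `records` data frame
#'   (`t_min`, one prediction column per analyte, one `<analyte>_flag`
#'   column, `error`), and `summary` (per-analyte RMSEP/RSEP/RPD, when
#'   a reference was given).
#' @export
monitor_stream <- function(calibration, source, reference = NULL,
                           control_limits = NULL, t_min = NULL) {
  models <- if (inherits(calibration, "nir_calibration"))
    calibration$models else calibration
  stopifnot(length(models) >= 1)
  if (is.character(source)) source <- read_spectra(source)
  if (inherits(source, "spectra_set")) {
    X <- source$A
    t_min <- source$t_min
  } else {
    X <- as_spectra_matrix(source)
    if (is.null(t_min)) t_min <- seq_len(nrow(X))
  }
  if (is.unsorted(t_min)) stop("timestamps must be non-decreasing")
  analytes <- names(models)

  records <- data.frame(t_min = t_min)
  for (an in analytes) {
    records[[an]] <- NA_real_
    records[[paste0(an, "_flag")]] <- FALSE
  }
  records$error <- ""
  for (i in seq_len(nrow(X))) {
    res <- tryCatch({
      p <- vapply(models, predict, numeric(1),
                  newdata = X[i, , drop = FALSE])
      for (an in analytes) {
        records[i, an] <- p[[an]]
        lim <- control_limits[[an]]
        if (!is.null(lim))
          records[i, paste0(an, "_flag")] <-
            p[[an]] < lim[1] || p[[an]] > lim[2]
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) records$error[i] <- res
  }

  summ <- NULL
  if (!is.null(reference)) {
    idx <- match(round(reference$t_min, 6), round(t_min, 6))
    ok <- !is.na(idx)
    summ <- do.call(rbind, lapply(analytes, function(an) {
      y <- reference[[an]][ok]
      yhat <- records[[an]][idx[ok]]
      rmsep <- rmse(y, yhat)
      data.frame(analyte = an, rmsep = rmsep, rsep = rse(y, yhat),
                 rpd = rpd(y, rmsep), stringsAsFactors = FALSE)
    }))
  }
  structure(list(records = records, summary = summ,
                 n_flagged = sum(vapply(
                   analytes, function(an) sum(records[[paste0(an, "_flag")]]),
                   numeric(1)))),
            class = "nir_monitor")
}

#' @export
print.nir_monitor <- function(x, ...) {
  cat("On-line monitoring:", nrow(x$records), "spectra,",
      x$n_flagged, "out-of-limit flags,",
      sum(x$records$error != ""), "record errors\n")
  if (!is.null(x$summary)) {
    cat("Agreement with reference assay:\n")
    s <- x$summary
    s$rmsep <- signif(s$rmsep, 3)
    s$rsep <- round(s$rsep, 2)
    s$rpd <- round(s$rpd, 2)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Default control limits from the study configuration
#'
#' Plateau concentration +/- 20 percent for every analyte.
#'
#' @param cfg a [study_config()].
#' @param fraction half-width as a fraction of the plateau.
#' @return Named list `analyte -> c(lo, hi)`.
#' @export
default_control_limits <- function(cfg, fraction = 0.2) {
  lapply(cfg$analytes, function(a)
    a$plateau_conc * c(1 - fraction, 1 + fraction))
}
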