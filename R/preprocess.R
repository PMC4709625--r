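#' Savitzky-Golay derivative
#'
#' Smoothed spectral derivative: at every channel a polynomial of degree
#' `polyorder` is fitted by least squares to the spectrum inside a
#' moving window, and the fitted polynomial's derivative at that channel
#' is returned, scaled by the grid step so that a first derivative has
#' units AU per cm^-1. Edge channels use shrink-to-valid asymmetric
#' windows (the same least-squares fit on the channels that exist), so
#' the channel count is preserved.
#'
#' @param X matrix of spectra, one per row.
#' @param window window length in channels; odd, `> polyorder`.
#' @param polyorder polynomial degree (default 2).
#' @param deriv_order derivative order, 1 or 2.
#' @param step grid spacing in cm^-1 (default 1: derivative per
#'   channel).
#' @param segments optional integer/character vector, one entry per
#'   channel: the filter is applied independently inside each contiguous
#'   run of equal labels (so windows never straddle the gap between
#'   disjoint spectral regions).
#' @return Matrix of the same dimensions as `X`.
#' @export
sg_derivative <- function(X, window = 17, polyorder = 2, deriv_order = 1,
                          step = 1, segments = NULL) {
  X <- as_spectra_matrix(X)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window < 5) stop("window must be >= 5")
  if (!deriv_order %in% c(1, 2)) stop("deriv_order must be 1 or 2")
  if (deriv_order > polyorder) stop("deriv_order must be <= polyorder")
  apply_by_segment(X, segments, function(Xs) {
    if (ncol(Xs) < window)
      stop("too few channels (", ncol(Xs), ") for window ", window)
    Xs %*% t(sg_matrix(ncol(Xs), window, polyorder, deriv_order)) /
      step^deriv_order
  })
}

# full n x n transformation matrix: row i holds the convolution weights
# producing the deriv_order-th derivative at channel i
sg_matrix <- function(n, window, polyorder, deriv_order) {
  h <- (window - 1) %/% 2
  Tm <- matrix(0, n, n)
  wts <- function(offsets) {
    V <- outer(offsets, 0:polyorder, "^")
    A <- solve(crossprod(V), t(V))      # (p+1) x m
    A[deriv_order + 1, ] * factorial(deriv_order)
  }
  interior <- wts(-h:h)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    if (hi - lo + 1 == window) {
      Tm[i, lo:hi] <- interior
    } else {
      Tm[i, lo:hi] <- wts((lo:hi) - i)
    }
  }
  Tm
}

#' Standard normal variate
#'
#' Per-spectrum autoscaling: each spectrum is centred to mean 0 and
#' scaled to unit sample standard deviation (n-1 denominator). Corrects
#' multiplicative scatter without a reference spectrum.
#'
#' @param X matrix of spectra, one per row.
#' @return Matrix of the same dimensions.
#' @export
snv <- function(X) {
  X <- as_spectra_matrix(X)
  if (ncol(X) < 2) stop("spectra need more than one channel")
  s <- apply(X, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance spectrum at row ", which(s == 0)[1])
  (X - rowMeans(X)) / s
}

#' Multiplicative scatter correction
#'
#' `msc_fit()` computes the correction reference (the mean calibration
#' spectrum). `msc_apply()` regresses every spectrum on that reference,
#' `x ~ a + b * ref` by ordinary least squares over all channels, and
#' returns `(x - a)/b`, removing additive and multiplicative scatter
#' effects. The reference fitted at calibration time must be reused at
#' prediction time.
#'
#' @param X matrix of calibration spectra, one per row.
#' @return `msc_fit`: the reference spectrum (numeric vector).
#' @export
msc_fit <- function(X) {
  X <- as_spectra_matrix(X)
  colMeans(X)
}

#' @rdname msc_fit
#' @param ref reference spectrum from [msc_fit()].
#' @export
msc_apply <- function(X, ref) {
  X <- as_spectra_matrix(X)
  if (ncol(X) != length(ref))
    stop("reference length ", length(ref), " does not match ",
         ncol(X), " channels")
  rc <- ref - mean(ref)
  den <- sum(rc^2)
  if (den == 0) stop("reference spectrum is constant")
  b <- as.vector(X %*% rc) / den        # slope of x ~ a + b*ref
  if (any(abs(b) < 1e-12)) stop("degenerate scatter fit")
  a <- rowMeans(X) - b * mean(ref)
  (X - a) / b
}

#' Vector normalization
#'
#' Subtracts each spectrum's mean intensity, then scales to unit
#' Euclidean norm.
#'
#' @param X matrix of spectra, one per row.
#' @return Matrix of the same dimensions; every row has mean 0 and
#'   2-norm 1.
#' @export
vector_normalize <- function(X) {
  X <- as_spectra_matrix(X)
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  if (any(nrm == 0))
    stop("zero vector after centering at row ", which(nrm == 0)[1])
  Xc / nrm
}

#' Straight line subtraction
#'
#' Baseline correction: for each spectrum the ordinary least squares
#' straight line in wavenumber is fitted and subtracted, leaving a
#' spectrum with zero mean and zero OLS slope. With `segments`, a
#' separate line is removed inside each contiguous spectral region.
#'
#' @param X matrix of spectra, one per row.
#' @param nu wavenumber (or channel position) per column.
#' @param segments optional per-channel region labels (see
#'   [sg_derivative()]).
#' @return Matrix of the same dimensions.
#' @export
straight_line_subtraction <- function(X, nu = seq_len(ncol(X)),
                                      segments = NULL) {
  X <- as_spectra_matrix(X)
  if (ncol(X) < 2) stop("need at least 2 channels")
  full_nu <- nu
  apply_by_segment(X, segments, function(Xs, cols) {
    v <- full_nu[cols]
    vc <- v - mean(v)
    den <- sum(vc^2)
    slope <- as.vector(Xs %*% vc) / den
    Xs - rowMeans(Xs) - outer(slope, vc)
  }, pass_cols = TRUE)
}

#' Constant offset elimination
#'
#' Subtracts each spectrum's minimum so the corrected spectrum has
#' minimum zero.
#'
#' @param X matrix of spectra, one per row.
#' @return Matrix of the same dimensions.
#' @export
constant_offset <- function(X) {
  X <- as_spectra_matrix(X)
  X - apply(X, 1, min)
}

as_spectra_matrix <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty spectra matrix")
  X
}

apply_by_segment <- function(X, segments, f, pass_cols = FALSE) {
  out <- X
  if (is.null(segments)) {
    cols <- seq_len(ncol(X))
    out[] <- if (pass_cols) f(X, cols) else f(X)
    return(out)
  }
  if (length(segments) != ncol(X))
    stop("segments must have one entry per channel")
  runs <- rle(as.character(segments))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(starts)) {
    cols <- starts[k]:ends[k]
    Xs <- X[, cols, drop = FALSE]
    out[, cols] <- if (pass_cols) f(Xs, cols) else f(Xs)
  }
  out
}

# ---- pretreatment pipelines -------------------------------------------

pp_methods <- c("raw", "sg_deriv", "sls", "vn", "snv", "msc", "offset")

#' Pretreatment pipeline specification
#'
#' An ordered list of named pretreatment steps applied identically at
#' calibration and prediction time. Steps: `"raw"` (identity),
#' `"sg_deriv"` (Savitzky-Golay derivative; params `window`,
#' `polyorder`, `deriv_order`), `"sls"`, `"vn"`, `"snv"`, `"msc"`,
#' `"offset"`. MSC may appear at most once; its reference spectrum is
#' estimated from the calibration set by [pp_fit()] and reused, never
#' refitted, on prediction data.
#'
#' @param ... steps created with [pp_step()] (or a single list of them).
#' @param label optional display label.
#' @return An object of class `"pp_spec"`.
#' @examples
#' first_derivative <- pp_spec(pp_step("sg_deriv", window = 17,
#'                                     polyorder = 2, deriv_order = 1))
#' @export
pp_spec <- function(..., label = NULL) {
  steps <- list(...)
  if (length(steps) == 1 && is.null(steps[[1]]$method) &&
      is.list(steps[[1]]))
    steps <- steps[[1]]
  if (length(steps) == 0) steps <- list(pp_step("raw"))
  for (s in steps) {
    if (!s$method %in% pp_methods)
      stop("unknown pretreatment method: ", s$method)
  }
  if (sum(vapply(steps, function(s) s$method == "msc", logical(1))) > 1)
    stop("MSC may appear at most once")
  structure(list(steps = steps, label = label), class = "pp_spec")
}

#' @rdname pp_spec
#' @param method step name (see Details of [pp_spec()]).
#' @export
pp_step <- function(method, ...) {
  params <- list(...)
  if (method == "sg_deriv") {
    params$window <- params$window %||% 17
    params$polyorder <- params$polyorder %||% 2
    params$deriv_order <- params$deriv_order %||% 1
    if (params$window %% 2 == 0 || params$window <= params$polyorder)
      stop("SG window must be odd and > polyorder")
    if (params$deriv_order > params$polyorder)
      stop("deriv_order must be <= polyorder")
  }
  list(method = method, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The pretreatments compared in a standard screening
#'
#' The six pipelines routinely screened for NIR process calibrations:
#' raw spectra, straight line subtraction, vector normalization, first
#' and second Savitzky-Golay derivative (17-point window, quadratic
#' polynomial), and first derivative followed by straight line
#' subtraction. SNV and MSC pipelines are available via [pp_spec()].
#'
#' @return Named list of `"pp_spec"` objects, simplest first.
#' @export
standard_pretreatments <- function() {
  list(
    raw = pp_spec(pp_step("raw"), label = "Raw spectra"),
    sls = pp_spec(pp_step("sls"), label = "SLS"),
    vn = pp_spec(pp_step("vn"), label = "VN"),
    der1 = pp_spec(pp_step("sg_deriv", deriv_order = 1), label = "1st Der"),
    der2 = pp_spec(pp_step("sg_deriv", deriv_order = 2), label = "2nd Der"),
    der1_sls = pp_spec(pp_step("sg_deriv", deriv_order = 1),
                       pp_step("sls"), label = "1st Der + SLS"))
}

#' Fit and apply a pretreatment pipeline
#'
#' `pp_fit()` runs the pipeline over the calibration spectra, estimating
#' any data-dependent state (currently the MSC reference spectrum) from
#' the calibration set only; `pp_apply()` replays the fitted pipeline on
#' new spectra using the stored state. Prediction data never contribute
#' to fitted state.
#'
#' @param spec a [pp_spec()].
#' @param X matrix of spectra, one per row.
#' @param nu wavenumber per channel (needed by SG and SLS steps).
#' @param segments optional per-channel region labels; segment-wise
#'   operators (SG derivative, SLS) are applied within each contiguous
#'   region.
#' @return `pp_fit`: an object of class `"pp_fitted"` with the
#'   transformed calibration matrix in `$train`; `pp_apply`: the
#'   transformed matrix.
#' @export
pp_fit <- function(spec, X, nu = seq_len(ncol(X)), segments = NULL) {
  stopifnot(inherits(spec, "pp_spec"))
  X <- as_spectra_matrix(X)
  state <- list()
  for (i in seq_along(spec$steps)) {
    s <- spec$steps[[i]]
    if (s$method == "msc") {
      state[[as.character(i)]] <- msc_fit(X)
      X <- msc_apply(X, state[[as.character(i)]])
    } else {
      X <- pp_run_step(s, X, nu, segments)
    }
  }
  structure(list(spec = spec, state = state, nu = nu,
                 segments = segments, n_channels = length(nu),
                 train = X),
            class = "pp_fitted")
}

#' @rdname pp_fit
#' @param fitted a `"pp_fitted"` object from [pp_fit()].
#' @export
pp_apply <- function(fitted, X) {
  stopifnot(inherits(fitted, "pp_fitted"))
  X <- as_spectra_matrix(X)
  if (ncol(X) != fitted$n_channels)
    stop("expected ", fitted$n_channels, " channels, got ", ncol(X))
  for (i in seq_along(fitted$spec$steps)) {
    s <- fitted$spec$steps[[i]]
    if (s$method == "msc") {
      ref <- fitted$state[[as.character(i)]]
      if (is.null(ref))
        stop("MSC reference missing from fitted state; fit the pipeline ",
             "on calibration data first")
      X <- msc_apply(X, ref)
    } else {
      X <- pp_run_step(s, X, fitted$nu, fitted$segments)
    }
  }
  X
}

pp_run_step <- function(s, X, nu, segments) {
  p <- s$params
  switch(s$method,
    raw = X,
    sg_deriv = sg_derivative(X, window = p$window, polyorder = p$polyorder,
                             deriv_order = p$deriv_order,
                             step = if (length(nu) > 1) nu[2] - nu[1] else 1,
                             segments = segments),
    sls = straight_line_subtraction(X, nu, segments),
    vn = vector_normalize(X),
    snv = snv(X),
    offset = constant_offset(X),
    stop("unknown method ", s$method))
}

#' @export
print.pp_spec <- function(x, ...) {
  cat("Pretreatment pipeline:", pp_label(x), "\n")
  invisible(x)
}

pp_label <- function(spec) {
  if (!is.null(spec$label)) return(spec$label)
  paste(vapply(spec$steps, function(s) {
    if (s$method == "sg_deriv")
      sprintf("SG%d(%d,%d)", s$params$deriv_order, s$params$window,
              s$params$polyorder)
    else toupper(s$method)
  }, character(1)), collapse = " + ")
}
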