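#' Spectral region set
#'
#' A set of closed wavenumber intervals `[lo, hi]` used as modeling
#' windows. Intervals must be pairwise disjoint; they are stored sorted
#' ascending.
#'
#' @param intervals a 2-column matrix / data frame of `(lo, hi)` rows, a
#'   list of length-2 vectors, or a string like
#'   `"5450-6100,7700-8700"`.
#' @return An object of class `"region_set"` (a 2-column matrix with
#'   columns `lo`, `hi`).
#' @export
region_set <- function(intervals) {
  if (is.character(intervals)) {
    parts <- strsplit(strsplit(intervals, ",")[[1]], "-")
    intervals <- t(vapply(parts, function(p) as.numeric(trimws(p)),
                          numeric(2)))
  }
  if (is.list(intervals) && !is.data.frame(intervals))
    intervals <- do.call(rbind, intervals)
  m <- as.matrix(intervals)
  if (ncol(m) != 2 || nrow(m) == 0 || anyNA(m))
    stop("intervals must be (lo, hi) pairs")
  if (any(m[, 1] >= m[, 2])) stop("each interval needs lo < hi")
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
    stop("intervals must be pairwise disjoint")
  dimnames(m) <- list(NULL, c("lo", "hi"))
  structure(m, class = c("region_set", "matrix"))
}

#' Default modeling windows
#'
#' `default_regions()` returns the two windows used for the final
#' calibration models, 5450--6100 and 7700--8700 cm^-1.
#' `alt_regions()` returns the wider screening alternative,
#' 5450--6100 and 7400--9500 cm^-1.
#'
#' @return A [region_set()].
#' @export
default_regions <- function()
  region_set(rbind(c(5450, 6100), c(7700, 8700)))

#' @rdname default_regions
#' @export
alt_regions <- function()
  region_set(rbind(c(5450, 6100), c(7400, 9500)))

#' Saturation mask
#'
#' Flags detector channels unusable for calibration: a channel is
#' excluded if any calibration spectrum reaches an absorbance greater
#' than or equal to `threshold` there (zero transmissivity; default
#' 1.5 AU).
#'
#' @param X matrix of raw calibration spectra, one per row.
#' @param threshold saturation absorbance, AU.
#' @return Logical vector, one per channel; `TRUE` = excluded.
#' @export
saturation_mask <- function(X, threshold = 1.5) {
  X <- as_spectra_matrix(X)
  if (threshold <= 0) stop("threshold must be > 0")
  apply(X, 2, max) >= threshold
}

#' Per-channel correlation profile
#'
#' Pearson correlation between each (pretreated) spectral channel and
#' the reference concentrations -- the diagnostic used to confirm that
#' the chosen modeling windows carry analyte information. Channels with
#' zero variance are reported as r = 0 and flagged degenerate.
#'
#' @param X matrix of pretreated spectra, one per row (>= 3 rows).
#' @param y reference concentration per spectrum; must not be constant.
#' @return List with `r` (per-channel correlation, in `[-1, 1]`) and
#'   `degenerate` (logical).
#' @export
correlation_profile <- function(X, y) {
  X <- as_spectra_matrix(X)
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (length(y) != nrow(X)) stop("y must have one value per spectrum")
  if (stats::sd(y) == 0) stop("constant y")
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  sx <- unname(sqrt(colSums(Xc^2)))
  degenerate <- sx == 0
  r <- numeric(ncol(X))
  r[!degenerate] <- as.vector(crossprod(Xc[, !degenerate, drop = FALSE],
                                        yc)) /
    (sx[!degenerate] * sqrt(sum(yc^2)))
  list(r = r, degenerate = degenerate)
}

#' Extract modeling channels
#'
#' Selects the grid channels lying inside the region set (closed
#' intervals) and not excluded by the saturation mask. The returned
#' segment labels identify which interval each channel belongs to, so
#' window-based operators can be applied per contiguous region.
#'
#' @param regions a [region_set()].
#' @param grid a [wn_grid()] or a numeric vector of channel positions.
#' @param mask optional logical exclusion mask (see
#'   [saturation_mask()]).
#' @return List with `index` (strictly increasing channel indices),
#'   `wavenumber` and `segment` (interval id per selected channel).
#' @export
extract_channels <- function(regions, grid, mask = NULL) {
  stopifnot(inherits(regions, "region_set"))
  nu <- if (inherits(grid, "wn_grid")) grid$points else as.numeric(grid)
  if (!is.null(mask) && length(mask) != length(nu))
    stop("mask must have one entry per channel")
  seg <- rep(NA_integer_, length(nu))
  for (k in seq_len(nrow(regions))) {
    inside <- nu >= regions[k, 1] & nu <= regions[k, 2]
    seg[inside] <- k
  }
  keep <- !is.na(seg)
  if (!is.null(mask)) keep <- keep & !mask
  idx <- which(keep)
  if (length(idx) == 0) stop("no channels in regions")
  list(index = idx, wavenumber = nu[idx], segment = seg[idx])
}
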