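#' Partial least squares regression by NIPALS
#'
#' Fits a single-response PLS regression with the classical NIPALS
#' factorization. Predictors and response are mean-centred (columns are
#' not variance-scaled: spectral channels share absorbance units). Per
#' component \eqn{a}: \eqn{w_a = X^\top y / \|X^\top y\|},
#' \eqn{t_a = X w_a}, \eqn{p_a = X^\top t_a / t_a^\top t_a},
#' \eqn{q_a = y^\top t_a / t_a^\top t_a}, then X and y are deflated by
#' the rank-one component. The regression vector is
#' \eqn{b = W (P^\top W)^{-1} q}, with the intercept recovered from the
#' centring means.
#'
#' @param X predictor matrix (samples x channels), no missing values.
#' @param y numeric response (e.g. concentrations in mg/mL).
#' @param ncomp number of latent variables; `1 <= ncomp <=
#'   min(ncol(X), nrow(X) - 1)`.
#' @return An object of class `"plsr_nipals"` with components `x_mean`,
#'   `y_mean`, `weights` (W), `loadings` (P), `y_loadings` (q),
#'   `scores` (T), `coefficients` (b), `intercept`, `n_lv`,
#'   `fitted.values`, `residuals`.
#' @seealso [predict.plsr_nipals()], [loo_rmsecv()], [select_lv()]
#' @export
plsr_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(y) == 0) stop("zero-variance y")
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (ncomp > min(p, n - 1))
    stop("ncomp must be <= min(channels, samples - 1)")

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- as.vector(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 * max(1, sqrt(sum(Xd^2))))
      stop("no covariance remaining at component ", a)
    w <- w / nw
    tt <- as.vector(Xd %*% w)
    t2 <- sum(tt^2)
    pa <- as.vector(crossprod(Xd, tt)) / t2
    qa <- sum(yd * tt) / t2
    Xd <- Xd - tcrossprod(tt, pa)
    yd <- yd - tt * qa
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt; q[a] <- qa
  }

  b <- pls_coefficients(W, P, q, ncomp)
  intercept <- y_mean - sum(x_mean * b)
  fitted <- as.vector(X %*% b) + intercept

  structure(
    list(x_mean = x_mean, y_mean = y_mean, weights = W, loadings = P,
         y_loadings = q, scores = Tm, coefficients = b,
         intercept = intercept, n_lv = ncomp,
         fitted.values = fitted, residuals = y - fitted,
         y = y, call = match.call()),
    class = "plsr_nipals")
}

pls_coefficients <- function(W, P, q, k) {
  Wk <- W[, seq_len(k), drop = FALSE]
  Pk <- P[, seq_len(k), drop = FALSE]
  as.vector(Wk %*% solve(crossprod(Pk, Wk), q[seq_len(k)]))
}

#' Predict from a NIPALS PLS model
#'
#' @param object a `"plsr_nipals"` fit.
#' @param newdata matrix of predictors on the model's channels (one row
#'   per sample), or a numeric vector for a single sample.
#' @param ncomp number of latent variables to use (default: all fitted;
#'   fewer re-assembles the coefficient vector from the leading
#'   factors).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_nipals <- function(object, newdata, ncomp = object$n_lv,
                                ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
       else as.matrix(newdata)
  if (ncol(X) != length(object$x_mean))
    stop("expected ", length(object$x_mean), " channels, got ", ncol(X))
  if (ncomp < 1 || ncomp > object$n_lv)
    stop("ncomp must be in 1..", object$n_lv)
  b <- if (ncomp == object$n_lv) object$coefficients
       else pls_coefficients(object$weights, object$loadings,
                             object$y_loadings, ncomp)
  intercept <- object$y_mean - sum(object$x_mean * b)
  as.vector(X %*% b) + intercept
}

#' @export
coef.plsr_nipals <- function(object, ...) {
  c("(Intercept)" = object$intercept,
    stats::setNames(object$coefficients,
                    paste0("ch", seq_along(object$coefficients))))
}

#' @export
fitted.plsr_nipals <- function(object, ...) object$fitted.values

#' @export
residuals.plsr_nipals <- function(object, ...) object$residuals

#' @export
print.plsr_nipals <- function(x, ...) {
  cat("NIPALS PLS regression:", x$n_lv, "latent variable(s),",
      length(x$coefficients), "channels,", length(x$y), "samples\n")
  cat(sprintf("  RMSEC %.4g, R2 %.4f\n",
              rmse(x$y, x$fitted.values),
              r_squared(x$y, x$fitted.values)))
  invisible(x)
}

#' @export
summary.plsr_nipals <- function(object, ...) {
  expl <- cumsum(object$y_loadings^2 * colSums(object$scores^2)) /
    sum((object$y - object$y_mean)^2)
  out <- list(n_lv = object$n_lv,
              rmsec = rmse(object$y, object$fitted.values),
              r2 = r_squared(object$y, object$fitted.values),
              y_variance_explained = expl)
  class(out) <- "summary.plsr_nipals"
  out
}

#' @export
print.summary.plsr_nipals <- function(x, ...) {
  cat("NIPALS PLS regression\n")
  cat(sprintf("  latent variables: %d\n  RMSEC: %.6g\n  R2: %.4f\n",
              x$n_lv, x$rmsec, x$r2))
  cat("  cumulative y-variance explained:\n")
  print(round(x$y_variance_explained, 4))
  invisible(x)
}

#' Leave-one-out cross-validated RMSE per latent-variable count
#'
#' For every sample i, the model is refitted on the remaining n-1
#' samples (including re-centring, and refitting any data-dependent
#' pretreatment state when `pretreat` is supplied) and sample i is
#' predicted with 1..`max_lv` latent variables.
#' \eqn{RMSECV(k) = \sqrt{\sum_i (\hat y_{(i)} - y_i)^2 / n}}.
#'
#' @param X predictor matrix (raw channels if `pretreat` given,
#'   otherwise already pretreated).
#' @param y response vector.
#' @param max_lv largest latent-variable count; `<= nrow(X) - 2`.
#' @param pretreat optional [pp_spec()] refitted inside each fold (its
#'   data-dependent state, e.g. the MSC reference, is then estimated
#'   without the held-out sample).
#' @param nu,segments passed to [pp_fit()] when `pretreat` is given.
#' @return Numeric vector `rmsecv[k]`, k = 1..max_lv.
#' @export
loo_rmsecv <- function(X, y, max_lv, pretreat = NULL,
                       nu = seq_len(ncol(X)), segments = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  if (max_lv > n - 2) stop("max_lv must be <= samples - 2")
  refit_pp <- !is.null(pretreat) && pp_has_state(pretreat)
  if (!is.null(pretreat) && !refit_pp) {
    X <- pp_fit(pretreat, X, nu, segments)$train
    pretreat <- NULL
  }
  pred <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    xi <- X[i, , drop = FALSE]
    if (refit_pp) {
      fp <- pp_fit(pretreat, Xi, nu, segments)
      Xi <- fp$train
      xi <- pp_apply(fp, xi)
    }
    fit <- plsr_nipals(Xi, y[-i], max_lv)
    for (k in seq_len(max_lv))
      pred[i, k] <- predict(fit, xi, ncomp = k)
  }
  sqrt(colMeans((pred - y)^2))
}

pp_has_state <- function(spec) {
  any(vapply(spec$steps, function(s) s$method == "msc", logical(1)))
}

#' Select the number of latent variables
#'
#' Returns the latent-variable count minimizing the cross-validated
#' RMSE, considering at most `cap` components; ties are broken toward
#' fewer components (parsimony).
#'
#' @param rmsecv numeric RMSECV curve, element k = k components.
#' @param cap largest component count considered (default 10).
#' @return Integer component count.
#' @export
select_lv <- function(rmsecv, cap = 10) {
  if (length(rmsecv) == 0) stop("empty RMSECV curve")
  curve <- rmsecv[seq_len(min(length(rmsecv), cap))]
  which.min(curve)  # which.min returns the first (fewest-LV) minimum
}
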