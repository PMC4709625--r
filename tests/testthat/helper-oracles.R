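# Independent reference computations used to validate the package
# implementations. These deliberately use different algorithms (explicit
# per-window lm() fits, textbook per-component NIPALS with score-space
# prediction, brute-force cross-validation loops).

# Savitzky-Golay oracle: at every channel, fit the windowed polynomial
# with lm() and differentiate it analytically at the channel position.
sg_oracle <- function(x, window = 17, polyorder = 2, deriv_order = 1,
                      step = 1) {
  n <- length(x)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    d <- (lo:hi) - i
    fit <- stats::lm(x[lo:hi] ~ poly(d, polyorder, raw = TRUE))
    co <- stats::coef(fit)
    out[i] <- if (deriv_order == 1) co[2] else 2 * co[3]
  }
  out / step^deriv_order
}

# Textbook single-response NIPALS, coded independently: predictions are
# made in score space (sequentially projecting and deflating the new
# sample), never through an assembled coefficient vector.
oracle_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- list(); P <- list(); q <- numeric(ncomp)
  for (a in 1:ncomp) {
    w <- drop(t(E) %*% f)
    w <- w / sqrt(sum(w * w))
    t_a <- drop(E %*% w)
    p <- drop(t(E) %*% t_a) / sum(t_a * t_a)
    q[a] <- sum(f * t_a) / sum(t_a * t_a)
    E <- E - outer(t_a, p)
    f <- f - t_a * q[a]
    W[[a]] <- w; P[[a]] <- p
  }
  list(
    predict = function(Xnew) {
      Xnew <- if (is.null(dim(Xnew))) matrix(Xnew, 1) else as.matrix(Xnew)
      apply(Xnew, 1, function(x) {
        e <- x - xm
        yhat <- ym
        for (a in 1:ncomp) {
          t_a <- sum(e * W[[a]])
          yhat <- yhat + t_a * q[a]
          e <- e - t_a * P[[a]]
        }
        yhat
      })
    })
}

# brute-force LOO: one full refit per (fold, component count)
loo_oracle <- function(X, y, max_lv) {
  n <- nrow(X)
  sapply(seq_len(max_lv), function(k) {
    pred <- vapply(seq_len(n), function(i) {
      fit <- plsr_nipals(X[-i, , drop = FALSE], y[-i], k)
      predict(fit, X[i, , drop = FALSE])
    }, numeric(1))
    sqrt(mean((pred - y)^2))
  })
}

# compact study used where the full-size campaign is unnecessary
small_config <- function(...) {
  study_config(spectra_cadence = 1, reference_cadence = 2,
               water_add_duration = 10, thermostat_duration = 20, ...)
}

random_spectra <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}
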