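test_that("SG derivative matches the windowed polynomial-fit oracle", {
  # exact cases: constants, lines, quadratics
  n <- 40
  nu <- seq(4000, by = 8, length.out = n)
  const <- matrix(5, 1, n)
  expect_equal(sg_derivative(const, 17, 2, 1, step = 8),
               matrix(0, 1, n), tolerance = 1e-12)
  lin <- matrix(2 + 0.003 * nu, 1, n)
  expect_equal(sg_derivative(lin, 17, 2, 1, step = 8),
               matrix(0.003, 1, n), tolerance = 1e-9)
  quad <- matrix((nu / 1000)^2, 1, n)
  d1 <- sg_derivative(quad, 17, 2, 1, step = 8)
  expect_equal(d1[1, ], 2 * nu / 1e6, tolerance = 1e-9)

  # random spectra against the brute-force per-window lm() oracle,
  # including the asymmetric edge windows
  X <- random_spectra(4, 60, seed = 7)
  for (cfg in list(c(17, 2, 1), c(17, 2, 2), c(9, 3, 1), c(5, 2, 2))) {
    got <- sg_derivative(X, cfg[1], cfg[2], cfg[3], step = 8)
    want <- t(apply(X, 1, sg_oracle, window = cfg[1],
                    polyorder = cfg[2], deriv_order = cfg[3], step = 8))
    expect_equal(got, want, tolerance = 1e-10)
  }

  expect_error(sg_derivative(X, 16, 2, 1), "odd")
  expect_error(sg_derivative(X, 5, 2, 2, segments = rep(1, 60)), NA)
  expect_error(sg_derivative(random_spectra(2, 10), 17, 2, 1),
               "too few channels")
  expect_error(sg_derivative(X, 17, 2, 3), "deriv_order")
})

test_that("SNV centres and scales every spectrum", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  X <- random_spectra(5, 30)
  Z <- snv(X)
  expect_equal(rowMeans(Z), rep(0, 5))
  expect_equal(apply(Z, 1, sd), rep(1, 5))
  # affine invariance
  expect_equal(snv(3.2 * X + 7), Z)
  expect_error(snv(matrix(4, 2, 10)), "zero-variance spectrum at row 1")
})

test_that("MSC inverts additive/multiplicative scatter against its reference", {
  X <- random_spectra(6, 50, seed = 3)
  ref <- msc_fit(X)
  expect_equal(ref, colMeans(X))
  # x = 2*ref + 1 is corrected back to ref exactly; x = ref unchanged
  expect_equal(msc_apply(rbind(2 * ref + 1), ref), rbind(ref),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(msc_apply(rbind(ref), ref), rbind(ref),
               tolerance = 1e-12, ignore_attr = TRUE)
  # round-trip property: corrected spectra regress on ref with slope 1,
  # intercept 0
  Z <- msc_apply(X, ref)
  for (i in 1:6) {
    co <- coef(lm(Z[i, ] ~ ref))
    expect_equal(unname(co), c(0, 1), tolerance = 1e-8)
  }
  expect_error(msc_apply(rbind(rep(1, 50)) * 0 + ref * 1e-15, ref),
               "degenerate scatter fit")
})

test_that("vector normalization yields zero-mean unit-norm spectra", {
  expect_equal(vector_normalize(matrix(c(1, 2, 3), 1)),
               matrix(c(-1, 0, 1) / sqrt(2), 1))
  X <- random_spectra(5, 20)
  Z <- vector_normalize(X)
  expect_equal(sqrt(rowSums(Z^2)), rep(1, 5))
  expect_equal(rowMeans(Z), rep(0, 5), tolerance = 1e-15)
  # scale invariance
  expect_equal(vector_normalize(0.2 * X), Z)
  expect_error(vector_normalize(matrix(1, 1, 5)), "zero vector")
})

test_that("straight line subtraction removes exactly the OLS baseline", {
  nu <- seq(5000, by = 8, length.out = 30)
  lin <- rbind(3 + 0.01 * nu)
  expect_equal(straight_line_subtraction(lin, nu), 0 * lin,
               tolerance = 1e-9)
  # baseline invariance
  X <- random_spectra(4, 30, seed = 5)
  expect_equal(straight_line_subtraction(X + 2 + outer(rep(1, 4), 0.05 * nu),
                                         nu),
               straight_line_subtraction(X, nu), tolerance = 1e-7)
  # quadratic: residual about its own OLS line, closed form
  quad <- rbind(nu^2)
  vc <- nu - mean(nu)
  bhat <- sum(vc * nu^2) / sum(vc^2)
  expect_equal(straight_line_subtraction(quad, nu)[1, ],
               nu^2 - mean(nu^2) - bhat * vc, tolerance = 1e-8)
})

test_that("constant offset elimination subtracts the spectrum minimum", {
  expect_equal(constant_offset(matrix(c(1, 2, 3), 1)),
               matrix(c(0, 1, 2), 1))
  X <- random_spectra(3, 15)
  expect_equal(constant_offset(X + 5), constant_offset(X))
  Z <- constant_offset(X)
  expect_equal(constant_offset(Z), Z)
  expect_equal(apply(Z, 1, min), rep(0, 3))
})

test_that("pipelines compose, store MSC state, and never refit on new data", {
  nu <- seq(4000, by = 8, length.out = 50)
  # raw pipeline is the identity
  X <- random_spectra(5, 50, seed = 11)
  raw <- pp_fit(pp_spec(pp_step("raw")), X, nu)
  expect_identical(raw$train, X)
  expect_identical(pp_apply(raw, X), X)

  # derivative then SLS annihilates any straight-line spectrum
  lin <- outer(c(1, 2), rep(1, 50)) + outer(c(0.01, 0.02), nu)
  spec <- pp_spec(pp_step("sg_deriv", window = 17), pp_step("sls"))
  f <- pp_fit(spec, lin, nu)
  expect_equal(f$train, 0 * lin, tolerance = 1e-9)

  # MSC reference comes from the calibration set and is reused
  mspec <- pp_spec(pp_step("msc"), pp_step("sg_deriv", window = 9))
  fm <- pp_fit(mspec, X, nu)
  Xnew <- random_spectra(3, 50, seed = 12)
  out1 <- pp_apply(fm, Xnew)
  out2 <- pp_apply(fm, Xnew)
  expect_identical(out1, out2)
  # applying an unfitted MSC pipeline errors
  broken <- fm
  broken$state <- list()
  expect_error(pp_apply(broken, Xnew), "MSC reference missing")
  expect_error(pp_spec(pp_step("msc"), pp_step("msc")), "at most once")

  # channel count preserved by every standard pipeline
  for (s in standard_pretreatments())
    expect_equal(dim(pp_fit(s, X, nu)$train), dim(X))
})
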