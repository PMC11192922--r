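test_that("Gaussian kernel evaluates exactly", {
  expect_equal(gaussian_kernel(0, 1000), 1)
  expect_equal(gaussian_kernel(1000, 1000), exp(-1))
  expect_equal(gaussian_kernel(2000, 1000), exp(-4))
  expect_error(gaussian_kernel(10, 0), "positive")
  expect_error(gaussian_kernel(-1, 10), "nonnegative")
})

test_that("local WLS solves the normal equations", {
  X <- cbind(1, c(0, 1, 2))
  beta <- fit_local(X, c(0, 1, 4), rep(1, 3))
  expect_equal(unname(beta[1]), -1 / 3, tolerance = 1e-12)
  expect_equal(unname(beta[2]), 2, tolerance = 1e-12)
  # all-one weights = OLS
  set.seed(8)
  Xr <- cbind(1, stats::runif(10), stats::runif(10))
  yr <- stats::runif(10)
  expect_equal(unname(fit_local(Xr, yr, rep(1, 10))[1:3]),
               unname(coef(stats::lm(yr ~ Xr[, 2] + Xr[, 3]))),
               tolerance = 1e-9)
  # exact linear data recovered under any positive weights
  y_lin <- drop(Xr %*% c(2, -1, 0.5))
  w <- stats::runif(10, 0.1, 1)
  expect_equal(as.vector(fit_local(Xr, y_lin, w)), c(2, -1, 0.5),
               tolerance = 1e-9)
})

test_that("LOOCV equals the brute-force refit loop and handles edge cases", {
  set.seed(12)
  u <- gen_coordinates(5, "jittered", 2)
  X <- cbind(1, stats::runif(5))
  y <- stats::runif(5)
  D <- distance_matrix(u)
  b <- 8e5
  expect_equal(loocv(X, y, D, b), oracle_loocv(X, y, D, b),
               tolerance = 1e-10)
  # noiseless globally linear data predicts perfectly
  y_lin <- drop(X %*% c(1, 2))
  expect_lt(loocv(X, y_lin, D, 5e6), 1e-16 * 5 + 1e-18)
  # bandwidth so small no neighbor has numeric weight -> Inf
  expect_equal(loocv(X, y, D, 1), Inf)
})

test_that("golden-section bandwidth matches a dense grid argmin", {
  sim <- gen_gwr_dataset(n = 25, seed = 9)
  X <- cbind(1, sim$X)
  D <- distance_matrix(sim$units)
  sel <- select_bandwidth(X, sim$y, D)
  offd <- D[upper.tri(D)]
  offd <- offd[offd > 0]
  grid <- exp(seq(log(min(offd)), log(2 * max(offd)), length.out = 500))
  cvs <- vapply(grid, function(b) loocv(X, sim$y, D, b), numeric(1))
  kmin <- which.min(cvs)
  step <- log(grid[2] / grid[1])
  expect_lte(abs(log(sel$bandwidth / grid[kmin])), step)
  # optimality on the evaluated set and determinism
  expect_true(all(sel$cv <= sel$cv_curve$cv + 1e-12))
  sel2 <- select_bandwidth(X, sim$y, D)
  expect_identical(sel$bandwidth, sel2$bandwidth)
})

test_that("kernel weights become constant in the large-bandwidth limit", {
  sim <- gen_gwr_dataset(n = 30, seed = 5)
  sim$data[, c("lon", "lat")] <- shrink_layout(sim$units)[, c("lon", "lat")]
  fit <- gwr_fit(sim$data, response = "y", predictors = c("x1", "x2"),
                 bandwidth = 1e9)
  ols <- unname(coef(stats::lm(y ~ x1 + x2, sim$data)))
  for (i in c(1, 15, 30))
    expect_equal(unname(fit$coefficients[i, ]), ols, tolerance = 1e-6)
})

test_that("spatially constant coefficients and zero noise are recovered", {
  surf <- list(intercept = coefficient_surface("constant", value = 0.7),
               x1 = coefficient_surface("constant", value = -1.2),
               x2 = coefficient_surface("constant", value = 0.4))
  sim <- gen_gwr_dataset(n = 20, surfaces = surf, noise_sd = 0, seed = 3)
  fit <- gwr_fit(sim$data, response = "y", predictors = c("x1", "x2"),
                 bandwidth = 1e6)
  for (i in 1:20)
    expect_equal(unname(fit$coefficients[i, ]), c(0.7, -1.2, 0.4),
                 tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # adding noise inflates RSS monotonically in sigma
  for (s in 1:3) {
    rss <- vapply(c(0.01, 0.05, 0.2), function(sd) {
      simn <- gen_gwr_dataset(n = 20, surfaces = surf, noise_sd = sd,
                              seed = s)
      gwr_fit(simn$data, response = "y", predictors = c("x1", "x2"),
              bandwidth = 1e6)$rss
    }, numeric(1))
    expect_true(all(diff(rss) > 0))
  }
})

test_that("hat matrix, residuals and diagnostics are self-consistent", {
  sim <- gen_gwr_dataset(n = 18, seed = 14)
  fit <- gwr_fit(sim$data, response = "y", predictors = c("x1", "x2"),
                 bandwidth = 8e5)
  expect_equal(as.vector(fit$hat %*% sim$y), fit$fitted, tolerance = 1e-10)
  expect_equal(fit$residuals, sim$y - fit$fitted, tolerance = 1e-12)
  expect_equal(fit$rss, sum(fit$residuals^2), tolerance = 1e-12)
  expect_gt(fit$trS, 0)
  expect_lt(fit$trS, fit$n)
  d <- gwr_diagnostics(fit)
  expect_equal(d$residual_squares, fit$rss)
  expect_lte(d$r2, 1)
})

test_that("AICc matches a separately coded formula on a frozen fit", {
  sim <- gen_gwr_dataset(n = 10, seed = 21)
  fit <- gwr_fit(sim$data, response = "y", predictors = c("x1", "x2"),
                 bandwidth = 2e6)
  n <- fit$n
  sigma <- sqrt(sum((sim$y - fit$fitted)^2) / n)
  aicc_oracle <- 2 * n * log(sigma) + n * log(2 * pi) +
    n * (n + sum(diag(fit$hat))) / (n - 2 - sum(diag(fit$hat)))
  expect_equal(fit$aicc, aicc_oracle, tolerance = 1e-10)
})

test_that("coefficient surfaces are recovered on the default dataset", {
  sim <- gen_gwr_dataset()
  fit <- gwr_fit(sim$data, response = "y", predictors = c("x1", "x2"),
                 bandwidth = "auto")
  for (k in seq_len(ncol(sim$beta_true))) {
    truth <- sim$beta_true[, k]
    est <- fit$coefficients[, k]
    if (stats::sd(truth) > 0) expect_gt(stats::cor(est, truth), 0.9)
    expect_lt(stats::median(abs(est - truth)), 0.1)
  }
})

test_that("cross-sectional contract and failure modes are enforced", {
  sim <- gen_gwr_dataset(n = 12, seed = 2)
  two_years <- rbind(cbind(sim$data, year = 2013),
                     cbind(sim$data, year = 2018))
  expect_error(gwr_fit(two_years, response = "y",
                       predictors = c("x1", "x2")), "single year")
  expect_error(gwr_fit(sim$data, response = "y", predictors = c("x1", "x2"),
                       bandwidth = -5), "positive")
  expect_error(gwr_fit(sim$data[1:3, ], response = "y",
                       predictors = c("x1", "x2")), "n >=")
})
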