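#' Fixed Gaussian distance-decay kernel
#'
#' w = exp(-(d / b)^2): weight 1 at the regression point, e^-1 at one
#' bandwidth, effectively zero beyond a few bandwidths.
#'
#' @param d Distance(s), same units as `b` (meters by default elsewhere).
#' @param b Bandwidth, > 0.
#' @return Weights in (0, 1].
#' @export
gaussian_kernel <- function(d, b) {
  if (length(b) != 1L || !is.finite(b) || b <= 0)
    stop("bandwidth b must be a single positive number")
  if (any(d < 0)) stop("distances must be nonnegative")
  exp(-(d / b)^2)
}

#' Weighted least squares at one regression point
#'
#' Solves beta = (X' W X)^-1 X' W y with W = diag(w). If the normal matrix
#' is numerically singular a ridge jitter of 1e-8 times its mean diagonal
#' is added and the fit is flagged (attribute `"ridged"`).
#'
#' @param X Design matrix including the intercept column.
#' @param y Response vector.
#' @param w Nonnegative observation weights; at least ncol(X) must be
#'   strictly positive.
#' @return Coefficient vector with attribute `ridged` (logical).
#' @export
fit_local <- function(X, y, w) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || nrow(X) != length(w))
    stop("X, y, w must have matching rows")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w > 0) < ncol(X))
    stop("need at least ncol(X) observations with positive weight")
  A <- crossprod(X, w * X)
  bvec <- crossprod(X, w * y)
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(beta)) {
    ridge <- 1e-8 * mean(diag(A))
    beta <- tryCatch(solve(A + diag(ridge, ncol(A)), bvec),
                     error = function(e) NULL)
    ridged <- TRUE
    if (is.null(beta))
      stop("singular local fit not recoverable by ridge jitter")
  }
  beta <- as.vector(beta)
  names(beta) <- colnames(X)
  attr(beta, "ridged") <- ridged
  beta
}

#' Leave-one-out cross-validation score for a bandwidth
#'
#' CV(b) = sum_i (y_i - yhat_(i))^2, where yhat_(i) is the prediction at
#' point i from a local fit that excludes observation i (w_ii = 0). If any
#' held-out local fit is singular, CV is +Inf for that bandwidth.
#'
#' @param X Design matrix with intercept column.
#' @param y Response vector.
#' @param D Pairwise distance matrix between observation locations.
#' @param b Bandwidth (same units as `D`).
#' @return The CV score (possibly `Inf`).
#' @export
loocv <- function(X, y, D, b) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2L) stop("need n >= ncol(X) + 2 observations")
  cv <- 0
  for (i in seq_len(n)) {
    w <- gaussian_kernel(D[i, ], b)
    w[i] <- 0
    if (sum(w > 0) < p) return(Inf)
    A <- crossprod(X, w * X)
    beta <- tryCatch(solve(A, crossprod(X, w * y)),
                     error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta))) return(Inf)
    cv <- cv + (y[i] - drop(X[i, ] %*% beta))^2
  }
  cv
}

#' Select the GWR bandwidth by minimizing the LOOCV score
#'
#' Scans a 20-point log-spaced grid over \[d_min, 2 d_max\] (smallest
#' nonzero and largest pairwise distances) to bracket the minimum, then
#' refines with golden-section search on the log scale to 1e-3 relative
#' tolerance. Deterministic for identical input.
#'
#' @inheritParams loocv
#' @return A list with `bandwidth` (the argmin), `cv` (its score) and
#'   `cv_curve` (data frame of evaluated `(bandwidth, cv)` pairs).
#' @export
select_bandwidth <- function(X, y, D) {
  offd <- D[upper.tri(D)]
  offd <- offd[offd > 0]
  if (!length(offd)) stop("all locations coincide: no bandwidth scale")
  lo <- log(min(offd))
  hi <- log(2 * max(offd))
  grid <- exp(seq(lo, hi, length.out = 20))
  cvs <- vapply(grid, function(b) loocv(X, y, D, b), numeric(1))
  curve <- data.frame(bandwidth = grid, cv = cvs)
  if (all(!is.finite(cvs)))
    stop("no bandwidth on the scan grid gives a valid fit")
  k <- which.min(cvs)
  a <- log(grid[max(k - 1L, 1L)])
  d <- log(grid[min(k + 1L, length(grid))])
  gr <- (sqrt(5) - 1) / 2
  f <- function(lb) loocv(X, y, D, exp(lb))
  x1 <- d - gr * (d - a); x2 <- a + gr * (d - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((d - a) > 1e-3) {
    if (f1 <= f2) {
      d <- x2; x2 <- x1; f2 <- f1
      x1 <- d - gr * (d - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (d - a); f2 <- f(x2)
    }
  }
  cand <- c(grid[k], exp((a + d) / 2))
  cand_cv <- c(cvs[k], loocv(X, y, D, cand[2]))
  best <- which.min(cand_cv)
  curve <- rbind(curve, data.frame(bandwidth = cand[2], cv = cand_cv[2]))
  curve <- curve[order(curve$bandwidth), ]
  list(bandwidth = cand[best], cv = cand_cv[best], cv_curve = curve)
}

#' Fit a geographically weighted regression
#'
#' At every observation location a weighted least-squares regression of the
#' response on the predictors is calibrated with Gaussian kernel weights
#' (self-weight 1), giving spatially varying coefficients. Global
#' diagnostics use the hat matrix S (row i: x_i' (X'W_i X)^-1 X'W_i):
#' R^2 = 1 - RSS/TSS, adjusted R^2 with tr(S) effective parameters, and
#' AICc = 2n log(sigma_hat) + n log(2 pi) + n (n + tr(S)) / (n - 2 - tr(S)).
#'
#' @param data Data frame with `lon`, `lat`, the response column and the
#'   predictor columns; one year / cross-section at a time (a `year` column,
#'   if present, must be constant).
#' @param response Name of the response column (default `"esi"`).
#' @param predictors Character vector of predictor column names.
#' @param bandwidth Positive bandwidth in distance units, or `"auto"` for
#'   LOOCV selection via [select_bandwidth()].
#' @param method Distance method, see [distance_matrix()].
#' @param standardize If `TRUE`, z-score the predictors before fitting.
#' @return Object of class `gwr_fit`: list with `local` (per-unit data
#'   frame: id, coefficients, fitted, residual, local R^2, hat diagonal),
#'   `coefficients` matrix, `bandwidth`, `cv`, `trS`, `rss`, `r2`,
#'   `adj_r2`, `aicc`, `fitted`, `residuals`, `hat` (full S matrix).
#' @export
gwr_fit <- function(data, response = "esi",
                    predictors = c("urbanization", "industrial_structure",
                                   "fdi"),
                    bandwidth = "auto",
                    method = c("haversine", "euclidean"),
                    standardize = FALSE) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  needed <- c("lon", "lat", response, predictors)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "))
  if ("year" %in% names(data) && length(unique(data$year)) > 1L)
    stop("gwr_fit is cross-sectional: filter to a single year first")
  n <- nrow(data)
  y <- data[[response]]
  Xp <- as.matrix(data[, predictors, drop = FALSE])
  if (standardize) Xp <- scale(Xp)
  X <- cbind(intercept = 1, Xp)
  p <- ncol(X)
  if (n < p + 2L) stop("need n >= p + 2 observations")
  D <- distance_matrix(data, method)

  cv <- NA_real_
  if (identical(bandwidth, "auto")) {
    sel <- select_bandwidth(X, y, D)
    bandwidth <- sel$bandwidth
    cv <- sel$cv
  } else {
    if (!is.numeric(bandwidth) || bandwidth <= 0)
      stop("bandwidth must be positive or 'auto'")
    cv <- loocv(X, y, D, bandwidth)
  }

  coefs <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  S <- matrix(NA_real_, n, n)
  local_r2 <- numeric(n)
  ridged <- logical(n)
  for (i in seq_len(n)) {
    w <- gaussian_kernel(D[i, ], bandwidth)
    beta <- fit_local(X, y, w)
    ridged[i] <- attr(beta, "ridged")
    coefs[i, ] <- beta
    A <- crossprod(X, w * X)
    if (ridged[i]) A <- A + diag(1e-8 * mean(diag(A)), p)
    S[i, ] <- drop(X[i, , drop = FALSE] %*% solve(A, t(X * w)))
    yhat_i <- drop(X %*% beta)
    ybar_w <- sum(w * y) / sum(w)
    tss_w <- sum(w * (y - ybar_w)^2)
    rss_w <- sum(w * (y - yhat_i)^2)
    local_r2[i] <- if (tss_w > 0) 1 - rss_w / tss_w else NA_real_
  }
  fitted <- as.vector(S %*% y)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  trS <- sum(diag(S))
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - trS - 1)
  if (n - 2 - trS <= 0)
    stop("AICc undefined: effective parameters tr(S) too close to n")
  sigma <- sqrt(rss / n)
  aicc <- 2 * n * log(sigma) + n * log(2 * pi) +
    n * (n + trS) / (n - 2 - trS)

  local <- data.frame(
    id = if ("id" %in% names(data)) data$id else seq_len(n),
    name = if ("name" %in% names(data)) data$name else as.character(seq_len(n)),
    lon = data$lon, lat = data$lat,
    as.data.frame(coefs),
    fitted = fitted, residual = resid,
    local_r2 = local_r2, hat_diag = diag(S),
    ridged = ridged,
    stringsAsFactors = FALSE)

  out <- list(local = local, coefficients = coefs,
              response = response, predictors = predictors,
              bandwidth = bandwidth, cv = cv, trS = trS,
              rss = rss, r2 = r2, adj_r2 = adj_r2, aicc = aicc,
              fitted = fitted, residuals = resid, hat = S,
              y = y, n = n, method = method)
  class(out) <- "gwr_fit"
  out
}

#' Global GWR diagnostics table
#'
#' One-row summary of a fit: R^2, adjusted R^2, residual sum of squares,
#' bandwidth and AICc.
#'
#' @param fit A [gwr_fit()] object.
#' @return A one-row data frame.
#' @export
gwr_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "gwr_fit"))
  data.frame(r2 = fit$r2, adj_r2 = fit$adj_r2,
             residual_squares = fit$rss,
             bandwidth = fit$bandwidth, aicc = fit$aicc)
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf("GWR fit: n = %d, bandwidth = %.1f, tr(S) = %.2f\n",
              x$n, x$bandwidth, x$trS))
  cat(sprintf("  R2 = %.3f (adj %.3f), RSS = %.4f, AICc = %.3f\n",
              x$r2, x$adj_r2, x$rss, x$aicc))
  invisible(x)
}
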