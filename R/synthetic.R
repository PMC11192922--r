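# Bounding box of the synthetic study region (roughly mainland China).
SYN_LON <- c(75, 130)
SYN_LAT <- c(20, 50)

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate synthetic spatial-unit coordinates
#'
#' Places `n` units inside a China-like bounding box (lon 75-130 E, lat
#' 20-50 N) on a near-square lattice, optionally jittered by up to 20% of
#' the cell size in each direction (clamped to the box).
#'
#' @param n Number of units, >= 4.
#' @param layout `"grid"` or `"jittered"`.
#' @param seed Integer seed; the same seed reproduces the same coordinates.
#' @return Data frame `id, name, lon, lat`.
#' @export
gen_coordinates <- function(n, layout = c("jittered", "grid"), seed = 1) {
  layout <- match.arg(layout)
  if (n < 4L) stop("need at least 4 units")
  nr <- max(2L, floor(sqrt(n)))
  nc <- ceiling(n / nr)
  cell_w <- diff(SYN_LON) / nc
  cell_h <- diff(SYN_LAT) / nr
  g <- expand.grid(col = seq_len(nc), row = seq_len(nr))[seq_len(n), ]
  lon <- SYN_LON[1] + (g$col - 0.5) * cell_w
  lat <- SYN_LAT[1] + (g$row - 0.5) * cell_h
  if (layout == "jittered") {
    with_seed(seed, {
      lon <- lon + stats::runif(n, -0.2, 0.2) * cell_w
      lat <- lat + stats::runif(n, -0.2, 0.2) * cell_h
    })
    lon <- pmin(pmax(lon, SYN_LON[1]), SYN_LON[2])
    lat <- pmin(pmax(lat, SYN_LAT[1]), SYN_LAT[2])
  }
  data.frame(id = sprintf("U%03d", seq_len(n)),
             name = sprintf("unit_%03d", seq_len(n)),
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

#' Generate a synthetic PSR indicator panel
#'
#' Emulates the structure of a provincial forest-security panel: positive
#' status indicators drawn uniform on plausible positive ranges, negative
#' pressure indicators drawn log-normal (heavy-tailed, like density or
#' emission intensities), positive response indicators drawn uniform on
#' small fractions. Optionally one unit is forced to the column-wise optimum
#' of every indicator, making it a known ESI maximizer.
#'
#' @param n_units Number of spatial units (default 30, two years — the
#'   panel shape of a provincial cross-section study).
#' @param years Integer vector of years.
#' @param spec An [indicator_spec()].
#' @param seed Integer seed.
#' @param best_unit If `TRUE`, unit 1 gets the most favorable value of
#'   every indicator in every year.
#' @return An `indicator_panel` (see [read_indicator_panel()]).
#' @export
gen_indicator_panel <- function(n_units = 30, years = c(2013, 2018),
                                spec = default_indicator_spec(), seed = 1,
                                best_unit = FALSE) {
  if (nrow(spec) < 1L) stop("spec must be non-empty")
  units <- gen_coordinates(n_units, "jittered", seed)
  m <- n_units * length(years)
  with_seed(seed + 1L, {
    vals <- matrix(NA_real_, m, nrow(spec))
    for (j in seq_len(nrow(spec))) {
      vals[, j] <- switch(spec$block[j],
        status = stats::runif(m, 5, 80),
        pressure = stats::rlnorm(m, meanlog = log(50), sdlog = 1),
        response = stats::runif(m, 0.01, 0.99))
    }
  })
  colnames(vals) <- spec$name
  df <- data.frame(
    id = rep(units$id, times = length(years)),
    name = rep(units$name, times = length(years)),
    lon = rep(units$lon, times = length(years)),
    lat = rep(units$lat, times = length(years)),
    year = rep(years, each = n_units),
    vals, stringsAsFactors = FALSE)
  if (best_unit) {
    rows1 <- which(df$id == units$id[1])
    for (j in seq_len(nrow(spec))) {
      col <- spec$name[j]
      # most favorable value: maximum of a positive indicator, minimum of
      # a negative one
      df[rows1, col] <- if (spec$orientation[j] == "positive")
        max(df[[col]]) else min(df[[col]])
    }
  }
  as_indicator_panel(df, spec)
}

#' Define a coefficient surface
#'
#' True spatially varying coefficient used by the synthetic GWR generator:
#' constant (`value`), planar (`a + b * (lon - lon0) + c * (lat - lat0)`) or
#' an isotropic Gaussian bump
#' (`amplitude * exp(-((lon-c1)^2 + (lat-c2)^2) / (2 width^2))`).
#'
#' @param kind `"constant"`, `"planar"` or `"gaussian_bump"`.
#' @param ... Parameters: `value`; or `a`, `b`, `c` (with optional `lon0`,
#'   `lat0` centering, default box center); or `center` (length-2),
#'   `amplitude`, `width` (degrees).
#' @return An object of class `coefficient_surface`.
#' @export
coefficient_surface <- function(kind = c("constant", "planar",
                                         "gaussian_bump"), ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  defaults <- switch(kind,
    constant = list(value = 1),
    planar = list(a = 0, b = 0, c = 0,
                  lon0 = mean(SYN_LON), lat0 = mean(SYN_LAT)),
    gaussian_bump = list(center = c(mean(SYN_LON), mean(SYN_LAT)),
                         amplitude = 1, width = 10))
  pars <- utils::modifyList(defaults, pars)
  out <- list(kind = kind, parameters = pars)
  class(out) <- "coefficient_surface"
  out
}

#' Evaluate a coefficient surface at coordinates
#'
#' @param surface A [coefficient_surface()].
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @return Numeric vector of surface values.
#' @export
eval_surface <- function(surface, lon, lat) {
  stopifnot(inherits(surface, "coefficient_surface"))
  p <- surface$parameters
  switch(surface$kind,
    constant = rep(p$value, length(lon)),
    planar = p$a + p$b * (lon - p$lon0) + p$c * (lat - p$lat0),
    gaussian_bump = p$amplitude *
      exp(-((lon - p$center[1])^2 + (lat - p$center[2])^2) /
            (2 * p$width^2)))
}

#' Default true coefficient surfaces for the synthetic GWR dataset
#'
#' Intercept: a gentle plane; first driver: a Gaussian bump centered in the
#' southwest of the box, with scale (width 15 degrees, about a quarter of
#' the region) chosen so the spatial variation is resolvable by a local
#' estimator at the default sample size; second driver: spatially constant.
#'
#' @return Named list of [coefficient_surface()] objects
#'   (`intercept`, `x1`, `x2`).
#' @export
default_surfaces <- function() {
  list(
    intercept = coefficient_surface("planar", a = 0.5, b = 0.01, c = 0.01),
    x1 = coefficient_surface("gaussian_bump", center = c(105, 32),
                             amplitude = 1, width = 15),
    x2 = coefficient_surface("constant", value = 0.5))
}

#' Generate a synthetic GWR dataset with known coefficient surfaces
#'
#' Drivers are independent uniform \[0, 1\]; the response is assembled
#' exactly from the generating model
#' y_i = beta_0(u_i, v_i) + sum_k beta_k(u_i, v_i) x_ik + eps_i with
#' eps_i ~ Normal(0, noise_sd^2), so the true coefficient at every location
#' is known and recovery can be scored.
#'
#' @param n Number of locations, >= 10 (default 100).
#' @param surfaces List of [coefficient_surface()]s; the first is the
#'   intercept, the rest one per driver.
#' @param noise_sd Noise standard deviation, >= 0 (default 0.05).
#' @param seed Integer seed (default 42).
#' @param layout Coordinate layout, see [gen_coordinates()].
#' @return Object of class `gwr_sim`: list with `units`, `X` (drivers),
#'   `y`, `beta_true` (n x p matrix of surface values), `noise`,
#'   `surfaces`, `noise_sd`, `seed`, and `data` (a data frame ready for
#'   [gwr_fit()], response column `y`, drivers `x1`, `x2`, ...).
#' @export
gen_gwr_dataset <- function(n = 100, surfaces = default_surfaces(),
                            noise_sd = 0.05, seed = 42,
                            layout = "jittered") {
  if (length(surfaces) < 1L) stop("need at least an intercept surface")
  if (n < 10L) stop("need n >= 10 locations")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  units <- gen_coordinates(n, layout, seed)
  p_drv <- length(surfaces) - 1L
  with_seed(seed + 1L, {
    X <- matrix(stats::runif(n * p_drv), n, p_drv)
    noise <- stats::rnorm(n, 0, noise_sd)
  })
  colnames(X) <- paste0("x", seq_len(p_drv))
  beta_true <- vapply(surfaces, eval_surface,
                      numeric(n), lon = units$lon, lat = units$lat)
  colnames(beta_true) <- c("intercept", colnames(X))
  y <- beta_true[, 1] + rowSums(beta_true[, -1, drop = FALSE] * X) + noise
  data <- data.frame(units, X, y = y, stringsAsFactors = FALSE)
  out <- list(units = units, X = X, y = y, beta_true = beta_true,
              noise = noise, surfaces = surfaces, noise_sd = noise_sd,
              seed = seed, data = data)
  class(out) <- "gwr_sim"
  out
}
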