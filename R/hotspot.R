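EARTH_RADIUS_M <- 6371000

#' Great-circle (haversine) distance between two points
#'
#' @param a,b Numeric length-2 vectors `c(lon, lat)` in decimal degrees.
#' @return Distance in meters on a sphere of radius 6,371,000 m.
#' @export
#' @examples
#' haversine_distance(c(0, 0), c(0, 90))  # a quarter meridian
haversine_distance <- function(a, b) {
  check_lonlat(rbind(a, b))
  geosphere::distHaversine(a, b, r = EARTH_RADIUS_M)
}

check_lonlat <- function(coords) {
  if (any(coords[, 1] < -180 | coords[, 1] > 180))
    stop("lon out of [-180, 180]")
  if (any(coords[, 2] < -90 | coords[, 2] > 90))
    stop("lat out of [-90, 90]")
  invisible(coords)
}

#' Pairwise distance matrix for spatial units
#'
#' @param units Data frame with `lon` and `lat` columns (degrees), or a
#'   two-column matrix.
#' @param method `"haversine"` (meters on the sphere) or `"euclidean"`
#'   (degrees treated as planar coordinates).
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(units, method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  coords <- as.matrix(as.data.frame(units)[, c("lon", "lat")])
  check_lonlat(coords)
  if (method == "haversine") {
    d <- geosphere::distm(coords, fun = function(p1, p2)
      geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M))
  } else {
    d <- as.matrix(stats::dist(coords))
  }
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Binary distance-band spatial weights
#'
#' w_ij = 1 iff d_ij <= threshold; the diagonal is always 1 (the Gi* "star"
#' form includes the focal unit). The default threshold is the largest
#' nearest-neighbor distance, the smallest band that leaves no unit
#' isolated.
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param threshold Band distance in the units of `D`, or `NULL` for the
#'   no-isolate default.
#' @return A list with the binary matrix `W` and the `threshold` used.
#' @export
distance_band_weights <- function(D, threshold = NULL) {
  D <- as.matrix(D)
  if (is.null(threshold)) {
    off <- D
    diag(off) <- Inf
    threshold <- max(apply(off, 1, min))
  }
  if (threshold < 0) stop("threshold must be nonnegative")
  W <- (D <= threshold) * 1
  diag(W) <- 1
  list(W = W, threshold = threshold)
}

#' Local Getis-Ord Gi* statistic (ratio form)
#'
#' G_i* = sum_j w_ij x_j / sum_j x_j: the share of the total attribute mass
#' lying within unit i's band, focal unit included.
#'
#' @param x Nonnegative attribute values, one per unit.
#' @param W Binary weights matrix (see [distance_band_weights()]).
#' @return Vector of ratios, one per unit.
#' @export
gi_star <- function(x, W) {
  W <- as.matrix(W)
  if (length(x) != nrow(W)) stop("length(x) must match dim(W)")
  if (any(x < 0)) stop("ratio-form Gi* needs nonnegative x")
  tot <- sum(x)
  if (tot == 0) stop("sum(x) is zero: Gi* ratio undefined")
  as.vector(W %*% x) / tot
}

#' Standardized Gi* z-scores
#'
#' Standardizes the local sums under the randomization null (Getis-Ord
#' moments): with Wi = sum_j w_ij, S1i = sum_j w_ij^2, xbar the mean and
#' S = sqrt(mean(x^2) - xbar^2),
#' z_i = (sum_j w_ij x_j - xbar Wi) / (S sqrt((n S1i - Wi^2) / (n - 1))).
#' A constant attribute (S = 0), or a band covering every unit (zero
#' denominator), yields z_i = 0.
#'
#' @param x Attribute values, one per unit (length >= 3).
#' @param W Binary weights matrix including the diagonal.
#' @return Vector of z-scores; positive values flag high-value clusters
#'   (hot spots), negative values low-value clusters (cold spots).
#' @export
gi_star_z <- function(x, W) {
  W <- as.matrix(W)
  n <- length(x)
  if (n < 3L) stop("need at least 3 units")
  if (n != nrow(W)) stop("length(x) must match dim(W)")
  xbar <- mean(x)
  s <- sqrt(max(mean(x^2) - xbar^2, 0))
  if (s == 0) return(rep(0, n))
  wi <- rowSums(W)
  s1i <- rowSums(W^2)
  num <- as.vector(W %*% x) - xbar * wi
  den <- s * sqrt(pmax(n * s1i - wi^2, 0) / (n - 1))
  z <- ifelse(den == 0, 0, num / den)
  z
}

#' Jenks natural-breaks classification
#'
#' Partitions values into `k` classes that are contiguous in sorted order,
#' minimizing the total within-class sum of squared deviations
#' (Fisher-Jenks dynamic programming, exact). Among cost ties the partition
#' with lexicographically smallest break indices is returned, so results
#' are deterministic.
#'
#' @param values Numeric vector.
#' @param k Number of classes, 1 <= k <= length(values).
#' @return A list with `assignment` (class 1..k per input value, in input
#'   order; class 1 holds the smallest values), `breaks` (upper value of
#'   each class) and `total_ssd`.
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 8, 9), 2)$assignment  # 1 1 2 2
jenks_breaks <- function(values, k) {
  n <- length(values)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= length(values)")
  if (any(!is.finite(values))) stop("values must be finite")
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {
    # SSD of sorted x[i..j]
    s1 <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - s1^2 / (j - i + 1), 0)
  }
  # opt[i, c]: minimal cost of splitting x[i..n] into c classes
  opt <- matrix(Inf, n + 1, k)
  for (i in n:1) opt[i, 1] <- seg_cost(i, n)
  if (k > 1) {
    for (cc in 2:k) {
      for (i in 1:(n - cc + 1)) {
        best <- Inf
        for (e in i:(n - cc + 1)) {
          v <- seg_cost(i, e) + opt[e + 1, cc - 1]
          if (v < best) best <- v
        }
        opt[i, cc] <- best
      }
    }
  }
  total <- opt[1, k]
  tol <- 1e-9 * (1 + abs(total))
  # greedy left-to-right reconstruction: earliest break achieving the optimum
  cls_sorted <- integer(n)
  start <- 1L
  breaks <- numeric(k)
  for (cc in seq_len(k)) {
    remaining <- k - cc
    if (remaining == 0L) {
      end <- n
    } else {
      for (e in start:(n - remaining)) {
        if (seg_cost(start, e) + opt[e + 1, remaining] <=
            opt[start, remaining + 1] + tol) {
          end <- e
          break
        }
      }
    }
    cls_sorted[start:end] <- cc
    breaks[cc] <- x[end]
    start <- end + 1L
    if (start > n && cc < k) stop("internal error: ran out of values")
  }
  assignment <- integer(n)
  assignment[ord] <- cls_sorted
  list(assignment = assignment, breaks = breaks,
       total_ssd = opt[1, k])
}

#' Classify units into four hot/cold-spot levels
#'
#' Applies 4-class Jenks natural breaks to the Gi* z-scores and labels the
#' classes, in ascending z order, cold, secondary cold, secondary hot, hot.
#'
#' @param z Gi* z-scores (length >= 4).
#' @return Ordered factor with levels
#'   `cold < secondary_cold < secondary_hot < hot`.
#' @export
classify_hotspots <- function(z) {
  if (length(z) < 4L) stop("need at least 4 units for 4 classes")
  jb <- jenks_breaks(z, 4L)
  lv <- c("cold", "secondary_cold", "secondary_hot", "hot")
  factor(lv[jb$assignment], levels = lv, ordered = TRUE)
}

#' Gi* hot/cold-spot analysis of an attribute over spatial units
#'
#' Convenience wrapper: builds the distance-band weights, computes the Gi*
#' ratio and z-score per unit and the four-level Jenks classification.
#'
#' @param units Data frame with `id`, `lon`, `lat` (and optionally `name`).
#' @param x Attribute values (e.g. ESI), one per unit, nonnegative.
#' @param threshold Band distance in meters, or `NULL` for the largest
#'   nearest-neighbor distance.
#' @param method Distance method, see [distance_matrix()].
#' @return Object of class `hotspot_result`: list with `table`
#'   (id, name, gi_star, z_score, hotclass), `threshold`, `W`.
#' @export
hotspot_analysis <- function(units, x, threshold = NULL,
                             method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  units <- as.data.frame(units)
  if (length(x) != nrow(units)) stop("one attribute value per unit required")
  D <- distance_matrix(units, method)
  bw <- distance_band_weights(D, threshold)
  g <- gi_star(x, bw$W)
  z <- gi_star_z(x, bw$W)
  out <- list(
    table = data.frame(
      id = units$id,
      name = if ("name" %in% names(units)) units$name else units$id,
      gi_star = g, z_score = z,
      hotclass = classify_hotspots(z),
      stringsAsFactors = FALSE),
    threshold = bw$threshold,
    W = bw$W)
  class(out) <- "hotspot_result"
  out
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat("Gi* hotspot analysis of", nrow(x$table), "units",
      sprintf("(band %.0f m)\n", x$threshold))
  print(table(x$table$hotclass))
  invisible(x)
}
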