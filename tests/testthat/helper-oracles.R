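# Independent brute-force oracles, deliberately coded as direct formula
# transcriptions (no shared code with the package internals they check).

# Entropy-weight chain: proportions -> entropy -> weights, one literal pass.
oracle_entropy_weights <- function(std_matrix) {
  m <- nrow(std_matrix)
  h <- numeric(ncol(std_matrix))
  for (j in seq_len(ncol(std_matrix))) {
    col <- std_matrix[, j]
    if (sum(col) == 0) { h[j] <- 1; next }
    p <- col / sum(col)
    acc <- 0
    for (i in seq_len(m)) if (p[i] > 0) acc <- acc + p[i] * log(p[i])
    h[j] <- -acc / log(m)
  }
  info <- 1 - h
  if (sum(info) == 0) rep(1 / length(h), length(h)) else info / sum(info)
}

# Getis-Ord randomization moments, one unit at a time.
oracle_gi_star_z <- function(x, W) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  vapply(seq_len(n), function(i) {
    Wi <- sum(W[i, ])
    S1i <- sum(W[i, ]^2)
    den <- S * sqrt((n * S1i - Wi^2) / (n - 1))
    if (den == 0) return(0)
    (sum(W[i, ] * x) - xbar * Wi) / den
  }, numeric(1))
}

# Exhaustive search over all contiguous partitions of the sorted values.
oracle_jenks_ssd <- function(x, k) {
  s <- sort(x)
  n <- length(s)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ssd(s))
  best <- Inf
  combs <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(combs))) {
    br <- c(0, combs[, ci], n)
    cost <- sum(vapply(seq_len(k), function(j)
      ssd(s[(br[j] + 1):br[j + 1]]), numeric(1)))
    if (cost < best) best <- cost
  }
  best
}

# Leave-one-out CV by literally refitting n times with diag-matrix algebra.
oracle_loocv <- function(X, y, D, b) {
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) {
    w <- exp(-(D[i, ] / b)^2)
    w[i] <- 0
    A <- t(X) %*% diag(w) %*% X
    beta <- solve(A, t(X) %*% diag(w) %*% y)
    total <- total + (y[i] - drop(X[i, , drop = FALSE] %*% beta))^2
  }
  total
}

# Shrink a layout towards its centroid (regional-extent variant).
shrink_layout <- function(units, factor = 0.3) {
  units$lon <- mean(units$lon) + factor * (units$lon - mean(units$lon))
  units$lat <- mean(units$lat) + factor * (units$lat - mean(units$lat))
  units
}

# Small well-formed panel CSV written to a temp file.
write_panel_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_spec <- function() {
  indicator_spec(name = c("s1", "p1"),
                 block = c("status", "pressure"),
                 orientation = c("positive", "negative"))
}
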