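#' Min-max standardize one indicator column
#'
#' Forward: (x - min) / (max - min); reverse: (max - x) / (max - min).
#' A constant column carries no ordering information and is mapped to 0.5
#' everywhere, so it cannot influence the index (its entropy weight is 0).
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @param direction `"forward"` (larger raw value scores higher) or
#'   `"reverse"`.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' standardize_column(c(2, 4, 10), "forward")  # 0, 0.25, 1
standardize_column <- function(values, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (length(values) < 2L) stop("need at least 2 values to standardize")
  if (!all(is.finite(values))) stop("values must all be finite")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0.5, length(values)))
  if (direction == "forward") (values - rng[1]) / (rng[2] - rng[1])
  else (rng[2] - values) / (rng[2] - rng[1])
}

#' Normalized Shannon entropy of a standardized column
#'
#' Converts the column to proportions p_i = y_i / sum(y) and returns
#' H = -sum(p_i log p_i) / log(m), where m is the number of rows, with the
#' convention 0 log 0 = 0. H is 1 for uniform proportions and 0 when all
#' mass sits on a single row. An all-zero column is defined to have H = 1
#' (no discriminating information).
#'
#' @param std_column Numeric vector in \[0, 1\], length >= 2.
#' @return Entropy H in \[0, 1\].
#' @export
information_entropy <- function(std_column) {
  m <- length(std_column)
  if (m < 2L) stop("need at least 2 values")
  if (any(std_column < 0)) stop("standardized values must be nonnegative")
  tot <- sum(std_column)
  if (tot == 0) return(1)
  p <- std_column / tot
  terms <- ifelse(p > 0, p * log(p), 0)
  h <- -sum(terms) / log(m)
  min(max(h, 0), 1)
}

#' Entropy weights for a block of standardized indicators
#'
#' Each indicator's weight is proportional to its information content
#' 1 - H_j, normalized to sum to one within the block. If every column is
#' uninformative (all H_j = 1) the weights fall back to equal.
#'
#' @param std_matrix Numeric matrix of standardized values, >= 2 rows.
#' @return A list with `entropy` (H_j per column) and `weights` (w_j,
#'   nonnegative, summing to 1).
#' @export
entropy_weights <- function(std_matrix) {
  std_matrix <- as.matrix(std_matrix)
  if (ncol(std_matrix) < 1L || nrow(std_matrix) < 2L)
    stop("need a matrix with >= 1 column and >= 2 rows")
  h <- apply(std_matrix, 2, information_entropy)
  info <- 1 - h
  w <- if (sum(info) == 0) rep(1 / length(h), length(h)) else info / sum(info)
  list(entropy = h, weights = w)
}

#' Weighted block index
#'
#' Row-wise weighted sum of standardized indicators; with weights summing to
#' one and values in \[0, 1\] the index is itself in \[0, 1\].
#'
#' @param std_matrix Numeric matrix of standardized values.
#' @param weights Numeric weights, one per column, summing to 1.
#' @return Numeric vector, one index per row.
#' @export
block_index <- function(std_matrix, weights) {
  std_matrix <- as.matrix(std_matrix)
  if (ncol(std_matrix) != length(weights))
    stop("weight length must match column count")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  as.vector(std_matrix %*% weights)
}

#' Composite forest ecological security index
#'
#' Geometric mean of the status index Z and the complement of the pressure
#' index Y: ESI = sqrt(Z * (1 - Y)). High status and low net pressure both
#' push the composite towards 1.
#'
#' @param Z Status index in \[0, 1\] (vectorized).
#' @param Y Pressure index in \[0, 1\] (vectorized).
#' @return ESI in \[0, 1\].
#' @export
#' @examples
#' composite_esi(0.5, 0.5)  # 0.5
composite_esi <- function(Z, Y) {
  if (any(!is.finite(Z)) || any(!is.finite(Y)))
    stop("Z and Y must be finite")
  if (any(Z < 0 | Z > 1)) stop("Z must lie in [0, 1]")
  if (any(Y < 0 | Y > 1)) stop("Y must lie in [0, 1]")
  sqrt(Z * (1 - Y))
}

# Direction with which a column enters its block:
# status(+) forward, status(-) reverse;
# pressure(-) forward into Y (more pressure -> larger Y),
# response(+) reverse into Y (more maintenance -> smaller Y).
standardize_direction <- function(block, orientation) {
  ifelse((block == "status") == (orientation == "positive"),
         "forward", "reverse")
}

#' Compute the forest ecological security index for a panel
#'
#' Standardizes every indicator (pooled over all years, so index levels are
#' comparable across years), computes entropy weights separately for the
#' status block (-> Z) and the combined pressure + response block (-> Y,
#' a net-pressure index), and composes ESI = sqrt(Z * (1 - Y)) per
#' (unit, year) row.
#'
#' @param panel An `indicator_panel` (see [read_indicator_panel()]).
#' @param spec The `indicator_spec`; defaults to the spec attached to the
#'   panel.
#' @return An object of class `esi_result`: a list with
#'   \describe{
#'     \item{index}{data frame `id,name,lon,lat,year,Z,Y,ESI`}
#'     \item{weights}{data frame `indicator,block,direction,entropy,weight`}
#'     \item{standardized}{matrix of y_ij values}
#'   }
#' @export
compute_esi <- function(panel, spec = attr(panel, "spec")) {
  if (is.null(spec)) spec <- default_indicator_spec()
  panel <- as_indicator_panel(as.data.frame(panel), spec)
  dirs <- standardize_direction(spec$block, spec$orientation)
  std <- vapply(seq_len(nrow(spec)), function(j)
    standardize_column(panel[[spec$name[j]]], dirs[j]),
    numeric(nrow(panel)))
  colnames(std) <- spec$name

  status_cols <- which(spec$block == "status")
  pressure_cols <- which(spec$block %in% c("pressure", "response"))
  if (!length(status_cols)) stop("spec has no status indicators")
  if (!length(pressure_cols)) stop("spec has no pressure/response indicators")

  ws <- entropy_weights(std[, status_cols, drop = FALSE])
  wp <- entropy_weights(std[, pressure_cols, drop = FALSE])

  Z <- block_index(std[, status_cols, drop = FALSE], ws$weights)
  Y <- block_index(std[, pressure_cols, drop = FALSE], wp$weights)
  # clip floating fuzz before the range-checked composite
  Z <- pmin(pmax(Z, 0), 1)
  Y <- pmin(pmax(Y, 0), 1)

  weights <- data.frame(
    indicator = spec$name,
    block = spec$block,
    direction = dirs,
    entropy = NA_real_,
    weight = NA_real_,
    stringsAsFactors = FALSE)
  weights$entropy[status_cols] <- ws$entropy
  weights$weight[status_cols] <- ws$weights
  weights$entropy[pressure_cols] <- wp$entropy
  weights$weight[pressure_cols] <- wp$weights

  out <- list(
    index = data.frame(panel[, c("id", "name", "lon", "lat", "year")],
                       Z = Z, Y = Y, ESI = composite_esi(Z, Y),
                       stringsAsFactors = FALSE),
    weights = weights,
    standardized = std)
  class(out) <- "esi_result"
  out
}

#' @export
print.esi_result <- function(x, ...) {
  cat("Forest ecological security index:",
      nrow(x$index), "(unit, year) rows\n")
  cat(sprintf("  ESI mean %.3f, range [%.3f, %.3f]\n",
              mean(x$index$ESI), min(x$index$ESI), max(x$index$ESI)))
  invisible(x)
}
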