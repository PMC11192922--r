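#' Default PSR indicator specification
#'
#' The ten-indicator pressure-state-response (PSR) system used to score
#' provincial forest ecological security: four positive status indicators
#' (forest quantity and quality), three negative pressure indicators
#' (human load on the land) and three positive response indicators
#' (maintenance effort).
#'
#' @return A data frame with columns `name`, `block`
#'   (`"status"`/`"pressure"`/`"response"`), `orientation`
#'   (`"positive"`/`"negative"`) and `description`.
#' @export
#' @examples
#' default_indicator_spec()
default_indicator_spec <- function() {
  indicator_spec(
    name = c("forest_cover_rate", "forestland_share", "stock_per_area",
             "natural_forest_share",
             "population_density", "energy_per_area", "so2_intensity",
             "nature_reserve_share", "forestry_investment",
             "afforestation_rate"),
    block = c(rep("status", 4), rep("pressure", 3), rep("response", 3)),
    orientation = c(rep("positive", 4), rep("negative", 3),
                    rep("positive", 3)),
    description = c(
      "Forest area / land area (%)",
      "Forestland area / national land area (%)",
      "Forest stock / forest area",
      "Natural forest area / forest area (%)",
      "Year-end population / land area",
      "Energy consumption / land area",
      "Sulfur dioxide emissions / land area",
      "Nature reserve area / land area (%)",
      "Government forestry investment / GDP",
      "Annual afforestation area / forest area (%)"))
}

#' Construct and validate an indicator specification
#'
#' @param name Character vector of unique indicator names.
#' @param block One of `"status"`, `"pressure"`, `"response"` per indicator.
#' @param orientation One of `"positive"`, `"negative"` per indicator:
#'   whether a larger raw value is good or bad for ecological security.
#' @param description Optional free-text description per indicator.
#' @return A validated `indicator_spec` data frame.
#' @export
indicator_spec <- function(name, block, orientation,
                           description = rep("", length(name))) {
  if (length(name) == 0L) stop("indicator spec must contain >= 1 indicator")
  if (anyDuplicated(name)) stop("indicator names must be unique")
  if (!all(block %in% c("status", "pressure", "response")))
    stop("block must be one of 'status', 'pressure', 'response'")
  if (!all(orientation %in% c("positive", "negative")))
    stop("orientation must be 'positive' or 'negative'")
  stopifnot(length(block) == length(name),
            length(orientation) == length(name),
            length(description) == length(name))
  out <- data.frame(name = as.character(name), block = block,
                    orientation = orientation,
                    description = as.character(description),
                    stringsAsFactors = FALSE)
  class(out) <- c("indicator_spec", "data.frame")
  out
}

id_columns <- c("id", "name", "lon", "lat", "year")

#' Read a PSR indicator panel from CSV
#'
#' The panel has one row per (spatial unit, year), with unit metadata columns
#' `id,name,lon,lat,year` followed by one numeric column per indicator in
#' `spec`. All cells must be present and finite; coordinates are WGS84
#' decimal degrees.
#'
#' @param path Path to a CSV file.
#' @param spec An [indicator_spec()]; defaults to [default_indicator_spec()].
#' @return A data frame of class `indicator_panel` with the spec attached as
#'   attribute `"spec"`; row order is preserved.
#' @export
read_indicator_panel <- function(path, spec = default_indicator_spec()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_indicator_panel(raw, spec)
}

#' Validate a data frame as an indicator panel
#'
#' @param df A data frame with columns `id,name,lon,lat,year` plus one
#'   column per indicator in `spec`.
#' @inheritParams read_indicator_panel
#' @return The validated `indicator_panel`.
#' @export
as_indicator_panel <- function(df, spec = default_indicator_spec()) {
  needed <- c(id_columns, spec$name)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) < 2L) stop("panel needs at least 2 (unit, year) rows")
  for (col in c("lon", "lat", "year", spec$name)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing value in column '%s', row %d",
                   col, bad[1]))
    df[[col]] <- v
  }
  if (any(df$lon < -180 | df$lon > 180)) stop("lon out of [-180, 180]")
  if (any(df$lat < -90 | df$lat > 90)) stop("lat out of [-90, 90]")
  if (anyDuplicated(df[, c("id", "year")]))
    stop("duplicate (id, year) rows in panel")
  df <- df[, needed]
  attr(df, "spec") <- spec
  class(df) <- c("indicator_panel", "data.frame")
  df
}

#' Read a driver table from CSV
#'
#' One row per (unit, year) with the three socioeconomic drivers —
#' urbanization level (fraction of population urban), industrial structure
#' (tertiary / secondary value added) and foreign direct investment — plus
#' the forest ecological security index `esi` as response.
#'
#' @param path Path to a CSV with columns
#'   `id,name,lon,lat,year,urbanization,industrial_structure,fdi,esi`.
#' @return A validated data frame of class `driver_table`.
#' @export
read_driver_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_driver_table(df)
}

#' @rdname read_driver_table
#' @param df A data frame to validate in place of a file.
#' @export
as_driver_table <- function(df) {
  needed <- c(id_columns, "urbanization", "industrial_structure", "fdi", "esi")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("driver table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(needed, c("id", "name"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing value in column '%s', row %d",
                   col, bad[1]))
    df[[col]] <- v
  }
  if (any(df$urbanization < 0 | df$urbanization > 1))
    stop("urbanization must lie in [0, 1]")
  if (any(df$fdi < 0)) stop("fdi must be nonnegative")
  if (anyDuplicated(df[, c("id", "year")]))
    stop("duplicate (id, year) rows in driver table")
  df <- df[, needed]
  class(df) <- c("driver_table", "data.frame")
  df
}

#' Load a packaged provincial GWR coefficient table
#'
#' Transcriptions of the published per-province geographically weighted
#' regression results for China's 30 mainland provinces (ex. Tibet): local
#' fitting coefficient, constant term, and coefficients of industrial
#' structure, foreign direct investment and urbanization, plus residual and
#' standard error. Two provinces are both romanized "Shanxi"; their ids are
#' disambiguated as `Shanxi_1` / `Shanxi_2` while the printed name is kept.
#'
#' @param year 2013 or 2018.
#' @return A 30-row data frame of class `coefficient_table`.
#' @export
#' @examples
#' tab <- load_gwr_table(2013)
#' tab[tab$id == "Shanghai", "urbanization"]
load_gwr_table <- function(year) {
  if (!(length(year) == 1L && year %in% c(2013, 2018)))
    stop("no packaged coefficient table for year ", paste(year, collapse = ","),
         "; available years: 2013, 2018")
  path <- system.file("extdata", sprintf("gwr_%d.csv", year),
                      package = "forestsec", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 30L, !anyDuplicated(df$id))
  class(df) <- c("coefficient_table", "data.frame")
  df
}

#' Write stage results to disk
#'
#' Writes the numeric tables of a stage result as CSV (full precision, so a
#' re-read reproduces the values exactly) together with a short plain-text
#' summary.
#'
#' @param x A stage result: an `esi_result`, `hotspot_result`, `gwr_fit` or
#'   plain data frame.
#' @param dir Output directory; created if absent.
#' @param prefix Optional file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir, prefix = "") UseMethod("write_report")

write_csv_full <- function(df, path) {
  # 17 significant digits: round-trips doubles exactly through text
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- formatC(df[[j]], digits = 17,
                                            format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

#' @export
write_report.data.frame <- function(x, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, "table.csv"))
  write_csv_full(as.data.frame(x), p)
  invisible(p)
}

#' @export
write_report.esi_result <- function(x, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- write_csv_full(x$index, file.path(dir, paste0(prefix, "esi.csv")))
  p2 <- write_csv_full(x$weights, file.path(dir, paste0(prefix, "weights.csv")))
  p3 <- file.path(dir, paste0(prefix, "esi_summary.txt"))
  writeLines(c(
    sprintf("Forest ecological security index over %d (unit, year) rows",
            nrow(x$index)),
    sprintf("mean ESI: %.3f  min: %.3f (%s %d)  max: %.3f (%s %d)",
            mean(x$index$ESI),
            min(x$index$ESI),
            x$index$id[which.min(x$index$ESI)],
            x$index$year[which.min(x$index$ESI)],
            max(x$index$ESI),
            x$index$id[which.max(x$index$ESI)],
            x$index$year[which.max(x$index$ESI)])), p3)
  invisible(c(p1, p2, p3))
}

#' @export
write_report.hotspot_result <- function(x, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- write_csv_full(x$table, file.path(dir, paste0(prefix, "hotspots.csv")))
  p2 <- file.path(dir, paste0(prefix, "hotspot_summary.txt"))
  writeLines(c(
    sprintf("Gi* hot/cold classification, %d units, threshold %.0f m",
            nrow(x$table), x$threshold),
    paste(utils::capture.output(print(table(x$table$hotclass))),
          collapse = "\n")), p2)
  invisible(c(p1, p2))
}

#' @export
write_report.gwr_fit <- function(x, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- write_csv_full(x$local, file.path(dir, paste0(prefix,
                                                      "gwr_coefficients.csv")))
  p2 <- write_csv_full(gwr_diagnostics(x),
                       file.path(dir, paste0(prefix, "gwr_summary.csv")))
  invisible(c(p1, p2))
}
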