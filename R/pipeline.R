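coef_driver <- function(table, driver) {
  driver <- match.arg(driver, c("urbanization", "industrial_structure",
                                "fdi", "constant_term",
                                "fitting_coefficient"))
  if (nrow(table) == 0L) stop("empty coefficient table")
  table[[driver]]
}

#' Mean of a coefficient column
#'
#' @param table A `coefficient_table` (see [load_gwr_table()]) or any data
#'   frame with the driver columns.
#' @param driver One of `"urbanization"`, `"industrial_structure"`, `"fdi"`,
#'   `"constant_term"`, `"fitting_coefficient"`.
#' @return The arithmetic mean at full precision (round to 3 decimals for
#'   reporting, the precision the source tables are printed at).
#' @export
#' @examples
#' round(column_mean(load_gwr_table(2013), "urbanization"), 3)
column_mean <- function(table, driver) {
  mean(coef_driver(table, driver))
}

#' Count strictly positive / negative coefficients
#'
#' @inheritParams column_mean
#' @param sign `"positive"` or `"negative"`.
#' @return Integer count of strictly positive (resp. negative) entries.
#' @export
sign_count <- function(table, driver, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  v <- coef_driver(table, driver)
  if (sign == "positive") sum(v > 0) else sum(v < 0)
}

#' Extreme coefficients with their units
#'
#' @inheritParams column_mean
#' @param k Number of units to return from each end, `k <= nrow(table)`.
#' @return A list with data frames `top` (largest values, descending) and
#'   `bottom` (smallest values, ascending), ties broken by unit id.
#' @export
extremes <- function(table, driver, k = 3) {
  v <- coef_driver(table, driver)
  if (k > nrow(table)) stop("k exceeds the number of rows")
  ord_desc <- order(-v, table$id)
  ord_asc <- order(v, table$id)
  list(
    top = data.frame(id = table$id[ord_desc[seq_len(k)]],
                     name = table$name[ord_desc[seq_len(k)]],
                     value = v[ord_desc[seq_len(k)]],
                     stringsAsFactors = FALSE),
    bottom = data.frame(id = table$id[ord_asc[seq_len(k)]],
                        name = table$name[ord_asc[seq_len(k)]],
                        value = v[ord_asc[seq_len(k)]],
                        stringsAsFactors = FALSE))
}

#' Summarize a coefficient table the way the study reports it
#'
#' Per driver: the mean coefficient (signed, and also rounded half-to-even
#' to 3 decimals for reporting), positive/negative counts, and the top /
#' bottom `k` units. Urbanization impact is conventionally discussed by
#' magnitude, so its absolute mean is included too.
#'
#' @inheritParams column_mean
#' @param k How many extreme units to list per driver.
#' @return A list, one entry per driver, each with `mean`, `mean_3dp`,
#'   `mean_abs`, `n_positive`, `n_negative`, `n_zero`, `top`, `bottom`.
#' @export
coefficient_summary <- function(table, k = 3) {
  drivers <- c("urbanization", "industrial_structure", "fdi")
  out <- lapply(drivers, function(d) {
    v <- coef_driver(table, d)
    ex <- extremes(table, d, k)
    list(mean = mean(v), mean_3dp = round(mean(v), 3),
         mean_abs = mean(abs(v)),
         n_positive = sum(v > 0), n_negative = sum(v < 0),
         n_zero = sum(v == 0),
         top = ex$top, bottom = ex$bottom)
  })
  names(out) <- drivers
  out
}

#' Run the full forest-security pipeline
#'
#' Composes the three stages: entropy-weighted ESI from the indicator
#' panel; per-year Gi* hot/cold-spot classification of the ESI; and, if a
#' driver table is given, a per-year GWR of the computed ESI on the
#' drivers, followed by the coefficient summary. If `out_dir` is given
#' every intermediate result is written to disk.
#'
#' @param panel An `indicator_panel`.
#' @param drivers Optional `driver_table` (its `esi` column is replaced by
#'   the ESI computed from `panel`, matched on id and year).
#' @param threshold Gi* band distance in meters, or `NULL` for the
#'   no-isolate default.
#' @param bandwidth GWR bandwidth in meters or `"auto"`.
#' @param out_dir Optional output directory.
#' @return A list with `esi`, `hotspots` (one `hotspot_result` per year),
#'   `gwr` (one `gwr_fit` per year, or `NULL` if no drivers), `summary`
#'   (one [coefficient_summary()] per year, or `NULL`).
#' @export
run_pipeline <- function(panel, drivers = NULL, threshold = NULL,
                         bandwidth = "auto", out_dir = NULL) {
  esi <- compute_esi(panel)
  years <- sort(unique(esi$index$year))

  hotspots <- lapply(years, function(yr) {
    sub <- esi$index[esi$index$year == yr, ]
    hotspot_analysis(sub, sub$ESI, threshold = threshold)
  })
  names(hotspots) <- as.character(years)

  gwr <- NULL
  summaries <- NULL
  if (!is.null(drivers)) {
    drivers <- as_driver_table(as.data.frame(drivers))
    key_d <- paste(drivers$id, drivers$year)
    key_e <- paste(esi$index$id, esi$index$year)
    hit <- match(key_d, key_e)
    if (anyNA(hit))
      stop("driver rows without matching (id, year) in the panel")
    drivers$esi <- esi$index$ESI[hit]
    gwr <- lapply(years, function(yr) {
      gwr_fit(drivers[drivers$year == yr, ], bandwidth = bandwidth)
    })
    names(gwr) <- as.character(years)
    summaries <- lapply(gwr, function(f) {
      tab <- data.frame(id = f$local$id, name = f$local$name,
                        constant_term = f$local$intercept,
                        urbanization = f$local$urbanization,
                        industrial_structure = f$local$industrial_structure,
                        fdi = f$local$fdi, stringsAsFactors = FALSE)
      coefficient_summary(tab)
    })
  }

  if (!is.null(out_dir)) {
    write_report(esi, out_dir)
    for (yr in names(hotspots))
      write_report(hotspots[[yr]], out_dir, prefix = paste0(yr, "_"))
    for (yr in names(gwr))
      write_report(gwr[[yr]], out_dir, prefix = paste0(yr, "_"))
  }

  list(esi = esi, hotspots = hotspots, gwr = gwr, summary = summaries)
}
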