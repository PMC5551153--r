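# Bundled field-trial reference tables: orchard characteristics (T3),
# sprayer set-up (T4), paired applications with product concentrations (T5)
# and tank/refill-time data (T6), transcribed from the published field
# evaluation. Each loader schema-validates the file.

.fixture_files <- c(
  T3 = "table3_orchards.csv",
  T4 = "table4_sprayers.csv",
  T5 = "table5_applications.csv",
  T6 = "table6_tanks.csv"
)

.fixture_schemas <- list(
  T3 = c("orchard_id", "cultivar", "sp_row", "sp_tree", "h", "d_across",
         "d_along", "vt1_printed"),
  T4 = c("orchard_id", "date", "pest", "pressure_bar", "forward_speed_kmh",
         "air_volume_m3h", "nozzles_vc", "nozzles_va"),
  T5 = c("orchard_id", "date", "pest", "active_ingredient",
         "concentration_pct", "vc", "va", "reduction_printed",
         "savings_printed"),
  T6 = c("orchard_id", "date", "vc", "va", "tank_capacity",
         "tanks_per_ha_vc", "tanks_per_ha_va", "savings_h_1ha",
         "savings_h_10ha", "savings_h_100ha")
)

#' Load a bundled field-trial table
#'
#' @param table_id One of `"T3"` (orchard geometry), `"T4"` (sprayer set-up),
#'   `"T5"` (applications: volumes, concentrations, reported reductions and
#'   savings), `"T6"` (tank capacities, tank counts and reported refill-time
#'   savings). Columns suffixed `_printed` (and the `savings_h_*`,
#'   `tanks_per_ha_*` columns of T6) carry the values as published, for
#'   regression against recomputation.
#' @return A schema-validated tibble.
#' @export
#' @examples
#' load_fixture("T3")
load_fixture <- function(table_id) {
  check_scalar(table_id, "table_id")
  if (!table_id %in% names(.fixture_files)) {
    stop("unknown fixture id '", table_id, "'; available: ",
         paste(names(.fixture_files), collapse = ", "), call. = FALSE)
  }
  df <- read_ref_csv(cv_extdata(.fixture_files[[table_id]]))
  check_columns(df, .fixture_schemas[[table_id]],
                paste("fixture", table_id))
  if (nrow(df) == 0) stop("fixture ", table_id, " is empty", call. = FALSE)
  df
}

#' Write and re-read a result table
#'
#' Plain-CSV export used by the command-line interface; `read_table_csv()`
#' restores what `export_table()` wrote (lossless round trip for numeric,
#' character and date columns).
#'
#' @param df A data frame.
#' @param path Output CSV path.
#' @return `export_table()` returns `path` invisibly; `read_table_csv()` the
#'   tibble.
#' @export
export_table <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname export_table
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
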