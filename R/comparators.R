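# Classical dose-expression systems, for side-by-side comparison with the
# deposit-based recommendation. All three reduce the canopy to a coarser
# descriptor: TRV to a rectangular box per row, LWA to a vertical wall,
# UCR to 100 m3 canopy units; none uses leaf density or the target pest.

comparison_result <- function(method, crop_metric, units, volume_rate = NA_real_) {
  tibble::tibble(method = method, crop_metric = crop_metric,
                 units = units, volume_rate = volume_rate)
}

#' Tree Row Volume (TRV)
#'
#' Treats each row as a rectangular box `h` high and `d_across` wide running
#' the length of the row, giving a foliage volume per hectare of
#' `h * d_across * 10000 / sp_row` m3/ha, and multiplies by an optimal rate
#' per canopy volume (default 0.094 L/m3, the classic value calibrated on a
#' standard apple orchard of 39,907 m3 foliage/ha). The box deliberately
#' overstates an ellipsoidal canopy; the comparator exists to show that
#' contrast.
#'
#' @param geometry An [orchard_geometry()].
#' @param rate_per_m3 Volume rate per unit foliage volume, L/m3.
#' @return One-row tibble: `method`, `crop_metric` (m3 foliage/ha), `units`,
#'   `volume_rate` (L/ha).
#' @export
#' @examples
#' trv(orchard_geometry(2.51, 4.33, 3.08, 3, 6))
trv <- function(geometry, rate_per_m3 = 0.094) {
  stopifnot(inherits(geometry, "orchard_geometry"))
  check_positive(rate_per_m3, "rate_per_m3")
  foliage <- geometry$h * geometry$d_across * 10000 / geometry$sp_row
  comparison_result("TRV", foliage, "m3 foliage/ha", foliage * rate_per_m3)
}

#' Leaf Wall Area (LWA)
#'
#' Treated wall area per hectare: canopy height times row length per hectare,
#' counting both faces of the row by default (`sides = 2`);
#' `sides * h * 10000 / sp_row` m2/ha. No volume rate is attached — LWA is a
#' dose expression (product per m2 of wall), not a volume model.
#'
#' @param geometry An [orchard_geometry()].
#' @param sides 2 for both wall faces (default), 1 for one-sided.
#' @return One-row tibble with the wall area in m2/ha.
#' @export
lwa <- function(geometry, sides = 2) {
  stopifnot(inherits(geometry, "orchard_geometry"))
  if (!sides %in% c(1, 2)) stop("`sides` must be 1 or 2", call. = FALSE)
  comparison_result("LWA", sides * geometry$h * 10000 / geometry$sp_row,
                    "m2 wall/ha")
}

#' Unit Canopy Row (UCR)
#'
#' Counts canopy in units of 100 m3 (1 m high x 1 m wide x 100 m of row):
#' `h * d_across * (10000 / sp_row) / 100` UCR units per hectare. The
#' volume applied per UCR is crop-specific and supplied by the user, so only
#' the crop metric is returned.
#'
#' @param geometry An [orchard_geometry()].
#' @return One-row tibble with UCR units per hectare.
#' @export
ucr_units <- function(geometry) {
  stopifnot(inherits(geometry, "orchard_geometry"))
  comparison_result("UCR", geometry$h * geometry$d_across *
                      (10000 / geometry$sp_row) / 100, "UCR units/ha")
}

#' Compare dose-expression systems for one orchard
#'
#' Stacks the TRV, LWA and UCR descriptors for a geometry and, when target
#' and product are given, appends the deposit-based recommendation (crop
#' metric: ellipsoid canopy volume per hectare; volume rate: the
#' recommendation for a conventional sprayer, i.e. `v_r2` when the rows are
#' gapped, `v_r1` otherwise).
#'
#' @inheritParams recommend
#' @param rate_per_m3 TRV rate, L/m3.
#' @param target,product Optional; when both given the CitrusVol row is added.
#' @return A tibble with one row per method.
#' @export
compare_methods <- function(geometry, cultivar_group = NULL, pruning = NULL,
                            target = NULL, product = NULL, lad = NULL,
                            rate_per_m3 = 0.094,
                            constants = dose_constants()) {
  out <- dplyr::bind_rows(trv(geometry, rate_per_m3), lwa(geometry),
                          ucr_units(geometry))
  if (!is.null(target) && !is.null(product)) {
    rec <- recommend(geometry, cultivar_group, pruning, target, product,
                     lad = lad, constants = constants)
    vr <- if (is.null(rec$v_r2)) rec$v_r1 else rec$v_r2
    out <- dplyr::bind_rows(out, comparison_result(
      "CitrusVol", rec$trace$vt1 * rec$trace$n_trees,
      "m3 canopy/ha (ellipsoid)", vr))
  }
  out
}
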