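# Field-evaluation arithmetic for paired conventional (Vc) / adjusted (Va)
# applications: mix-volume reduction, product savings, tank counts and
# refill-time savings.

#' Mix-volume reduction
#'
#' Percentage reduction of spray mix between a conventional and an adjusted
#' application, `100 (Vc - Va) / Vc`. Vectorized.
#'
#' @param vc Conventional volume rate, L/ha.
#' @param va Adjusted volume rate, L/ha; must not exceed `vc`.
#' @return Reduction in percent.
#' @export
#' @examples
#' mix_reduction(6702, 1737)   # 74.08
mix_reduction <- function(vc, va) {
  check_positive(vc, "vc")
  check_positive(va, "va")
  if (any(va > vc)) {
    stop("`va` exceeds `vc`: the adjusted rate is larger than the conventional one",
         call. = FALSE)
  }
  100 * (vc - va) / vc
}

#' Product savings per hectare
#'
#' Labels for citrus in Spain express the dose as a concentration of the mix,
#' so the product saved is the concentration applied to the volume saved:
#' `(concentration/100) * (Vc - Va)`, in kg or L of product per ha depending
#' on the formulation. Vectorized.
#'
#' @param concentration_pct Label concentration of the product in the mix, %.
#' @param vc,va Conventional and adjusted volume rates, L/ha.
#' @return Product saved per hectare (kg/ha or L/ha).
#' @export
#' @examples
#' ppp_savings(0.20, 6702, 1737)   # 9.93
ppp_savings <- function(concentration_pct, vc, va) {
  check_positive(concentration_pct, "concentration_pct")
  if (any(concentration_pct >= 100)) {
    stop("`concentration_pct` must be below 100", call. = FALSE)
  }
  check_positive(vc, "vc")
  check_positive(va, "va")
  if (any(va > vc)) {
    stop("`va` exceeds `vc`", call. = FALSE)
  }
  (concentration_pct / 100) * (vc - va)
}

#' Tanks needed to spray an area
#'
#' Number of sprayer tank fills needed: the ceiling of total mix volume over
#' tank capacity, taken over the whole area in one pass (a part-filled tank
#' still has to be filled once). Vectorized.
#'
#' @param volume_rate Volume rate, L/ha.
#' @param area_ha Sprayed area, ha.
#' @param capacity Tank capacity, L.
#' @return Integer number of tank fills (>= 1).
#' @export
#' @examples
#' tanks_needed(7311, 1, 2000)   # 4
tanks_needed <- function(volume_rate, area_ha, capacity) {
  check_positive(volume_rate, "volume_rate")
  check_positive(area_ha, "area_ha")
  check_positive(capacity, "capacity")
  as.integer(ceiling(volume_rate * area_ha / capacity))
}

#' Refill time saved by the adjusted rate
#'
#' Tank fills avoided by spraying at `va` instead of `vc` over `area_ha`,
#' times the refill time (default 40 min per tank, including transit to and
#' from the water source), in hours. Vectorized.
#'
#' @inheritParams tanks_needed
#' @param vc,va Conventional and adjusted volume rates, L/ha.
#' @param refill_minutes Minutes per tank refill (default 40).
#' @return Time saved in hours.
#' @export
#' @examples
#' refill_time_savings(7311, 3011, 2000, 1)   # 1.33 h
refill_time_savings <- function(vc, va, capacity, area_ha,
                                refill_minutes = 40) {
  if (any(va > vc)) stop("`va` exceeds `vc`", call. = FALSE)
  check_positive(refill_minutes, "refill_minutes")
  (tanks_needed(vc, area_ha, capacity) - tanks_needed(va, area_ha, capacity)) *
    refill_minutes / 60
}

#' Summarize a set of paired field applications
#'
#' Takes a long-format trial table (one row per active ingredient per
#' application; an application is an orchard x date pair) and computes, per
#' application: the mix-volume reduction, tank counts per hectare and refill
#' time saved at 1, 10 and 100 ha; per ingredient: the product saved per
#' hectare; and overall: minimum, maximum and unweighted mean reduction
#' across applications. If the table carries a `reduction_printed` column
#' (a previously reported reduction), applications where the recomputed value
#' disagrees by more than `discrepancy_tol` percentage points are flagged in
#' a `discrepancy` column rather than silently replaced, and the mean of the
#' reported column is returned alongside the recomputed mean.
#'
#' @param records Tibble with columns `orchard_id`, `date`, `vc`, `va` and
#'   optionally `pest`, `tank_capacity`, `active_ingredient`,
#'   `concentration_pct`, `reduction_printed`.
#' @param refill_minutes Minutes per tank refill (default 40).
#' @param discrepancy_tol Tolerance (percentage points) between a reported
#'   and the recomputed reduction before a row is flagged (default 0.5,
#'   generous to print rounding of Vc/Va).
#' @return A list of class `"trial_summary"`: `applications` (one row per
#'   application), `ingredients` (one row per ingredient per application, if
#'   ingredient columns are present) and `overall` (one-row tibble).
#' @export
#' @examples
#' summarize_trials(load_fixture("T5"))
summarize_trials <- function(records, refill_minutes = 40,
                             discrepancy_tol = 0.5) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  check_columns(records, c("orchard_id", "date", "vc", "va"), "trial table")
  records <- tibble::as_tibble(records)

  apps <- dplyr::distinct(
    records,
    dplyr::across(dplyr::any_of(c("orchard_id", "date", "pest", "vc", "va",
                                  "tank_capacity", "reduction_printed"))))
  if (anyDuplicated(paste(apps$orchard_id, apps$date))) {
    stop("trial table: inconsistent vc/va/capacity within an application",
         call. = FALSE)
  }
  apps$reduction_pct <- mix_reduction(apps$vc, apps$va)
  if ("reduction_printed" %in% names(apps)) {
    apps$discrepancy <-
      abs(apps$reduction_pct - apps$reduction_printed) > discrepancy_tol
  }
  if ("tank_capacity" %in% names(apps)) {
    for (a in c(1, 10, 100)) {
      apps[[paste0("time_saved_h_", a, "ha")]] <- refill_time_savings(
        apps$vc, apps$va, apps$tank_capacity, a, refill_minutes)
    }
  }

  ingredients <- NULL
  if (all(c("active_ingredient", "concentration_pct") %in% names(records))) {
    ingredients <- dplyr::mutate(
      dplyr::select(records, dplyr::any_of(c(
        "orchard_id", "date", "active_ingredient", "concentration_pct",
        "vc", "va", "savings_printed"))),
      savings = ppp_savings(.data$concentration_pct, .data$vc, .data$va))
  }

  overall <- tibble::tibble(
    n_applications = nrow(apps),
    min_reduction_pct = min(apps$reduction_pct),
    max_reduction_pct = max(apps$reduction_pct),
    mean_reduction_pct = mean(apps$reduction_pct)
  )
  if ("reduction_printed" %in% names(apps)) {
    overall$mean_reported_reduction_pct <- mean(apps$reduction_printed)
    overall$n_discrepancies <- sum(apps$discrepancy)
  }

  structure(list(applications = apps, ingredients = ingredients,
                 overall = overall),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "Trial summary: %d applications, mix reduction %.2f-%.2f%% (mean %.1f%%)\n",
    o$n_applications, o$min_reduction_pct, o$max_reduction_pct,
    o$mean_reduction_pct))
  if (!is.null(o$n_discrepancies) && o$n_discrepancies > 0) {
    cat(sprintf(
      "  note: %d application(s) where the reported reduction disagrees with Vc/Va\n",
      o$n_discrepancies))
  }
  print(x$applications)
  invisible(x)
}
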