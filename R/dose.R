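# Dose engine: from minimum deposit and canopy metrics to the theoretical
# volume (V) and the recommended volume rate (V_R), including the dual-case
# recommendation for gapped rows.

#' Dose model constants
#'
#' The two fixed correction factors of the deposit model:
#' `f_lab_field` (default 0.8) scales the laboratory minimum deposit down
#' because pest survival in the field is lower than in the laboratory, and
#' `f_E` (default 0.6) is the application efficiency — the fraction of spray
#' delivered by a conventional airblast sprayer that reaches the target
#' canopy, with an adjuvant in the mix.
#'
#' @param f_lab_field Laboratory-to-field deposit correction, in (0, 1].
#' @param f_E Application efficiency, in (0, 1].
#' @return A list of class `"dose_constants"`.
#' @export
dose_constants <- function(f_lab_field = 0.8, f_E = 0.6) {
  check_scalar(f_lab_field, "f_lab_field")
  check_scalar(f_E, "f_E")
  check_fraction(f_lab_field, "f_lab_field")
  check_fraction(f_E, "f_E")
  structure(list(f_lab_field = f_lab_field, f_E = f_E),
            class = "dose_constants")
}

#' Theoretical volume rate
#'
#' `V = D * S_W * N * f_lab_field`, with the unit bridge
#' 1 uL/cm2 x 1 m2 = 0.01 L (10^4 cm2 per m2, 10^-6 L per uL), so
#' `V [L/ha] = D [uL/cm2] * S_W [m2/tree] * 0.01 * f_lab_field * N [trees/ha]`.
#'
#' @param deposit Minimum deposit D, uL/cm2.
#' @param s_w Leaf surface to be wetted, m2/tree.
#' @param n_trees Trees per hectare.
#' @param f_lab_field Laboratory-to-field correction in (0, 1].
#' @return Theoretical volume rate, L/ha.
#' @export
#' @examples
#' theoretical_volume(3.41, 129.72, 555.56, 0.8)   # ~1966 L/ha
theoretical_volume <- function(deposit, s_w, n_trees, f_lab_field = 0.8) {
  check_positive(deposit, "deposit")
  check_positive(s_w, "s_w")
  check_positive(n_trees, "n_trees")
  check_fraction(f_lab_field, "f_lab_field")
  deposit * s_w * 0.01 * f_lab_field * n_trees
}

#' Recommended volume rate
#'
#' `V_R = V / f_E`: inflates the theoretical volume by the application
#' efficiency so the target canopy still receives the theoretical amount.
#'
#' @param v Theoretical volume rate, L/ha.
#' @param f_E Application efficiency in (0, 1].
#' @return Recommended volume rate, L/ha.
#' @export
recommended_volume <- function(v, f_E = 0.6) {
  check_positive(v, "v")
  check_fraction(f_E, "f_E")
  v / f_E
}

#' Recommend a spray volume rate for an orchard
#'
#' Full pipeline: resolves leaf area density (from cultivar density group and
#' pruning level, or an explicit `lad` override), the target's wetting
#' fraction and the product's minimum deposit, then computes the recommended
#' volume rate. When the canopy diameter along the row is smaller than the
#' tree spacing (gapped rows) two rates are produced: `v_r1` for sprayers
#' with canopy-detection technology (nozzles close over the gaps) and `v_r2`
#' for conventional sprayers, together with the volume saving a detection
#' sprayer would achieve. At `d_along >= sp_tree` only `v_r1` applies.
#'
#' The label-check advisory is always attached: the recommendation is based
#' on biological efficacy only and does not know label-imposed maxima.
#'
#' @param geometry An [orchard_geometry()].
#' @param cultivar_group,pruning Canopy class used to look up LAD; ignored if
#'   `lad` is given. `cultivar_group` also accepts a cultivar name present in
#'   the cultivar registry (e.g. `"Clemenules"`).
#' @param target Pest or disease name, resolved with [lookup_f_target()].
#' @param product Active ingredient or mode-of-action class, resolved with
#'   [lookup_deposit()].
#' @param lad Optional explicit leaf area density, m2/m3.
#' @param constants A [dose_constants()] object.
#' @return An object of class `"vr_recommendation"`: `v_r1`, `v_r2` (NULL if
#'   not applicable), `sensor_savings_pct` (NULL unless `v_r2` exists),
#'   `warnings` (identifiers), `messages` (rendered texts) and `trace` (all
#'   intermediates: N, VT, S, S_W, V per case, plus resolved LAD, f_target,
#'   deposit and constants).
#' @export
#' @examples
#' geom <- orchard_geometry(2.51, 4.33, 3.08, sp_tree = 3, sp_row = 6)
#' recommend(geom, "medium", "normal",
#'           target = "California red scale", product = "chlorpyrifos")
recommend <- function(geometry, cultivar_group = NULL, pruning = NULL,
                      target, product, lad = NULL,
                      constants = dose_constants()) {
  stopifnot(inherits(geometry, "orchard_geometry"),
            inherits(constants, "dose_constants"))
  if (is.null(lad)) {
    if (is.null(cultivar_group) || is.null(pruning)) {
      stop("either `lad` or both `cultivar_group` and `pruning` must be given",
           call. = FALSE)
    }
    if (!cultivar_group %in% .cultivar_groups) {
      cultivar_group <- lookup_cultivar_group(cultivar_group)
    }
    lad <- lookup_lad(cultivar_group, pruning)
  } else {
    check_positive(lad, "lad")
  }

  tspec <- lookup_f_target(target)
  pspec <- lookup_deposit(product)

  cm <- canopy_metrics(geometry, lad, tspec$f_target)
  v1 <- theoretical_volume(pspec$deposit_ul_cm2, cm$s_w1, cm$n_trees,
                           constants$f_lab_field)
  v_r1 <- recommended_volume(v1, constants$f_E)

  v2 <- v_r2 <- sensor_savings <- NULL
  if (!is.null(cm$vt2)) {
    v2 <- theoretical_volume(pspec$deposit_ul_cm2, cm$s_w2, cm$n_trees,
                             constants$f_lab_field)
    v_r2 <- recommended_volume(v2, constants$f_E)
    sensor_savings <- 100 * (v_r2 - v_r1) / v_r2
  }

  ids <- unique(c("check_label", tspec$warnings, pspec$warnings))
  structure(list(
    v_r1 = v_r1,
    v_r2 = v_r2,
    sensor_savings_pct = sensor_savings,
    warnings = ids,
    messages = unname(warning_messages()[ids]),
    trace = list(
      geometry = geometry,
      lad = lad,
      target = tspec,
      product = pspec,
      constants = constants,
      n_trees = cm$n_trees,
      vt1 = cm$vt1, s1 = cm$s1, s_w1 = cm$s_w1, v1 = v1,
      vt2 = cm$vt2, s2 = cm$s2, s_w2 = cm$s_w2, v2 = v2
    )
  ), class = "vr_recommendation")
}

#' @export
print.vr_recommendation <- function(x, digits = 0, ...) {
  tr <- x$trace
  cat("Volume rate recommendation\n")
  cat(sprintf("  target:  %s (%s, f_target = %g)\n", tr$target$target_name,
              tr$target$application_class, tr$target$f_target))
  cat(sprintf("  product: %s (%s, D = %g uL/cm2)\n",
              ifelse(is.na(tr$product$active_ingredient), "<by class>",
                     tr$product$active_ingredient),
              tr$product$moa_class, tr$product$deposit_ul_cm2))
  cat(sprintf("  LAD = %g m2/m3, N = %.2f trees/ha, VT1 = %.2f m3/tree\n",
              tr$lad, tr$n_trees, tr$vt1))
  if (is.null(x$v_r2)) {
    cat(sprintf("  Recommended volume rate: %s L/ha\n",
                format(round(x$v_r1, digits))))
  } else {
    cat(sprintf("  Recommended volume rate (canopy-detection sprayer): %s L/ha\n",
                format(round(x$v_r1, digits))))
    cat(sprintf("  Recommended volume rate (conventional sprayer):     %s L/ha\n",
                format(round(x$v_r2, digits))))
    cat(sprintf("  Volume saved with canopy detection: %.1f%%\n",
                x$sensor_savings_pct))
  }
  for (m in x$messages) cat("  ! ", m, "\n", sep = "")
  invisible(x)
}
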