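# Leaf area density field survey: cube sampling. In each canopy quadrant a
# 70 x 70 x 70 cm frame (0.343 m3) is installed, all leaves inside are
# collected and weighed (g leaf / m3 canopy); a weighed subsample is scanned
# to get specific leaf area (cm2 leaf / g). The product, converted to m2,
# is the quadrant LAD.

#' Build a validated table of cube samples
#'
#' @param repetition Repetition (tree) identifier, one per sampled tree.
#' @param quadrant Quadrant identifier within the tree (e.g. height x sector).
#' @param leaf_mass_g Fresh mass of all leaves inside the cube, g.
#' @param subsample_mass_g Mass of the scanned leaf subsample, g.
#' @param subsample_area_cm2 One-sided area of the scanned subsample, cm2.
#' @param cube_volume_m3 Sampling cube volume, m3 (default 0.343 = 0.7 m cube).
#' @return A tibble with one row per quadrant sample.
#' @export
cube_samples <- function(repetition, quadrant, leaf_mass_g,
                         subsample_mass_g, subsample_area_cm2,
                         cube_volume_m3 = 0.343) {
  df <- tibble::tibble(
    repetition = as.character(repetition),
    quadrant = as.character(quadrant),
    leaf_mass_g = leaf_mass_g,
    subsample_mass_g = subsample_mass_g,
    subsample_area_cm2 = subsample_area_cm2,
    cube_volume_m3 = cube_volume_m3
  )
  check_positive(df$leaf_mass_g, "leaf_mass_g")
  check_positive(df$subsample_mass_g, "subsample_mass_g")
  check_positive(df$subsample_area_cm2, "subsample_area_cm2")
  check_positive(df$cube_volume_m3, "cube_volume_m3")
  df
}

#' Leaf area density of one sampled quadrant
#'
#' `LAD = (leaf mass / cube volume) * (subsample area / subsample mass) * 1e-4`,
#' i.e. g/m3 times cm2/g, converted from cm2 to m2. Vectorized.
#'
#' @inheritParams cube_samples
#' @return LAD in m2 leaf / m3 canopy.
#' @export
#' @examples
#' quadrant_lad(343, 10, 370)   # 3.7 m2/m3
quadrant_lad <- function(leaf_mass_g, subsample_mass_g, subsample_area_cm2,
                         cube_volume_m3 = 0.343) {
  check_positive(leaf_mass_g, "leaf_mass_g")
  check_positive(subsample_mass_g, "subsample_mass_g")
  check_positive(subsample_area_cm2, "subsample_area_cm2")
  check_positive(cube_volume_m3, "cube_volume_m3")
  (leaf_mass_g / cube_volume_m3) * (subsample_area_cm2 / subsample_mass_g) * 1e-4
}

#' Orchard-level leaf area density
#'
#' Averages quadrant LADs within each repetition (sampled tree), then
#' averages the repetition means; the standard error is that of the
#' repetition means. For balanced designs this equals the grand mean of all
#' quadrants. The survey protocol uses three repetitions per orchard.
#'
#' @param samples A tibble from [cube_samples()] (columns `repetition`,
#'   `leaf_mass_g`, `subsample_mass_g`, `subsample_area_cm2`,
#'   `cube_volume_m3`).
#' @return A list of class `"lad_estimate"`: `lad` (mean, m2/m3), `se`
#'   (standard error across repetitions, `NA` for a single repetition),
#'   `n_repetitions`, and `per_repetition` (tibble of repetition means).
#' @export
orchard_lad <- function(samples) {
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    stop("`samples` must be a non-empty data frame of cube samples",
         call. = FALSE)
  }
  check_columns(samples, c("repetition", "leaf_mass_g", "subsample_mass_g",
                           "subsample_area_cm2", "cube_volume_m3"),
                "cube sample table")
  samples <- dplyr::mutate(samples,
    lad = quadrant_lad(.data$leaf_mass_g, .data$subsample_mass_g,
                       .data$subsample_area_cm2, .data$cube_volume_m3))
  per_rep <- dplyr::summarise(
    dplyr::group_by(samples, .data$repetition),
    n_quadrants = dplyr::n(),
    lad = mean(.data$lad), .groups = "drop")
  n_rep <- nrow(per_rep)
  if (length(unique(per_rep$n_quadrants)) > 1) {
    warning("unbalanced design: repetitions have different quadrant counts; ",
            "repetition means are weighted equally", call. = FALSE)
  }
  structure(list(
    lad = mean(per_rep$lad),
    se = if (n_rep > 1) stats::sd(per_rep$lad) / sqrt(n_rep) else NA_real_,
    n_repetitions = n_rep,
    per_repetition = per_rep
  ), class = "lad_estimate")
}

#' @export
print.lad_estimate <- function(x, ...) {
  cat(sprintf("LAD estimate: %.2f m2/m3", x$lad))
  if (!is.na(x$se)) cat(sprintf(" (SE %.3f, %d repetitions)", x$se,
                                x$n_repetitions))
  cat("\n")
  invisible(x)
}
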