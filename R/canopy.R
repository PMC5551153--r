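# Canopy geometry: planting density, apparent (ellipsoid) canopy volume and
# leaf surface. The citrus canopy is modelled as an ellipsoid with axes
# h (height, bottom of canopy to top), d_across (diameter across the row) and
# d_along (diameter along the row).

# canopy dimensions beyond this are treated as data-entry errors
.max_canopy_dim <- 15

#' Orchard geometry
#'
#' Bundles the five field measurements describing an orchard: canopy height
#' (measured from the bottom of the canopy, not the ground), the two canopy
#' diameters, and the planting frame. Hedged rows where the canopy overlaps
#' the frame (`d_along > sp_tree` or `d_across > sp_row`) are legitimate;
#' canopy dimensions above 15 m are rejected as physically implausible.
#'
#' @param h Canopy height in m (bottom of canopy to top).
#' @param d_across Mean canopy diameter perpendicular to the row, m.
#' @param d_along Mean canopy diameter parallel to the row, m.
#' @param sp_tree Spacing between trunks within the row, m.
#' @param sp_row Spacing between rows, m.
#' @return An object of class `"orchard_geometry"`.
#' @export
#' @examples
#' orchard_geometry(h = 2.51, d_across = 4.33, d_along = 3.08,
#'                  sp_tree = 3, sp_row = 6)
orchard_geometry <- function(h, d_across, d_along, sp_tree, sp_row) {
  for (nm in c("h", "d_across", "d_along", "sp_tree", "sp_row")) {
    v <- get(nm)
    check_scalar(v, nm)
    check_positive(v, nm)
  }
  for (nm in c("h", "d_across", "d_along")) {
    if (get(nm) > .max_canopy_dim) {
      stop(sprintf("`%s` = %g m exceeds the plausible canopy limit of %g m",
                   nm, get(nm), .max_canopy_dim), call. = FALSE)
    }
  }
  structure(list(h = h, d_across = d_across, d_along = d_along,
                 sp_tree = sp_tree, sp_row = sp_row),
            class = "orchard_geometry")
}

#' @export
print.orchard_geometry <- function(x, ...) {
  cat(sprintf("Orchard geometry: canopy %g x %g x %g m (h x across x along), frame %g x %g m (row x tree)\n",
              x$h, x$d_across, x$d_along, x$sp_row, x$sp_tree))
  invisible(x)
}

#' Planting density
#'
#' Number of trees per hectare from the planting frame,
#' `N = 10000 / (sp_tree * sp_row)`. Kept as a real number; the frame rarely
#' divides a hectare evenly and downstream volume rates are continuous.
#'
#' @param sp_tree Spacing within the row, m.
#' @param sp_row Row spacing, m.
#' @return Trees per hectare (not rounded).
#' @export
#' @examples
#' tree_density(3, 6)   # 555.56 trees/ha
tree_density <- function(sp_tree, sp_row) {
  check_positive(sp_tree, "sp_tree")
  check_positive(sp_row, "sp_row")
  10000 / (sp_tree * sp_row)
}

#' Apparent canopy volume, ellipsoid cases
#'
#' `canopy_volume_case1()` is the ellipsoid volume of an individual canopy,
#' `(pi/6) h * d_across * d_along`. `canopy_volume_case2()` replaces the
#' along-row diameter by the tree spacing, `(pi/6) h * d_across * sp_tree`:
#' the volume a sprayer without canopy-detection technology effectively
#' treats when gaps separate the trees (`d_along < sp_tree`), since its
#' nozzles stay open across the gaps.
#'
#' @param h Canopy height, m.
#' @param d_across Canopy diameter across the row, m.
#' @param d_along Canopy diameter along the row, m.
#' @param sp_tree Spacing within the row, m.
#' @return Apparent canopy volume in m3/tree.
#' @export
#' @examples
#' canopy_volume_case1(2.51, 4.33, 3.08)   # 17.53 m3
canopy_volume_case1 <- function(h, d_across, d_along) {
  check_positive(h, "h")
  check_positive(d_across, "d_across")
  check_positive(d_along, "d_along")
  pi / 6 * h * d_across * d_along
}

#' @rdname canopy_volume_case1
#' @export
canopy_volume_case2 <- function(h, d_across, sp_tree) {
  check_positive(h, "h")
  check_positive(d_across, "d_across")
  check_positive(sp_tree, "sp_tree")
  pi / 6 * h * d_across * sp_tree
}

#' Leaf surface per tree
#'
#' One-sided leaf area per tree, `S = LAD * VT`.
#'
#' @param lad Leaf area density, m2 leaf / m3 canopy.
#' @param vt Apparent canopy volume, m3/tree.
#' @return One-sided leaf area, m2/tree.
#' @export
leaf_surface <- function(lad, vt) {
  check_positive(lad, "lad")
  check_positive(vt, "vt")
  lad * vt
}

#' Leaf surface to be wetted
#'
#' `S_W = 2 * S * f_target`: both leaf sides must receive product, and only
#' the canopy fraction relevant to the target class needs wetting (all of it
#' for internal applications, two thirds for intermediate, one third for
#' external, encoded by `f_target` of 1, 0.75 and 0.49 respectively).
#'
#' @param s One-sided leaf area, m2/tree.
#' @param f_target Wetting fraction in (0, 1].
#' @return Leaf surface to be wetted, m2/tree.
#' @export
wetted_surface <- function(s, f_target) {
  check_positive(s, "s")
  check_fraction(f_target, "f_target")
  2 * s * f_target
}

#' Canopy metrics for a whole orchard
#'
#' Evaluates density, both volume cases where applicable, and leaf surfaces
#' for one geometry. `vt2` and the derived case-2 surfaces are present only
#' when `d_along < sp_tree` (gapped rows); at `d_along = sp_tree` the two
#' cases coincide and only case 1 is reported.
#'
#' @param geometry An [orchard_geometry()].
#' @param lad Leaf area density, m2/m3.
#' @param f_target Wetting fraction in (0, 1].
#' @return A list of class `"canopy_metrics"` with `n_trees`, `vt1`, `s1`,
#'   `s_w1`, and (when applicable) `vt2`, `s2`, `s_w2`.
#' @export
canopy_metrics <- function(geometry, lad, f_target = 1) {
  stopifnot(inherits(geometry, "orchard_geometry"))
  check_positive(lad, "lad")
  check_fraction(f_target, "f_target")
  n <- tree_density(geometry$sp_tree, geometry$sp_row)
  vt1 <- canopy_volume_case1(geometry$h, geometry$d_across, geometry$d_along)
  s1 <- leaf_surface(lad, vt1)
  out <- list(n_trees = n, vt1 = vt1, s1 = s1,
              s_w1 = wetted_surface(s1, f_target),
              vt2 = NULL, s2 = NULL, s_w2 = NULL)
  if (geometry$d_along < geometry$sp_tree) {
    out$vt2 <- canopy_volume_case2(geometry$h, geometry$d_across,
                                   geometry$sp_tree)
    out$s2 <- leaf_surface(lad, out$vt2)
    out$s_w2 <- wetted_surface(out$s2, f_target)
  }
  structure(out, class = "canopy_metrics")
}
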