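# Reference databases: pest/disease targets, leaf area density (LAD) by
# cultivar density group x pruning level, and the product registry mapping
# active ingredients to a mode-of-action class and its minimum deposit.
# All three ship as editable CSV files under inst/extdata and are re-validated
# on every load, so user-edited copies pass through the same checks.

#' Message catalogue for advisory warnings
#'
#' Warning messages attached to recommendations are stored as stable
#' identifiers in the databases and rendered to English text with this
#' catalogue, so the texts can be localized without touching data files.
#'
#' @return Named character vector: identifier -> message template.
#' @export
#' @examples
#' warning_messages()[["check_label"]]
warning_messages <- function() {
  c(
    check_label = paste(
      "Check the technical data sheet of the product to verify if it is",
      "authorized for this use and/or if there are limits of maximum",
      "application volume rate or maximum dose"),
    no_authorized_products = "There are no authorized products",
    trunk_application = "Applications directly on the trunk",
    bait_treatment = "Application as bait treatment"
  )
}

cv_extdata <- function(file) {
  path <- system.file("extdata", file, package = "citrusvol", mustWork = TRUE)
  path
}

read_ref_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# valid enum levels, shared by loaders and lookups
.cultivar_groups <- c("low", "medium", "high")
.pruning_levels <- c("severe", "normal", "without_pruning")
.application_classes <- c("internal", "intermediate", "external")
.moa_classes <- c("contact", "suffocating")

# class -> wetting fraction; the shipped target table must agree with this map
.f_target_by_class <- c(internal = 1.0, intermediate = 0.75, external = 0.49)

# mode of action -> minimum deposit (uL/cm2) on the safety side:
# organophosphate (contact reference) 3.41, mineral oil (suffocating) 4.72
.deposit_by_class <- c(contact = 3.41, suffocating = 4.72)

#' Validate a target database
#'
#' Checks the schema and the structural invariants of a pest/disease target
#' table: every `application_class` is one of internal/intermediate/external,
#' `f_target` is exactly the fraction implied by the class (1, 0.75, 0.49),
#' names are unique, and all warning identifiers are known.
#'
#' @param db A data frame with columns `target_name`, `application_class`,
#'   `f_target` and optionally `aliases`, `warnings`.
#' @return The validated table, invisibly, as a tibble.
#' @export
validate_targets <- function(db) {
  check_columns(db, c("target_name", "application_class", "f_target"),
                "target database")
  db <- tibble::as_tibble(db)
  bad <- setdiff(unique(db$application_class), .application_classes)
  if (length(bad) > 0) {
    stop("target database: invalid application_class value(s): ",
         paste(bad, collapse = ", "), "; allowed: ",
         paste(.application_classes, collapse = ", "), call. = FALSE)
  }
  expected <- unname(.f_target_by_class[db$application_class])
  off <- which(abs(db$f_target - expected) > 1e-12)
  if (length(off) > 0) {
    stop(sprintf(
      "target database: f_target for '%s' is %s but class '%s' requires %s",
      db$target_name[off[1]], format(db$f_target[off[1]]),
      db$application_class[off[1]], format(expected[off[1]])), call. = FALSE)
  }
  if (anyDuplicated(tolower(db$target_name))) {
    stop("target database: duplicated target_name entries", call. = FALSE)
  }
  if ("warnings" %in% names(db)) {
    ids <- unlist(strsplit(db$warnings[!is.na(db$warnings)], ";", fixed = TRUE))
    unknown <- setdiff(ids, names(warning_messages()))
    if (length(unknown) > 0) {
      stop("target database: unknown warning identifier(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(db)
}

#' Validate a LAD database
#'
#' Checks the 3 x 3 leaf-area-density table: all nine combinations of
#' cultivar density group and pruning level present exactly once, LAD strictly
#' positive, and LAD strictly increasing both along
#' severe -> normal -> without_pruning (within a group) and along
#' low -> medium -> high (within a pruning level).
#'
#' @param db Data frame with columns `cultivar_group`, `pruning`, `lad`.
#' @return The validated table, invisibly, as a tibble.
#' @export
validate_lad_table <- function(db) {
  check_columns(db, c("cultivar_group", "pruning", "lad"), "LAD database")
  db <- tibble::as_tibble(db)
  if (!all(db$cultivar_group %in% .cultivar_groups)) {
    stop("LAD database: cultivar_group must be one of: ",
         paste(.cultivar_groups, collapse = ", "), call. = FALSE)
  }
  if (!all(db$pruning %in% .pruning_levels)) {
    stop("LAD database: pruning must be one of: ",
         paste(.pruning_levels, collapse = ", "), call. = FALSE)
  }
  if (nrow(db) != 9 ||
      anyDuplicated(paste(db$cultivar_group, db$pruning))) {
    stop("LAD database must contain each group x pruning combination exactly once",
         call. = FALSE)
  }
  if (any(db$lad <= 0)) stop("LAD database: lad must be > 0", call. = FALSE)
  m <- matrix(NA_real_, 3, 3, dimnames = list(.cultivar_groups, .pruning_levels))
  m[cbind(db$cultivar_group, db$pruning)] <- db$lad
  if (any(apply(m, 1, diff) <= 0)) {
    stop("LAD database: lad must increase strictly with lighter pruning",
         call. = FALSE)
  }
  if (any(apply(m, 2, diff) <= 0)) {
    stop("LAD database: lad must increase strictly with cultivar density group",
         call. = FALSE)
  }
  invisible(db)
}

#' Validate a product registry
#'
#' Checks that every active ingredient maps to a known mode-of-action class
#' and that the registered minimum deposit equals the class reference value
#' (3.41 uL/cm2 for contact products, 4.72 uL/cm2 for suffocating products).
#'
#' @param db Data frame with columns `active_ingredient`, `moa_class`,
#'   `deposit_ul_cm2` and optionally `label_warnings`.
#' @return The validated table, invisibly, as a tibble.
#' @export
validate_products <- function(db) {
  check_columns(db, c("active_ingredient", "moa_class", "deposit_ul_cm2"),
                "product registry")
  db <- tibble::as_tibble(db)
  bad <- setdiff(unique(db$moa_class), .moa_classes)
  if (length(bad) > 0) {
    stop("product registry: invalid moa_class value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(db$deposit_ul_cm2 <= 0)) {
    stop("product registry: deposit_ul_cm2 must be > 0", call. = FALSE)
  }
  expected <- unname(.deposit_by_class[db$moa_class])
  off <- which(abs(db$deposit_ul_cm2 - expected) > 1e-12)
  if (length(off) > 0) {
    stop(sprintf(
      "product registry: deposit for '%s' is %s but class '%s' requires %s",
      db$active_ingredient[off[1]], format(db$deposit_ul_cm2[off[1]]),
      db$moa_class[off[1]], format(expected[off[1]])), call. = FALSE)
  }
  if (anyDuplicated(tolower(db$active_ingredient))) {
    stop("product registry: duplicated active_ingredient entries", call. = FALSE)
  }
  invisible(db)
}

#' Load the target, LAD, product and cultivar databases
#'
#' Each loader reads the bundled CSV (or a user-supplied replacement with the
#' same schema) and runs the corresponding validator, so an edited database
#' that breaks an invariant is rejected at load time.
#'
#' @param path Optional path to a replacement CSV; default is the bundled file.
#' @return A validated tibble.
#' @export
#' @examples
#' target_db()
#' lad_db()
target_db <- function(path = NULL) {
  db <- read_ref_csv(path %||% cv_extdata("targets.csv"))
  validate_targets(db)
  db
}

#' @rdname target_db
#' @export
lad_db <- function(path = NULL) {
  db <- read_ref_csv(path %||% cv_extdata("lad.csv"))
  validate_lad_table(db)
  db
}

#' @rdname target_db
#' @export
product_db <- function(path = NULL) {
  db <- read_ref_csv(path %||% cv_extdata("products.csv"))
  validate_products(db)
  db
}

#' @rdname target_db
#' @export
cultivar_db <- function(path = NULL) {
  db <- read_ref_csv(path %||% cv_extdata("cultivars.csv"))
  check_columns(db, c("cultivar", "cultivar_group"), "cultivar registry")
  if (!all(db$cultivar_group %in% .cultivar_groups)) {
    stop("cultivar registry: cultivar_group must be one of: ",
         paste(.cultivar_groups, collapse = ", "), call. = FALSE)
  }
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# case-insensitive match against names + ";"-separated aliases; on failure,
# error listing the closest names by edit distance
match_by_name <- function(query, names, aliases = NULL, what = "entry") {
  q <- tolower(trimws(query))
  idx <- match(q, tolower(names))
  if (is.na(idx) && !is.null(aliases)) {
    alias_list <- strsplit(ifelse(is.na(aliases), "", tolower(aliases)),
                           ";", fixed = TRUE)
    hit <- which(vapply(alias_list, function(a) q %in% trimws(a), logical(1)))
    if (length(hit) >= 1) idx <- hit[1]
  }
  if (is.na(idx)) {
    d <- utils::adist(q, tolower(names), partial = TRUE)
    nearest <- names[order(d)][seq_len(min(3, length(names)))]
    stop(sprintf("unknown %s: '%s'. Closest matches: %s", what, query,
                 paste(nearest, collapse = ", ")), call. = FALSE)
  }
  idx
}

warning_ids <- function(field) {
  if (length(field) != 1 || is.na(field) || !nzchar(field)) return(character(0))
  trimws(unlist(strsplit(field, ";", fixed = TRUE)))
}

#' Look up the target factor for a pest or disease
#'
#' Matches the target name (case-insensitive, scientific-name aliases
#' accepted) in the target database and returns its application class, the
#' wetting fraction `f_target` and any special advisory messages (e.g. the
#' trunk-application note for Phytophthora foot rot).
#'
#' @param target_name Pest or disease name, e.g. `"California red scale"`.
#' @param db Target database, by default the bundled one.
#' @return A list of class `"target_spec"` with elements `target_name`,
#'   `application_class`, `f_target`, `warnings` (character identifiers) and
#'   `messages` (rendered texts).
#' @export
#' @examples
#' lookup_f_target("California red scale")$f_target   # 1
#' lookup_f_target("Pezothrips kellyanus")$f_target   # 0.75
lookup_f_target <- function(target_name, db = target_db()) {
  check_scalar(target_name, "target_name")
  idx <- match_by_name(target_name, db$target_name,
                       if ("aliases" %in% names(db)) db$aliases else NULL,
                       what = "target")
  ids <- warning_ids(if ("warnings" %in% names(db)) db$warnings[idx] else NA)
  structure(list(
    target_name = db$target_name[idx],
    application_class = db$application_class[idx],
    f_target = db$f_target[idx],
    warnings = ids,
    messages = unname(warning_messages()[ids])
  ), class = "target_spec")
}

#' Look up the leaf area density for a canopy class
#'
#' @param cultivar_group One of `"low"`, `"medium"`, `"high"` (cultivar
#'   density group).
#' @param pruning One of `"severe"`, `"normal"`, `"without_pruning"`.
#' @param db LAD database, by default the bundled one.
#' @return The tabulated LAD in m2 leaf / m3 canopy.
#' @export
#' @examples
#' lookup_lad("medium", "normal")   # 3.7
lookup_lad <- function(cultivar_group, pruning, db = lad_db()) {
  cultivar_group <- match.arg(cultivar_group, .cultivar_groups)
  pruning <- match.arg(pruning, .pruning_levels)
  db$lad[db$cultivar_group == cultivar_group & db$pruning == pruning]
}

#' Look up the cultivar density group of a named cultivar
#'
#' @param cultivar Cultivar name, e.g. `"Clemenules"`.
#' @param db Cultivar registry, by default the bundled one.
#' @return One of `"low"`, `"medium"`, `"high"`.
#' @export
lookup_cultivar_group <- function(cultivar, db = cultivar_db()) {
  check_scalar(cultivar, "cultivar")
  idx <- match_by_name(cultivar, db$cultivar, what = "cultivar")
  db$cultivar_group[idx]
}

#' Look up the minimum deposit for a product
#'
#' Resolves an active ingredient through the product registry, or accepts a
#' mode-of-action class (`"contact"` or `"suffocating"`) directly for
#' products not yet registered.
#'
#' @param active_ingredient_or_class Active ingredient name (e.g.
#'   `"chlorpyrifos"`) or a class name.
#' @param db Product registry, by default the bundled one.
#' @return A list of class `"product_spec"` with elements `active_ingredient`,
#'   `moa_class`, `deposit_ul_cm2`, `warnings`, `messages`.
#' @export
#' @examples
#' lookup_deposit("chlorpyrifos")$deposit_ul_cm2   # 3.41
#' lookup_deposit("mineral oil")$deposit_ul_cm2    # 4.72
lookup_deposit <- function(active_ingredient_or_class, db = product_db()) {
  check_scalar(active_ingredient_or_class, "active_ingredient_or_class")
  q <- tolower(trimws(active_ingredient_or_class))
  if (q %in% .moa_classes) {
    return(structure(list(
      active_ingredient = NA_character_,
      moa_class = q,
      deposit_ul_cm2 = unname(.deposit_by_class[q]),
      warnings = character(0),
      messages = character(0)
    ), class = "product_spec"))
  }
  idx <- match_by_name(q, db$active_ingredient, what = "product")
  ids <- warning_ids(
    if ("label_warnings" %in% names(db)) db$label_warnings[idx] else NA)
  structure(list(
    active_ingredient = db$active_ingredient[idx],
    moa_class = db$moa_class[idx],
    deposit_ul_cm2 = db$deposit_ul_cm2[idx],
    warnings = ids,
    messages = unname(warning_messages()[ids])
  ), class = "product_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("Target: %s (%s application, f_target = %g)\n",
              x$target_name, x$application_class, x$f_target))
  for (m in x$messages) cat("  note:", m, "\n")
  invisible(x)
}

#' @export
print.product_spec <- function(x, ...) {
  cat(sprintf("Product: %s (%s, minimum deposit %g uL/cm2)\n",
              ifelse(is.na(x$active_ingredient), "<by class>",
                     x$active_ingredient),
              x$moa_class, x$deposit_ul_cm2))
  invisible(x)
}
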