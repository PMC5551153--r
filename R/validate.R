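# Internal argument checks shared across modules. All user-facing functions
# validate scalars/vectors with these so error messages name the offending
# argument consistently.

check_positive <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    stop(sprintf("`%s` must be numeric and non-missing", name), call. = FALSE)
  }
  if (finite && any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive (got %s)", name,
                 paste(format(x[x <= 0][1]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# fraction in (0, 1]
check_fraction <- function(x, name) {
  check_positive(x, name)
  if (any(x > 1)) {
    stop(sprintf("`%s` must lie in (0, 1] (got %s)", name,
                 format(x[x > 1][1])), call. = FALSE)
  }
  invisible(x)
}

check_scalar <- function(x, name) {
  if (length(x) != 1) {
    stop(sprintf("`%s` must be a single value", name), call. = FALSE)
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
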