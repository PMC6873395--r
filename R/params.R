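#' Simulation parameter set
#'
#' Bundles, for each experimental group, the per-feature average abundance
#' level `mu`, the per-feature biological variability (dispersion) `phi`,
#' and one library size per sample.  All groups share the same feature set
#' and ordering.  `mu` sets the gamma mean for a feature, `phi` its squared
#' coefficient of variation across biological replicates (the gamma draw has
#' mean `mu` and variance `phi * mu^2`); library sizes are the number of
#' reads drawn without replacement at the sequencing step.
#'
#' @param feature_ids character vector of unique feature (OTU/ASV) ids.
#' @param groups named list; each element a list with numeric vectors
#'   `mu` (length C, >= 0), `phi` (length C, >= 0) and `lib_sizes`
#'   (one positive integer per sample in the group).
#' @param .allow_na_phi internal: permit `NA` phi vectors for groups whose
#'   dispersion could not be estimated (to be filled in via
#'   [assemble_params()] hybrid mode).
#'
#' @return an object of class `sim_params`.
#' @examples
#' p <- sim_params(
#'   feature_ids = c("otu1", "otu2", "otu3"),
#'   groups = list(
#'     ctrl = list(mu = c(100, 10, 1), phi = c(0.3, 0.3, 0.3),
#'                 lib_sizes = c(5000, 6000, 5500))
#'   )
#' )
#' p
#' @export
sim_params <- function(feature_ids, groups, .allow_na_phi = FALSE) {
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids)) {
    abort_data("feature_ids must be unique")
  }
  C <- length(feature_ids)
  if (C < 1L) abort_data("at least one feature is required")
  if (!is.list(groups) || length(groups) < 1L) {
    abort_data("at least one group is required")
  }
  if (is.null(names(groups)) || any(names(groups) == "") ||
      anyDuplicated(names(groups))) {
    abort_data("groups must be a named list with unique names")
  }
  for (g in names(groups)) {
    grp <- groups[[g]]
    for (fld in c("mu", "phi", "lib_sizes")) {
      if (is.null(grp[[fld]]) || !is.numeric(grp[[fld]])) {
        abort_data(sprintf("group '%s': missing or non-numeric '%s'", g, fld))
      }
    }
    if (length(grp$mu) != C) {
      abort_data(sprintf(
        "group '%s': mu has length %d but there are %d features",
        g, length(grp$mu), C))
    }
    if (length(grp$phi) != C) {
      abort_data(sprintf(
        "group '%s': phi has length %d but there are %d features",
        g, length(grp$phi), C))
    }
    if (any(grp$mu < 0) || anyNA(grp$mu)) {
      abort_data(sprintf("group '%s': mu must be non-negative and non-missing", g))
    }
    phi_na <- anyNA(grp$phi)
    if (phi_na && !.allow_na_phi) {
      abort_data(sprintf("group '%s': phi contains missing values", g))
    }
    if (!phi_na && any(grp$phi < 0)) {
      abort_data(sprintf("group '%s': phi must be non-negative", g))
    }
    ls <- grp$lib_sizes
    if (length(ls) < 1L) {
      abort_data(sprintf("group '%s': needs at least one sample", g))
    }
    if (anyNA(ls) || any(ls < 1) || any(!is_wholenumber(ls))) {
      abort_data(sprintf("group '%s': lib_sizes must be positive integers", g))
    }
    groups[[g]]$mu <- as.numeric(grp$mu)
    groups[[g]]$phi <- as.numeric(grp$phi)
    groups[[g]]$lib_sizes <- as.integer(round(ls))
  }
  structure(list(feature_ids = feature_ids, groups = groups),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  C <- length(x$feature_ids)
  cat(sprintf("<sim_params> %d features, %d group(s)\n", C, length(x$groups)))
  for (g in names(x$groups)) {
    grp <- x$groups[[g]]
    cat(sprintf("  %s: %d sample(s), depth %s..%s, mean mu %.3g, mean phi %s\n",
                g, length(grp$lib_sizes),
                format(min(grp$lib_sizes)), format(max(grp$lib_sizes)),
                mean(grp$mu),
                if (anyNA(grp$phi)) "<not set>" else sprintf("%.3g", mean(grp$phi))))
  }
  invisible(x)
}

n_features <- function(params) length(params$feature_ids)

n_samples_total <- function(params) {
  sum(vapply(params$groups, function(g) length(g$lib_sizes), integer(1)))
}

params_has_na_phi <- function(params) {
  any(vapply(params$groups, function(g) anyNA(g$phi), logical(1)))
}
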