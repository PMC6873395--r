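## Parameter estimation from real grouped count tables.

#' Estimator configuration
#'
#' @param normalization how samples are put on a common scale before
#'   moments are taken: `"total_sum"` (default) rescales each sample by
#'   mean library size / its library size, keeping values on the count
#'   scale; `"median_of_ratios"` uses DESeq-style size factors computed
#'   from features observed in every sample.
#' @param phi_estimator `"poisson_corrected"` (default) subtracts the
#'   Poisson sampling component from the within-group variance before
#'   forming the dispersion, following `Var = mu * (1 + mu * phi)`:
#'   `phi_hat = (s^2 - mu_hat) / mu_hat^2`; `"cv2"` is the naive squared
#'   coefficient of variation `s^2 / mu_hat^2`, which conflates technical
#'   and biological variance.
#' @param phi_floor lower clip for estimated dispersions of present
#'   features (the corrected moment estimator can go negative at low
#'   variance).
#' @param min_replicates_for_phi minimum number of replicates a group needs
#'   before its dispersion is estimated (>= 2; variance is undefined below).
#' @return an `estimator_config` object.
#' @export
estimator_config <- function(normalization = c("total_sum", "median_of_ratios"),
                             phi_estimator = c("poisson_corrected", "cv2"),
                             phi_floor = 1e-8,
                             min_replicates_for_phi = 2L) {
  normalization <- match.arg(normalization)
  phi_estimator <- match.arg(phi_estimator)
  if (phi_floor <= 0) abort_data("phi_floor must be > 0")
  if (min_replicates_for_phi < 2L) {
    abort_data("min_replicates_for_phi must be >= 2")
  }
  structure(list(normalization = normalization,
                 phi_estimator = phi_estimator,
                 phi_floor = phi_floor,
                 min_replicates_for_phi = as.integer(min_replicates_for_phi)),
            class = "estimator_config")
}

#' Normalize a count table to a common library-size scale
#'
#' @param table a [grouped_count_table()].
#' @param config an [estimator_config()]; only `normalization` is used.
#' @return numeric matrix of normalized, count-scale intensities (same
#'   dimnames as the input counts).
#' @examples
#' m <- matrix(c(10, 90, 30, 270), nrow = 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' tab <- grouped_count_table(m, c(s1 = "g", s2 = "g"))
#' colSums(normalize_counts(tab)) # equalized
#' @export
normalize_counts <- function(table, config = estimator_config()) {
  counts <- table$counts
  depths <- colSums(counts)
  zero_cols <- which(depths == 0)
  if (length(zero_cols) > 0L) {
    abort_data("degenerate sample(s) with all-zero counts: ",
               paste(colnames(counts)[zero_cols], collapse = ", "))
  }
  if (config$normalization == "total_sum") {
    factors <- mean(depths) / depths
    sweep(counts + 0, 2, factors, `*`)
  } else {
    log_counts <- log(counts)
    log_counts[!is.finite(log_counts)] <- NA
    ref <- rowMeans(log_counts)            # NA unless feature seen everywhere
    usable <- is.finite(ref)
    if (!any(usable)) {
      abort_data("median-of-ratios normalization needs at least one feature ",
                 "observed in every sample; none found (use total_sum)")
    }
    sf <- apply(log_counts[usable, , drop = FALSE], 2, function(lc) {
      exp(median(lc - ref[usable], na.rm = TRUE))
    })
    sweep(counts + 0, 2, sf, `/`)
  }
}

#' Estimate simulation parameters from a real count table
#'
#' Per group: `mu_hat` is the mean of normalized counts over replicates;
#' `phi_hat` is a moment estimator of the dispersion (see
#' [estimator_config()]), clipped at `phi_floor` and set to 0 for features
#' that are absent from the group (`mu_hat = 0`); library sizes are the raw
#' column sums of the group's samples.
#'
#' Groups with fewer than `min_replicates_for_phi` replicates cannot yield
#' a variance: by default this is an error pointing at hybrid mode, or with
#' `allow_missing_phi = TRUE` the group's `phi` is returned as `NA` so a
#' user-supplied vector can be merged in via [assemble_params()].
#'
#' @param table a [grouped_count_table()].
#' @param config an [estimator_config()].
#' @param allow_missing_phi return `NA` phi for under-replicated groups
#'   instead of failing.
#' @return a [sim_params()] object (scale of `mu` is the normalized count
#'   scale; only relative abundances are identifiable from a count table).
#' @export
estimate_parameters <- function(table, config = estimator_config(),
                                allow_missing_phi = FALSE) {
  norm <- normalize_counts(table, config)
  depths <- colSums(table$counts)
  groups <- list()
  for (g in table_groups(table)) {
    cols <- group_columns(table, g)
    sub <- norm[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    if (length(cols) < config$min_replicates_for_phi) {
      if (!allow_missing_phi) {
        abort_data(sprintf(
          paste0("group '%s' has %d replicate(s) but dispersion estimation ",
                 "needs at least %d; supply phi for this group via ",
                 "assemble_params() hybrid mode"),
          g, length(cols), config$min_replicates_for_phi))
      }
      phi <- rep(NA_real_, length(mu))
    } else {
      s2 <- apply(sub, 1, var)
      raw_phi <- if (config$phi_estimator == "poisson_corrected") {
        (s2 - mu) / mu^2
      } else {
        s2 / mu^2
      }
      phi <- ifelse(mu > 0, pmax(config$phi_floor, raw_phi), 0)
    }
    groups[[g]] <- list(mu = unname(mu), phi = unname(phi),
                        lib_sizes = unname(depths[cols]))
  }
  sim_params(rownames(table$counts), groups,
             .allow_na_phi = allow_missing_phi)
}

#' Assemble simulation parameters from estimated and user-supplied parts
#'
#' Hybrid mode: user-supplied vectors override estimated ones
#' component-wise per group.  Each of `mu`, `phi` and `lib_sizes` must be
#' available for every group from at least one source.
#'
#' @param estimated a [sim_params()] (possibly with `NA` phi from
#'   [estimate_parameters()]) or `NULL`.
#' @param user_mu,user_phi,user_lib_sizes `NULL`, or named lists of numeric
#'   vectors keyed by group name.
#' @param feature_ids required when `estimated` is `NULL`; otherwise taken
#'   from it.
#' @return a fully validated [sim_params()] object.
#' @examples
#' p <- assemble_params(
#'   estimated = NULL,
#'   user_mu = list(a = c(10, 5)), user_phi = list(a = c(0.2, 0.2)),
#'   user_lib_sizes = list(a = c(100, 100)),
#'   feature_ids = c("otu1", "otu2"))
#' @export
assemble_params <- function(estimated = NULL, user_mu = NULL, user_phi = NULL,
                            user_lib_sizes = NULL, feature_ids = NULL) {
  user <- list(mu = user_mu, phi = user_phi, lib_sizes = user_lib_sizes)
  for (fld in names(user)) {
    u <- user[[fld]]
    if (!is.null(u) && (!is.list(u) || is.null(names(u)) || any(names(u) == ""))) {
      abort_data(sprintf("user_%s must be a named list keyed by group", fld))
    }
  }
  if (is.null(estimated)) {
    group_names <- unique(unlist(lapply(user, names)))
    if (length(group_names) == 0L) {
      abort_data("nothing to assemble: no estimate and no user vectors")
    }
    if (is.null(feature_ids)) {
      len <- unique(unlist(lapply(user[c("mu", "phi")], function(u)
        vapply(u, length, integer(1)))))
      if (length(len) != 1L) {
        abort_data("cannot infer the feature set: supply feature_ids")
      }
      feature_ids <- sprintf("feature_%d", seq_len(len))
    }
    base_groups <- stats::setNames(
      rep(list(list(mu = NULL, phi = NULL, lib_sizes = NULL)),
          length(group_names)), group_names)
  } else {
    if (!inherits(estimated, "sim_params")) {
      abort_data("estimated must be a sim_params object or NULL")
    }
    feature_ids <- feature_ids %||% estimated$feature_ids
    group_names <- names(estimated$groups)
    base_groups <- estimated$groups
    for (grp in names(base_groups)) {
      if (anyNA(base_groups[[grp]]$phi)) base_groups[[grp]]$phi <- NULL
    }
    unknown <- setdiff(unique(unlist(lapply(user, names))), group_names)
    if (length(unknown) > 0L) {
      abort_data("user vectors reference unknown group(s): ",
                 paste(unknown, collapse = ", "))
    }
  }
  C <- length(feature_ids)
  groups <- list()
  for (g in group_names) {
    grp <- base_groups[[g]]
    for (fld in c("mu", "phi", "lib_sizes")) {
      if (!is.null(user[[fld]][[g]])) grp[[fld]] <- user[[fld]][[g]]
      if (is.null(grp[[fld]])) {
        abort_data(sprintf(
          "group '%s': no source provides '%s' (hybrid mode needs every ",
          g, fld), "component from the estimate or the user")
      }
    }
    for (fld in c("mu", "phi")) {
      if (length(grp[[fld]]) != C) {
        abort_data(sprintf(
          "group '%s': %s has length %d but there are %d features",
          g, fld, length(grp[[fld]]), C))
      }
    }
    groups[[g]] <- grp[c("mu", "phi", "lib_sizes")]
  }
  sim_params(feature_ids, groups)
}
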