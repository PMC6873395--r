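## Parameterized scenario families and the test fixture generator.

#' Define a preset simulation scenario
#'
#' A scenario is a compact, named recipe that deterministically expands
#' (given its seed) into a full [sim_params()] object: a baseline abundance
#' profile for group 1, differential-abundance perturbations for the other
#' groups, a dispersion level, and uniformly drawn library sizes.
#'
#' @param name identifier.
#' @param n_features number of features (>= 2).
#' @param n_groups number of experimental groups.
#' @param replicates_per_group samples per group.
#' @param abundance_shape `"uniform"`, `"geometric_skew"` (abundance of
#'   feature i proportional to `skew_parameter^(i-1)`) or
#'   `"lognormal_skew"` (log-normal weights with sdlog `skew_parameter`,
#'   the classical skewed species-abundance distribution).
#' @param skew_parameter ratio in (0, 1] for `geometric_skew`; sdlog > 0
#'   for `lognormal_skew`; ignored for `uniform`.
#' @param phi_level dispersion: a scalar applied to all features or a
#'   vector of length `n_features`.
#' @param depth_range integer pair `(min, max)`; each sample's library size
#'   is drawn uniformly from this range.
#' @param fraction_da_features fraction of features made differentially
#'   abundant in groups 2..K relative to group 1.
#' @param da_fold_change fold change (> 1) applied to the perturbed
#'   features, half up and half down (ties to up).
#' @param fraction_absent_per_group fraction of features structurally
#'   absent (`mu = 0`) in each group, drawn independently per group.
#'   Emulates community turnover between conditions — the dominant source
#'   of zeros in multi-community designs (e.g. many food or body-site
#'   groups sharing one feature catalogue), where sparsity is mostly
#'   structural rather than depth-driven.
#' @param total_intensity total of the group-1 `mu` vector, i.e. the
#'   expected size of the fragment pool each sample is sequenced from.
#'   Default `NULL` means 20 x the mean depth, so the sequencing step draws
#'   about 5% of the pool — a without-replacement regime close to, but
#'   measurably distinct from, multinomial sampling.
#' @param seed integer seed owned by the scenario; expansion is pure given
#'   the scenario object.
#' @return a `preset_scenario` object.
#' @export
preset_scenario <- function(name, n_features,
                            n_groups = 2L,
                            replicates_per_group = 5L,
                            abundance_shape = c("uniform", "geometric_skew",
                                                "lognormal_skew"),
                            skew_parameter = 1,
                            phi_level = 0.3,
                            depth_range = c(5000L, 50000L),
                            fraction_da_features = 0.1,
                            da_fold_change = 3,
                            fraction_absent_per_group = 0,
                            total_intensity = NULL,
                            seed = 1L) {
  abundance_shape <- match.arg(abundance_shape)
  if (n_features < 2L) abort_data("n_features must be >= 2")
  if (n_groups < 1L) abort_data("n_groups must be >= 1")
  if (replicates_per_group < 1L) abort_data("replicates_per_group must be >= 1")
  if (length(depth_range) != 2L || depth_range[1] < 1 ||
      depth_range[1] > depth_range[2]) {
    abort_data("depth_range must be (min, max) with 1 <= min <= max")
  }
  if (fraction_da_features < 0 || fraction_da_features > 1) {
    abort_data("fraction_da_features must be in [0, 1]")
  }
  if (da_fold_change <= 1) abort_data("da_fold_change must be > 1")
  if (fraction_absent_per_group < 0 || fraction_absent_per_group >= 1) {
    abort_data("fraction_absent_per_group must be in [0, 1)")
  }
  if (!length(phi_level) %in% c(1L, n_features) || any(phi_level < 0)) {
    abort_data("phi_level must be a non-negative scalar or length-n_features vector")
  }
  structure(list(name = name,
                 n_features = as.integer(n_features),
                 n_groups = as.integer(n_groups),
                 replicates_per_group = as.integer(replicates_per_group),
                 abundance_shape = abundance_shape,
                 skew_parameter = skew_parameter,
                 phi_level = phi_level,
                 depth_range = as.integer(round(depth_range)),
                 fraction_da_features = fraction_da_features,
                 da_fold_change = da_fold_change,
                 fraction_absent_per_group = fraction_absent_per_group,
                 total_intensity = total_intensity %||%
                   (20 * mean(depth_range)),
                 seed = as.integer(seed)),
            class = "preset_scenario")
}

#' @export
print.preset_scenario <- function(x, ...) {
  cat(sprintf("<preset_scenario> '%s'\n", x$name))
  cat(sprintf("  %d features, %d group(s) x %d replicate(s)\n",
              x$n_features, x$n_groups, x$replicates_per_group))
  cat(sprintf("  abundance: %s (skew %.3g), phi %.3g, depth %s..%s\n",
              x$abundance_shape, x$skew_parameter, mean(x$phi_level),
              format(x$depth_range[1]), format(x$depth_range[2])))
  cat(sprintf("  DA: %.0f%% of features at fold change %.3g, seed %d\n",
              100 * x$fraction_da_features, x$da_fold_change, x$seed))
  invisible(x)
}

baseline_mu <- function(scenario) {
  C <- scenario$n_features
  total <- scenario$total_intensity
  w <- switch(scenario$abundance_shape,
    uniform = rep(1, C),
    geometric_skew = {
      r <- scenario$skew_parameter
      if (r <= 0 || r > 1) abort_data("geometric_skew needs ratio in (0, 1]")
      r^(seq_len(C) - 1)
    },
    lognormal_skew = {
      if (scenario$skew_parameter <= 0) {
        abort_data("lognormal_skew needs sdlog > 0")
      }
      rlnorm(C, meanlog = 0, sdlog = scenario$skew_parameter)
    },
    abort_data("unknown abundance shape: ", scenario$abundance_shape))
  total * w / sum(w)
}

#' Expand a preset scenario into simulation parameters
#'
#' Deterministic given `scenario$seed` (the caller's RNG state is left
#' untouched).  Group 1 carries the baseline abundance profile; every
#' further group perturbs its own random `fraction_da_features` subset of
#' features by `da_fold_change`, half up and half down (odd counts round
#' toward "up").
#'
#' @param scenario a [preset_scenario()].
#' @return a [sim_params()] object.
#' @examples
#' sc <- preset_scenario("demo", n_features = 4,
#'                       abundance_shape = "geometric_skew",
#'                       skew_parameter = 0.5, total_intensity = 150)
#' expand_preset(sc)$groups$group_1$mu # 80 40 20 10
#' @export
expand_preset <- function(scenario) {
  stopifnot(inherits(scenario, "preset_scenario"))
  with_local_seed(scenario$seed, {
    C <- scenario$n_features
    mu1 <- baseline_mu(scenario)
    phi <- rep(scenario$phi_level, length.out = C)
    groups <- list()
    for (k in seq_len(scenario$n_groups)) {
      mu <- mu1
      if (scenario$fraction_absent_per_group > 0) {
        n_absent <- round(scenario$fraction_absent_per_group * C)
        if (n_absent >= C) n_absent <- C - 1L
        mu[sample.int(C, n_absent)] <- 0
      }
      if (k > 1L && scenario$fraction_da_features > 0) {
        n_da <- round(scenario$fraction_da_features * C)
        if (n_da > 0L) {
          da_idx <- sample.int(C, n_da)
          n_up <- ceiling(n_da / 2)
          mu[da_idx[seq_len(n_up)]] <-
            mu[da_idx[seq_len(n_up)]] * scenario$da_fold_change
          if (n_da > n_up) {
            dn <- da_idx[(n_up + 1):n_da]
            mu[dn] <- mu[dn] / scenario$da_fold_change
          }
        }
      }
      ## sample.int avoids the sample() scalar-range surprise when
      ## depth_range collapses to a single value
      lib_sizes <- scenario$depth_range[1] - 1L +
        sample.int(scenario$depth_range[2] - scenario$depth_range[1] + 1L,
                   scenario$replicates_per_group, replace = TRUE)
      groups[[sprintf("group_%d", k)]] <-
        list(mu = mu, phi = phi, lib_sizes = lib_sizes)
    }
    sim_params(sprintf("OTU_%04d", seq_len(C)), groups)
  })
}

#' Expand a preset and simulate it, returning ground truth and data
#'
#' Convenience fixture generator used heavily by the round-trip tests:
#' the returned pair holds the true parameters next to the simulated table.
#'
#' @param scenario a [preset_scenario()].
#' @param population_scale passed to [simulate_counts()].
#' @return list with elements `params` ([sim_params()]) and `result`
#'   (`sim_result`).
#' @export
generate_fixture <- function(scenario, population_scale = 1) {
  params <- expand_preset(scenario)
  result <- simulate_counts(params, seed = scenario$seed,
                            population_scale = population_scale)
  list(params = params, result = result)
}

preset_catalogue <- list(
  tiny_demo = list(
    description = "30 features, 2 groups x 3 replicates, shallow depth; for examples and smoke tests",
    args = list(n_features = 30L, n_groups = 2L, replicates_per_group = 3L,
                abundance_shape = "geometric_skew", skew_parameter = 0.8,
                phi_level = 0.3, depth_range = c(500L, 1000L),
                fraction_da_features = 0.2, da_fold_change = 3)),
  animal_gut_like = list(
    description = "gut microbiome regime: 3541 features, 2 groups x 5 replicates, deep sequencing, moderate (~79%) sparsity",
    args = list(n_features = 3541L, n_groups = 2L, replicates_per_group = 5L,
                abundance_shape = "lognormal_skew", skew_parameter = 2.8,
                phi_level = 0.4, depth_range = c(88692L, 832309L),
                fraction_da_features = 0.1, da_fold_change = 3,
                fraction_absent_per_group = 0.72)),
  raw_milk_cheese_like = list(
    description = "food microbiome regime: 310 features, 40 groups x 3 replicates, extreme (~97%) sparsity",
    args = list(n_features = 310L, n_groups = 40L, replicates_per_group = 3L,
                abundance_shape = "lognormal_skew", skew_parameter = 2.8,
                phi_level = 0.8, depth_range = c(28536L, 349754L),
                fraction_da_features = 0.15, da_fold_change = 4,
                fraction_absent_per_group = 0.96)),
  hmp_like = list(
    description = "human microbiome regime: 9758 features, 8 body-site groups x 5 replicates, shallow depth, high biological variability",
    args = list(n_features = 9758L, n_groups = 8L, replicates_per_group = 5L,
                abundance_shape = "lognormal_skew", skew_parameter = 2.5,
                phi_level = 1.0, depth_range = c(2798L, 24095L),
                fraction_da_features = 0.2, da_fold_change = 4))
)

#' List the built-in preset scenario families
#'
#' @return data.frame with columns `name` and `description`.
#' @export
list_presets <- function() {
  data.frame(
    name = names(preset_catalogue),
    description = vapply(preset_catalogue, `[[`, character(1), "description"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Fetch a built-in preset scenario by name
#'
#' @param name one of the names in [list_presets()].
#' @param ... overrides for any [preset_scenario()] field (e.g. `seed`).
#' @return a [preset_scenario()] object.
#' @export
get_preset <- function(name, ...) {
  if (!name %in% names(preset_catalogue)) {
    abort_data(sprintf("unknown preset '%s'; available: %s", name,
                       paste(names(preset_catalogue), collapse = ", ")))
  }
  args <- utils::modifyList(
    c(list(name = name), preset_catalogue[[name]]$args), list(...))
  do.call(preset_scenario, args)
}
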