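## Core generative model: gamma biological step, integer fragment-pool
## construction, and exact multivariate hypergeometric (MHG) sequencing.

#' Draw per-replicate feature abundances from a gamma law
#'
#' For feature i the draw has shape `1/phi[i]` and scale `phi[i] * mu[i]`,
#' hence mean `mu[i]` and variance `phi[i] * mu[i]^2`.  The degenerate
#' limits are handled without sampling: `phi = 0` yields exactly `mu`
#' (the Poisson-only limit, no biological variability) and `mu = 0` yields
#' exactly 0 (a structurally absent feature).
#'
#' @param mu numeric vector of non-negative mean abundance levels.
#' @param phi numeric vector of non-negative dispersions, same length.
#' @param n_replicates number of replicate columns to draw.
#' @param seed optional integer seed set before drawing.
#' @return numeric matrix, `length(mu)` x `n_replicates`.
#' @examples
#' set.seed(1)
#' x <- sample_gamma_abundances(mu = c(10, 0, 5), phi = c(0.5, 0.2, 0))
#' x[2, ] # structurally absent -> 0
#' x[3, ] # phi = 0 -> exactly mu
#' @export
sample_gamma_abundances <- function(mu, phi, n_replicates = 1L, seed = NULL) {
  if (length(mu) != length(phi)) {
    abort_data("mu and phi must have the same length")
  }
  if (anyNA(mu) || anyNA(phi) || any(mu < 0) || any(phi < 0)) {
    abort_data("mu and phi must be non-negative and non-missing")
  }
  if (n_replicates < 1L) abort_data("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  C <- length(mu)
  out <- matrix(0, nrow = C, ncol = n_replicates)
  stochastic <- mu > 0 & phi > 0
  fixed <- mu > 0 & phi == 0
  if (any(fixed)) out[fixed, ] <- mu[fixed]
  if (any(stochastic)) {
    ns <- sum(stochastic)
    out[stochastic, ] <- rgamma(ns * n_replicates,
                                shape = rep(1 / phi[stochastic], n_replicates),
                                scale = rep(phi[stochastic] * mu[stochastic],
                                            n_replicates))
  }
  out
}

#' Build an integer fragment pool from continuous abundances
#'
#' The MHG sequencing step needs an integer urn.  Continuous abundances are
#' apportioned by largest remainder onto a target total
#' `max(round(sum(raw)), ceiling(lib_size * population_scale))`, which hits
#' the target exactly, preserves proportions as closely as integer rounding
#' allows, guarantees the pool can cover the requested library size, and
#' never assigns fragments to a feature with zero raw abundance.
#'
#' @param raw numeric vector of non-negative continuous abundances.
#' @param lib_size library size (number of reads) the pool will be sampled
#'   with.
#' @param population_scale multiplier (>= 1) on `lib_size` for the minimum
#'   pool total; larger values make the pool large relative to the depth,
#'   pushing the sequencing step toward the with-replacement (multinomial)
#'   regime.
#' @return a `population` object: list with integer vector `m` and `total`.
#' @examples
#' build_population(c(0.6, 0.4), lib_size = 10)
#' @export
build_population <- function(raw, lib_size, population_scale = 1) {
  if (anyNA(raw) || any(raw < 0)) {
    abort_data("raw abundances must be non-negative and non-missing")
  }
  if (sum(raw) <= 0) {
    abort_data("degenerate sample: all abundances are zero")
  }
  if (population_scale < 1) abort_data("population_scale must be >= 1")
  if (lib_size < 0 || !is_wholenumber(lib_size)) {
    abort_data("lib_size must be a non-negative integer")
  }
  target <- max(round(sum(raw)), ceiling(lib_size * population_scale))
  m <- largest_remainder(raw, target)
  structure(list(m = m, total = sum(m)), class = "population")
}

#' Exact multivariate hypergeometric draw
#'
#' Samples `n_draws` items without replacement from an urn whose class
#' counts are `pop$m`, by the exact sequential decomposition: class i is a
#' univariate hypergeometric draw conditional on what the previous classes
#' used up, and the last class takes the remainder.  The column sum is
#' `n_draws` exactly and each count is bounded by its class size.
#'
#' @param pop a `population` object from [build_population()], or a list
#'   with integer vector `m` (and optionally `total`).
#' @param n_draws number of items to draw, `0 <= n_draws <= pop$total`.
#' @param seed optional integer seed.
#' @return integer vector of class counts summing to `n_draws`.
#' @examples
#' pop <- list(m = c(3L, 2L, 5L), total = 10L)
#' sample_mhg(pop, 4, seed = 1)
#' @export
sample_mhg <- function(pop, n_draws, seed = NULL) {
  m <- as.integer(pop$m)
  total <- as.integer(pop$total %||% sum(m))
  if (anyNA(m) || any(m < 0)) abort_data("population counts must be >= 0")
  if (total != sum(m)) abort_data("population total does not match sum(m)")
  if (n_draws < 0) abort_data("n_draws must be >= 0")
  if (n_draws > total) {
    abort_data(sprintf(
      "insufficient population: requested %d draws from a pool of %d fragments",
      n_draws, total))
  }
  if (!is.null(seed)) set.seed(seed)
  C <- length(m)
  y <- integer(C)
  rem_draws <- as.integer(n_draws)
  rem_total <- total
  for (i in seq_len(C)) {
    if (rem_draws == 0L) break
    if (i == C) {
      y[i] <- rem_draws
      break
    }
    if (rem_draws == rem_total) {
      ## exhaustive draw on the remaining urn
      y[i:C] <- m[i:C]
      break
    }
    y[i] <- rhyper(1L, m[i], rem_total - m[i], rem_draws)
    rem_draws <- rem_draws - y[i]
    rem_total <- rem_total - m[i]
  }
  y
}

#' Probability that a feature receives zero counts
#'
#' Closed form for the marginal dropout probability of feature i under the
#' MHG sequencing step: `P(Y_i = 0) = choose(total - m_i, n) / choose(total, n)`,
#' evaluated in log space so it is overflow-safe for realistic pool sizes.
#' This is the mechanism by which rare features end up as "random" zeros:
#' the fewer fragments a feature has in the pool, the likelier the
#' sequencer never picks one.
#'
#' @param pop a `population` object (or list with `m`).
#' @param n_draws number of reads drawn.
#' @param feature feature index (1-based).
#' @return probability in `[0, 1]`.
#' @examples
#' zero_probability(list(m = c(1L, 9L)), n_draws = 5, feature = 1) # 0.5
#' @export
zero_probability <- function(pop, n_draws, feature) {
  m <- as.integer(pop$m)
  total <- sum(m)
  if (feature < 1 || feature > length(m)) abort_data("feature index out of range")
  if (n_draws > total) abort_data("n_draws exceeds population total")
  mi <- m[feature]
  if (mi == 0L) return(1)
  if (n_draws > total - mi) return(0)
  exp(lchoose(total - mi, n_draws) - lchoose(total, n_draws))
}

#' Simulate a grouped 16S count table
#'
#' Runs the full two-step generative process for every sample: (1) a gamma
#' draw per feature gives the biological abundance of that replicate; the
#' per-sample relative abundances `m_ij / sum_i m_ij` recorded at this point
#' are the declared ground truth of the simulation; (2) the continuous
#' abundances are apportioned into an integer fragment pool and the
#' library size is drawn from it without replacement (exact MHG).  Zeros
#' therefore arise intrinsically: structurally when `mu = 0`, and randomly
#' when a rare feature's fragments are never sampled.
#'
#' Reproducibility: one root `seed` is expanded into per-sample substreams
#' in a fixed (group, sample) enumeration order, so the same seed and
#' parameters give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @param seed integer root seed (required; the run is stochastic).
#' @param population_scale passed to [build_population()].
#' @return a `sim_result` object: list with integer matrix `counts`
#'   (features x samples; column j sums exactly to its library size),
#'   `rel_abundance` (same shape, columns sum to 1), `params_used`, `seed`,
#'   and `group_of` (named character vector mapping sample id to group).
#' @examples
#' p <- sim_params(
#'   feature_ids = paste0("otu", 1:4),
#'   groups = list(a = list(mu = c(50, 30, 15, 5), phi = rep(0.3, 4),
#'                          lib_sizes = c(100, 120)))
#' )
#' r <- simulate_counts(p, seed = 7)
#' colSums(r$counts)
#' @export
simulate_counts <- function(params, seed, population_scale = 1) {
  if (!inherits(params, "sim_params")) {
    params <- sim_params(params$feature_ids, params$groups)
  }
  if (params_has_na_phi(params)) {
    abort_data(paste0(
      "parameters are incomplete: some groups have no phi ",
      "(supply one via assemble_params() hybrid mode)"))
  }
  if (missing(seed) || is.null(seed) || anyNA(seed)) {
    abort_data("a seed is required for simulation")
  }
  seed <- as.integer(seed)
  C <- n_features(params)
  N <- n_samples_total(params)
  sub_seeds <- derive_substream_seeds(seed, N)

  counts <- matrix(0L, nrow = C, ncol = N)
  rel <- matrix(0, nrow = C, ncol = N)
  sample_ids <- character(N)
  group_of <- character(N)
  col <- 0L
  for (g in names(params$groups)) {
    grp <- params$groups[[g]]
    for (j in seq_along(grp$lib_sizes)) {
      col <- col + 1L
      sid <- sprintf("%s_s%d", g, j)
      sample_ids[col] <- sid
      group_of[col] <- g
      set.seed(sub_seeds[col])
      raw <- tryCatch(
        drop(sample_gamma_abundances(grp$mu, grp$phi, 1L)),
        error = function(e) abort_data(sprintf(
          "group '%s', sample '%s': %s", g, sid, conditionMessage(e))))
      if (sum(raw) <= 0) {
        abort_data(sprintf(
          "group '%s', sample '%s': degenerate sample, all abundances are zero",
          g, sid))
      }
      rel[, col] <- raw / sum(raw)
      pop <- tryCatch(
        build_population(raw, grp$lib_sizes[j], population_scale),
        error = function(e) abort_data(sprintf(
          "group '%s', sample '%s': %s", g, sid, conditionMessage(e))))
      counts[, col] <- tryCatch(
        sample_mhg(pop, grp$lib_sizes[j]),
        error = function(e) abort_data(sprintf(
          "group '%s', sample '%s': %s", g, sid, conditionMessage(e))))
    }
  }
  dimnames(counts) <- list(params$feature_ids, sample_ids)
  dimnames(rel) <- list(params$feature_ids, sample_ids)
  names(group_of) <- sample_ids
  structure(list(counts = counts, rel_abundance = rel,
                 params_used = params, seed = seed,
                 population_scale = population_scale,
                 group_of = group_of),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d features x %d samples, %d group(s), seed %d\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$group_of)), x$seed))
  cat(sprintf("  overall sparsity: %.1f%%\n",
              100 * mean(x$counts == 0)))
  invisible(x)
}

#' Convert a simulation result to a grouped count table
#'
#' @param result a `sim_result`.
#' @return a [grouped_count_table()] over the simulated counts.
#' @export
as_grouped_count_table <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  grouped_count_table(result$counts, result$group_of)
}
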