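## Real-versus-simulated comparison protocol: sparsity, intensity and
## variability summaries plus a Mann-Whitney U / effect-size / bootstrap
## testing layer.

#' Sparsity summaries of a count table
#'
#' @param table a [grouped_count_table()].
#' @return list with `total` (percentage of zero entries), `per_row` and
#'   `per_col` (percentages per feature / per sample) and `per_group`
#'   (percentage within each group's submatrix).
#' @examples
#' m <- matrix(c(0, 1, 2, 0), nrow = 2)
#' sparsity_metrics(grouped_count_table(m, c("g", "g")))$total # 50
#' @export
sparsity_metrics <- function(table) {
  z <- table$counts == 0L
  per_group <- vapply(table_groups(table), function(g) {
    100 * mean(z[, group_columns(table, g), drop = FALSE])
  }, numeric(1))
  names(per_group) <- table_groups(table)
  list(total = 100 * mean(z),
       per_row = 100 * rowMeans(z),
       per_col = 100 * colMeans(z),
       per_group = per_group)
}

#' Per-feature, per-group mean intensity of normalized counts
#'
#' @param table a [grouped_count_table()].
#' @param config an [estimator_config()] (normalization choice).
#' @return list with `mean` (features x groups matrix of within-group means
#'   of normalized counts) and `zero_mean` (logical matrix flagging
#'   features with zero mean, which distribution-level comparisons
#'   exclude).
#' @export
intensity_metrics <- function(table, config = estimator_config()) {
  norm <- normalize_counts(table, config)
  groups <- table_groups(table)
  mean_mat <- vapply(groups, function(g) {
    rowMeans(norm[, group_columns(table, g), drop = FALSE])
  }, numeric(nrow(norm)))
  mean_mat <- matrix(mean_mat, nrow = nrow(norm),
                     dimnames = list(rownames(norm), groups))
  list(mean = mean_mat, zero_mean = mean_mat == 0)
}

#' Per-feature, per-group variability of normalized counts
#'
#' Variance across replicates and relative variance `RV = sigma^2 / mu`
#' (the variance-to-mean ratio).  Groups with a single replicate yield
#' `NA` variance (undefined, not zero); features with zero mean yield `NA`
#' RV.
#'
#' @inheritParams intensity_metrics
#' @return list with matrices `variance` and `relative_variance`
#'   (features x groups).
#' @export
variability_metrics <- function(table, config = estimator_config()) {
  norm <- normalize_counts(table, config)
  groups <- table_groups(table)
  var_mat <- vapply(groups, function(g) {
    cols <- group_columns(table, g)
    if (length(cols) < 2L) return(rep(NA_real_, nrow(norm)))
    apply(norm[, cols, drop = FALSE], 1, var)
  }, numeric(nrow(norm)))
  var_mat <- matrix(var_mat, nrow = nrow(norm),
                    dimnames = list(rownames(norm), groups))
  mean_mat <- intensity_metrics(table, config)$mean
  rv <- var_mat / mean_mat
  rv[mean_mat == 0] <- NA_real_
  list(variance = var_mat, relative_variance = rv)
}

## Mann-Whitney U statistic, two-sided normal-approximation p-value with
## tie correction and continuity correction (matches
## wilcox.test(exact = FALSE, correct = TRUE)), and the rank-biserial
## effect size r = 1 - 2U / (n1 n2).  Hand-rolled because the bootstrap
## calls it tens of thousands of times.
mwu_test <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu_u <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z_num <- U - mu_u
  correction <- sign(z_num) * 0.5
  p <- if (sigma2 <= 0) 1 else {
    z <- (z_num - correction) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p_value = p, effect_size = 1 - 2 * U / (n1 * n2))
}

## Bootstrap over feature subsets: each iteration draws `round(fraction*C)`
## features without replacement (the same subset from both vectors) and
## tests them; returns the fraction of iterations significant at alpha.
bootstrap_mwu_fraction <- function(x, y, n_boot, fraction, alpha) {
  C <- length(x)
  k <- max(2L, round(fraction * C))
  hits <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(C, k)
    if (mwu_test(x[idx], y[idx])$p_value < alpha) hits <- hits + 1L
  }
  hits / n_boot
}

#' Compare a real and a simulated count table
#'
#' Implements the evaluation protocol used to validate the generative
#' model: per group and per metric (mean intensity; within-group variance)
#' the per-feature distributions of the two tables are compared with a
#' two-sided Mann-Whitney U test, the rank-biserial correlation
#' `r = 1 - 2U/(n1 n2)` as effect size, and a feature-subset bootstrap
#' (`n_boot` iterations, each drawing `boot_fraction` of the features
#' without replacement) reporting the fraction of subsets significant at
#' `alpha` — which decouples the verdict from the huge number of features.
#' Sparsity agreement is summarized as coefficients of determination
#' between real and simulated group sparsities and between quantiles of
#' the per-feature / per-sample sparsity distributions.
#'
#' Features with zero mean in both tables are excluded from the intensity
#' and variance distributions; single-replicate groups contribute no
#' variance comparison.
#'
#' @param real,sim [grouped_count_table()] objects with identical feature
#'   counts and the same set of group labels.
#' @param config an [estimator_config()] (normalization applied
#'   symmetrically to both tables).
#' @param n_boot bootstrap iterations.
#' @param boot_fraction fraction of features per bootstrap subset.
#' @param alpha significance level for the bootstrap test count.
#' @param seed seed for the bootstrap subsampling.
#' @return an `eval_report` object: list with `tests` (data.frame: group,
#'   metric, n_features, p_value, effect_size, boot_sig_fraction),
#'   `sparsity` (real/sim summaries), and `r_squared` (group sparsity,
#'   per-feature and per-sample sparsity quantile agreement).
#' @export
compare_tables <- function(real, sim, config = estimator_config(),
                           n_boot = 10000L, boot_fraction = 0.05,
                           alpha = 0.05, seed = 1L) {
  stopifnot(inherits(real, "grouped_count_table"),
            inherits(sim, "grouped_count_table"))
  if (nrow(real$counts) != nrow(sim$counts)) {
    abort_data("tables have different feature counts")
  }
  groups <- table_groups(real)
  if (!setequal(groups, table_groups(sim))) {
    abort_data("tables have different group labels")
  }
  int_real <- intensity_metrics(real, config)
  int_sim <- intensity_metrics(sim, config)
  var_real <- variability_metrics(real, config)
  var_sim <- variability_metrics(sim, config)

  rows <- list()
  with_local_seed(seed, {
    for (g in groups) {
      metric_values <- list(
        intensity = list(x = int_real$mean[, g], y = int_sim$mean[, g],
                         keep = !(int_real$zero_mean[, g] &
                                  int_sim$zero_mean[, g])),
        variance = list(x = var_real$variance[, g], y = var_sim$variance[, g],
                        keep = !(int_real$zero_mean[, g] &
                                 int_sim$zero_mean[, g]) &
                               !is.na(var_real$variance[, g]) &
                               !is.na(var_sim$variance[, g]))
      )
      for (metric in names(metric_values)) {
        mv <- metric_values[[metric]]
        x <- mv$x[mv$keep]
        y <- mv$y[mv$keep]
        if (length(x) < 2L) next
        tst <- mwu_test(x, y)
        frac <- bootstrap_mwu_fraction(x, y, n_boot, boot_fraction, alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, metric = metric, n_features = length(x),
          p_value = tst$p_value, effect_size = tst$effect_size,
          boot_sig_fraction = frac, stringsAsFactors = FALSE)
      }
    }
  })
  tests <- do.call(rbind, rows)

  sp_real <- sparsity_metrics(real)
  sp_sim <- sparsity_metrics(sim)
  probs <- seq(0.01, 0.99, by = 0.01)
  r2 <- function(a, b) {
    if (isTRUE(all.equal(unname(a), unname(b)))) return(1)  # perfect agreement
    if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    cor(a, b)^2
  }
  r_squared <- list(
    group_sparsity = r2(sp_real$per_group[groups], sp_sim$per_group[groups]),
    row_sparsity_qq = r2(quantile(sp_real$per_row, probs),
                         quantile(sp_sim$per_row, probs)),
    col_sparsity_qq = r2(quantile(sp_real$per_col, probs),
                         quantile(sp_sim$per_col, probs)))

  structure(list(tests = tests,
                 sparsity = list(real = sp_real, sim = sp_sim),
                 r_squared = r_squared,
                 settings = list(n_boot = n_boot,
                                 boot_fraction = boot_fraction,
                                 alpha = alpha, seed = seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  total sparsity: real %.1f%%, simulated %.1f%%\n",
              x$sparsity$real$total, x$sparsity$sim$total))
  cat(sprintf("  R^2 group sparsity %.3f | row-QQ %.3f | col-QQ %.3f\n",
              x$r_squared$group_sparsity, x$r_squared$row_sparsity_qq,
              x$r_squared$col_sparsity_qq))
  cat(sprintf("  tests (%d rows): max |effect size| %.3f, max bootstrap sig. fraction %.3f\n",
              nrow(x$tests), max(abs(x$tests$effect_size)),
              max(x$tests$boot_sig_fraction)))
  invisible(x)
}
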