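make_table <- function(counts, groups) {
  grouped_count_table(counts, stats::setNames(groups, colnames(counts)))
}

test_that("total-sum normalization rescales to the mean depth", {
  m <- matrix(c(10L, 90L, 30L, 270L), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- make_table(m, c("g", "g"))
  norm <- normalize_counts(tab)
  # column sums 100 and 300, mean 200 -> factors 2 and 2/3
  expect_equal(unname(norm[, 1]), c(20, 180))
  expect_equal(unname(norm[, 2]), c(20, 180))
  expect_equal(unname(colSums(norm)), c(200, 200))

  single <- make_table(m[, 1, drop = FALSE], "g")
  expect_equal(normalize_counts(single), m[, 1, drop = FALSE] + 0)

  z <- m; z[, 2] <- 0L
  expect_error(normalize_counts(make_table(z, c("g", "g"))), "s2")
})

test_that("normalization is invariant to per-sample scaling (monotonicity)", {
  set.seed(5)
  counts <- matrix(rpois(60, 20), nrow = 10)
  colnames(counts) <- paste0("s", 1:6)
  rownames(counts) <- paste0("f", 1:10)
  tab <- make_table(counts, rep("g", 6))
  norm1 <- normalize_counts(tab)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7L
  norm2 <- normalize_counts(make_table(scaled, rep("g", 6)))
  # sample 3's normalized profile is unchanged up to the shared mean-depth
  # factor, i.e. its relative profile is identical
  expect_equal(norm2[, 3] / sum(norm2[, 3]), norm1[, 3] / sum(norm1[, 3]))
})

test_that("median-of-ratios normalization undoes per-sample scale factors", {
  set.seed(6)
  base <- rpois(40, 50) + 1L
  counts <- cbind(s1 = base, s2 = base * 3L, s3 = base * 5L)
  rownames(counts) <- paste0("f", 1:40)
  tab <- make_table(counts, rep("g", 3))
  norm <- normalize_counts(tab, estimator_config(normalization = "median_of_ratios"))
  expect_equal(norm[, "s1"], norm[, "s2"])
  expect_equal(norm[, "s1"], norm[, "s3"])
})

test_that("estimate_parameters applies the moment formulas per group", {
  set.seed(9)
  counts <- matrix(rpois(40, 30), nrow = 5,
                   dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
  counts[5, 1:4] <- 0L  # absent in group x
  tab <- make_table(counts, rep(c("x", "y"), each = 4))
  cfg <- estimator_config()
  norm <- normalize_counts(tab, cfg)
  est <- estimate_parameters(tab, cfg)

  for (g in c("x", "y")) {
    cols <- which(tab$group_of == g)
    mu_hand <- rowMeans(norm[, cols])
    s2_hand <- apply(norm[, cols], 1, var)
    phi_hand <- ifelse(mu_hand > 0,
                       pmax(cfg$phi_floor, (s2_hand - mu_hand) / mu_hand^2), 0)
    expect_equal(est$groups[[g]]$mu, unname(mu_hand))
    expect_equal(est$groups[[g]]$phi, unname(phi_hand))
    expect_equal(est$groups[[g]]$lib_sizes,
                 as.integer(colSums(counts[, cols])))
  }
  # absent feature: mu = 0 forces phi = 0
  expect_identical(est$groups$x$mu[5], 0)
  expect_identical(est$groups$x$phi[5], 0)

  # constant replicates -> variance 0 -> phi at the floor
  const <- matrix(10L, nrow = 2, ncol = 3,
                  dimnames = list(c("a", "b"), paste0("s", 1:3)))
  est2 <- estimate_parameters(make_table(const, rep("g", 3)))
  expect_equal(est2$groups$g$mu, c(10, 10))
  expect_equal(est2$groups$g$phi, rep(estimator_config()$phi_floor, 2))

  # worked arithmetic: mu = 10, s2 = 50 -> poisson-corrected 0.4, cv2 0.5
  expect_equal((50 - 10) / 10^2, 0.4)
  vals <- c(10 - sqrt(50), 10, 10 + sqrt(50))
  expect_equal(var(vals), 50)
  expect_equal(mean(vals), 10)
})

test_that("cv2 dispersion dominates the Poisson-corrected one", {
  fx <- generate_fixture(get_preset("tiny_demo", seed = 21))
  tab <- as_grouped_count_table(fx$result)
  p1 <- estimate_parameters(tab, estimator_config(phi_estimator = "poisson_corrected"))
  p2 <- estimate_parameters(tab, estimator_config(phi_estimator = "cv2"))
  for (g in names(p1$groups)) {
    pos <- p1$groups[[g]]$mu > 0
    expect_true(all(p2$groups[[g]]$phi[pos] >= p1$groups[[g]]$phi[pos]))
    expect_true(all(p1$groups[[g]]$phi >= 0))
  }
})

test_that("estimation is invariant to sample column order within groups", {
  tab <- tiny_table(seed = 31)
  perm <- c(2, 3, 1, 6, 4, 5)  # permutes within each group
  tab2 <- grouped_count_table(tab$counts[, perm], tab$group_of[perm])
  e1 <- estimate_parameters(tab)
  e2 <- estimate_parameters(tab2)
  for (g in names(e1$groups)) {
    expect_equal(e1$groups[[g]]$mu, e2$groups[[g]]$mu)
    expect_equal(e1$groups[[g]]$phi, e2$groups[[g]]$phi)
    expect_setequal(e1$groups[[g]]$lib_sizes, e2$groups[[g]]$lib_sizes)
  }
})

test_that("under-replicated groups fail unless hybrid mode is requested", {
  counts <- matrix(rpois(15, 20), nrow = 5,
                   dimnames = list(paste0("f", 1:5), paste0("s", 1:3)))
  tab <- make_table(counts, c("solo", "pair", "pair"))
  expect_error(estimate_parameters(tab), "solo.*hybrid", ignore.case = TRUE)
  est <- estimate_parameters(tab, allow_missing_phi = TRUE)
  expect_true(all(is.na(est$groups$solo$phi)))
  expect_false(anyNA(est$groups$pair$phi))
  # incomplete params cannot be simulated directly
  expect_error(simulate_counts(est, seed = 1), "incomplete")
  # ...but hybrid assembly completes them
  full <- assemble_params(est, user_phi = list(solo = rep(0.2, 5)))
  expect_equal(full$groups$solo$phi, rep(0.2, 5))
  expect_equal(full$groups$pair$phi, est$groups$pair$phi)
  r <- simulate_counts(full, seed = 1)
  expect_equal(nrow(r$counts), 5)
})

test_that("assemble_params overrides component-wise and validates shapes", {
  est <- estimate_parameters(tiny_table(seed = 41))
  out <- assemble_params(est, user_lib_sizes = list(a = c(1000L, 1000L)))
  expect_equal(out$groups$a$lib_sizes, c(1000L, 1000L))
  expect_equal(out$groups$a$mu, est$groups$a$mu)
  expect_equal(out$groups$b$lib_sizes, est$groups$b$lib_sizes)

  # pure pass-through without an estimate
  direct <- assemble_params(
    user_mu = list(g1 = c(5, 5)), user_phi = list(g1 = c(0.1, 0.2)),
    user_lib_sizes = list(g1 = 50L), feature_ids = c("a", "b"))
  expect_s3_class(direct, "sim_params")
  expect_equal(direct$groups$g1$mu, c(5, 5))

  expect_error(assemble_params(est, user_mu = list(a = c(1, 2))),
               "length")
  expect_error(assemble_params(user_mu = list(g = c(1, 2)),
                               feature_ids = c("a", "b")),
               "no source provides")
  expect_error(assemble_params(est, user_mu = list(nope = rep(1, 5))),
               "unknown group")
})

test_that("estimation round-trips parameters from simulated data (reduced scale)", {
  sc <- preset_scenario("roundtrip", n_features = 200, n_groups = 2,
                        replicates_per_group = 10,
                        abundance_shape = "geometric_skew",
                        skew_parameter = 0.97, phi_level = 0.3,
                        depth_range = c(20000L, 20000L),
                        fraction_da_features = 0, seed = 77)
  fx <- generate_fixture(sc)
  est <- estimate_parameters(as_grouped_count_table(fx$result))
  mean_depth <- mean(unlist(lapply(fx$params$groups, `[[`, "lib_sizes")))
  for (g in names(fx$params$groups)) {
    mu_true <- fx$params$groups[[g]]$mu
    mu_true_scaled <- mu_true / sum(mu_true) * mean_depth
    mu_hat <- est$groups[[g]]$mu
    sel <- mu_true_scaled >= 10
    expect_gt(sum(sel), 20)
    # 10 replicates at phi = 0.3 give ~18% per-feature noise on mu_hat,
    # so demand strong but not near-perfect linear agreement here; the
    # strict bounds run at 50 replicates in the acceptance suite
    expect_gt(cor(mu_hat[sel], mu_true_scaled[sel]), 0.95)
    # reduced scale (10 replicates): looser bounds than the acceptance run
    expect_lt(median(abs(mu_hat[sel] / mu_true_scaled[sel] - 1)), 0.20)
    phi_hat <- est$groups[[g]]$phi
    expect_lt(median(abs(phi_hat[sel] / 0.3 - 1)), 0.45)
  }
})
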