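## Independent oracles used across the suite.  These deliberately avoid the
## code paths they check: probabilities come from exhaustive enumeration or
## direct binomial-coefficient arithmetic, never from the samplers.

## All feasible outcomes of drawing n items without replacement from an urn
## with class counts m, with their exact probabilities
## P(y) = prod_i choose(m_i, y_i) / choose(sum(m), n).
enumerate_mhg_pmf <- function(m, n) {
  grids <- lapply(m, function(mi) 0:mi)
  grid <- expand.grid(grids)
  keep <- rowSums(grid) == n
  grid <- as.matrix(grid[keep, , drop = FALSE])
  total <- sum(m)
  probs <- apply(grid, 1, function(y) {
    exp(sum(lchoose(m, y)) - lchoose(total, n))
  })
  dimnames(grid) <- NULL
  list(outcomes = grid, probs = probs)
}

## Ball-level urn enumeration: probability of a specific class-count vector
## by counting unordered subsets of distinct balls.  Independent of the
## choose()-based pmf above; only feasible for tiny urns.
ball_enumeration_prob <- function(m, n, target) {
  balls <- rep(seq_along(m), m)
  subsets <- utils::combn(length(balls), n)
  hits <- sum(apply(subsets, 2, function(idx) {
    y <- tabulate(balls[idx], nbins = length(m))
    all(y == target)
  }))
  hits / ncol(subsets)
}

## Exhaustive apportionment oracle: among all non-negative integer vectors
## summing to `total`, the ones minimizing the summed absolute proportion
## error against `weights` (largest-remainder always lies in this set).
best_apportionments <- function(weights, total) {
  C <- length(weights)
  grids <- rep(list(0:total), C)
  grid <- as.matrix(expand.grid(grids))
  grid <- grid[rowSums(grid) == total, , drop = FALSE]
  target <- weights / sum(weights) * total
  err <- apply(grid, 1, function(v) sum(abs(v - target)))
  grid[err <= min(err) + 1e-12, , drop = FALSE]
}

## Tiny ready-made parameter set
tiny_params <- function() {
  sim_params(
    feature_ids = paste0("otu", 1:5),
    groups = list(
      a = list(mu = c(100, 50, 20, 5, 0), phi = rep(0.3, 5),
               lib_sizes = c(400L, 500L, 450L)),
      b = list(mu = c(100, 10, 60, 5, 0), phi = rep(0.5, 5),
               lib_sizes = c(380L, 520L, 470L))))
}

tiny_table <- function(seed = 11L) {
  as_grouped_count_table(simulate_counts(tiny_params(), seed = seed))
}

## Repeated MHG draws as a matrix (reps x classes)
draw_mhg_many <- function(m, n, reps, seed) {
  set.seed(seed)
  pop <- list(m = as.integer(m), total = sum(m))
  t(vapply(seq_len(reps), function(i) sample_mhg(pop, n),
           integer(length(m))))
}
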