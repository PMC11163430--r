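# Morris elementary effects: grids, trajectory construction, EE algebra,
# screening, ensemble statistics, reproducibility.

fake_params <- function(values, us) {
  p <- data.frame(id = paste0("x", seq_along(values)),
                  kind = "G", target = paste0("x", seq_along(values)),
                  value = values, u = us,
                  rank = 1L, barrierless = FALSE,
                  stringsAsFactors = FALSE)
  rownames(p) <- p$id
  class(p) <- c("rn_params", "data.frame")
  p
}

test_that("grids span the uncertainty interval with equal spacing", {
  p <- fake_params(c(0, 5), c(3, 0))
  g4 <- morris_grid(p, 4)
  expect_equal(g4$grid$x1, c(-3, -1, 1, 3))
  expect_equal(g4$excluded, "x2")
  g2 <- morris_grid(fake_params(7, 2), 2)
  expect_equal(g2$grid$x1, c(5, 9))
  # symmetry about the baseline value
  g5 <- morris_grid(fake_params(1.5, 4), 5)
  expect_equal(g5$grid$x1 + rev(g5$grid$x1), rep(3, 5))
  expect_error(morris_grid(p, 1), "levels")
})

test_that("trajectories change each parameter exactly once by one grid step", {
  p <- fake_params(c(0, 0, 0, 0), c(1, 2, 3, 4))
  d <- morris_design(p, levels = 4, trajectories = 6, seed = 42)
  expect_length(d$trajectories, 6)
  for (tr in d$trajectories) {
    expect_equal(dim(tr$points), c(5L, 4L))
    steps <- diff(tr$points)
    # exactly one coordinate changes per consecutive pair, by +/- delta
    expect_true(all(rowSums(steps != 0) == 1))
    expect_equal(sort(unname(apply(steps, 1, function(r) which(r != 0)))),
                 1:4)  # each parameter exactly once
    expect_true(all(abs(steps[steps != 0]) - d$delta < 1e-12))
    expect_true(all(tr$points >= 0 & tr$points <= 1))
  }
  # k = 1: two points differing in the single parameter
  d1 <- morris_design(fake_params(0, 1), trajectories = 3, seed = 1)
  for (tr in d1$trajectories) expect_equal(dim(tr$points), c(2L, 1L))
})

test_that("designs are bit-identical under the same seed", {
  p <- fake_params(rep(0, 3), rep(1, 3))
  d1 <- morris_design(p, trajectories = 5, seed = 7)
  d2 <- morris_design(p, trajectories = 5, seed = 7)
  expect_identical(d1, d2)
  d3 <- morris_design(p, trajectories = 5, seed = 8)
  expect_false(identical(d1$trajectories, d3$trajectories))
})

test_that("spread-maximizing selection with pool size N returns the pool", {
  p <- fake_params(rep(0, 3), rep(1, 3))
  dr <- morris_design(p, trajectories = 4, seed = 3, method = "random")
  ds <- morris_design(p, trajectories = 4, seed = 3,
                      method = "spread_maximizing", pool_factor = 1)
  expect_identical(dr$trajectories, ds$trajectories)
})

test_that("spread-maximizing trajectories cover at least as much space", {
  p <- fake_params(rep(0, 4), rep(2, 4))
  total_dist <- function(d) {
    n <- length(d$trajectories); s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      s <- s + kinsteer:::traj_distance(d$trajectories[[i]],
                                        d$trajectories[[j]])^2
    s
  }
  dr <- morris_design(p, trajectories = 5, seed = 9, method = "random")
  ds <- morris_design(p, trajectories = 5, seed = 9,
                      method = "spread_maximizing", pool_factor = 10)
  expect_gte(total_dist(ds), total_dist(dr))
})

test_that("elementary effects are exact for linear responses", {
  p <- fake_params(c(10, -5), c(2, 4))
  d <- morris_design(p, levels = 4, trajectories = 5, seed = 5)
  a <- c(x1 = 0.7, x2 = -1.3)
  evals <- kinsteer:::morris_evaluate(function(x)
    c(y = sum(a[names(x)] * x)), d)
  ee <- elementary_effects(evals, d)
  expect_equal(unname(ee$mu_star["y", ]), unname(abs(a)), tolerance = 1e-10)
  expect_equal(ee$mu_star_max, apply(ee$mu_star, 2, max))
  # constant output: all effects vanish
  ev0 <- kinsteer:::morris_evaluate(function(x) c(y = 1), d)
  expect_true(all(elementary_effects(ev0, d)$mu_star == 0))
})

test_that("mu* matches an exhaustive finite-difference oracle on a 2-parameter toy", {
  p <- fake_params(c(1, 2), c(3, 1))
  d <- morris_design(p, levels = 4, trajectories = 8, seed = 13)
  f <- function(x) c(y = x[["x1"]]^2 - 3 * x[["x2"]] + 0.5 * x[["x1"]] * x[["x2"]])
  evals <- kinsteer:::morris_evaluate(f, d)
  ee <- elementary_effects(evals, d)
  # oracle: recompute |EE| for every trajectory step by direct evaluation
  range_kj <- d$upper - d$lower
  acc <- matrix(0, 2, 1, dimnames = list(d$param_ids, NULL))
  for (tr in d$trajectories) {
    for (s in seq_len(2)) {
      i <- tr$order[s]
      x_before <- d$lower + tr$points[s, ] * range_kj
      x_after <- d$lower + tr$points[s + 1, ] * range_kj
      names(x_before) <- names(x_after) <- d$param_ids
      dee <- (f(x_after) - f(x_before)) / (x_after[i] - x_before[i])
      acc[i, 1] <- acc[i, 1] + abs(dee)
    }
  }
  expect_equal(unname(ee$mu_star["y", ]), unname(acc[, 1] / 8),
               tolerance = 1e-10)
})

test_that("screening activates only above the size threshold", {
  net <- chain3_network()
  p <- assemble_parameters(net)
  base <- simulate_network(net, p, simulation_settings(T = 400, t_max = 20))
  # small model: untouched even with a high threshold
  expect_setequal(morris_screen(base, p, threshold = 1e9,
                                activation_size = 1000L), p$id)
  # forced small activation size: the flux rule applies
  kept <- morris_screen(base, p, threshold = 1e-9, activation_size = 1L)
  expect_true(all(kept %in% oat_screen(base, p, 1e-9)))
  expect_setequal(morris_screen(base, p, threshold = 0,
                                activation_size = 1L), p$id)
})

test_that("ensemble statistics are the arithmetic mean and sample sd", {
  m <- cbind(s1 = c(0.1, 0.2, 0.3), s2 = c(1, 1, 1))
  st <- ensemble_statistics(m)
  expect_equal(st$mean, c(0.2, 1))
  expect_equal(st$sd, c(0.1, 0))
  expect_error(ensemble_statistics(m[1, , drop = FALSE]), "at least 2")
})

test_that("a full Morris run is reproducible and satisfies the count formula", {
  net <- chain3_network()
  p <- assemble_parameters(net)
  s <- simulation_settings(T = 380, t_max = 20)
  m1 <- morris_sensitivity(net, p, s, trajectories = 4, seed = 21)
  m2 <- morris_sensitivity(net, p, s, trajectories = 4, seed = 21)
  expect_identical(m1$mu_star, m2$mu_star)
  expect_identical(m1$cmax_stats, m2$cmax_stats)
  k <- length(m1$design$param_ids)
  expect_equal(m1$n_model_evals, 4L * (k + 1L))
  expect_true(all(m1$mu_star >= 0))
  expect_equal(m1$mu_star_max, apply(m1$mu_star, 2, max))
  expect_true(all(m1$cmax_stats$sd >= 0))
})
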