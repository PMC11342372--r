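table1 <- cluster_models_fixture()

test_that("the packaged cluster models load with the expected shape", {
  expect_s3_class(table1, "cluster_models")
  expect_equal(nrow(table1), 9)
  expect_true(all(table1$sd > 0))
  expect_equal(range(table1$mean), c(-558.11, -555.47))
})

test_that("surrogate draws follow the cluster's Gaussian", {
  m <- cluster_models(mean = -558.11, sd = 1e-12)
  set.seed(101)
  expect_equal(draw_run_minimum(m, 1), -558.11, tolerance = 1e-9)
  set.seed(102)
  a <- draw_run_minimum(table1, 6)
  set.seed(102)
  b <- draw_run_minimum(table1, 6)
  expect_identical(a, b)
  set.seed(103)
  draws <- replicate(1e5, draw_run_minimum(table1, 6))
  expect_lt(abs(mean(draws) - (-558.11)), 3 * 1.79 / sqrt(1e5))
})

test_that("an unreachable threshold exhausts all batches and 5000 iterations", {
  cfg <- trial_config(e_min = -1e9)
  set.seed(104)
  r <- run_trial(table1, learning_params(), cfg)
  expect_true(is.na(r$success_iteration))
  expect_equal(r$batches_run, 20)
  expect_equal(cfg$max_iter, 5000L)
})

test_that("a certain threshold succeeds on the first draw at iteration 50", {
  cfg <- trial_config(e_min = 1e9)
  set.seed(105)
  r <- run_trial(table1, learning_params(), cfg)
  expect_equal(r$success_iteration, 50L)
  expect_equal(r$batches_run, 1)
})

test_that("success iterations are positive multiples of the run length", {
  cfg <- trial_config(e_min = -560)
  set.seed(106)
  for (i in 1:40) {
    r <- run_trial(table1, learning_params(), cfg)
    if (!is.na(r$success_iteration)) {
      expect_equal(r$success_iteration %% 50, 0)
      expect_gte(r$success_iteration, 50)
      expect_lte(r$success_iteration, 5000)
    }
  }
})

test_that("single-cluster trials reproduce the geometric draw count", {
  m <- cluster_models(mean = -558.11, sd = 1.79)
  p <- pnorm((-560.0 - (-558.11)) / 1.79)
  cfg <- trial_config(e_min = -560.0, max_batches = 1000L)
  set.seed(107)
  n_draws <- replicate(2000, {
    r <- run_trial(m, learning_params(0, 0, 0, 0), cfg)
    # draws consumed = iterations / iters_per_run
    r$success_iteration / 50
  })
  expect_true(all(!is.na(n_draws)))
  se <- sqrt((1 - p) / p^2 / 2000)
  expect_lt(abs(mean(n_draws) - 1 / p), 3 * se)
})

test_that("cumulative success curves step correctly", {
  none <- cumulative_success_curve(c(NA, NA, NA), 5000)
  expect_equal(success_fraction(none, c(1, 2500, 5000)), c(0, 0, 0))
  expect_equal(success_area(none), 0)
  two <- cumulative_success_curve(c(100, 200), 5000)
  expect_equal(success_fraction(two, c(99, 100, 150, 199, 200, 5000)),
               c(0, 0.5, 0.5, 0.5, 1, 1))
  all1 <- cumulative_success_curve(rep(1, 4), 5000)
  expect_equal(success_fraction(all1, c(1, 5000)), c(1, 1))
  expect_equal(success_area(all1), 5000)
})

test_that("success area equals the hand-summed step area", {
  two <- cumulative_success_curve(c(100, 200), 5000)
  # step sum: 0.5 over [100,199], 1.0 over [200,5000]
  expect_equal(success_area(two), 0.5 * 100 + 1.0 * 4801)
  # monotone under pointwise dominance
  earlier <- cumulative_success_curve(c(50, 200), 5000)
  expect_gt(success_area(earlier), success_area(two))
})

test_that("combo evaluation is seed-deterministic and monotone in e_min", {
  cfg <- trial_config(e_min = -560, n_trials = 20L)
  set.seed(108); a1 <- evaluate_combo(table1, learning_params(), cfg)
  set.seed(108); a2 <- evaluate_combo(table1, learning_params(), cfg)
  expect_identical(a1, a2)
  cfg_hard <- trial_config(e_min = -561, n_trials = 20L)
  set.seed(109); easy <- evaluate_combo(table1, learning_params(), cfg)
  set.seed(109); hard <- evaluate_combo(table1, learning_params(), cfg_hard)
  expect_gte(easy, hard)
  cfg_none <- trial_config(e_min = -1e9, n_trials = 5L)
  set.seed(110)
  expect_equal(evaluate_combo(table1, learning_params(), cfg_none), 0)
})

test_that("grid search ranks combinations reproducibly", {
  cfg <- trial_config(e_min = -560, n_trials = 10L)
  one <- grid_search(table1, a_values = 79, b_values = 3, c_values = 19,
                     d_values = 68, cfg = cfg, seed = 5)
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one[1, 1:4]), c(A = 79, B = 3, C = 19, D = 68))
  g <- grid_search(table1, a_values = c(0, 60), b_values = 0, c_values = 0,
                   d_values = c(0, 60), cfg = cfg, seed = 5)
  expect_equal(nrow(g), 4)
  expect_true(all(diff(g$area) <= 0))
  # areas equal a serial recomputation under the same substream seeds
  grid <- expand.grid(A = c(0, 60), B = 0, C = 0, D = c(0, 60))
  for (i in seq_len(nrow(grid))) {
    set.seed(clusterEA:::combo_seed(5, i))
    area <- evaluate_combo(table1, learning_params(grid$A[i], grid$B[i],
                                                   grid$C[i], grid$D[i]),
                           cfg)
    row <- which(g$A == grid$A[i] & g$D == grid$D[i])
    expect_equal(g$area[row], area)
  }
  expect_error(grid_search(table1, a_values = numeric(0), cfg = cfg,
                           seed = 1), "empty")
})

test_that("zero-parameter trials reduce to uniform mixture sampling", {
  # per-draw success probability under uniform cluster choice
  p_draw <- mean(pnorm((-560 - table1$mean) / table1$sd))
  cfg <- trial_config(e_min = -560)
  set.seed(111)
  iters <- replicate(3000, {
    r <- run_trial(table1, learning_params(0, 0, 0, 0), cfg)
    if (is.na(r$success_iteration)) Inf else r$success_iteration / 50
  })
  # mean draw count of the truncated geometric (capped at 100 draws)
  draws <- pmin(iters, 100)
  want <- sum((1 - p_draw)^(0:99)) # E[min(Geom, 100)] = sum_{k>=0} P(X>k)
  se <- sd(draws) / sqrt(3000)
  expect_lt(abs(mean(draws) - want), 4 * se)
})

test_that("a dominant cluster is exploited when A is large", {
  means <- c(-570, rep(-556, 5))  # cluster 1 is ~3 SD better than the rest
  m <- cluster_models(mean = means, sd = rep(2, 6))
  cfg <- trial_config(e_min = -1e9, max_batches = 20L)
  set.seed(112)
  share <- replicate(300, {
    st <- init_agent(6)
    for (b in 1:cfg$max_batches) {
      sel <- agent_select(st, 5)
      st <- agent_update(sel$state, sel$ids,
                         rnorm(5, m$mean[sel$ids], m$sd[sel$ids]),
                         learning_params(79, 3, 19, 0))
    }
    st$selections[1] / st$total_selections
  })
  expect_gt(mean(share), 1 / 6)
})

test_that("the selection penalty pushes long-run counts toward uniform", {
  m <- cluster_models(mean = c(-560, rep(-556, 4)), sd = rep(2, 5))
  chisq_for <- function(params, seed) {
    set.seed(seed)
    st <- init_agent(5)
    for (b in 1:60) {
      sel <- agent_select(st, 5)
      st <- agent_update(sel$state, sel$ids,
                         rnorm(5, m$mean[sel$ids], m$sd[sel$ids]), params)
    }
    expected <- st$total_selections / 5
    sum((st$selections - expected)^2 / expected)
  }
  explore <- mean(sapply(1:40, function(s)
    chisq_for(learning_params(0, 0, 0, 90), s)))
  exploit <- mean(sapply(1:40, function(s)
    chisq_for(learning_params(79, 3, 19, 0), s)))
  expect_lt(explore, exploit)
})

test_that("grid orderings favour high A when one cluster is clearly superior", {
  # one cluster 4 SD below the rest: reward (low run minima) and success
  # probability point at the same cluster, so exploitation must win
  m <- cluster_models(mean = c(-564, rep(-556, 8)), sd = rep(2, 9))
  cfg <- trial_config(e_min = -566, n_trials = 30L)
  for (seed in 1:3) {
    g <- grid_search(m, stride = 20L, cfg = cfg, seed = seed)
    opt_region <- g$area[g$A == 60 & g$D %in% c(40, 60)]
    low_a_high_d <- g$area[g$A <= 20 & g$D == 80]
    expect_gt(mean(opt_region), mean(low_a_high_d))
    top_decile <- g[seq_len(ceiling(nrow(g) / 10)), ]
    expect_false(any(top_decile$A == 0 & top_decile$B == 0 &
                       top_decile$C == 0 & top_decile$D == 0))
    expect_gte(g$A[1], 40)  # the best combo sits in the high-A region
  }
})
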