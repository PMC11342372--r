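# fast settings for toy-potential runs: short quenches, lookalike check off
fast_cfg <- ea_config(iters_per_run = 10L, n_selections = 10L,
                      relax_max_steps = 25L, lookalike_threshold = 0)

evaluated_population <- function(n, symbols = c(rep("C", 4), rep("H", 4)),
                                 capacity = n) {
  calc <- toy_calculator()
  members <- lapply(seq_len(n), function(i) {
    s <- build_structure(table(symbols) |> as.integer() |>
                           setNames(names(table(symbols))))
    calc$relax(s, 25, 0.05)
  })
  new_population(members, capacity)
}

test_that("fitness follows the half-tanh form", {
  expect_equal(fitness(-558, -560, -556), 0.5)           # rho = 0.5
  expect_equal(fitness(-560, -560, -556), (1 - tanh(-1)) / 2)  # 0.8807971
  expect_equal(fitness(-556, -560, -556), (1 - tanh(1)) / 2)   # 0.1192029
  expect_equal(fitness(-560, -560, -556) + fitness(-556, -560, -556), 1)
  # strictly decreasing in E
  e <- seq(-560, -556, length.out = 20)
  expect_true(all(diff(fitness(e, -560, -556)) < 0))
  # degenerate population
  expect_equal(fitness(c(-1, -1), -1, -1), c(0.5, 0.5))
})

test_that("uniqueness decays with pairing and lookalike counts", {
  expect_equal(uniqueness(0, 0), 1)
  expect_equal(uniqueness(3, 0), 0.5)
  expect_equal(uniqueness(3, 3), 0.25)
  expect_true(all(diff(uniqueness(0:20, 0)) < 0))
  expect_error(uniqueness(-1, 0), ">= 0")
})

test_that("parent selection follows the F*U weights", {
  set.seed(121)
  pop <- evaluated_population(2)
  sel <- select_parents(pop)
  expect_setequal(sel$parents, 1:2)
  expect_equal(sel$pop$n_pair, c(1L, 1L))
  # zero-weight members are never chosen
  pop3 <- evaluated_population(3)
  for (i in 1:20) {
    sel <- select_parents(pop3, weights = c(1, 1, 0))
    expect_false(3 %in% sel$parents)
  }
  # empirical marginals match renormalised weights over distinct pairs
  w <- c(0.5, 0.25, 0.15, 0.10)
  pop4 <- evaluated_population(4)
  set.seed(122)
  counts <- integer(4)
  n_draw <- 30000
  for (i in seq_len(n_draw)) {
    idx <- sample.int(4, 2, prob = w)
    counts[idx] <- counts[idx] + 1L
  }
  set.seed(122)
  counts_pkg <- integer(4)
  for (i in seq_len(n_draw)) {
    sel <- select_parents(pop4, weights = w)
    counts_pkg[sel$parents] <- counts_pkg[sel$parents] + 1L
  }
  expect_equal(counts_pkg, counts)  # identical sampling law, same seed
})

test_that("cut-and-splice conserves stoichiometry across seeded crossovers", {
  set.seed(123)
  target <- c(C = 5, H = 4, N = 1)
  p1 <- build_structure(target)
  p2 <- build_structure(target)
  for (i in 1:200) {
    child <- tryCatch(cut_and_splice(p1, p2, max_retries = 100),
                      crossover_failure = function(e) NULL)
    if (!is.null(child)) {
      expect_equal(composition(child)[names(target)], target,
                   ignore_attr = TRUE)
      r <- covalent_radii(child$symbols)
      d <- as.matrix(dist(child$coords))
      lim <- 0.70 * outer(r, r, `+`)
      expect_true(all(d[upper.tri(d)] >= lim[upper.tri(lim)]))
    }
  }
})

test_that("splicing a structure with itself reuses only parent atom positions", {
  set.seed(124)
  p <- build_structure(c(C = 5, H = 4))
  centred <- sweep(p$coords, 2, colMeans(p$coords))
  child <- cut_and_splice(p, p, max_retries = 200)
  expect_equal(composition(child), composition(p))
  # every child atom coincides with some centred parent atom
  for (i in seq_len(n_atoms(child))) {
    dists <- sqrt(rowSums((centred - matrix(child$coords[i, ],
                                            n_atoms(p), 3,
                                            byrow = TRUE))^2))
    expect_lt(min(dists), 1e-9)
  }
})

test_that("impossible splices fail after the retry budget", {
  squash <- mol_structure(rep("C", 4), matrix(rnorm(12, sd = 0.01), ncol = 3))
  expect_error(cut_and_splice(squash, squash, max_retries = 5),
               class = "crossover_failure")
})

test_that("the swap-only EA run preserves size and never worsens the best", {
  set.seed(125)
  calc <- toy_calculator()
  members <- lapply(1:6, function(i)
    calc$relax(build_structure(c(C = 4, H = 4)), 25, 0.05))
  pop <- new_population(members, capacity = 6)
  res0 <- ea_run(pop, calc, 0, fast_cfg)
  expect_identical(res0$pop, pop)
  expect_length(res0$offspring, 0)
  best_before <- min(pop$energies)
  res <- ea_run(pop, calc, 15, fast_cfg)
  expect_equal(length(res$pop$members), 6)
  expect_lte(min(res$pop$energies), best_before)
  expect_true(all(diff(res$pop$energies) >= 0))  # stays sorted
  # offspring log holds every evaluated candidate
  expect_equal(length(res$offspring), length(res$offspring_energies))
})

test_that("lookalike offspring are rejected and counted", {
  set.seed(126)
  calc <- toy_calculator()
  members <- lapply(1:4, function(i)
    calc$relax(build_structure(c(C = 4, H = 4)), 40, 0.05))
  pop <- new_population(members, capacity = 4)
  cfg <- ea_config(relax_max_steps = 40, lookalike_threshold = 0.4)
  res <- ea_run(pop, calc, 10, cfg)
  # with a huge threshold every offspring is a lookalike: population frozen
  expect_equal(sort(res$pop$energies), sort(pop$energies))
  expect_gt(sum(res$pop$m_lookalike), 0)
})

test_that("curation rules match the sequential oracles", {
  mk <- function(e) {
    s <- mol_structure("C", matrix(0, 1, 3)); s$energy <- e; s
  }
  pool <- lapply(c(0, 0.1, 0.25, 1.0), mk)
  got1 <- curate_parents(pool, curation_config(1, 0.3, target_size = 2))
  e1 <- vapply(got1, function(s) s$energy, 0)
  expect_equal(oracle_curate(c(0, 0.1, 0.25, 1.0), 1, 0.3), 1.0)
  expect_true(1.0 %in% e1)            # the only rule-surviving member
  expect_setequal(e1, c(0, 1.0))      # padded with the lowest excluded
  got2 <- curate_parents(pool, curation_config(2, 0.3, target_size = 2))
  e2 <- vapply(got2, function(s) s$energy, 0)
  expect_equal(e2, c(0, 1.0))
  expect_equal(oracle_curate(c(0, 0.1, 0.25, 1.0), 2, 0.3), c(0, 1.0))
  # vanishing threshold keeps all distinct energies, both methods
  for (m in 1:2) {
    got <- curate_parents(pool, curation_config(m, 1e-9, target_size = 4))
    expect_equal(vapply(got, function(s) s$energy, 0), c(0, 0.1, 0.25, 1.0))
  }
  expect_error(curate_parents(list(), curation_config(1, 0.3)), "empty")
})

test_that("curation agrees with the oracles on random pools and pads shortfalls", {
  mk <- function(e) {
    s <- mol_structure("C", matrix(0, 1, 3)); s$energy <- e; s
  }
  set.seed(127)
  for (trial in 1:60) {
    energies <- round(sort(runif(sample(5:30, 1), -560, -550)), 3)
    delta_e <- runif(1, 0.05, 2)
    method <- sample(1:3, 1)
    target <- sample(2:10, 1)
    pool <- lapply(energies, mk)
    got <- curate_parents(pool, curation_config(method, delta_e, target))
    got_e <- vapply(got, function(s) s$energy, 0)
    want <- oracle_curate(energies, method, delta_e)
    k <- min(length(want), target)
    expect_equal(got_e[seq_len(k)][got_e[seq_len(k)] %in% want],
                 want[want %in% got_e[seq_len(k)]])
    expect_lte(length(got_e), target)
    # padded up to target when enough candidates exist
    expect_equal(length(got_e), min(target, length(energies)))
    if (method != 1) {
      kept_rule <- got_e[got_e %in% want]
      if (length(kept_rule) > 1) {
        expect_true(all(diff(kept_rule) > 0))
      }
    }
  }
})

test_that("clustered driver runs its selection budget and beats nothing it should not", {
  set.seed(128)
  calc <- toy_calculator()
  clusters <- lapply(1:3, function(k)
    build_library(6, c(C = 4, H = 4)))
  cur <- curation_config(2, delta_e = 0.05, target_size = 4)
  rec <- clustered_ea(clusters, learning_params(), cur, calc,
                      fast_cfg, e_success = -Inf)
  expect_equal(nrow(rec$log), fast_cfg$n_selections)
  expect_true(is.na(rec$success_iteration))
  expect_true(all(diff(rec$log$best_so_far) <= 0))
  expect_equal(rec$best_energy, min(rec$log$best_so_far))
  expect_lte(nrow(rec$log) * fast_cfg$iters_per_run,
             fast_cfg$n_selections * fast_cfg$iters_per_run)
  # early stop: an easily reachable success threshold ends the run
  set.seed(129)
  rec2 <- clustered_ea(clusters, learning_params(), cur, calc, fast_cfg,
                       e_success = -20)
  expect_false(is.na(rec2$success_iteration))
  expect_lte(nrow(rec2$log), fast_cfg$n_selections)
})

test_that("a cluster rigged to produce the lowest energies dominates selection", {
  set.seed(130)
  # cluster 3 carries nitrogen; the stub calculator rewards nitrogen heavily
  rig_calc <- stub_calculator(function(s)
    toy_energy(s) / 50 - 40 * sum(s$symbols == "N"))
  clusters <- c(lapply(1:2, function(k) build_library(6, c(C = 4, H = 4))),
                list(build_library(6, c(C = 4, H = 2, N = 2))))
  cfg <- ea_config(iters_per_run = 5L, n_selections = 40L,
                   relax_max_steps = 5L, lookalike_threshold = 0)
  rec <- clustered_ea(clusters, learning_params(79, 3, 19, 68),
                      curation_config(2, 0.05, 4), rig_calc, cfg)
  freq <- mean(rec$log$cluster == 3)
  expect_gt(freq, 1 / 3)
})

test_that("the unclustered baseline grows its population and logs a monotone minimum", {
  set.seed(131)
  calc <- toy_calculator()
  lib <- lapply(1:10, function(i)
    calc$relax(build_structure(c(C = 4, H = 4)), 25, 0.05))
  cfg <- ea_config(relax_max_steps = 25L, lookalike_threshold = 0)
  out0 <- unclustered_ea(lib, calc, 0, cfg)
  expect_equal(out0$best_energy, min(vapply(lib, function(s) s$energy, 0)))
  out <- unclustered_ea(lib, calc, 30, cfg)
  expect_length(out$running_min, 30)
  expect_true(all(diff(out$running_min) <= 0))
  expect_gte(out$n_members, 10)
  expect_lte(out$best_energy, out0$best_energy)
})
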