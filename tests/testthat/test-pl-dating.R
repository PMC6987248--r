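# The penalized-likelihood core: objective, constrained fitting, smoothing
# grid, cross-validation machinery and the clock test.

test_that("pl_objective: clock penalty vanishes, lambda scales linearly", {
  truth <- fix_truth(n_tips = 10, seed = 1)
  sr <- split_root_cal(truth)
  prob <- pl_problem(truth$phylogram, sr$cals, sr$root, lambda = 3)
  ages <- truth$ages
  E <- nrow(truth$chronogram$edge)
  # equal rates: the penalty term contributes exactly zero
  o_clock <- pl_objective(prob, rates = rep(0.002, E), ages = ages)
  prob10 <- pl_problem(truth$phylogram, sr$cals, sr$root, lambda = 10)
  expect_equal(pl_objective(prob10, rep(0.002, E), ages), o_clock)
  # heterogeneous rates: objective = likelihood + lambda * penalty, so the
  # lambda-difference isolates the penalty and scales linearly
  r2 <- truth$rates
  d3 <- pl_objective(prob, r2, ages)
  d10 <- pl_objective(prob10, r2, ages)
  tiny <- pl_problem(truth$phylogram, sr$cals, sr$root, lambda = 1e-9)
  like <- pl_objective(tiny, r2, ages)
  expect_equal((d10 - like) / (d3 - like), 10 / 3, tolerance = 1e-6)
  # bound violations are refused
  bad <- ages; bad[map_to_node(truth$chronogram, sr$cals[1, ])] <-
    sr$cals$max_age[1] + 5
  expect_error(pl_objective(prob, r2, bad), "bound|ordering")
})

test_that("single-edge Poisson term matches the closed-form log-pmf", {
  # two tips, one-sided: tree (a:t, b:t); x = 10 on an edge with mu = 10
  tr <- ape::read.tree(text = "(a:0.001006,b:0.001006);")
  ph <- phylogram(tr, 1e4)   # x = round(0.001006 * 1e4) = 10 per edge
  prob <- pl_problem(ph, NULL, root_constraint(1 - 1e-12, 1 + 1e-12),
                     lambda = 1)
  ages <- c(0, 0, 1)
  rates <- rep(10 / 1e4, 2)  # r * t * n_sites = 10
  val <- pl_objective(prob, rates, ages)
  expect_equal(val, -2 * stats::dpois(10, 10, log = TRUE),
               tolerance = 1e-10)
})

test_that("pl_objective agrees with a brute-force oracle on random trees", {
  errs <- numeric(0)
  for (i in 1:200) {
    cfg <- sim_config(n_tips = 6, rate_log_sd = 0.4, seed = 1000 + i)
    ch <- simulate_chronogram(cfg)
    rates <- simulate_rates(ch, cfg)
    ph <- chronogram_to_phylogram(ch, rates, cfg)
    ra <- max(node_ages(ch))
    prob <- pl_problem(ph, NULL, root_constraint(ra - 1e-9, ra + 1e-9),
                       lambda = runif(1, 0.1, 10))
    ages <- node_ages(ch)
    v1 <- pl_objective(prob, unname(rates), ages)
    v2 <- oracle_pl_objective(ch, ph$tree$edge.length, cfg$n_sites,
                              prob$lambda, unname(rates), ages)
    errs <- c(errs, abs(v1 - v2))
  }
  expect_lt(max(errs), 1e-8)
})

test_that("fully pinned calibrations force the exact ages", {
  truth <- fix_truth(n_tips = 15, seed = 4)
  ch <- truth$chronogram
  ages <- node_ages(ch)
  keys <- clade_keys(ch)
  nodes <- as.integer(names(keys))
  root <- ape::Ntip(ch) + 1L
  taxa <- lapply(names(keys), function(v)
    strsplit(keys[[v]], "\r", fixed = TRUE)[[1]])
  cals <- calibration_set(paste0("n", nodes), ages[nodes], ages[nodes],
                          "crown", taxa)
  prob <- pl_problem(truth$phylogram,
                     cals[nodes != root, ],
                     root_constraint(ages[root] - 1e-12,
                                     ages[root] + 1e-12), 1e5)
  fit <- date_tree(prob, seed = 1, n_starts = 1, maxit = 200)
  expect_equal(unname(fit$ages[nodes]), unname(ages[nodes]),
               tolerance = 1e-10)
})

test_that("noiseless clock data is recovered within 0.5% when the root is known", {
  for (seed in c(5, 9)) {
    cfg <- sim_config(n_tips = 40, rate_log_sd = 0, poisson_noise = FALSE,
                      n_sites = 1e5, seed = seed)
    ch <- simulate_chronogram(cfg)
    ph <- chronogram_to_phylogram(ch, simulate_rates(ch, cfg), cfg)
    ra <- max(node_ages(ch))
    prob <- pl_problem(ph, NULL, root_constraint(ra - 1e-9, ra + 1e-9),
                       lambda = 1e6)
    fit <- date_tree(prob, seed = 1, maxit = 5000, factr = 1e1)
    ta <- node_ages(ch)
    ints <- (ape::Ntip(ch) + 1):(ape::Ntip(ch) + ch$Nnode)
    # all ages within 0.5% of tree height; informative nodes (>= 1 My,
    # above the count-rounding floor) within 0.5% of their own age
    expect_lt(max(abs(fit$ages[ints] - ta[ints])) / ra, 0.005)
    deep <- ints[ta[ints] >= 1]
    expect_lt(max(abs(fit$ages[deep] - ta[deep]) / ta[deep]), 0.005)
  }
})

test_that("huge smoothing drives the fit to a single clock rate", {
  cfg <- sim_config(n_tips = 20, birth_rate = 1, root_rate = 1,
                    rate_log_sd = 0.2, n_sites = 300, seed = 2)
  truth <- simulate_truth(cfg, k_calibrations = 4, cal_width = 2)
  sr <- split_root_cal(truth)
  prob <- pl_problem(truth$phylogram, sr$cals, sr$root, lambda = 1e6)
  fit <- date_tree(prob, seed = 1, maxit = 5000)
  expect_lt(stats::sd(fit$rates) / mean(fit$rates), 1e-3)
})

test_that("date_tree is deterministic and respects every hard bound", {
  truth <- fix_truth(n_tips = 25, seed = 14)
  sr <- split_root_cal(truth)
  prob <- pl_problem(truth$phylogram, sr$cals, sr$root, lambda = 1e5)
  f1 <- date_tree(prob, seed = 3)
  f2 <- date_tree(prob, seed = 3)
  expect_identical(f1$ages, f2$ages)
  expect_identical(f1$rates, f2$rates)
  ages <- f1$ages
  for (i in seq_len(nrow(sr$cals))) {
    v <- map_to_node(truth$chronogram, sr$cals[i, ])
    expect_gte(ages[v], sr$cals$min_age[i] - 1e-9)
    expect_lte(ages[v], sr$cals$max_age[i] + 1e-9)
  }
  root <- ape::Ntip(truth$chronogram) + 1L
  expect_gte(ages[root], sr$root$min_age - 1e-9)
  expect_lte(ages[root], sr$root$max_age + 1e-9)
  expect_true(all(f1$chronogram$edge.length >= 0))
  expect_true(is_ultrametric(f1$chronogram, tol = 1e-6))
})

test_that("infeasible constraint systems are rejected with the pair named", {
  truth <- fix_truth(n_tips = 12, seed = 19, k_calibrations = 2)
  tr <- truth$chronogram
  keys <- clade_keys(tr)
  # find a non-root internal node and pin its minimum above the root max
  v <- as.integer(names(keys))[2]
  taxa <- strsplit(keys[[as.character(v)]], "\r", fixed = TRUE)[[1]]
  cal <- calibration_set("deep_min", 300, 320, "crown", list(taxa))
  expect_warning(
    prob <- pl_problem(truth$phylogram, cal, root_constraint(180, 220), 1),
    "infeasible")
  expect_error(date_tree(prob), "infeasible")
})

test_that("smoothing_grid reproduces the published cross-validation grid", {
  g <- smoothing_grid()
  expect_length(g, 110)                       # 10 * 0.9^k down to 1e-4
  expect_equal(g[1], 10)
  expect_gte(min(g), 1e-4)
  expect_equal(unique(round(g[-1] / g[-length(g)], 12)), 0.9)
  expect_identical(smoothing_grid(1, 1, 0.9), 1)
  expect_error(smoothing_grid(1, 2, 0.9), "cvstop")
  expect_error(smoothing_grid(10, 1, 1.5), "cvmultstep")
})

test_that("cross-validation scores clock data best at maximal smoothing", {
  cfg <- sim_config(n_tips = 40, rate_log_sd = 0, seed = 2)
  truth <- simulate_truth(cfg, k_calibrations = 5)
  sr <- split_root_cal(truth)
  grid <- smoothing_grid(1e6, 1e2, 0.1)   # 5 values
  cv <- grid_cv(truth$phylogram, grid, sr$cals, sr$root, n_terminals = 8,
                seed = 1)
  expect_equal(cv$best_lambda, 1e6)
  expect_lt(cv$scores[1], cv$scores[length(grid)])
  # determinism of a single score under a fixed seed
  s1 <- cv_score(truth$phylogram, 1e4, sr$cals, sr$root, n_terminals = 5,
                 seed = 7)
  s2 <- cv_score(truth$phylogram, 1e4, sr$cals, sr$root, n_terminals = 5,
                 seed = 7)
  expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("near-noiseless self-prediction gives a near-zero cv score", {
  cfg <- sim_config(n_tips = 20, rate_log_sd = 0, poisson_noise = FALSE,
                    n_sites = 1e6, seed = 3)
  ch <- simulate_chronogram(cfg)
  ph <- chronogram_to_phylogram(ch, simulate_rates(ch, cfg), cfg)
  ra <- max(node_ages(ch))
  s <- cv_score(ph, 1e8, NULL, root_constraint(ra - 1e-9, ra + 1e-9),
                n_terminals = 6, seed = 2, maxit = 3000)
  expect_lt(as.numeric(s), 0.01)
})

test_that("subsampled replicates have the right size and proportions", {
  cfg <- sim_config(n_tips = 60, rate_log_sd = 0, seed = 17)
  truth <- simulate_truth(cfg, k_calibrations = 6)
  sr <- split_root_cal(truth)
  grid <- smoothing_grid(1e6, 1e4, 0.1)  # 3 values
  scv <- subsampled_cv(truth$phylogram, sr$cals, sr$root,
                       n_replicates = 4, keep_fraction = 0.25,
                       grid = grid, seed = 5, n_terminals = 5)
  expect_equal(sum(scv$proportions), 1)
  expect_length(scv$best_lambdas, 4)
  expect_true(all(scv$best_lambdas %in% grid))
  expect_true(scv$modal_lambda %in% grid)
  expect_equal(scv$modal_proportion,
               max(table(scv$best_lambdas)) / 4)
  # keep_fraction sets the replicate tip count exactly
  expect_error(subsampled_cv(truth$phylogram, sr$cals, sr$root,
                             n_replicates = 1, keep_fraction = 0.01,
                             grid = grid), ">= 4")
  expect_error(subsampled_cv(truth$phylogram, sr$cals, sr$root,
                             n_replicates = 1, keep_fraction = 1.2,
                             grid = grid), "keep_fraction")
})

test_that("clock test: boundary p-value, determinism, and power", {
  # identical likelihoods: a phylogram that the clock fits exactly
  tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  ct0 <- clock_test(phylogram(tr, 1e4))
  expect_gte(ct0$p_value, 0.95)
  expect_lte(ct0$p_value, 1)
  # strong heterogeneity is detected decisively
  pv <- vapply(1:15, function(s) {
    cfg <- sim_config(n_tips = 12, rate_log_sd = 0.5, n_sites = 5000,
                      seed = 300 + s)
    ch <- simulate_chronogram(cfg)
    clock_test(chronogram_to_phylogram(ch, simulate_rates(ch, cfg), cfg),
               seed = s)$p_value
  }, 0)
  expect_gte(mean(pv < 0.001), 0.95)
})
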