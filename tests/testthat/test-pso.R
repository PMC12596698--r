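make_swarm_fixture <- function(n_models = 2, n = 60, d = 4, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0)
  arch <- network_architecture(d, c(5), 1, output_activation = "sigmoid")
  task <- task_spec("binary", 1, epochs = 3, batch_size = 16, seed = seed)
  idx_tr <- 1:40; idx_va <- 41:60
  models <- lapply(seq_len(n_models), function(i)
    train_model(init_model(arch, seed = seed + i), X[idx_tr, ], y[idx_tr], task))
  list(models = models, task = task,
       train_inputs = rep(list(X[idx_tr, ]), n_models), train_labels = y[idx_tr],
       val_inputs = rep(list(X[idx_va, ]), n_models), val_labels = y[idx_va])
}

test_that("velocity update evaluates the standard rule exactly", {
  cfg <- swarm_config(inertia = 0.7, cognitive = 1.5, social = 1.5)
  # worked scalar example: 0.7*1 + 1.5*0.5*(1-0) + 1.5*0.5*(2-0) = 2.95
  expect_equal(velocity_update(1, 0, 1, 2, cfg, 0.5, 0.5), 2.95)
  expect_equal(position_update(0, 2.95), 2.95)

  # all difference terms vanish
  x <- rnorm(5)
  expect_equal(velocity_update(numeric(5), x, x, x, cfg,
                               runif(5), runif(5)), numeric(5))
  # zero coefficients kill any input
  cfg0 <- swarm_config(inertia = 0, cognitive = 0, social = 0)
  expect_equal(velocity_update(rnorm(5), rnorm(5), rnorm(5), rnorm(5), cfg0,
                               runif(5), runif(5)), numeric(5))

  expect_error(velocity_update(1:2, 1:3, 1:2, 1:2, cfg, 0.5, 0.5),
               class = "psofusion_invalid_input")
  expect_error(position_update(1:2, 1:3), class = "psofusion_invalid_input")
})

test_that("velocity and position rules match scalar brute force on random draws", {
  set.seed(77)
  for (i in 1:1000) {
    w <- runif(1); c1 <- runif(1, 0, 3); c2 <- runif(1, 0, 3)
    v <- rnorm(1); x <- rnorm(1); pi_ <- rnorm(1); pg <- rnorm(1)
    r1 <- runif(1); r2 <- runif(1)
    cfg <- swarm_config(inertia = w, cognitive = c1, social = c2)
    expected_v <- w * v + c1 * r1 * (pi_ - x) + c2 * r2 * (pg - x)
    got_v <- velocity_update(v, x, pi_, pg, cfg, r1, r2)
    expect_identical(got_v, expected_v)
    expect_identical(position_update(x, got_v), x + expected_v)
  }
})

test_that("velocity clamping bounds each coordinate after the update", {
  cfg <- swarm_config(velocity_clamp = 0.5)
  v <- velocity_update(c(10, -10, 0.1), c(0, 0, 0), c(5, -5, 0), c(5, -5, 0),
                       cfg, 1, 1)
  expect_true(all(abs(v) <= 0.5))
  expect_equal(v[3], 0.7 * 0.1)
})

test_that("fitness is the validation loss with known closed forms", {
  arch <- tiny_arch(3, c(4), 5, "softmax")
  zero <- set_model_params(init_model(arch, 1), numeric(param_count(arch)))
  X <- matrix(rnorm(30), 10, 3)
  y <- sample(1:5, 10, replace = TRUE)
  task <- task_spec("multiclass", 5)
  # uniform softmax: cross-entropy is ln(C)
  expect_equal(evaluate_fitness(zero, X, y, task), log(5), tolerance = 1e-12)
  expect_error(evaluate_fitness(zero, X[0, , drop = FALSE], integer(0), task),
               class = "psofusion_invalid_config")

  # near-perfect one-hot predictions: loss ~ 0 (via an extreme bias)
  v <- numeric(param_count(arch))
  biased <- init_model(arch, 1)
  p <- biased$parameters
  for (l in seq_along(p)) { p[[l]]$W[] <- 0; p[[l]]$b[] <- 0 }
  p[[2]]$b <- c(50, 0, 0, 0, 0)
  biased$parameters <- p
  expect_lt(evaluate_fitness(biased, X, rep(1L, 10), task), 1e-10)

  # matches an independent per-sample oracle on a small fixed problem
  set.seed(12)
  net <- init_model(tiny_arch(2, c(3), 2, "softmax"), 99)
  Xs <- matrix(rnorm(10), 5, 2)
  ys <- c(1L, 2L, 1L, 2L, 2L)
  P <- predict(net, Xs)
  oracle <- -mean(sapply(1:5, function(i) log(P[i, ys[i]])))
  expect_equal(evaluate_fitness(net, Xs, ys, task_spec("multiclass", 2)),
               oracle, tolerance = 1e-12)
})

test_that("a zero-iteration swarm is the identity and history is empty", {
  fx <- make_swarm_fixture()
  cfg <- swarm_config(iterations = 0, seed = 1)
  res <- run_swarm(fx$models, fx$train_inputs, fx$train_labels,
                   fx$val_inputs, fx$val_labels, fx$task, cfg)
  expect_length(res$fitness_history, 0)
  expect_equal(nrow(res$records), 0)
  for (i in seq_along(fx$models))
    expect_identical(flatten_params(res$models[[i]]),
                     flatten_params(fx$models[[i]]))
})

test_that("global-best fitness is monotone non-increasing for many seeds", {
  fx <- make_swarm_fixture(n_models = 3)
  for (seed in 1:5) {
    cfg <- swarm_config(iterations = 4, retrain_epochs = 1, seed = seed)
    res <- run_swarm(fx$models, fx$train_inputs, fx$train_labels,
                     fx$val_inputs, fx$val_labels, fx$task, cfg)
    expect_true(all(diff(res$fitness_history) <= 0))
    expect_lte(res$global_best_fitness, min(res$initial_fitness))
    expect_equal(res$global_best_fitness, min(res$personal_best_fitness))
  }
})

test_that("the swarm is deterministic under a fixed seed", {
  fx <- make_swarm_fixture(n_models = 4)
  cfg <- swarm_config(iterations = 3, retrain_epochs = 2, seed = 17)
  r1 <- run_swarm(fx$models, fx$train_inputs, fx$train_labels,
                  fx$val_inputs, fx$val_labels, fx$task, cfg)
  r2 <- run_swarm(fx$models, fx$train_inputs, fx$train_labels,
                  fx$val_inputs, fx$val_labels, fx$task, cfg)
  expect_identical(r1$fitness_history, r2$fitness_history)
  expect_identical(r1$records, r2$records)
  expect_identical(flatten_params(r1$models[[1]]), flatten_params(r2$models[[1]]))
})

test_that("with zero coefficients and no retraining, velocity decays by the inertia factor", {
  fx <- make_swarm_fixture(n_models = 2)
  w <- 0.6
  cfg <- swarm_config(inertia = w, cognitive = 0, social = 0,
                      iterations = 4, retrain_epochs = 0, seed = 2)
  v0 <- lapply(fx$models, function(m) {
    set.seed(1); rnorm(length(flatten_params(m)))
  })
  res <- run_swarm(fx$models, fx$train_inputs, fx$train_labels,
                   fx$val_inputs, fx$val_labels, fx$task, cfg,
                   initial_velocities = v0)
  for (i in 1:2) {
    expect_equal(res$velocities[[i]], w^4 * v0[[i]], tolerance = 1e-12)
    expect_equal(sqrt(sum(res$velocities[[i]]^2)),
                 w^4 * sqrt(sum(v0[[i]]^2)), tolerance = 1e-12)
  }
})

test_that("fitness history CSV export carries the per-particle records", {
  fx <- make_swarm_fixture(n_models = 2)
  cfg <- swarm_config(iterations = 2, retrain_epochs = 0, seed = 4)
  res <- run_swarm(fx$models, fx$train_inputs, fx$train_labels,
                   fx$val_inputs, fx$val_labels, fx$task, cfg)
  path <- tempfile(fileext = ".csv")
  write_fitness_history(res, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 2 * 2)
  expect_named(back, c("iteration", "particle", "fitness",
                       "is_personal_best", "is_global_best"))
  expect_equal(back$fitness, res$records$fitness)
})

test_that("swarm input mismatches are rejected", {
  fx <- make_swarm_fixture(n_models = 2)
  cfg <- swarm_config(iterations = 1, seed = 1)
  expect_error(run_swarm(fx$models, fx$train_inputs[1], fx$train_labels,
                         fx$val_inputs, fx$val_labels, fx$task, cfg),
               class = "psofusion_invalid_config")
  expect_error(swarm_config(inertia = -1), class = "psofusion_invalid_config")
})
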