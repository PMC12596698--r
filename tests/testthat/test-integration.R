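zero_models <- function(n_models, input_dim, out_dim) {
  combos <- enumerate_feature_pairs(n_models, 1)
  lapply(seq_len(n_models), function(i) {
    arch <- network_architecture(input_dim, c(2), out_dim,
      output_activation = if (out_dim == 1) "sigmoid" else "softmax")
    set_model_params(init_model(arch, i, combination = combos[i, ]),
                     numeric(param_count(arch)))
  })
}

test_that("stacked output width is combinations x output dim, models frozen", {
  X <- matrix(rnorm(6 * 3), 6, 3)

  models25 <- zero_models(25, 3, 65)
  before <- lapply(models25, flatten_params)
  st <- collect_base_outputs(models25, rep(list(X), 25))
  expect_equal(ncol(st), 25 * 65)   # 1625
  expect_equal(nrow(st), 6)
  expect_identical(lapply(models25, flatten_params), before)

  models7 <- zero_models(7, 3, 1)
  st7 <- collect_base_outputs(models7, rep(list(X), 7))
  expect_equal(ncol(st7), 7)
  expect_equal(attr(st7, "base_output_dim"), 1L)

  expect_error(collect_base_outputs(models7, rep(list(X), 6)),
               class = "psofusion_invalid_config")
})

test_that("averaging across blocks is the per-cell mean", {
  # identical blocks collapse to one block
  b <- matrix(runif(8), 4, 2)
  st <- cbind(b, b, b)
  expect_equal(average_outputs(st, 2), b)

  # two scalar blocks 0.2 and 0.8 average to 0.5
  expect_equal(average_outputs(cbind(rep(0.2, 3), rep(0.8, 3)), 1),
               matrix(0.5, 3, 1), ignore_attr = TRUE)

  # random blocks match a loop-based oracle
  set.seed(8)
  st3 <- matrix(runif(5 * 12), 5, 12)
  got <- average_outputs(st3, 3)
  oracle <- matrix(0, 5, 3)
  for (i in 1:5) for (j in 1:3)
    oracle[i, j] <- mean(st3[i, c(j, j + 3, j + 6, j + 9)])
  expect_equal(got, oracle)

  expect_error(average_outputs(st3, 5), class = "psofusion_invalid_input")
})

test_that("majority vote counts blocks and breaks ties low", {
  # 3 blocks of 2-class scores voting (A, A, B) -> A
  blockA <- c(0.9, 0.1); blockB <- c(0.2, 0.8)
  st <- rbind(c(blockA, blockA, blockB))
  expect_equal(majority_vote(st, 2), 1)
  # unanimous
  st2 <- rbind(c(blockB, blockB, blockB))
  expect_equal(majority_vote(st2, 2), 2)
  # 2 blocks voting (A, B): tie -> lower class index
  st3 <- rbind(c(blockA, blockB))
  expect_equal(majority_vote(st3, 2), 1)
  # binary single-column blocks vote at threshold 0.5
  st4 <- rbind(c(0.9, 0.8, 0.1), c(0.1, 0.2, 0.3))
  expect_equal(majority_vote(st4, 1), c(1, 0))
  expect_error(majority_vote(st4, 1, task_kind = "regression"),
               class = "psofusion_invalid_config")
})

test_that("weighted sums are convex combinations; uniform weights equal averaging", {
  set.seed(9)
  st <- matrix(runif(4 * 6), 4, 6)
  # one-hot weight selects that block exactly
  expect_equal(weighted_sum(st, c(0, 1, 0), 2), st[, 3:4])
  # weights (0.25, 0.75) on scalar blocks 0 and 1 -> 0.75
  expect_equal(weighted_sum(cbind(rep(0, 3), rep(1, 3)), c(0.25, 0.75), 1),
               matrix(0.75, 3, 1), ignore_attr = TRUE)
  # exact equivalence with averaging under uniform weights
  expect_identical(weighted_sum(st, c(1, 1, 1), 2), average_outputs(st, 2))
  expect_identical(weighted_sum(st, c(5, 5, 5), 2), average_outputs(st, 2))

  expect_error(weighted_sum(st, c(1, 1), 2), class = "psofusion_invalid_input")
  expect_error(weighted_sum(st, c(-1, 1, 1), 2), class = "psofusion_invalid_input")
})

test_that("stacker training is seeded, skippable, and can exploit a perfect base", {
  set.seed(10)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  # block 1 is a perfect base model; blocks 2-3 are noise
  st <- cbind(0.98 * y + 0.01, runif(n), runif(n))
  task <- task_spec("binary", 1, epochs = 40, batch_size = 16, seed = 4)

  init_only <- train_stacker(st, y, task, hidden_dims = c(4), epochs = 0)
  expect_identical(flatten_params(init_only),
                   flatten_params(init_model(init_only$architecture, seed = 4)))

  s1 <- train_stacker(st, y, task, hidden_dims = c(8), epochs = 300)
  s2 <- train_stacker(st, y, task, hidden_dims = c(8), epochs = 300)
  expect_identical(flatten_params(s1), flatten_params(s2))

  # validation loss close to what copying the perfect input would give
  val <- 101:120
  base_loss <- -mean(y[val] * log(st[val, 1]) +
                     (1 - y[val]) * log(1 - st[val, 1]))
  stacker_loss <- evaluate_fitness(s1, st[val, , drop = FALSE], y[val], task)
  expect_lte(stacker_loss, base_loss + 0.15)
})

test_that("single-combination stacking reproduces the base model's ranking", {
  # with one combination, the stacker sees only the base model's score and
  # learns a monotone transform of it: rankings and discrimination match
  toy <- toy_binary_data(60)
  arch <- network_architecture(3, c(6), 1, output_activation = "sigmoid")
  task <- task_spec("binary", 1, epochs = 100, batch_size = 16, seed = 3)
  base <- train_model(init_model(arch, 3), toy$X, toy$y, task)
  st <- collect_base_outputs(list(base), list(toy$X))
  stacker <- train_stacker(st, toy$y, task, hidden_dims = c(4), epochs = 300)
  p_base <- predict(base, toy$X)[, 1]
  p_stack <- predict(stacker, unclass(st))[, 1]
  expect_gt(cor(p_base, p_stack, method = "spearman"), 0.95)
  auroc <- function(s) compute_metrics(toy$y, s, "binary")$auroc
  expect_equal(auroc(p_stack), auroc(p_base), tolerance = 0.02)
})
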