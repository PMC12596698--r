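test_that("parameter counts follow the per-layer closed form", {
  arch <- network_architecture(8, c(512, 256, 128), 65)
  expect_equal(param_count(arch),
               8 * 512 + 512 + 512 * 256 + 256 + 256 * 128 + 128 +
                 128 * 65 + 65)
  set.seed(21)
  for (rep in 1:20) {
    dims <- sample(1:40, sample(2:5, 1) + 1)
    arch <- network_architecture(dims[1], dims[-c(1, length(dims))],
                                 dims[length(dims)],
                                 output_activation = "sigmoid")
    expect_equal(param_count(arch), count_oracle(dims))
    expect_length(flatten_params(init_model(arch, seed = rep)),
                  count_oracle(dims))
  }
})

test_that("initialization is seed-determined", {
  arch <- tiny_arch(5, c(6, 4), 3)
  m1 <- init_model(arch, seed = 42)
  m2 <- init_model(arch, seed = 42)
  m3 <- init_model(arch, seed = 43)
  expect_identical(flatten_params(m1), flatten_params(m2))
  expect_false(all(flatten_params(m1) == flatten_params(m3)))
})

test_that("flatten/unflatten round trips and the layout is as documented", {
  arch <- tiny_arch(3, c(4), 2)
  model <- init_model(arch, seed = 1)
  v <- flatten_params(model)
  expect_identical(flatten_params(set_model_params(model, v)), v)

  # all-zeros -> all-zero weights and biases
  z <- set_model_params(model, numeric(param_count(arch)))
  expect_true(all(vapply(z$parameters,
                         function(l) all(l$W == 0) && all(l$b == 0),
                         logical(1))))

  # consecutive integers: layer 1's W column-major first, then its bias
  cons <- set_model_params(model, as.numeric(seq_len(param_count(arch))))
  expect_equal(cons$parameters[[1]]$W[1, 1], 1)
  expect_equal(cons$parameters[[1]]$W[2, 1], 2)   # column-major
  expect_equal(cons$parameters[[1]]$W[1, 2], 4)
  expect_equal(cons$parameters[[1]]$b, c(13, 14, 15, 16))
  expect_equal(cons$parameters[[2]]$W[1, 1], 17)

  expect_error(unflatten_params(numeric(3), arch),
               class = "psofusion_invalid_input")
  expect_error(unflatten_params(numeric(3), arch), "expected 26, received 3")
})

test_that("training honours epochs, reduces loss, and is reproducible", {
  toy <- toy_binary_data(40)
  arch <- network_architecture(3, c(8), 1, output_activation = "sigmoid")
  task <- task_spec("binary", 1, epochs = 50, batch_size = 8, seed = 5)
  model <- init_model(arch, seed = 5)

  frozen <- train_model(model, toy$X, toy$y, task, epochs_override = 0)
  expect_identical(flatten_params(frozen), flatten_params(model))
  expect_length(frozen$training_history, 0)

  t1 <- train_model(model, toy$X, toy$y, task)
  expect_length(t1$training_history, 50)
  expect_lt(t1$training_history[50], t1$training_history[1])

  t2 <- train_model(model, toy$X, toy$y, task)
  expect_identical(flatten_params(t1), flatten_params(t2))

  # zero learning rate leaves parameters unchanged
  task0 <- task_spec("binary", 1, epochs = 3, batch_size = 8,
                     learning_rate = 0, seed = 5)
  t0 <- train_model(model, toy$X, toy$y, task0)
  expect_identical(flatten_params(t0), flatten_params(model))

  expect_error(train_model(model, toy$X, toy$y[-1], task),
               class = "psofusion_invalid_input")
  expect_error(train_model(model, toy$X[, 1:2], toy$y, task),
               class = "psofusion_invalid_input")
})

test_that("prediction obeys the output activation's constraints", {
  X <- matrix(rnorm(12), 4, 3)

  soft <- init_model(tiny_arch(3, c(5), 4, "softmax"), seed = 2)
  P <- predict(soft, X)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)

  # zero-weight networks: sigmoid gives 0.5, softmax gives 1/C
  zero_sig <- set_model_params(init_model(tiny_arch(3, c(5), 1, "sigmoid"), 1),
                               numeric(param_count(tiny_arch(3, c(5), 1, "sigmoid"))))
  expect_equal(predict(zero_sig, X), matrix(0.5, 4, 1))
  zero_soft <- set_model_params(soft, numeric(param_count(soft$architecture)))
  expect_equal(predict(zero_soft, X), matrix(0.25, 4, 4))

  # pure function of (parameters, inputs)
  expect_identical(predict(soft, X), predict(soft, X))
  expect_error(predict(soft, X[, 1:2]), class = "psofusion_invalid_input")
})

test_that("checkpoints restore bit-identical predictions", {
  toy <- toy_binary_data(20)
  arch <- network_architecture(3, c(6, 4), 1, output_activation = "sigmoid")
  task <- task_spec("binary", 1, epochs = 10, batch_size = 8, seed = 9)
  model <- train_model(init_model(arch, seed = 9,
                                  combination = enumerate_feature_pairs(2, 2)[3, ]),
                       toy$X, toy$y, task)
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict(back, toy$X), predict(model, toy$X))
  expect_identical(flatten_params(back), flatten_params(model))
  expect_equal(back$combination$ordinal, 2)
  expect_equal(back$training_history, model$training_history)
})

test_that("task specs enforce loss compatibility and split sums", {
  expect_error(task_spec("multiclass", 5, loss = "mse"),
               class = "psofusion_invalid_config")
  expect_error(task_spec("binary", 1, split = c(0.5, 0.2, 0.2)),
               class = "psofusion_invalid_config")
  expect_equal(task_spec("multilabel", 7)$loss, "binary cross-entropy")
  expect_equal(task_spec("regression", 1)$loss, "mse")
})
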