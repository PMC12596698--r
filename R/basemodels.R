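# Per-combination base models: task specification, seeded initialization,
# Adam training, prediction, flat parameter views and portable checkpoints.

default_loss_for <- function(task_kind) {
  switch(task_kind,
    multiclass = "cross-entropy",
    multilabel = "binary cross-entropy",
    binary = "binary cross-entropy",
    regression = "mse")
}

activation_for <- function(task_kind) {
  switch(task_kind,
    multiclass = "softmax",
    multilabel = "sigmoid",
    binary = "sigmoid",
    regression = "identity")
}

#' Specify a prediction task
#'
#' @param task_kind One of `"multiclass"`, `"multilabel"`, `"binary"`,
#'   `"regression"`.
#' @param n_classes Label dimension (number of classes or labels; 1 for
#'   binary and scalar regression).
#' @param loss Training loss; defaults to the task's standard choice
#'   (cross-entropy, binary cross-entropy, or MSE) and must stay compatible
#'   with `task_kind`.
#' @param epochs Training epochs for base models (default 50).
#' @param batch_size Mini-batch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param split Train/validation/test fractions summing to 1.
#' @param seed Integer seed governing initialization and batch order.
#' @return Object of class `task_spec`.
#' @export
task_spec <- function(task_kind = c("multiclass", "multilabel", "binary", "regression"),
                      n_classes, loss = NULL, epochs = 50L, batch_size = 128L,
                      learning_rate = 1e-3, split = c(0.8, 0.1, 0.1),
                      seed = 1L) {
  task_kind <- match.arg(task_kind)
  loss <- loss %||% default_loss_for(task_kind)
  ok <- switch(task_kind,
    multiclass = loss == "cross-entropy",
    multilabel = loss == "binary cross-entropy",
    binary = loss %in% c("binary cross-entropy", "mse"),
    regression = loss == "mse")
  if (!ok) err_invalid_config("loss '%s' is incompatible with task kind '%s'",
                              loss, task_kind)
  if (abs(sum(split) - 1) > 1e-8)
    err_invalid_config("split fractions must sum to 1")
  if (task_kind %in% c("binary", "regression") && n_classes != 1)
    n_classes <- 1L
  structure(list(task_kind = task_kind, n_classes = as.integer(n_classes),
                 loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, split = split,
                 seed = as.integer(seed)),
            class = "task_spec")
}

# Coerce user-facing labels to the numeric target matrix the trainer wants.
labels_to_matrix <- function(labels, task) {
  if (task$task_kind == "multiclass") {
    if (is.matrix(labels)) return(labels)     # already one-hot
    y <- as.integer(labels)
    if (any(y < 1 | y > task$n_classes))
      err_invalid_input("multiclass labels must lie in 1..%d", task$n_classes)
    Y <- matrix(0, length(y), task$n_classes)
    Y[cbind(seq_along(y), y)] <- 1
    Y
  } else {
    Y <- as.matrix(labels)
    if (task$task_kind %in% c("binary", "multilabel"))
      check_binary(Y, "labels")
    Y
  }
}

#' Initialize a base model
#'
#' Weights are drawn uniformly on `+/- 1/sqrt(fan_in)` per layer (fan-in
#' scaling), biases start at zero; the draw is fully determined by `seed`.
#'
#' @param architecture A [network_architecture()].
#' @param seed Integer seed.
#' @param combination Optional `pair_combinations` row this model is bound to.
#' @return Object of class `pair_model` with `parameters` (internal layer
#'   list), `architecture`, `combination` and an empty `training_history`.
#' @export
init_model <- function(architecture, seed, combination = NULL) {
  stopifnot(inherits(architecture, "network_architecture"))
  params <- with_seed(seed, init_layer_params(architecture))
  structure(list(combination = combination, architecture = architecture,
                 parameters = params, training_history = numeric(0)),
            class = "pair_model")
}

#' @export
print.pair_model <- function(x, ...) {
  comb <- if (is.null(x$combination)) "unbound" else
    sprintf("combination #%d (A:%s, B:%s)", x$combination$ordinal,
            x$combination$index_a, x$combination$index_b)
  cat(sprintf("<pair_model> %s; %d parameters; %d epochs trained\n", comb,
              param_count(x$architecture), length(x$training_history)))
  invisible(x)
}

check_input_width <- function(model, inputs) {
  if (ncol(inputs) != model$architecture$input_dim)
    err_invalid_input("input width %d does not match architecture input_dim %d",
                      ncol(inputs), model$architecture$input_dim)
}

#' Train a base model
#'
#' Mini-batch Adam for a fixed number of epochs; the returned model's
#' `training_history` holds exactly one mean loss per epoch of this call.
#' With `epochs = 0` the model is returned untouched with an empty history.
#'
#' @param model A [init_model()] result.
#' @param inputs Numeric matrix, samples x `input_dim`.
#' @param labels Labels in the task's natural form (integer classes for
#'   multiclass, 0/1 vector/matrix for binary/multilabel, numeric for
#'   regression).
#' @param task A [task_spec()].
#' @param epochs_override Optional epoch count replacing `task$epochs`.
#' @param seed Seed for batch shuffling; defaults to `task$seed`.
#' @return The trained `pair_model`.
#' @export
train_model <- function(model, inputs, labels, task, epochs_override = NULL,
                        seed = NULL) {
  stopifnot(inherits(model, "pair_model"), inherits(task, "task_spec"))
  inputs <- as.matrix(inputs)
  check_input_width(model, inputs)
  Y <- labels_to_matrix(labels, task)
  if (nrow(Y) != nrow(inputs))
    err_invalid_input("inputs have %d rows but labels %d", nrow(inputs), nrow(Y))
  if (ncol(Y) != model$architecture$output_dim)
    err_invalid_input("label dimension %d does not match output_dim %d",
                      ncol(Y), model$architecture$output_dim)
  epochs <- epochs_override %||% task$epochs
  res <- nn_train(model$parameters, inputs, Y, model$architecture, task$loss,
                  epochs, task$batch_size, task$learning_rate,
                  seed %||% task$seed)
  model$parameters <- res$params
  model$training_history <- res$history
  model
}

#' Predict scores from a base (or stacking) model
#'
#' @param object A `pair_model`.
#' @param inputs Numeric matrix, samples x `input_dim`.
#' @param ... Unused.
#' @return Score matrix: rows sum to 1 for softmax output, entries in
#'   `[0, 1]` for sigmoid, unconstrained for identity.
#' @export
predict.pair_model <- function(object, inputs, ...) {
  inputs <- as.matrix(inputs)
  check_input_width(object, inputs)
  nn_forward(object$parameters, inputs, object$architecture)
}

#' Flat parameter vector of a model
#'
#' Layout: layers in input-to-output order; per layer the weight matrix in
#' column-major order, then the biases. This is the position vector the
#' swarm optimizer moves.
#'
#' @param model A `pair_model`.
#' @return Numeric vector of length [param_count()].
#' @export
flatten_params <- function(model) {
  flatten_layer_params(model$parameters)
}

#' Rebuild structured parameters from a flat vector
#'
#' Inverse of [flatten_params()]; the round trip is exact.
#'
#' @param vector Numeric vector of length [param_count()].
#' @param architecture The matching [network_architecture()].
#' @return Internal layer-parameter list (a list of `W`/`b` pairs).
#' @export
unflatten_params <- function(vector, architecture) {
  unflatten_layer_params(vector, architecture)
}

#' Replace a model's parameters from a flat vector
#'
#' @param model A `pair_model`.
#' @param vector Flat parameter vector.
#' @return The model carrying the new parameters.
#' @export
set_model_params <- function(model, vector) {
  model$parameters <- unflatten_layer_params(vector, model$architecture)
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON document: the architecture descriptor,
#' the bound combination (if any), the training history, and the flat
#' parameter vector as a base64-encoded block of little-endian doubles.
#' Loading reconstructs bit-identical predictions.
#'
#' @param model A `pair_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  raw <- writeBin(flatten_params(model), raw(), size = 8, endian = "little")
  doc <- list(
    format = "psofusion-checkpoint-v1",
    architecture = model$architecture[c("input_dim", "hidden_dims",
                                        "output_dim", "output_activation",
                                        "hidden_activation")],
    combination = if (!is.null(model$combination))
      as.list(model$combination[c("ordinal", "index_a", "index_b")]),
    training_history = model$training_history,
    parameters_base64 = jsonlite::base64_enc(raw))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  arch <- network_architecture(doc$architecture$input_dim,
                               doc$architecture$hidden_dims,
                               doc$architecture$output_dim,
                               doc$architecture$output_activation,
                               doc$architecture$hidden_activation)
  vec <- readBin(jsonlite::base64_dec(doc$parameters_base64), "double",
                 n = param_count(arch), size = 8, endian = "little")
  model <- init_model(arch, seed = 0L,
                      combination = if (!is.null(doc$combination))
                        as.data.frame(doc$combination))
  model <- set_model_params(model, vec)
  model$training_history <- as.numeric(doc$training_history %||% numeric(0))
  model
}
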