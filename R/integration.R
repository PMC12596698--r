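# Output integration: the frozen base models' scores are fused either by a
# stacking network trained on their concatenation (the default strategy) or
# by averaging / majority voting / weighted summation.

#' Concatenate frozen base-model outputs
#'
#' Scores every model on its own combined inputs (all models see the same
#' sample set) and binds the score blocks column-wise in combination-ordinal
#' order. Base parameters are read, never written.
#'
#' @param models List of trained `pair_model`s, one per combination.
#' @param inputs_list List of input matrices aligned with `models`, equal
#'   row counts.
#' @return Matrix of class `stacked_output`, samples x
#'   `(n_combinations * base_output_dim)`, with attributes
#'   `base_output_dim` and `n_combinations`.
#' @export
collect_base_outputs <- function(models, inputs_list) {
  if (length(models) < 1) err_invalid_config("no base models supplied")
  if (length(inputs_list) != length(models))
    err_invalid_config("missing inputs: %d models but %d input matrices",
                       length(models), length(inputs_list))
  dims <- vapply(models, function(m) m$architecture$output_dim, integer(1))
  if (length(unique(dims)) != 1)
    err_invalid_config("base models disagree on output dimension")
  nrows <- vapply(inputs_list, nrow, integer(1))
  if (length(unique(nrows)) != 1)
    err_invalid_input("all models must receive the same sample set")
  blocks <- lapply(seq_along(models), function(i)
    predict(models[[i]], inputs_list[[i]]))
  out <- do.call(cbind, blocks)
  structure(out, base_output_dim = dims[1],
            n_combinations = length(models),
            class = c("stacked_output", class(out)))
}

block_view <- function(stacked, base_output_dim) {
  nc <- ncol(stacked)
  if (nc %% base_output_dim != 0)
    err_invalid_input("column count %d is not divisible by base_output_dim %d",
                      nc, base_output_dim)
  nb <- nc / base_output_dim
  lapply(seq_len(nb), function(b)
    stacked[, (b - 1) * base_output_dim + seq_len(base_output_dim),
            drop = FALSE])
}

#' Default stacking architecture
#'
#' Two hidden layers of 64 and 32 units over the concatenated base outputs,
#' with the task's output activation.
#'
#' @param input_dim Number of stacked columns.
#' @param task A [task_spec()].
#' @param hidden_dims Hidden widths (default `c(64, 32)`).
#' @return A [network_architecture()].
#' @export
stacker_architecture <- function(input_dim, task, hidden_dims = c(64L, 32L)) {
  network_architecture(input_dim, hidden_dims, task$n_classes,
                       output_activation = activation_for(task$task_kind))
}

#' Train the stacking network
#'
#' A lightweight network trained by ordinary backpropagation on the frozen
#' base models' concatenated outputs; the swarm is not involved here.
#'
#' @param stacked A [collect_base_outputs()] matrix (or any numeric matrix).
#' @param labels Training labels in the task's natural form.
#' @param task A [task_spec()].
#' @param hidden_dims Hidden widths (default `c(64, 32)`).
#' @param epochs Training epochs (default 50).
#' @param seed Seed for initialization and batch order; defaults to
#'   `task$seed`.
#' @return A trained `pair_model` acting as the stacker.
#' @export
train_stacker <- function(stacked, labels, task, hidden_dims = c(64L, 32L),
                          epochs = 50L, seed = NULL) {
  seed <- seed %||% task$seed
  arch <- stacker_architecture(ncol(stacked), task, hidden_dims)
  model <- init_model(arch, seed = seed)
  train_model(model, unclass_stacked(stacked), labels, task,
              epochs_override = epochs, seed = seed)
}

unclass_stacked <- function(stacked) {
  attr(stacked, "base_output_dim") <- NULL
  attr(stacked, "n_combinations") <- NULL
  class(stacked) <- "matrix"
  stacked
}

#' Average base-model outputs
#'
#' Elementwise mean across the combination blocks of a stacked score matrix.
#'
#' @param stacked Stacked score matrix.
#' @param base_output_dim Columns per combination block.
#' @return Samples x `base_output_dim` score matrix.
#' @export
average_outputs <- function(stacked, base_output_dim) {
  nb <- ncol(stacked) / base_output_dim
  # via weighted_sum so uniform-weight equivalence is exact, not just close
  weighted_sum(stacked, rep(1, nb), base_output_dim)
}

#' Majority vote across base models
#'
#' Each block casts one vote per sample: the arg-max class for multi-column
#' blocks, or class 1 vs 0 at threshold 0.5 for single-column (binary)
#' blocks. Ties are broken toward the lowest class index.
#'
#' @param stacked Stacked score matrix.
#' @param base_output_dim Columns per combination block.
#' @param task_kind Task kind; voting is defined for classification only.
#' @return Integer labels: 1-based class indices when
#'   `base_output_dim > 1`, otherwise 0/1.
#' @export
majority_vote <- function(stacked, base_output_dim, task_kind = "multiclass") {
  if (task_kind == "regression")
    err_invalid_config("majority vote is undefined for regression tasks")
  blocks <- block_view(stacked, base_output_dim)
  votes <- vapply(blocks, function(b) {
    if (ncol(b) == 1) as.integer(b[, 1] >= 0.5)
    else max.col(b, ties.method = "first")
  }, integer(nrow(stacked)))
  votes <- matrix(votes, nrow = nrow(stacked))
  apply(votes, 1, function(v) {
    tab <- table(v)
    cands <- as.integer(names(tab)[tab == max(tab)])
    min(cands)                                 # tie -> lowest class index
  })
}

#' Weighted sum of base-model outputs
#'
#' Nonnegative per-block weights are normalized to sum to 1, then the blocks
#' are combined convexly. With uniform weights this equals
#' [average_outputs()] exactly.
#'
#' @param stacked Stacked score matrix.
#' @param weights One nonnegative weight per combination block.
#' @param base_output_dim Columns per combination block.
#' @return Samples x `base_output_dim` score matrix.
#' @export
weighted_sum <- function(stacked, weights, base_output_dim) {
  blocks <- block_view(stacked, base_output_dim)
  if (length(weights) != length(blocks))
    err_invalid_input("expected %d weights (one per block), received %d",
                      length(blocks), length(weights))
  if (any(weights < 0)) err_invalid_input("weights must be nonnegative")
  if (sum(weights) == 0) err_invalid_input("weights must not all be zero")
  w <- weights / sum(weights)
  Reduce(`+`, Map(function(b, wi) b * wi, blocks, w))
}
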