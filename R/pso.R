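# Particle swarm refinement of the base models. Each particle is one
# per-combination network; its position is the flat parameter vector. Moves
# follow the canonical update rules
#   v(t+1) = w*v(t) + c1*r1*(p_i - x) + c2*r2*(p_g - x)
#   x(t+1) = x(t) + v(t+1)
# and every move is followed by a short re-training phase; fitness is the
# validation-set task loss of the re-trained network, so personal/global
# bests always refer to evaluated (post-retraining) parameters.

#' Configure the swarm
#'
#' Defaults follow the framework's reference settings: inertia 0.7,
#' cognitive and social coefficients 1.5, 10 iterations, with a short
#' 5-epoch re-training after every move.
#'
#' @param inertia Inertia weight `w` (>= 0).
#' @param cognitive,social Coefficients `c1`, `c2` (>= 0).
#' @param iterations Number of swarm iterations (>= 0).
#' @param retrain_epochs Gradient-descent epochs run after each position
#'   update, using the moved position as initialization.
#' @param velocity_clamp Optional bound: velocities are clipped to
#'   `+/- velocity_clamp` after each update.
#' @param convergence_tol Optional early-stopping tolerance: stop once the
#'   global-best improvement stays below it for 3 consecutive iterations.
#'   `NULL` (default) disables early stopping.
#' @param r_mode `"per-dimension"` draws the stochastic factors `r1`, `r2`
#'   independently per coordinate (standard practice); `"scalar"` draws one
#'   pair per particle per iteration.
#' @param seed Integer seed for all swarm randomness.
#' @return Object of class `swarm_config`.
#' @export
swarm_config <- function(inertia = 0.7, cognitive = 1.5, social = 1.5,
                         iterations = 10L, retrain_epochs = 5L,
                         velocity_clamp = NULL, convergence_tol = NULL,
                         r_mode = c("per-dimension", "scalar"), seed = 1L) {
  r_mode <- match.arg(r_mode)
  if (inertia < 0 || cognitive < 0 || social < 0)
    err_invalid_config("inertia, cognitive and social coefficients must be >= 0")
  if (iterations < 0) err_invalid_config("iterations must be >= 0")
  structure(list(inertia = inertia, cognitive = cognitive, social = social,
                 iterations = as.integer(iterations),
                 retrain_epochs = as.integer(retrain_epochs),
                 velocity_clamp = velocity_clamp,
                 convergence_tol = convergence_tol,
                 r_mode = r_mode, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Velocity update rule
#'
#' Elementwise evaluation of
#' `w*v + c1*r1*(p_i - x) + c2*r2*(p_g - x)`, optionally clamped to
#' `+/- velocity_clamp`.
#'
#' @param v Current velocity vector.
#' @param x Current position vector.
#' @param p_i Personal-best position.
#' @param p_g Global-best position.
#' @param config A [swarm_config()].
#' @param r1,r2 Stochastic factors in `[0, 1]`, scalars or vectors of
#'   `length(v)`.
#' @return The new velocity vector.
#' @export
velocity_update <- function(v, x, p_i, p_g, config, r1, r2) {
  n <- length(v)
  if (length(x) != n || length(p_i) != n || length(p_g) != n)
    err_invalid_input("velocity/position/best vectors must share one length")
  if (!all(length(r1) %in% c(1L, n)) || !all(length(r2) %in% c(1L, n)))
    err_invalid_input("r1 and r2 must be scalars or vectors of length %d", n)
  v_new <- config$inertia * v +
    config$cognitive * r1 * (p_i - x) +
    config$social * r2 * (p_g - x)
  if (!is.null(config$velocity_clamp))
    v_new <- pmin(pmax(v_new, -config$velocity_clamp), config$velocity_clamp)
  v_new
}

#' Position update rule
#'
#' `x(t+1) = x(t) + v(t+1)`, elementwise.
#'
#' @param x Position vector.
#' @param v_new Updated velocity vector.
#' @return The new position vector.
#' @export
position_update <- function(x, v_new) {
  if (length(x) != length(v_new))
    err_invalid_input("position and velocity must share one length")
  x + v_new
}

#' Validation fitness of a model
#'
#' The task loss (lower is better) of the model's current parameters on a
#' held-out validation set; a pure function of (parameters, data).
#'
#' @param model A `pair_model`.
#' @param inputs Validation input matrix (nonempty).
#' @param labels Validation labels.
#' @param task A [task_spec()].
#' @return Scalar loss.
#' @export
evaluate_fitness <- function(model, inputs, labels, task) {
  inputs <- as.matrix(inputs)
  if (nrow(inputs) == 0) err_invalid_config("validation set is empty")
  Y <- labels_to_matrix(labels, task)
  P <- predict(model, inputs)
  nn_loss(P, Y, task$loss)
}

#' Run the particle swarm over all base models
#'
#' Preliminarily trained models become particles: their flat parameter
#' vectors are the initial positions (velocities start at zero unless
#' supplied), initial fitness seeds the personal and global bests. Each
#' iteration then, per particle: draw `r1`, `r2`, update velocity and
#' position, load the moved position into the network, re-train it for
#' `retrain_epochs`, take the post-retraining parameters as the particle's
#' evaluated position, score it on the validation set, and update the
#' personal and global bests.
#'
#' @param models List of preliminarily trained `pair_model`s, one per
#'   combination (distinct ordinals required when combinations are bound).
#' @param train_inputs,validation_inputs Lists of input matrices, one per
#'   model (each model sees its own combined features; rows are shared
#'   samples).
#' @param train_labels,validation_labels Labels shared by all models.
#' @param task A [task_spec()].
#' @param config A [swarm_config()].
#' @param initial_velocities Optional list of starting velocity vectors.
#' @return Object of class `swarm_result`: `models` (each carrying its
#'   personal-best parameters), `global_best_position`,
#'   `global_best_fitness`, `fitness_history` (global best per iteration,
#'   non-increasing), `initial_fitness`, per-particle `velocities` and
#'   `personal_best_fitness`, and a long-format `records` data frame
#'   (iteration, particle ordinal, fitness, is_personal_best,
#'   is_global_best).
#' @export
run_swarm <- function(models, train_inputs, train_labels,
                      validation_inputs, validation_labels, task, config,
                      initial_velocities = NULL) {
  stopifnot(inherits(task, "task_spec"), inherits(config, "swarm_config"))
  np <- length(models)
  if (np < 1) err_invalid_config("need at least one particle")
  if (length(train_inputs) != np || length(validation_inputs) != np)
    err_invalid_config("one train and one validation input matrix required per particle (got %d/%d for %d particles)",
                       length(train_inputs), length(validation_inputs), np)
  ords <- vapply(models, function(m)
    if (is.null(m$combination)) NA_integer_ else as.integer(m$combination$ordinal),
    integer(1))
  if (!anyNA(ords) && anyDuplicated(ords))
    err_invalid_config("models must cover distinct combinations (duplicate ordinal %d)",
                       ords[duplicated(ords)][1])

  positions <- lapply(models, flatten_params)
  velocities <- initial_velocities %||% lapply(positions, function(p) numeric(length(p)))
  fitness <- vapply(seq_len(np), function(i)
    evaluate_fitness(models[[i]], validation_inputs[[i]], validation_labels, task),
    numeric(1))
  if (any(!is.finite(fitness)))
    err_numerical("non-finite initial fitness for particle %d",
                  which(!is.finite(fitness))[1])
  pbest_pos <- positions
  pbest_fit <- fitness
  g <- which.min(pbest_fit)
  gbest_pos <- pbest_pos[[g]]
  gbest_fit <- pbest_fit[g]
  initial_fitness <- fitness

  history <- numeric(0)
  records <- list()
  stall <- 0L

  with_seed(config$seed, {
    for (t in seq_len(config$iterations)) {
      prev_gbest <- gbest_fit
      for (i in seq_len(np)) {
        d <- length(positions[[i]])
        if (config$r_mode == "per-dimension") {
          r1 <- stats::runif(d); r2 <- stats::runif(d)
        } else {
          r1 <- stats::runif(1); r2 <- stats::runif(1)
        }
        velocities[[i]] <- velocity_update(velocities[[i]], positions[[i]],
                                           pbest_pos[[i]], gbest_pos,
                                           config, r1, r2)
        moved <- position_update(positions[[i]], velocities[[i]])
        models[[i]] <- set_model_params(models[[i]], moved)
        if (config$retrain_epochs > 0) {
          models[[i]] <- train_model(models[[i]], train_inputs[[i]],
                                     train_labels, task,
                                     epochs_override = config$retrain_epochs,
                                     seed = derive_seed(config$seed, t, i))
        }
        positions[[i]] <- flatten_params(models[[i]])   # evaluated position
        f <- evaluate_fitness(models[[i]], validation_inputs[[i]],
                              validation_labels, task)
        if (!is.finite(f))
          err_numerical("non-finite fitness for particle %d at iteration %d", i, t)
        is_pb <- f < pbest_fit[i]
        if (is_pb) {
          pbest_fit[i] <- f
          pbest_pos[[i]] <- positions[[i]]
        }
        is_gb <- f < gbest_fit
        if (is_gb) {
          gbest_fit <- f
          gbest_pos <- positions[[i]]
        }
        records[[length(records) + 1L]] <- data.frame(
          iteration = t,
          particle = if (is.na(ords[i])) i - 1L else ords[i],
          fitness = f,
          is_personal_best = is_pb, is_global_best = is_gb)
      }
      history <- c(history, gbest_fit)
      if (!is.null(config$convergence_tol)) {
        stall <- if (prev_gbest - gbest_fit < config$convergence_tol)
          stall + 1L else 0L
        if (stall >= 3L) break
      }
    }
  })

  # refined models carry their personal-best (i.e. best evaluated) parameters
  for (i in seq_len(np))
    models[[i]] <- set_model_params(models[[i]], pbest_pos[[i]])

  structure(list(models = models,
                 global_best_position = gbest_pos,
                 global_best_fitness = gbest_fit,
                 fitness_history = history,
                 initial_fitness = initial_fitness,
                 personal_best_fitness = pbest_fit,
                 velocities = velocities,
                 records = if (length(records)) do.call(rbind, records)
                           else data.frame(iteration = integer(0),
                                           particle = integer(0),
                                           fitness = numeric(0),
                                           is_personal_best = logical(0),
                                           is_global_best = logical(0))),
            class = "swarm_result")
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("<swarm_result> %d particles, %d iterations; global best fitness %.6g (from %.6g)\n",
              length(x$models), length(x$fitness_history),
              x$global_best_fitness, min(x$initial_fitness)))
  invisible(x)
}

#' Write the swarm fitness history as CSV
#'
#' Columns: iteration, particle ordinal, fitness, is_personal_best,
#' is_global_best.
#'
#' @param swarm_result A [run_swarm()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fitness_history <- function(swarm_result, path) {
  utils::write.csv(swarm_result$records, path, row.names = FALSE)
  invisible(path)
}
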