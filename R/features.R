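# Feature standardization: binary feature matrices -> similarity profiles,
# enumeration of feature-type pairs, and combined pair-input construction.

#' Create a feature set
#'
#' Bundles one entity set's binary feature matrices, one matrix per feature
#' type. Rows follow `entity_ids` order; every entry must be 0 or 1.
#'
#' @param entity_ids Character vector of unique entity identifiers.
#' @param matrices Named list of binary matrices (entities x indicators), one
#'   per feature type. Row counts must equal `length(entity_ids)`.
#' @return An object of class `feature_set` with elements `entity_ids` and
#'   `matrices`.
#' @examples
#' fs <- feature_set(c("d1", "d2"),
#'                   list(targets = matrix(c(1, 0, 1, 1), 2, 2)))
#' @export
feature_set <- function(entity_ids, matrices) {
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids))
    err_invalid_input("duplicate entity id: '%s'",
                      entity_ids[duplicated(entity_ids)][1])
  if (!is.list(matrices) || is.null(names(matrices)) ||
      any(names(matrices) == ""))
    err_invalid_input("matrices must be a fully named list (one per feature type)")
  if (anyDuplicated(names(matrices)))
    err_invalid_input("feature-type names must be unique within a set")
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    if (!is.matrix(m)) matrices[[nm]] <- m <- as.matrix(m)
    if (nrow(m) != length(entity_ids))
      err_invalid_input("feature type '%s': %d rows but %d entity ids",
                        nm, nrow(m), length(entity_ids))
    check_binary(m, sprintf("feature type '%s'", nm))
    rownames(matrices[[nm]]) <- entity_ids
  }
  structure(list(entity_ids = entity_ids, matrices = matrices),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d entities, %d feature types\n",
              length(x$entity_ids), length(x$matrices)))
  for (nm in names(x$matrices))
    cat(sprintf("  %s: %d indicators, density %.3f\n", nm,
                ncol(x$matrices[[nm]]), mean(x$matrices[[nm]])))
  invisible(x)
}

check_binary <- function(m, what) {
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    err_invalid_input("%s: non-binary entry %s at row %d, column %d",
                      what, format(m[bad[1, 1], bad[1, 2]]),
                      bad[1, 1], bad[1, 2])
  invisible(TRUE)
}

#' Jaccard similarity matrix of a binary feature matrix
#'
#' For entities `i`, `j` with support sets `S_i`, `S_j` (indices of their 1
#' entries), the similarity is `|S_i n S_j| / |S_i u S_j|`. Two entities with
#' empty supports get similarity 0: an entity with no recorded features is
#' not evidence of similarity, so the diagonal entry of an all-zero entity
#' is 0 while every nonzero entity has diagonal 1.
#'
#' @param binary_matrix Binary matrix, entities x feature indicators.
#' @param feature_type Optional name attached to the resulting profile.
#' @return An object of class `similarity_profile`: a list with
#'   `feature_type` and the square symmetric `matrix` (values in `[0, 1]`,
#'   entity ids as dimnames when present on the input).
#' @examples
#' m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' jaccard_similarity_matrix(m)$matrix  # off-diagonal 1/3
#' @export
jaccard_similarity_matrix <- function(binary_matrix, feature_type = NA_character_) {
  if (!is.matrix(binary_matrix)) binary_matrix <- as.matrix(binary_matrix)
  if (nrow(binary_matrix) < 1) err_invalid_input("need at least one row")
  storage.mode(binary_matrix) <- "double"
  check_binary(binary_matrix, "binary_matrix")
  inter <- tcrossprod(binary_matrix)
  sizes <- rowSums(binary_matrix)
  un <- outer(sizes, sizes, `+`) - inter
  sim <- ifelse(un == 0, 0, inter / un)
  ids <- rownames(binary_matrix)
  if (!is.null(ids)) dimnames(sim) <- list(ids, ids)
  structure(list(feature_type = feature_type, matrix = sim),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("<similarity_profile> feature type '%s', %d x %d\n",
              x$feature_type, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# Memoised variant; the cache key is a content hash of the input matrix, so
# recomputation is skipped when the same feature matrix is standardized again
# (as happens when pipeline stages re-derive their inputs).
.sim_cache <- new.env(parent = emptyenv())

cached_jaccard <- function(binary_matrix, feature_type = NA_character_) {
  key <- rlang::hash(list(binary_matrix, feature_type))
  hit <- .sim_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- jaccard_similarity_matrix(binary_matrix, feature_type)
  .sim_cache[[key]] <- res
  res
}

#' Standardize every feature type of a feature set
#'
#' @param fs A [feature_set()].
#' @return Named list of `similarity_profile` objects, one per feature type.
#' @export
standardize_features <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  profiles <- lapply(names(fs$matrices), function(nm)
    cached_jaccard(fs$matrices[[nm]], nm))
  names(profiles) <- names(fs$matrices)
  profiles
}

#' Project similarity profiles onto principal components
#'
#' Optional alternative representation: instead of using raw similarity rows,
#' entities are represented by their scores on the leading principal
#' components of the (column-centred) similarity matrix. Component signs are
#' fixed so that each loading vector's largest-magnitude element is positive,
#' making the output deterministic.
#'
#' @param similarity_profile A `similarity_profile`.
#' @param n_components Number of components to keep (`>= 1`, at most the
#'   number of entities).
#' @param seed Unused (the decomposition is exact); kept so all
#'   representation builders share one signature.
#' @return List with `scores` (entities x `n_components`), `loadings`, and
#'   `explained_variance_ratio`.
#' @export
pca_reduce <- function(similarity_profile, n_components, seed = NULL) {
  stopifnot(inherits(similarity_profile, "similarity_profile"))
  m <- similarity_profile$matrix
  if (n_components < 1) err_invalid_config("n_components must be >= 1")
  if (n_components > nrow(m))
    err_invalid_config("n_components (%d) exceeds number of entities (%d)",
                       n_components, nrow(m))
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  load <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                       # deterministic sign convention
    piv <- which.max(abs(load[, j]))
    if (load[piv, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = load,
       explained_variance_ratio = evr[seq_len(k)])
}

#' Enumerate all feature-type combinations of two entity sets
#'
#' Every feature type of set A is paired with every feature type of set B,
#' giving `n_types_a * n_types_b` combinations in row-major order (A-types
#' outer, B-types inner) with 0-based contiguous ordinals.
#'
#' @param n_types_a,n_types_b Feature-type counts (or character vectors of
#'   type names, whose lengths are used).
#' @return Data frame of class `pair_combinations` with columns `ordinal`,
#'   `index_a`, `index_b` (1-based type indices) and, when names were given,
#'   `type_a`, `type_b`.
#' @examples
#' nrow(enumerate_feature_pairs(5, 5))  # 25
#' @export
enumerate_feature_pairs <- function(n_types_a, n_types_b) {
  names_a <- names_b <- NULL
  if (is.character(n_types_a)) { names_a <- n_types_a; n_types_a <- length(n_types_a) }
  if (is.character(n_types_b)) { names_b <- n_types_b; n_types_b <- length(n_types_b) }
  if (length(n_types_a) != 1 || length(n_types_b) != 1 ||
      n_types_a < 1 || n_types_b < 1 ||
      n_types_a != round(n_types_a) || n_types_b != round(n_types_b))
    err_invalid_config("feature-type counts must be positive integers")
  idx <- expand.grid(index_b = seq_len(n_types_b), index_a = seq_len(n_types_a))
  out <- data.frame(ordinal = seq_len(nrow(idx)) - 1L,
                    index_a = idx$index_a, index_b = idx$index_b)
  if (!is.null(names_a)) out$type_a <- names_a[out$index_a]
  if (!is.null(names_b)) out$type_b <- names_b[out$index_b]
  class(out) <- c("pair_combinations", "data.frame")
  out
}

profile_row <- function(profiles, index, entity_index) {
  if (is.character(index)) {
    if (!index %in% names(profiles))
      err_invalid_config("no similarity profile for feature type '%s'", index)
    p <- profiles[[index]]
  } else {
    if (index < 1 || index > length(profiles))
      err_invalid_config("no similarity profile for feature type #%d", index)
    p <- profiles[[index]]
  }
  p$matrix[entity_index, ]
}

#' Build the combined input vector for one entity pair
#'
#' Concatenates entity A's similarity-profile row for the combination's
#' A-side feature type with entity B's row for the B-side type. The result
#' has length `k + l` (the two entity-set sizes; `2k` for a same-set task).
#'
#' @param entity_a_index,entity_b_index Row indices into the two profiles.
#' @param combination One row of [enumerate_feature_pairs()] output (or any
#'   list with `index_a`/`index_b`).
#' @param profiles_a,profiles_b Named or positional lists of
#'   `similarity_profile` objects.
#' @return Numeric vector of length `k + l`.
#' @export
build_pair_input <- function(entity_a_index, entity_b_index, combination,
                             profiles_a, profiles_b) {
  ia <- combination$index_a %||% combination[["type_a"]]
  ib <- combination$index_b %||% combination[["type_b"]]
  c(profile_row(profiles_a, ia, entity_a_index),
    profile_row(profiles_b, ib, entity_b_index))
}

#' Build the combined input matrix for many entity pairs
#'
#' Vectorised form of [build_pair_input()]: one row per pair.
#'
#' @param idx_a,idx_b Integer vectors of entity row indices (same length).
#' @param combination As in [build_pair_input()].
#' @param profiles_a,profiles_b Lists of `similarity_profile` objects.
#' @return Numeric matrix, `length(idx_a)` x `(k + l)`.
#' @export
build_pair_inputs <- function(idx_a, idx_b, combination, profiles_a, profiles_b) {
  if (length(idx_a) != length(idx_b))
    err_invalid_input("idx_a and idx_b must have the same length")
  ia <- combination$index_a
  ib <- combination$index_b
  if (ia < 1 || ia > length(profiles_a))
    err_invalid_config("no similarity profile for feature type #%d of set A", ia)
  if (ib < 1 || ib > length(profiles_b))
    err_invalid_config("no similarity profile for feature type #%d of set B", ib)
  cbind(profiles_a[[ia]]$matrix[idx_a, , drop = FALSE],
        profiles_b[[ib]]$matrix[idx_b, , drop = FALSE])
}

#' Canonically order same-set entity pairs
#'
#' For a same-set task (e.g. drug-drug interaction) the unordered pair
#' `(a_i, a_j)` is presented once, with the lower entity index first.
#'
#' @param idx_a,idx_b Integer vectors of entity indices.
#' @return List with reordered `idx_a`, `idx_b` (`idx_a <= idx_b` elementwise).
#' @export
canonicalize_pairs <- function(idx_a, idx_b) {
  swap <- idx_b < idx_a
  list(idx_a = ifelse(swap, idx_b, idx_a),
       idx_b = ifelse(swap, idx_a, idx_b))
}
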