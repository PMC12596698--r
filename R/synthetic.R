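# Planted-signal synthetic tasks. Entities carry latent group memberships;
# informative feature types have group-biased indicator columns, so Jaccard
# rows of informative types separate the groups. Pair labels depend on
# whether the two entities' groups agree, expressed through similarity
# products to designated anchor entities — exactly the structure the
# similarity-profile representation is meant to capture.

#' Configure a synthetic pairwise-prediction task
#'
#' Defaults describe the package's reference study conditions: two entity
#' sets of 60, three feature types each (3 x 3 = 9 combinations), a single
#' informative type pair (1, 1), and 5% label noise.
#'
#' @param k,l Entity counts for sets A and B.
#' @param n_types_a,n_types_b Feature-type counts.
#' @param feature_dims Indicator columns per type (recycled across types).
#' @param sparsity Marginal probability of a 1 entry.
#' @param informative_pairs List of `c(type_a, type_b)` combinations that
#'   carry the label signal.
#' @param signal_strength Slope of the logistic link from planted-pair
#'   similarity score to label probability (0 = pure noise).
#' @param label_noise Probability of flipping each final label.
#' @param task_kind `"binary"` or `"multiclass"`.
#' @param n_classes Number of classes (multiclass only).
#' @param n_groups Number of latent entity groups.
#' @param group_bias In `[0, 1)`: how strongly informative columns
#'   concentrate within their group (0 = no signal in the features).
#' @param n_pairs Number of labeled entity pairs to sample.
#' @param same_set If `TRUE`, set B is an alias of set A (a same-set task
#'   such as drug-drug interaction) and pairs are distinct unordered pairs.
#' @param seed Master seed; all substreams derive from it.
#' @return Object of class `synthetic_task_config`.
#' @export
synthetic_task_config <- function(k = 60L, l = 60L, n_types_a = 3L,
                                  n_types_b = 3L, feature_dims = 40L,
                                  sparsity = 0.15,
                                  informative_pairs = list(c(1L, 1L)),
                                  signal_strength = 10, label_noise = 0.05,
                                  task_kind = c("binary", "multiclass"),
                                  n_classes = 2L, n_groups = 2L,
                                  group_bias = 0.8, n_pairs = 500L,
                                  same_set = FALSE, seed = 1L) {
  task_kind <- match.arg(task_kind)
  if (k < 1 || n_types_a < 1 || (!same_set && (l < 1 || n_types_b < 1)))
    err_invalid_config("entity and feature-type counts must be >= 1")
  if (sparsity < 0 || sparsity > 1 || label_noise < 0 || label_noise > 1)
    err_invalid_config("sparsity and label_noise must lie in [0, 1]")
  if (group_bias < 0 || group_bias >= 1)
    err_invalid_config("group_bias must lie in [0, 1)")
  if (same_set) { l <- k; n_types_b <- n_types_a }
  for (ip in informative_pairs)
    if (ip[1] < 1 || ip[1] > n_types_a || ip[2] < 1 || ip[2] > n_types_b)
      err_invalid_config("informative pair (%d, %d) references an unknown feature type",
                         ip[1], ip[2])
  structure(list(k = as.integer(k), l = as.integer(l),
                 n_types_a = as.integer(n_types_a),
                 n_types_b = as.integer(n_types_b),
                 feature_dims = as.integer(feature_dims),
                 sparsity = sparsity,
                 informative_pairs = informative_pairs,
                 signal_strength = signal_strength,
                 label_noise = label_noise, task_kind = task_kind,
                 n_classes = as.integer(n_classes),
                 n_groups = as.integer(n_groups), group_bias = group_bias,
                 n_pairs = as.integer(n_pairs), same_set = same_set,
                 seed = as.integer(seed)),
            class = "synthetic_task_config")
}

# Bernoulli probabilities for an informative column preferring group g:
# within-group probability is inflated, between-group deflated, preserving
# the marginal `sparsity` (groups assumed near-balanced). Degenerate
# sparsities 0 and 1 stay exact.
biased_probs <- function(sparsity, n_groups, group_bias) {
  p_in <- min(1, sparsity * (1 + group_bias * (n_groups - 1)))
  p_out <- if (n_groups == 1) p_in else
    max(0, (sparsity * n_groups - p_in) / (n_groups - 1))
  c(p_in = p_in, p_out = p_out)
}

generate_one_set <- function(config, n_entities, n_types, informative_types,
                             prefix, groups, seed) {
  mats <- list()
  for (tp in seq_len(n_types)) {
    dim_tp <- config$feature_dims[((tp - 1) %% length(config$feature_dims)) + 1]
    m <- with_seed(derive_seed(seed, tp), {
      if (tp %in% informative_types) {
        pr <- biased_probs(config$sparsity, config$n_groups, config$group_bias)
        col_groups <- rep_len(seq_len(config$n_groups), dim_tp)
        probs <- ifelse(outer(groups, col_groups, `==`), pr["p_in"], pr["p_out"])
        matrix(as.double(stats::runif(n_entities * dim_tp) < probs),
               n_entities, dim_tp)
      } else {
        matrix(stats::rbinom(n_entities * dim_tp, 1, config$sparsity),
               n_entities, dim_tp)
      }
    })
    mats[[sprintf("%s_type%d", prefix, tp)]] <- m
  }
  fs <- feature_set(sprintf("%s%03d", prefix, seq_len(n_entities)), mats)
  attr(fs, "groups") <- groups
  fs
}

#' Generate the synthetic feature sets
#'
#' Entities are partitioned into `n_groups` latent groups (round-robin).
#' Feature types appearing in an informative pair get group-biased columns
#' so that within-group Jaccard similarity exceeds between-group similarity;
#' other types are i.i.d. Bernoulli(`sparsity`).
#'
#' @param config A [synthetic_task_config()].
#' @return List with `set_a` and `set_b` ([feature_set()] objects carrying a
#'   `groups` attribute; `set_b` is `set_a` for same-set tasks).
#' @export
generate_feature_sets <- function(config) {
  stopifnot(inherits(config, "synthetic_task_config"))
  inf_a <- unique(vapply(config$informative_pairs, `[`, integer(1), 1))
  inf_b <- unique(vapply(config$informative_pairs, `[`, integer(1), 2))
  groups_a <- rep_len(seq_len(config$n_groups), config$k)
  set_a <- generate_one_set(config, config$k, config$n_types_a, inf_a, "a",
                            groups_a, derive_seed(config$seed, 101))
  if (config$same_set) return(list(set_a = set_a, set_b = set_a))
  groups_b <- rep_len(seq_len(config$n_groups), config$l)
  set_b <- generate_one_set(config, config$l, config$n_types_b, inf_b, "b",
                            groups_b, derive_seed(config$seed, 202))
  list(set_a = set_a, set_b = set_b)
}

# Planted similarity score for pairs (i, j): for each informative type pair
# and each latent group g, the product of i's mean similarity to set A's
# group-g members and j's mean similarity to set B's group-g members,
# summed over groups. High exactly when both entities resemble the same
# group. The score has rank `n_groups` as a function of entity identity, so
# recovering it without the informative similarity rows requires learning
# n_groups values per entity from the few labeled pairs that entity appears
# in, while the informative-pair model reads it off its own input.
planted_scores <- function(feature_sets, config, idx_a, idx_b) {
  ga <- attr(feature_sets$set_a, "groups")
  gb <- attr(feature_sets$set_b, "groups")
  group_mean_sim <- function(S, groups) {
    vapply(seq_len(config$n_groups), function(g)
      rowMeans(S[, groups == g, drop = FALSE]), numeric(nrow(S)))
  }
  score <- numeric(length(idx_a))
  for (ip in config$informative_pairs) {
    Sa <- cached_jaccard(feature_sets$set_a$matrices[[ip[1]]],
                         names(feature_sets$set_a$matrices)[ip[1]])$matrix
    Sb <- cached_jaccard(feature_sets$set_b$matrices[[ip[2]]],
                         names(feature_sets$set_b$matrices)[ip[2]])$matrix
    Ga <- group_mean_sim(Sa, ga)
    Gb <- group_mean_sim(Sb, gb)
    score <- score + rowSums(Ga[idx_a, , drop = FALSE] *
                             Gb[idx_b, , drop = FALSE])
  }
  score
}

#' Generate labeled entity pairs
#'
#' Pairs are sampled uniformly without replacement (unordered distinct pairs
#' for same-set tasks). The positive-label probability is a logistic
#' function of the standardized planted similarity score scaled by
#' `signal_strength`; each label is then flipped with probability
#' `label_noise`. For multiclass tasks the class is determined by the two
#' entities' latent groups, with `label_noise` replacing a label by a
#' uniform random class.
#'
#' @param feature_sets A [generate_feature_sets()] result.
#' @param config The matching [synthetic_task_config()].
#' @return Data frame with columns `id_a`, `id_b`, `idx_a`, `idx_b`,
#'   `label`, carrying the class balance as attribute `class_balance`.
#' @export
generate_pair_labels <- function(feature_sets, config) {
  stopifnot(inherits(config, "synthetic_task_config"))
  with_seed(derive_seed(config$seed, 303), {
    if (config$same_set) {
      all_pairs <- utils::combn(config$k, 2)
      take <- sample.int(ncol(all_pairs), min(config$n_pairs, ncol(all_pairs)))
      idx_a <- all_pairs[1, take]; idx_b <- all_pairs[2, take]
    } else {
      cells <- sample.int(config$k * config$l,
                          min(config$n_pairs, config$k * config$l))
      idx_a <- ((cells - 1) %% config$k) + 1L
      idx_b <- ((cells - 1) %/% config$k) + 1L
    }
    np <- length(idx_a)

    if (config$task_kind == "binary") {
      score <- planted_scores(feature_sets, config, idx_a, idx_b)
      z <- score - mean(score)
      sdz <- stats::sd(z)
      if (is.finite(sdz) && sdz > 0) z <- z / sdz
      prob <- stats::plogis(config$signal_strength * z)
      label <- as.integer(stats::runif(np) < prob)
      flip <- stats::runif(np) < config$label_noise
      label[flip] <- 1L - label[flip]
    } else {
      ga <- attr(feature_sets$set_a, "groups")[idx_a]
      gb <- attr(feature_sets$set_b, "groups")[idx_b]
      label <- ((ga + gb) %% config$n_classes) + 1L
      resample <- stats::runif(np) < config$label_noise
      label[resample] <- sample.int(config$n_classes, sum(resample),
                                    replace = TRUE)
    }

    out <- data.frame(id_a = feature_sets$set_a$entity_ids[idx_a],
                      id_b = feature_sets$set_b$entity_ids[idx_b],
                      idx_a = idx_a, idx_b = idx_b, label = label,
                      stringsAsFactors = FALSE)
    attr(out, "class_balance") <- table(label) / np
    out
  })
}

#' Generate a complete synthetic task
#'
#' Convenience wrapper: feature sets plus labeled pairs, optionally written
#' to `outdir` in the package's TSV formats (the same files the readers
#' consume).
#'
#' @param config A [synthetic_task_config()].
#' @param outdir Optional directory for TSV output.
#' @return List with `feature_sets`, `pairs` and `config`.
#' @export
simulate_task <- function(config, outdir = NULL) {
  feature_sets <- generate_feature_sets(config)
  pairs <- generate_pair_labels(feature_sets, config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(feature_sets$set_a$matrices))
      write_feature_matrix(feature_sets$set_a$matrices[[nm]],
                           feature_sets$set_a$entity_ids,
                           file.path(outdir, paste0("features_", nm, ".tsv")))
    if (!config$same_set)
      for (nm in names(feature_sets$set_b$matrices))
        write_feature_matrix(feature_sets$set_b$matrices[[nm]],
                             feature_sets$set_b$entity_ids,
                             file.path(outdir, paste0("features_", nm, ".tsv")))
    write_pair_labels(pairs, file.path(outdir, "pairs.tsv"))
  }
  list(feature_sets = feature_sets, pairs = pairs, config = config)
}
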