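# Delimited-text readers and writers plus the run configuration.
#
# Feature matrices: TSV/CSV, first column the entity ID, header row of
# indicator names, cells 0/1. Pair files: one pair per line, tab-separated
# id_a, id_b, label (integer class, 0/1, comma-joined indicator list for
# multilabel, or a real for regression).
#
# Parsing is done line-by-line on purpose: format errors must name the
# offending line/row and column, which whole-file readers cannot report.

split_fields <- function(line, sep) strsplit(line, sep, fixed = TRUE)[[1]]

detect_sep <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read a binary feature matrix from delimited text
#'
#' @param path TSV (default) or CSV file: header row of indicator names,
#'   first column entity IDs, cells 0/1.
#' @return Binary matrix with entity IDs as rownames, in file order.
#' @export
load_feature_matrix <- function(path) {
  if (!file.exists(path)) err_format("file not found: %s", path)
  sep <- detect_sep(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) err_format("%s: need a header and at least one entity row", path)
  header <- split_fields(lines[1], sep)
  ncol_expected <- length(header)
  ids <- character(length(lines) - 1)
  m <- matrix(0, length(lines) - 1, ncol_expected - 1)
  for (i in seq_along(lines)[-1]) {
    f <- split_fields(lines[i], sep)
    if (length(f) != ncol_expected)
      err_format("%s: line %d has %d fields, expected %d", path, i,
                 length(f), ncol_expected)
    ids[i - 1] <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(vals) | !(vals %in% c(0, 1)))
    if (length(bad) > 0)
      err_format("%s: line %d, column '%s': non-binary cell '%s'", path, i,
                 header[bad[1] + 1], f[bad[1] + 1])
    m[i - 1, ] <- vals
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    err_format("%s: duplicate entity id '%s'", path, dup[1])
  dimnames(m) <- list(ids, header[-1])
  m
}

#' Write a binary feature matrix as TSV
#'
#' @param matrix Binary matrix.
#' @param entity_ids Entity identifiers (one per row).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, entity_ids, path) {
  cols <- colnames(matrix) %||% sprintf("f%d", seq_len(ncol(matrix)))
  lines <- c(paste(c("entity_id", cols), collapse = "\t"),
             vapply(seq_len(nrow(matrix)), function(i)
               paste(c(entity_ids[i], format(matrix[i, ], trim = TRUE)),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Export a similarity profile as TSV
#'
#' Entity IDs appear on both axes.
#'
#' @param profile A `similarity_profile`.
#' @param path Output path.
#' @param ids Entity IDs (defaults to the profile's dimnames).
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(profile, path, ids = NULL) {
  m <- profile$matrix
  ids <- ids %||% rownames(m) %||% sprintf("e%d", seq_len(nrow(m)))
  lines <- c(paste(c("entity_id", ids), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(ids[i], format(m[i, ], trim = TRUE, digits = 15)),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read labeled entity pairs
#'
#' Tab-separated, one pair per line: `id_a`, `id_b`, `label`. Multiclass
#' labels are integers, binary labels 0/1, multilabel labels comma-joined
#' 0/1 indicator lists, regression labels reals. IDs are resolved against
#' the feature sets' entity orders; in strict mode an unresolvable ID is an
#' error, in lenient mode such pairs are dropped with a warning tally.
#'
#' @param path Pair file.
#' @param entity_ids_a,entity_ids_b ID vectors of the two entity sets.
#' @param task_kind Label interpretation.
#' @param strict Fail on unresolvable IDs (default) or drop them?
#' @return Data frame `id_a`, `id_b`, `idx_a`, `idx_b`, `label` (for
#'   multilabel, `label` is a 0/1 matrix column-bound as
#'   `label.1 ... label.L`).
#' @export
load_pair_labels <- function(path, entity_ids_a, entity_ids_b,
                             task_kind = "binary", strict = TRUE) {
  if (!file.exists(path)) err_format("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && startsWith(lines[1], "id_a\t"))
    lines <- lines[-1]
  if (length(lines) == 0) err_invalid_input("%s: no pairs", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3))
    err_format("%s: line %d has %d fields, expected 3 (id_a, id_b, label)",
               path, which(nf != 3)[1], nf[nf != 3][1])
  id_a <- vapply(parts, `[`, character(1), 1)
  id_b <- vapply(parts, `[`, character(1), 2)
  lab <- vapply(parts, `[`, character(1), 3)
  idx_a <- match(id_a, entity_ids_a)
  idx_b <- match(id_b, entity_ids_b)
  unresolved <- is.na(idx_a) | is.na(idx_b)
  if (any(unresolved)) {
    if (strict)
      err_invalid_input("%s: %d pair(s) with unresolvable entity ids (first: '%s' / '%s')",
                        path, sum(unresolved), id_a[unresolved][1],
                        id_b[unresolved][1])
    warning(sprintf("%s: dropping %d pair(s) with unresolvable entity ids",
                    path, sum(unresolved)))
    keep <- !unresolved
    id_a <- id_a[keep]; id_b <- id_b[keep]
    idx_a <- idx_a[keep]; idx_b <- idx_b[keep]; lab <- lab[keep]
  }
  if (length(id_a) == 0) err_invalid_input("%s: no resolvable pairs", path)
  out <- data.frame(id_a = id_a, id_b = id_b, idx_a = idx_a, idx_b = idx_b,
                    stringsAsFactors = FALSE)
  if (task_kind == "multilabel") {
    labmat <- do.call(rbind, lapply(strsplit(lab, ",", fixed = TRUE), as.numeric))
    check_binary(labmat, "multilabel labels")
    out$label <- labmat
  } else if (task_kind == "regression") {
    out$label <- as.numeric(lab)
  } else {
    out$label <- as.integer(lab)
  }
  out
}

#' Write labeled pairs as TSV
#'
#' @param pairs Data frame with `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_labels <- function(pairs, path) {
  lab <- pairs$label
  lab_str <- if (is.matrix(lab)) apply(lab, 1, paste, collapse = ",")
             else as.character(lab)
  writeLines(c("id_a\tid_b\tlabel",
               paste(pairs$id_a, pairs$id_b, lab_str, sep = "\t")), path)
  invisible(path)
}

#' Default run configuration
#'
#' Every default matches the framework's reference settings: base networks
#' 512/256/128, stacker 64/32, 50 training epochs, batch size 128, inertia
#' 0.7, cognitive and social coefficients 1.5, 10 swarm iterations. An empty
#' override therefore reproduces the reference configuration.
#'
#' @return Nested named list understood by [run_all()] and the stage
#'   functions.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "psofusion_run",
    task = list(task_kind = "binary", n_classes = 1L, epochs = 50L,
                batch_size = 128L, learning_rate = 1e-3,
                split = c(0.8, 0.1, 0.1)),
    architecture = list(hidden_dims = c(512L, 256L, 128L)),
    stacker = list(hidden_dims = c(64L, 32L), epochs = 50L),
    swarm = list(inertia = 0.7, cognitive = 1.5, social = 1.5,
                 iterations = 10L, retrain_epochs = 5L),
    integration = "stack",
    representation = "similarity",      # or "pca"
    pca_components = NULL,
    augment_symmetric = FALSE,
    stratify_split = TRUE,
    data = NULL,                        # list(features_a=, features_b=, pairs=, same_set=)
    synthetic = NULL,                   # args for synthetic_task_config()
    log_level = "info"
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.null(override[[nm]])) next      # NULL override keeps the default
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration (YAML or JSON)
#'
#' Values in the file override [default_run_config()]; everything else keeps
#' its default. The load -> save -> load round trip is lossless.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Resolved configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) err_format("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), raw)
  if (!is.null(cfg$data)) {
    for (f in c(unlist(cfg$data$features_a), unlist(cfg$data$features_b),
                cfg$data$pairs))
      if (!is.null(f) && !file.exists(f))
        err_invalid_config("configured input file does not exist: %s", f)
  }
  cfg
}

#' Save a run configuration as YAML
#'
#' @param config Configuration list.
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  if (grepl("\\.json$", path))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                null = "null"), path)
  else yaml::write_yaml(config, path)
  invisible(path)
}

psf_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[psofusion] ", fmt), ...))
}
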