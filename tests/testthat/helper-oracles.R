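# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately naive (loops, explicit set operations,
# exhaustive pair enumeration) and share no code with the implementation.

# Jaccard by explicit set operations, one entry at a time.
jaccard_oracle <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- which(m[i, ] == 1)
    sj <- which(m[j, ] == 1)
    u <- length(union(si, sj))
    out[i, j] <- if (u == 0) 0 else length(intersect(si, sj)) / u
  }
  out
}

# AUROC by exhaustive concordance-pair counting (ties count 1/2).
auroc_oracle <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Per-layer parameter-count summation, independent of param_count().
count_oracle <- function(dims) {
  s <- 0
  for (i in seq_len(length(dims) - 1)) s <- s + dims[i] * dims[i + 1] + dims[i + 1]
  s
}

tiny_arch <- function(input = 3L, hidden = c(4L), out = 2L,
                      act = "softmax") {
  network_architecture(input, hidden, out, output_activation = act)
}

# Linearly separable two-class toy set: class from the sign of the first
# coordinate, remaining coordinates noise.
toy_binary_data <- function(n = 40, d = 3, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- as.integer(X[, 1] > 0)
  list(X = X, y = y)
}

# A fast run-all configuration for pipeline smoke tests.
tiny_run_config <- function(seed = 1L, outdir = tempfile("psf_run_")) {
  cfg <- default_run_config()
  cfg$seed <- seed
  cfg$outdir <- outdir
  cfg$synthetic <- list(k = 24L, l = 24L, n_pairs = 120L)
  cfg$task <- list(task_kind = "binary", n_classes = 1L, epochs = 4L,
                   batch_size = 32L)
  cfg$architecture$hidden_dims <- c(8L, 4L)
  cfg$stacker <- list(hidden_dims = c(4L), epochs = 5L)
  cfg$swarm$iterations <- 2L
  cfg$swarm$retrain_epochs <- 1L
  cfg$log_level <- "quiet"
  cfg
}
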