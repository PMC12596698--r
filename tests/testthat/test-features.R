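test_that("Jaccard similarity handles the canonical cases", {
  # identical nonzero rows; disjoint supports; a worked 1/3 example
  m <- rbind(c(1, 1, 0, 0),
             c(1, 1, 0, 0),
             c(0, 0, 1, 1),
             c(1, 0, 1, 0))
  S <- jaccard_similarity_matrix(m)$matrix
  expect_equal(S[1, 2], 1.0)
  expect_equal(S[1, 3], 0.0)
  expect_equal(S[1, 4], 1 / 3)  # intersection {1}, union {1,2,3}
  expect_equal(S, t(S))
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(diag(S), rep(1, 4))
})

test_that("all-zero entities have zero similarity, including to themselves", {
  m <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 1))
  S <- jaccard_similarity_matrix(m)$matrix
  expect_equal(S[1, 2], 0)
  expect_equal(S[1, 1], 0)   # documented convention: empty support => 0
  expect_equal(S[3, 3], 1)
})

test_that("non-binary entries are rejected with the offending cell named", {
  m <- rbind(c(1, 0), c(0, 2))
  expect_error(jaccard_similarity_matrix(m),
               class = "psofusion_invalid_input")
  expect_error(jaccard_similarity_matrix(m), "row 2, column 2")
})

test_that("Jaccard agrees with a set-based oracle and ignores column order", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rbinom(20 * 30, 1, runif(1, 0.1, 0.6)), 20, 30)
    S <- jaccard_similarity_matrix(m)$matrix
    expect_equal(S, jaccard_oracle(m), tolerance = 1e-12)
    perm <- sample(ncol(m))
    expect_equal(jaccard_similarity_matrix(m[, perm])$matrix, S)
  }
})

test_that("PCA reduction is deterministic and matches an eigen oracle", {
  set.seed(3)
  b <- matrix(rbinom(10 * 25, 1, 0.4), 10, 25)
  prof <- jaccard_similarity_matrix(b)
  red <- pca_reduce(prof, 3)
  # oracle: eigendecomposition of the covariance of the centred matrix
  X <- scale(prof$matrix, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  oracle_scores <- X %*% eig$vectors[, 1:3]
  for (j in 1:3)
    expect_equal(abs(red$scores[, j]), abs(oracle_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(red$scores, pca_reduce(prof, 3)$scores)
})

test_that("PCA of a rank-1 profile explains everything; bad configs error", {
  v <- c(1, 1, 0, 0, 1)
  m <- outer(v, v)            # rank-1 symmetric, binary
  prof <- structure(list(feature_type = "t", matrix = outer(seq(0.1, 0.5, 0.1),
                                                            seq(0.1, 0.5, 0.1))),
                    class = "similarity_profile")
  red <- pca_reduce(prof, 1)
  expect_equal(red$explained_variance_ratio[1], 1.0, tolerance = 1e-10)
  expect_error(pca_reduce(prof, 0), class = "psofusion_invalid_config")
  expect_error(pca_reduce(prof, 99), class = "psofusion_invalid_config")
})

test_that("feature-pair enumeration is exhaustive, ordered, and validated", {
  expect_equal(nrow(enumerate_feature_pairs(5, 5)), 25)
  expect_equal(nrow(enumerate_feature_pairs(7, 3)), 21)
  one <- enumerate_feature_pairs(1, 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$ordinal, 0L)

  for (n in 1:10) for (m in c(1, 3, 10)) {
    e <- enumerate_feature_pairs(n, m)
    expect_equal(nrow(e), n * m)
    expect_equal(e$ordinal, seq_len(n * m) - 1L)
    expect_false(anyDuplicated(e[, c("index_a", "index_b")]) > 0)
  }
  # row-major: A-types outer, B-types inner
  e <- enumerate_feature_pairs(2, 3)
  expect_equal(e$index_a, rep(1:2, each = 3))
  expect_equal(e$index_b, rep(1:3, times = 2))
  expect_error(enumerate_feature_pairs(0, 3), class = "psofusion_invalid_config")
})

test_that("pair inputs concatenate the two profile rows exactly", {
  set.seed(5)
  ma <- matrix(rbinom(4 * 6, 1, 0.5), 4, 6)
  mb <- matrix(rbinom(3 * 6, 1, 0.5), 3, 6)
  pa <- list(jaccard_similarity_matrix(ma, "t1"))
  pb <- list(jaccard_similarity_matrix(mb, "T1"))
  combo <- enumerate_feature_pairs(1, 1)[1, ]

  v <- build_pair_input(2, 3, combo, pa, pb)
  expect_length(v, 4 + 3)
  expect_equal(unname(v[1:4]), unname(pa[[1]]$matrix[2, ]))
  expect_equal(unname(v[5:7]), unname(pb[[1]]$matrix[3, ]))
  expect_identical(v, build_pair_input(2, 3, combo, pa, pb))

  # same-set task: both halves from one profile list, length 2k
  v2 <- build_pair_input(1, 1, combo, pa, pa)
  expect_length(v2, 8)
  expect_equal(unname(v2[1:4]), unname(v2[5:8]))

  X <- build_pair_inputs(c(1, 2), c(3, 1), combo, pa, pb)
  expect_equal(dim(X), c(2, 7))
  expect_equal(unname(X[1, ]), unname(build_pair_input(1, 3, combo, pa, pb)))

  expect_error(build_pair_input(1, 1, list(index_a = 2, index_b = 1), pa, pb),
               class = "psofusion_invalid_config")
})

test_that("same-set pairs are canonically ordered by entity index", {
  cn <- canonicalize_pairs(c(5, 2, 3), c(1, 4, 3))
  expect_equal(cn$idx_a, c(1, 2, 3))
  expect_equal(cn$idx_b, c(5, 4, 3))
})

test_that("feature sets validate shape, binarity and name uniqueness", {
  expect_error(feature_set(c("a", "a"), list(t = matrix(0, 2, 2))),
               class = "psofusion_invalid_input")
  expect_error(feature_set(c("a", "b"), list(t = matrix(0, 3, 2))),
               class = "psofusion_invalid_input")
  expect_error(feature_set(c("a", "b"), list(t = matrix(0.5, 2, 2))),
               class = "psofusion_invalid_input")
  fs <- feature_set(c("a", "b"), list(t1 = matrix(1, 2, 2),
                                      t2 = matrix(0, 2, 3)))
  expect_s3_class(fs, "feature_set")
  profs <- standardize_features(fs)
  expect_named(profs, c("t1", "t2"))
  expect_equal(profs$t1$matrix, matrix(1, 2, 2, dimnames = list(c("a", "b"),
                                                                c("a", "b"))))
})
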