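test_that("1-D LDA reproduces the closed-form midpoint threshold", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(0, 0, 2, 2)
  m <- fit_lda(X, y)
  # raw midpoint 0 projects exactly onto the threshold, and ties go to level 0
  mid <- matrix(0, ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(project(m, mid), m$t, tolerance = 1e-12)
  expect_identical(classify(m, mid), 0)
  expect_identical(classify(m, matrix(-1.5, ncol = 1,
                                      dimnames = list(NULL, "f"))), 0)
  expect_identical(classify(m, matrix(1.5, ncol = 1,
                                      dimnames = list(NULL, "f"))), 2)
  # monotonicity along +w
  lds <- project(m, matrix(seq(-2, 2, by = 0.5), ncol = 1,
                           dimnames = list(NULL, "f")))
  expect_true(all(diff(lds) > 0))
  # training data reproduce the fit-time class ordering
  expect_true(all(project(m, X)[y == 2] > m$t))
  expect_true(all(project(m, X)[y == 0] < m$t))
})

test_that("degenerate fits fall back to the majority class with a warning", {
  X <- matrix(c(1, 2, 1, 2, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(0, 0, 0, 0, 2, 2)
  expect_warning(m <- fit_lda(X[c(1, 2, 1, 2, 1, 2), , drop = FALSE], y),
                 class = "ibdq_warning")
  expect_true(m$degenerate)
  expect_identical(classify(m, X[1:2, , drop = FALSE]), c(0, 0))
  expect_error(fit_lda(X[1:3, , drop = FALSE], c(0, 0, 2)),
               class = "ibdq_degenerate_classes")
})

test_that("the estimated discriminant direction approaches Sigma^-1 delta-mu", {
  set.seed(10)
  Sg <- matrix(c(2, 0.8, 0.8, 1), 2)
  L <- chol(Sg)
  n <- 2000
  X <- rbind(matrix(rnorm(n), n / 2) %*% L,
             sweep(matrix(rnorm(n), n / 2) %*% L, 2, c(-2, -1), "+"))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(2, 0), each = n / 2)
  m <- fit_lda(X, y, lambda = 1e-9)
  w_eff <- m$w / m$scale                  # undo the internal standardisation
  w_true <- solve(Sg, c(2, 1))            # population direction
  ang <- acos(sum(w_eff * w_true) /
                sqrt(sum(w_eff^2) * sum(w_true^2))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("predictions agree with an independent LDA implementation", {
  set.seed(11)
  n <- 60
  X <- rbind(matrix(rnorm(5 * n / 2), n / 2),
             matrix(rnorm(5 * n / 2, mean = 0.8), n / 2))
  colnames(X) <- paste0("f", 1:5)
  y <- rep(c(0, 2), each = n / 2)
  m <- fit_lda(X, y, lambda = 1e-9)
  ref <- MASS::lda(X, grouping = y)
  expect_identical(classify(m, X),
                   as.numeric(as.character(predict(ref, X)$class)))
})

test_that("leave-one-out cross-validation honours its contracts", {
  # perfectly separated feature
  X <- matrix(c(rnorm(10, -5, 0.1), rnorm(10, 5, 0.1)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), each = 10)
  cv <- loo_cv(X, y)
  expect_identical(cv$accuracy, 1)
  expect_true(all(cv$ld[y == 1] > 0) && all(cv$ld[y == 0] < 0))

  # constant feature: majority-class fraction (unequal classes)
  Xc <- matrix(1, 10, 1, dimnames = list(NULL, "f"))
  yc <- rep(c(0, 1), c(6, 4))
  expect_identical(suppressWarnings(loo_cv(Xc, yc))$accuracy, 0.6)

  # n = 3 violates the precondition
  expect_error(loo_cv(Xc[1:3, , drop = FALSE], c(0, 1, 1)),
               class = "ibdq_degenerate_classes")

  # held-out predictions equal an explicit refit oracle (no leakage)
  set.seed(12)
  Xr <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, paste0("f", 1:3)))
  yr <- rep(c(0, 2), each = 10)
  cvr <- loo_cv(Xr, yr)
  for (i in c(1, 7, 15, 20)) {
    mi <- fit_lda(Xr[-i, ], yr[-i])
    expect_identical(cvr$predicted[i],
                     classify(mi, Xr[i, , drop = FALSE]))
  }
})

test_that("greedy selection finds separating features and respects caps", {
  set.seed(13)
  n <- 24
  noise <- matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("n", 1:20)))
  signal <- c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3))
  v <- cbind(noise, perfect = signal)
  meta <- data.frame(feature = colnames(v), family = "irp", kind = "texture",
                     roi = "crypts", modality = "TPEF525",
                     modality_b = NA_character_, stat = "mean")
  ids <- sprintf("s%02d", seq_len(n))
  ft <- feature_table(v, ids, meta)
  labs <- setNames(lapply(seq_len(n), function(i)
    if (i <= n / 2) index_labels(0, 0, 0) else index_labels(2, 2, 1)), ids)
  sel <- select_features(ft, labs, "architecture")
  expect_identical(sel$selected_features[1], "perfect")
  expect_identical(sel$loo_accuracy, 1)
  sel1 <- select_features(ft, labs, "activity", max_features = 1)
  expect_lte(length(sel1$selected_features), 1L)
  expect_identical(sel1$trace$feature[1], "perfect")
})

test_that("index prediction recovers synthetic ground truth end to end", {
  mc <- mini_cohort()
  models <- setNames(lapply(index_names(), function(ix)
    select_features(mc$features, mc$labels, ix)), index_names())
  for (i in seq_along(mc$labels)) {
    row <- mc$features$values[i, , drop = FALSE]
    pred <- predict_indices(row, models)
    expect_identical(unclass(pred), unclass(mc$labels[[i]]))
  }
  # invariant to feature-column permutation
  perm <- sample(ncol(mc$features$values))
  row_p <- mc$features$values[1, perm, drop = FALSE]
  expect_identical(unclass(predict_indices(row_p, models)),
                   unclass(mc$labels[[1]]))
  # missing feature is a typed error
  expect_error(predict_indices(mc$features$values[1, 1:10, drop = FALSE],
                               models),
               class = "ibdq_feature_mismatch")
})
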