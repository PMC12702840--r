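test_that("fit uses population sd, declared-order one-hot, zero-variance guard", {
  sch <- feature_schema(D = list(x = "numeric"),
                        C = list(k = c("a", "b", "c"), z = "numeric"))
  dat <- data.frame(x = c(1, 2, 3), k = c("b", "a", "c"), z = c(5, 5, 5))
  y <- rep("non_MAFLD", 3)
  tab <- cohort_table(dat, y, sch)
  expect_warning(fit_preprocessor(tab), "zero-variance")
  st <- suppressWarnings(fit_preprocessor(tab))
  expect_equal(unname(st$num_stats$x), c(2, sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(unname(st$num_stats$x[2]), 0.8165, tolerance = 1e-4)
  M <- transform_cohort(st, tab)
  expect_identical(colnames(M)[2:4], c("k=a", "k=b", "k=c"))
  expect_equal(unname(M[1, 2:4]), c(0, 1, 0))       # level 2 of 3
  expect_equal(unname(M[, "z"]), c(0, 0, 0))        # constant column
})

test_that("transform applies training statistics and propagates missingness", {
  sch <- feature_schema(D = list(x = "numeric"),
                        S_lif = list(s = c("u", "v")))
  train <- cohort_table(data.frame(x = c(0, 2), s = c("u", "v")),
                        rep("non_MAFLD", 2), sch)
  st <- fit_preprocessor(train)
  test <- cohort_table(data.frame(x = 1, s = NA_character_),
                       "diabetic_MAFLD", sch)
  M <- transform_cohort(st, test)
  expect_equal(unname(M[1, "x"]), 0)                # (1 - 1) / 1
  expect_true(all(is.na(M[1, c("s=u", "s=v")])))    # masked cell preserved

  # training numerics transform to mean 0, population sd 1
  sim <- small_sim(n = 120, seed = 8)
  stf <- fit_preprocessor(sim$table)
  Mt <- transform_cohort(stf, sim$table)
  clin <- Mt[, "clin_03"]
  expect_lt(abs(mean(clin)), 1e-9)
  expect_lt(abs(sqrt(mean((clin - mean(clin))^2)) - 1), 1e-9)
})

test_that("unseen categorical level encodes as an all-zero block with warning", {
  sch1 <- feature_schema(D = list(s = c("a", "b")))
  train <- cohort_table(data.frame(s = c("a", "b")), rep("non_MAFLD", 2), sch1)
  st <- fit_preprocessor(train)
  sch2 <- feature_schema(D = list(s = c("a", "b", "c")))
  test <- cohort_table(data.frame(s = "c"), "non_MAFLD", sch2)
  expect_warning(transform_cohort(st, test), "unseen level")
  M <- suppressWarnings(transform_cohort(st, test))
  expect_equal(unname(M[1, ]), c(0, 0))
})

test_that("knn imputation matches a brute-force neighbour oracle", {
  M <- matrix(c(1.0, 2.0,
                1.1, 2.2,
                0.9, 1.9,
                5.0, 6.0,
                1.2, 2.1,
                1.0, NA), ncol = 2, byrow = TRUE)
  out <- knn_impute(M, k = 5)
  # oracle: distances from row 6 on column 1 only; all 5 others donate col 2
  d <- abs(M[1:5, 1] - M[6, 1])
  nb <- order(d)[1:5]
  expect_equal(out[6, 2], mean(M[nb, 2]))
  expect_identical(out[1:5, ], M[1:5, ])            # untouched rows
  expect_identical(knn_impute(M[1:5, ], k = 2), M[1:5, ])  # no-missing identity
  # imputed value lies within the observed range of its feature
  expect_gte(out[6, 2], min(M[1:5, 2]))
  expect_lte(out[6, 2], max(M[1:5, 2]))
})

test_that("knn imputation: constant neighbourhoods, modes, degenerate rows", {
  M <- matrix(c(rep(c(1, 7), 5), 1.05, NA), ncol = 2, byrow = TRUE)
  expect_equal(knn_impute(M, k = 5)[6, 2], 7)       # all donors hold 7

  # one-hot block takes the donor mode re-encoded as an indicator
  blocks <- list(x = list(cols = 1L, type = "numeric"),
                 s = list(cols = 2:3, type = "onehot"))
  B <- rbind(c(0.0, 1, 0), c(0.1, 1, 0), c(0.2, 0, 1), c(0.05, NA, NA))
  out <- knn_impute(B, k = 3, blocks = blocks)
  expect_equal(unname(out[4, 2:3]), c(1, 0))
  expect_error(knn_impute(rbind(c(1, 2), c(NA, NA)), k = 1),
               "all features missing")
})

test_that("class weights follow N / (K * n_c)", {
  w <- compute_class_weights(factor(rep(mafld_classes(), c(3747, 507, 154)),
                                    levels = mafld_classes()))
  expect_equal(unname(round(w, 3)), c(0.392, 2.898, 9.541))
  expect_equal(unname(sum(w * c(3747, 507, 154))), 4408)  # weighted freq = N
  expect_equal(unname(compute_class_weights(c("a", "b", "a", "b"))), c(1, 1))
  expect_equal(unname(compute_class_weights(c("a", "b"))), c(1, 1))
  expect_error(compute_class_weights(factor(c("a", "a"), levels = c("a", "b"))),
               "absent")
})
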