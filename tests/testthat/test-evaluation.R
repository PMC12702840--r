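test_that("precision/recall/F1 match hand-counted confusions", {
  perfect <- macro_prf(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_true(all(perfect$per_class[, c("precision", "recall", "f1")] == 1))
  expect_equal(unname(perfect$macro), c(1, 1, 1))

  # class 1: TP=2, FP=1, FN=1 -> P = R = F1 = 2/3
  truth <- c(1, 1, 1, 0, 0, 2)
  pred <- c(1, 1, 0, 1, 2, 2)
  prf <- macro_prf(truth, pred)
  expect_equal(unname(unlist(prf$per_class[2, c("precision", "recall", "f1")])),
               rep(2 / 3, 3))
  expect_equal(unname(prf$macro["f1"]), mean(prf$per_class$f1))
  expect_error(macro_prf(integer(0), integer(0)), "empty")
  w <- testthat::capture_warnings(macro_prf(c(0, 0, 1), c(0, 0, 0)))
  expect_true(any(grepl("never predicted", w)))
  expect_true(any(grepl("absent from truth", w)))
})

test_that("one-vs-rest AUC: extremes, null behaviour, exhaustive pair oracle", {
  # perfectly separating scores
  truth <- c(0, 0, 1, 1, 2, 2)
  sc <- rbind(c(9, 0, 0), c(8, 1, 0), c(0, 9, 1), c(1, 8, 0),
              c(0, 1, 9), c(1, 0, 8))
  expect_equal(ovr_auc(truth, sc)$per_class, rep(1, 3))

  # label-independent scores stay within 3 SE of 0.5
  withr::with_seed(21, {
    n <- 3000
    truth <- sample(0:2, n, replace = TRUE)
    sc <- matrix(runif(3 * n), n, 3)
    auc <- ovr_auc(truth, sc)
    for (k in 1:3) {
      n1 <- sum(truth == k - 1); n0 <- n - n1
      se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
      expect_lt(abs(auc$per_class[k] - 0.5), 3 * se)
    }
  })

  # 10-row toy vs brute-force counting over all (positive, negative) pairs
  withr::with_seed(22, {
    truth <- c(0, 1, 2, 0, 1, 0, 2, 1, 0, 0)
    sc <- matrix(round(runif(30), 1), 10, 3)   # rounded to force ties
    auc <- ovr_auc(truth, sc)
    for (k in 0:2) {
      pos <- which(truth == k); neg <- which(truth != k)
      cmp <- outer(sc[pos, k + 1], sc[neg, k + 1],
                   function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(auc$per_class[k + 1], mean(cmp), tolerance = 1e-12)
    }
    expect_equal(auc$macro, mean(auc$per_class), tolerance = 1e-12)
    # independent cross-check against pROC
    for (k in 0:2) {
      expect_equal(auc$per_class[k + 1],
                   as.numeric(pROC::auc(pROC::roc((truth == k) + 0,
                                                  sc[, k + 1],
                                                  quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    }
  })

  sc1 <- matrix(runif(12), 4, 3)
  expect_warning(ovr_auc(c(0, 0, 1, 1), sc1), "undefined")
  one_sided <- suppressWarnings(ovr_auc(c(0, 0, 1, 1), sc1))
  expect_true(is.na(one_sided$per_class[3]))
  expect_equal(one_sided$macro, mean(one_sided$per_class[1:2]))
})

test_that("metrics are invariant to row permutation", {
  withr::with_seed(23, {
    truth <- sample(0:2, 60, replace = TRUE)
    sc <- matrix(runif(180), 60, 3)
    pred <- max.col(sc) - 1L
    perm <- sample(60)
    expect_equal(ovr_auc(truth[perm], sc[perm, ]), ovr_auc(truth, sc))
    expect_equal(suppressWarnings(macro_prf(truth[perm], pred[perm])),
                 suppressWarnings(macro_prf(truth, pred)))
  })
})

test_that("relative improvement reproduces reported percentages", {
  expect_equal(relative_improvement(0.531, 0.400), 32.8)
  expect_equal(relative_improvement(0.652, 0.559), 16.6)
  expect_equal(relative_improvement(0.3, 0.3), 0.0)
  expect_error(relative_improvement(0.5, 0), "positive")
})

test_that("paired t-test: hand value, antisymmetry, degenerate case", {
  r <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  r2 <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  deg <- paired_t_test(c(1, 2), c(1, 2))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t))
})

test_that("run_trials aggregates per-trial metrics with mean and SE", {
  sim <- small_sim(n = 300, seed = 31)
  cfg <- pipeline_config(classifier = loss_config(epochs = 60))
  rep <- suppressWarnings(run_trials(sim$table, mode = "MLP", seeds = 1:3,
                                     config = cfg))
  expect_equal(nrow(rep$per_trial), 3)
  expect_equal(unname(rep$mean["macro_auc"]),
               mean(rep$per_trial$macro_auc))
  expect_equal(unname(rep$se["macro_auc"]),
               sd(rep$per_trial$macro_auc) / sqrt(3))
})

test_that("cross-validation recovers a planted winning configuration", {
  withr::with_seed(32, {
    n <- 300
    labels <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    signal <- cbind(rnorm(n) + 1.5 * (labels > 0),
                    rnorm(n) + 1.5 * (labels == 2))
    noise <- matrix(rnorm(n * 2), n, 2)
    X <- cbind(signal, noise)
  })
  grid <- list(list(cols = 3:4), list(cols = 1:2))  # winner planted second
  cv <- cross_validate(
    X, labels, grid, k = 5,
    fit_fun = function(X, labels, par)
      list(m = fit_mlp_classifier(X[, par$cols, drop = FALSE], labels, 3L,
                                  loss_config(epochs = 60)),
           cols = par$cols),
    score_fun = function(model, X)
      predict_mlp_classifier(model$m, X[, model$cols, drop = FALSE]),
    seed = 1)
  expect_equal(cv$best_index, 2)
  expect_true(all(table(cv$folds) > 0) && length(cv$folds) == 300)
  # degenerate single-point grid returns that point
  one <- cross_validate(X, labels, grid[1], k = 3,
                        fit_fun = function(X, labels, par)
                          fit_mlp_classifier(X, labels, 3L,
                                             loss_config(epochs = 30)),
                        seed = 2)
  expect_equal(one$best_index, 1)
  expect_error(cross_validate(X, labels, list(), k = 3), "empty")
})

test_that("ablation study returns one paired row per mode", {
  sim <- small_sim(n = 300, seed = 33)
  cfg <- pipeline_config(graph = triplet_config(epochs = 10),
                         classifier = loss_config(epochs = 60))
  tab <- suppressWarnings(ablation_study(sim$table, modes = c("MLP", "Graph"),
                                         seeds = 1:2, config = cfg))
  expect_equal(tab$mode, c("MLP", "Graph"))
  pt <- attr(tab, "per_trial")
  expect_equal(dim(pt), c(2, 2))
  expect_equal(unname(tab$auc_mean), unname(colMeans(pt)))
})
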