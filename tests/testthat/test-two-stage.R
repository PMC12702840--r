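test_that("composition substitutes the stage probabilities exactly", {
  expect_equal(compose_probabilities(1, c(0.7, 0.3)), c(0, 0.7, 0.3))
  expect_equal(compose_probabilities(0, c(0.9, 0.1)), c(1, 0, 0))
  expect_equal(compose_probabilities(0.4, c(0.5, 0.5)), c(0.6, 0.2, 0.2))
  expect_error(compose_probabilities(0.5, c(0.6, 0.6)), "sum to 1")
  # composed distribution sums to 1 for random inputs
  withr::with_seed(11, {
    for (i in 1:200) {
      p <- runif(1); q <- runif(1)
      expect_equal(sum(compose_probabilities(p, c(q, 1 - q))), 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("two-stage loss matches a hand-computed three-term sum", {
  # 4-row batch, explicit arithmetic oracle
  p <- c(0.9, 0.2, 0.7, 0.6)
  yb <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.3, 0.7), c(0.6, 0.4))
  labels <- c(1L, 0L, 2L, 0L)
  w3 <- c(0.5, 2, 4); wbin <- c(0.8, 1.5); wph <- c(1.2, 2.5)
  cfg <- loss_config(gamma = 0.7, lambda = 1.3)
  comp <- rbind(c(0.1, 0.72, 0.18), c(0.8, 0.1, 0.1),
                c(0.3, 0.21, 0.49), c(0.4, 0.36, 0.24))
  t1 <- -(w3[2] * log(0.72) + w3[1] * log(0.8) + w3[3] * log(0.49) +
            w3[1] * log(0.4))
  t2 <- 0.7 * -(wbin[2] * log(0.9) + wbin[1] * log(0.8) +
                  wbin[2] * log(0.7) + wbin[1] * log(0.4))
  t3 <- 1.3 * -(wph[1] * log(0.8) + wph[2] * log(0.7))
  got <- two_stage_loss(list(p = p, yb = yb), labels, cfg,
                        w3 = w3, wbin = wbin, wph = wph)
  expect_equal(as.numeric(got), t1 + t2 + t3, tolerance = 1e-12)
  expect_equal(unname(attr(got, "terms")), c(t1, t2, t3), tolerance = 1e-12)

  # gamma = lambda = 0 leaves the plain weighted NLL term
  cfg0 <- loss_config(gamma = 0, lambda = 0)
  got0 <- two_stage_loss(list(p = p, yb = yb), labels, cfg0, w3 = w3)
  expect_equal(as.numeric(got0), -sum(w3[labels + 1] *
                                        log(comp[cbind(1:4, labels + 1)])),
               tolerance = 1e-12)

  # perfect one-hot predictions give zero loss
  perf <- two_stage_loss(list(p = c(1, 0), yb = rbind(c(1, 0), c(0.5, 0.5))),
                         c(1L, 0L), loss_config())
  expect_equal(as.numeric(perf), 0)
})

test_that("fit is deterministic, separates a separable fixture, emits distributions", {
  withr::with_seed(14, {
    n <- 240
    labels <- rep(0:2, c(160, 50, 30))
    X <- cbind(rnorm(n) + 2 * (labels > 0), rnorm(n) + 2 * (labels == 2),
               matrix(rnorm(n * 3), n, 3))
  })
  cfg <- loss_config(epochs = 150, seed = 2)
  m1 <- fit_two_stage(X, labels, cfg)
  m2 <- fit_two_stage(X, labels, cfg)
  p1 <- predict_two_stage(m1, X)
  expect_identical(p1$composed, predict_two_stage(m2, X)$composed)
  expect_true(all(abs(rowSums(p1$composed) - 1) < 1e-9))
  expect_true(all(p1$composed >= 0))
  expect_equal(length(p1$label), n)

  # beats the majority-class baseline on training macro F1
  f1 <- suppressWarnings(macro_prf(labels, p1$label)$macro["f1"])
  f1_major <- suppressWarnings(macro_prf(labels, rep(0L, n))$macro["f1"])
  expect_gt(f1, f1_major)

  expect_error(fit_two_stage(X, rep(0L, n), cfg), "no MAFLD")
  expect_error(predict_two_stage(m1, X[, 1:3]), "columns")
})

test_that("hard labels use argmax with ties toward the lower class", {
  expect_equal(mafldcl:::.hard_label(rbind(c(0.6, 0.2, 0.2))), 0L)
  expect_equal(mafldcl:::.hard_label(rbind(c(0.2, 0.4, 0.4))), 1L)
  expect_equal(mafldcl:::.hard_label(rbind(c(0.1, 0.2, 0.7),
                                           c(0.5, 0.25, 0.25))), c(2L, 0L))
})

test_that("threshold report: monotone flags/recall, absent precision", {
  withr::with_seed(15, {
    p <- runif(200)
    y <- runif(200) < p                 # correlated membership
  })
  th <- seq(0, 1, by = 0.1)
  rep <- threshold_report(p, y, th)
  expect_equal(rep$recall[1], 1)                       # t = 0 flags everyone
  expect_true(all(diff(rep$flagged) <= 0))
  expect_true(all(diff(rep$recall) <= 0))
  over <- threshold_report(p, y, max(p) + 0.01)
  expect_equal(over$flagged, 0)
  expect_true(is.na(over$precision))
  expect_error(threshold_report(p, y, numeric(0)), "empty")
})

test_that("the MLP baseline is deterministic and order-preserving", {
  withr::with_seed(16, {
    X <- matrix(rnorm(150 * 4), 150, 4)
    labels <- sample(0:2, 150, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  })
  cfg <- loss_config(epochs = 100, seed = 8)
  m <- fit_mlp_classifier(X, labels, 3L, cfg)
  sc <- predict_mlp_classifier(m, X)
  expect_identical(sc, predict_mlp_classifier(fit_mlp_classifier(X, labels,
                                                                 3L, cfg), X))
  expect_true(all(abs(rowSums(sc) - 1) < 1e-9))
  expect_equal(unname(predict_mlp_classifier(m, X[10, , drop = FALSE])[1, ]),
               unname(sc[10, ]), tolerance = 1e-10)
})
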