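test_that("teacher pretraining is deterministic and reduces reconstruction error", {
  X <- withr::with_seed(2, matrix(rnorm(500 * 10), 500, 10))
  t1 <- pretrain_teacher(X, d_z = 8, epochs = 60, seed = 4)
  t2 <- pretrain_teacher(X, d_z = 8, epochs = 60, seed = 4)
  expect_identical(encode_teacher(t1, X), encode_teacher(t2, X))
  expect_lt(t1$loss[length(t1$loss)], t1$loss[1])
})

test_that("linear autoencoder on rank-r input approaches zero error (PCA limit)", {
  X <- withr::with_seed(3, {
    U <- matrix(rnorm(400 * 2), 400, 2)
    V <- matrix(rnorm(2 * 6), 2, 6)
    U %*% V
  })
  tch <- pretrain_teacher(X, d_z = 4, hidden = 8, epochs = 1500, lr = 1e-2,
                          activation = "linear", seed = 1)
  expect_lt(tch$loss[length(tch$loss)], 0.01 * tch$loss[1])
})

test_that("batch temperature: softplus form, positivity, permutation invariance", {
  zb <- withr::with_seed(5, matrix(rnorm(12), 3, 4))
  expect_equal(batch_temperature(zb, rep(0, 4)), log(2) + 0.05)
  withr::with_seed(6, {
    for (i in 1:20) {
      W <- rnorm(4, sd = 3)
      B <- matrix(rnorm(20), 5, 4)
      expect_gt(batch_temperature(B, W), 0)
      expect_equal(batch_temperature(B[sample(5), ], W),
                   batch_temperature(B, W))
    }
  })
})

test_that("InfoNCE identities and brute-force oracle", {
  ones <- matrix(1, 5, 3)
  expect_equal(infonce_loss(ones, ones, 0.7), log(5))
  expect_equal(infonce_loss(matrix(rnorm(3), 1, 3),
                            matrix(rnorm(3), 1, 3), 0.3), 0)
  expect_error(infonce_loss(rbind(c(0, 0)), rbind(c(1, 1)), 0.5), "zero-norm")
  expect_error(infonce_loss(ones, ones, 0))

  withr::with_seed(7, {
    zx <- matrix(rnorm(32), 8, 4); zb <- matrix(rnorm(32), 8, 4)
    tau <- 0.37
    # independent evaluation with explicit loops
    cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    terms <- sapply(1:8, function(i) {
      s <- sapply(1:8, function(k) cosine(zx[i, ], zb[k, ]))
      -log(exp(s[i] / tau) / sum(exp(s / tau)))
    })
    expect_equal(infonce_loss(zx, zb, tau), mean(terms), tolerance = 1e-12)
    expect_gte(infonce_loss(zx, zb, tau), 0)
  })
})

test_that("multiview loss is the sum of its two anchored terms", {
  withr::with_seed(8, {
    za <- matrix(rnorm(24), 6, 4); zb <- matrix(rnorm(24), 6, 4)
    zc <- matrix(rnorm(24), 6, 4)
    expect_equal(multiview_loss(za, zb, zc, 0.5),
                 infonce_loss(za, zb, 0.5) + infonce_loss(zc, zb, 0.5))
    expect_equal(multiview_loss(za, zb, za, 0.5),
                 2 * infonce_loss(za, zb, 0.5))
    ones <- matrix(1, 6, 4)
    expect_equal(multiview_loss(ones, ones, ones, 0.9), 2 * log(6))
  })
})

test_that("learner training is deterministic and aligns views when coupled", {
  sim <- small_sim(n = 250, rho = 1, seed = 9)
  split <- trial_split(250, 1, 0.8, y = sim$table$y)
  feats_inputs <- local({
    prep <- fit_preprocessor(subset_cohort(sim$table, split$train))
    M <- transform_cohort(prep, sim$table)
    Mi <- knn_impute(M, 5, donors = M[split$train, , drop = FALSE])
    ccols <- unlist(lapply(schema_features(sim$table$schema, "C"),
                           function(nm) attr(M, "blocks")[[nm]]$cols))
    list(
      A_lif = train_graph_encoder(build_graph(sim$table, "S_lif"),
                                  triplet_config(epochs = 20, seed = 2)),
      A_gen = train_graph_encoder(build_graph(sim$table, "S_gen"),
                                  triplet_config(epochs = 20, seed = 3)),
      clinical = Mi[, ccols]
    )
  })
  cfg <- contrastive_config(epochs = 30, teacher_epochs = 80, seed = 10)
  m1 <- train_learners(feats_inputs$A_lif, feats_inputs$A_gen,
                       feats_inputs$clinical, cfg, train_idx = split$train)
  m2 <- train_learners(feats_inputs$A_lif, feats_inputs$A_gen,
                       feats_inputs$clinical, cfg, train_idx = split$train)
  expect_identical(m1$embeddings, m2$embeddings)
  expect_true(all(vapply(m1$embeddings, function(z) all(is.finite(z)), TRUE)))
  # frozen-teacher contract: z_b is the pretrained teacher's output
  tch <- m1$stack$teacher
  expect_identical(m1$embeddings$z_b,
                   encode_teacher(tch, feats_inputs$clinical))
  # alignment improves on the coupled cohort
  expect_gt(attr(m1, "align_after"), attr(m1, "align_before"))
})

test_that("no spurious alignment signal survives at rho = 0", {
  sim <- small_sim(n = 250, rho = 0, seed = 12)
  split <- trial_split(250, 1, 0.8, y = sim$table$y)
  prep <- fit_preprocessor(subset_cohort(sim$table, split$train))
  M <- transform_cohort(prep, sim$table)
  Mi <- knn_impute(M, 5, donors = M[split$train, , drop = FALSE])
  ccols <- unlist(lapply(schema_features(sim$table$schema, "C"),
                         function(nm) attr(M, "blocks")[[nm]]$cols))
  A_lif <- train_graph_encoder(build_graph(sim$table, "S_lif"),
                               triplet_config(epochs = 20, seed = 2))
  A_gen <- train_graph_encoder(build_graph(sim$table, "S_gen"),
                               triplet_config(epochs = 20, seed = 3))
  m <- train_learners(A_lif, A_gen, Mi[, ccols],
                      contrastive_config(epochs = 30, teacher_epochs = 80,
                                         seed = 13),
                      train_idx = split$train)
  # on held-out rows, positive-pair similarity should not beat shuffled pairs
  te <- split$test
  za <- m$embeddings$z_a[te, ]; zb <- m$embeddings$z_b[te, ]
  za <- za / sqrt(rowSums(za^2)); zb <- zb / sqrt(rowSums(zb^2))
  pos <- mean(rowSums(za * zb))
  shuf <- withr::with_seed(3, mean(rowSums(za * zb[sample(nrow(zb)), ])))
  expect_lt(abs(pos - shuf), 0.15)
})
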