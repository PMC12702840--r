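#' Per-class and macro precision / recall / F1
#'
#' One-vs-rest counts per class; macro values are the unweighted mean over
#' the three classes. A class never predicted gets precision 0 with a
#' warning (and a class absent from the truth gets recall 0 with a warning),
#' so macro aggregates stay defined on degenerate inputs.
#'
#' @param truth,pred Integer label vectors in `{0, 1, 2}`, same length.
#' @return List with `per_class` (data frame: class, precision, recall, f1)
#'   and `macro` (named vector precision/recall/f1).
#' @export
macro_prf <- function(truth, pred) {
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(truth) == length(pred))
  classes <- 0:2
  rows <- lapply(classes, function(c) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    if (tp + fp == 0) {
      warning("class ", c, " never predicted: precision set to 0",
              call. = FALSE)
      prec <- 0
    } else prec <- tp / (tp + fp)
    if (tp + fn == 0) {
      warning("class ", c, " absent from truth: recall set to 0",
              call. = FALSE)
      rec <- 0
    } else rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = c, precision = prec, recall = rec, f1 = f1)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class,
       macro = c(precision = mean(per_class$precision),
                 recall = mean(per_class$recall),
                 f1 = mean(per_class$f1)))
}

#' One-vs-rest AUC per class and macro
#'
#' Per class, the AUC of that class's score column for class-vs-rest,
#' computed as the Mann-Whitney rank statistic with mid-ranks for ties. A
#' class absent from the truth (or filling it entirely) has undefined AUC:
#' it is reported as `NA` and excluded from the macro mean with a warning.
#'
#' @param truth Integer labels in `{0, 1, 2}`.
#' @param scores n x 3 matrix of class scores (column c scores class c).
#' @return List with `per_class` (length-3 numeric, possibly `NA`) and
#'   `macro` (unweighted mean of the defined per-class AUCs).
#' @export
ovr_auc <- function(truth, scores) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(truth), ncol(scores) == 3)
  per_class <- vapply(0:2, function(c) {
    pos <- truth == c
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      warning("class ", c, " AUC undefined (one-sided truth); excluded",
              call. = FALSE)
      return(NA_real_)
    }
    r <- rank(scores[, c + 1L])           # mid-ranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  list(per_class = per_class, macro = mean(per_class, na.rm = TRUE))
}

#' Relative improvement of a metric, in percent
#'
#' `100 * (new - base) / base`, rounded to one decimal for reporting.
#'
#' @param new,base Metric values; `base` must be positive.
#' @return Percent improvement, one decimal.
#' @export
relative_improvement <- function(new, base) {
  if (base <= 0) stop("base metric must be positive", call. = FALSE)
  round(100 * (new - base) / base, 1)
}

#' Paired two-tailed t-test on per-trial metrics
#'
#' Classical paired t with `length - 1` degrees of freedom. Zero-variance
#' differences make the statistic undefined; the degenerate case is
#' reported explicitly rather than as a number.
#'
#' @param a,b Equal-length (`>= 2`) numeric vectors of per-trial metrics.
#' @return List of class `paired_t`: `t`, `df`, `p`, `mean_diff` and
#'   logical `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = length(a) - 1L, p = NA_real_,
                          mean_diff = mean(d), degenerate = TRUE),
                     class = "paired_t"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(d), degenerate = FALSE),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate)
    cat("<paired_t> degenerate: zero-variance differences (mean diff ",
        x$mean_diff, ")\n", sep = "")
  else
    cat(sprintf("<paired_t> t = %.4f, df = %d, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Pipeline configuration for evaluation runs
#'
#' Bundles the per-component configurations used by [run_trials()],
#' [ablation_study()] and the CLI. Component seeds are derived from the
#' per-trial split seed.
#'
#' @param graph A [triplet_config()].
#' @param contrastive A [contrastive_config()].
#' @param classifier A [loss_config()].
#' @param knn_k Neighbour count for dense-path imputation.
#' @param f Training fraction per trial.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(graph = triplet_config(),
                            contrastive = contrastive_config(),
                            classifier = loss_config(),
                            knn_k = 5L, f = 0.8) {
  structure(list(graph = graph, contrastive = contrastive,
                 classifier = classifier, knn_k = as.integer(knn_k), f = f),
            class = "pipeline_config")
}

# z-score embedding columns with training-row statistics (population sd,
# zero-variance guarded) before concatenation to the classifier input.
.scale_by_train <- function(M, train) {
  mu <- colMeans(M[train, , drop = FALSE])
  sd <- sqrt(colMeans(sweep(M[train, , drop = FALSE], 2, mu)^2))
  sd[sd == 0] <- 1
  sweep(sweep(M, 2, mu), 2, sd, "/")
}

#' Prepare one trial's features: preprocessing, graphs, embeddings
#'
#' Fits the preprocessor on the training rows, imputes the dense path with
#' training-row donors, builds the two survey graphs over all persons
#' (labels are never used), trains the graph encoders and the contrastive
#' learners, and z-scores every embedding block with training statistics.
#' Computes only what the requested modes need; [ablation_study()] reuses
#' one preparation across all modes of a trial.
#'
#' @param cohort A [cohort_table()].
#' @param split A [trial_split()].
#' @param config A [pipeline_config()].
#' @param seed Integer base seed for the component training runs.
#' @param need_graph,need_cl Whether graph embeddings / contrastive
#'   embeddings are required.
#' @return List with `dense` (imputed full design matrix), `X_dc`
#'   (demographics + clinical columns), `clinical`, and when requested
#'   `A_lif`/`A_gen` and `z_a`/`z_c`.
#' @export
prepare_trial <- function(cohort, split, config, seed,
                          need_graph = TRUE, need_cl = TRUE) {
  train <- split$train
  prep_all <- fit_preprocessor(subset_cohort(cohort, train), k = config$knn_k)
  M_all <- transform_cohort(prep_all, cohort)
  blocks <- attr(M_all, "blocks")
  dense <- knn_impute(M_all, k = config$knn_k, blocks = blocks,
                      donors = M_all[train, , drop = FALSE])
  dc_cols <- unlist(lapply(
    schema_features(cohort$schema, c("D", "C")),
    function(nm) blocks[[nm]]$cols))
  c_cols <- unlist(lapply(
    schema_features(cohort$schema, "C"),
    function(nm) blocks[[nm]]$cols))
  out <- list(dense = dense, X_dc = dense[, dc_cols, drop = FALSE],
              clinical = dense[, c_cols, drop = FALSE])
  if (need_graph) {
    gcfg <- config$graph; gcfg$seed <- seed
    A_lif <- train_graph_encoder(build_graph(cohort, "S_lif"), gcfg)
    gcfg$seed <- seed + 1L
    A_gen <- train_graph_encoder(build_graph(cohort, "S_gen"), gcfg)
    out$A_lif <- .scale_by_train(A_lif, train)
    out$A_gen <- .scale_by_train(A_gen, train)
  }
  if (need_cl) {
    ccfg <- config$contrastive; ccfg$seed <- seed + 2L
    mvc <- train_learners(out$A_lif, out$A_gen, out$clinical, ccfg,
                          train_idx = train)
    out$z_a <- .scale_by_train(mvc$embeddings$z_a, train)
    out$z_c <- .scale_by_train(mvc$embeddings$z_c, train)
  }
  out
}

#' Fit and score one method variant on prepared trial features
#'
#' `"MLP"` fits the baseline classifier on the imputed dense matrix;
#' `"Graph"` and `"Graph+CL"` concatenate the graph / contrastive
#' embeddings to it; `"Full"` fits the two-stage estimator on demographics,
#' clinical features and the contrastive view embeddings.
#'
#' @param feats A [prepare_trial()] result.
#' @param mode One of `"MLP"`, `"Graph"`, `"Graph+CL"`, `"Full"`.
#' @param labels Integer labels in `{0, 1, 2}` for all rows.
#' @param split The [trial_split()] used in [prepare_trial()].
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the classifier fit.
#' @return List with test-set `scores` (n x 3), hard `label`s, the fitted
#'   `model`, and for `"Full"` the stage-1 probabilities `p`.
#' @export
classify_mode <- function(feats, mode, labels, split, config, seed) {
  ccfg <- config$classifier; ccfg$seed <- seed + 3L
  X <- switch(mode,
    "MLP" = feats$dense,
    "Graph" = cbind(feats$dense, feats$A_lif, feats$A_gen),
    "Graph+CL" = cbind(feats$dense, feats$z_a, feats$z_c),
    "Full" = cbind(feats$X_dc, feats$z_a, feats$z_c),
    stop("unknown ablation mode: ", mode, call. = FALSE))
  tr <- split$train; te <- split$test
  if (mode == "Full") {
    model <- fit_two_stage(X[tr, , drop = FALSE], labels[tr], ccfg)
    pr <- predict_two_stage(model, X[te, , drop = FALSE])
    list(scores = pr$composed, label = pr$label, p = pr$p, model = model)
  } else {
    model <- fit_mlp_classifier(X[tr, , drop = FALSE], labels[tr],
                                n_class = 3L, ccfg)
    sc <- predict_mlp_classifier(model, X[te, , drop = FALSE])
    list(scores = sc, label = max.col(sc, ties.method = "first") - 1L,
         model = model)
  }
}

# Metrics for one scored test set, as a single data-frame row.
.trial_metrics <- function(truth, scores, label) {
  prf <- macro_prf(truth, label)
  auc <- ovr_auc(truth, scores)
  data.frame(macro_precision = prf$macro["precision"],
             macro_recall = prf$macro["recall"],
             macro_f1 = prf$macro["f1"],
             macro_auc = auc$macro,
             auc_non = auc$per_class[1],
             auc_nondiab = auc$per_class[2],
             auc_diab = auc$per_class[3],
             row.names = NULL)
}

#' Repeated stratified train/test trials of one method
#'
#' For each seed: stratified 80/20 split, fit the requested mode on the
#' training rows, score the test rows; per-trial macro metrics are
#' aggregated as mean and standard error (`sd / sqrt(trials)`).
#'
#' @param cohort A [cohort_table()].
#' @param mode One of `"MLP"`, `"Graph"`, `"Graph+CL"`, `"Full"`.
#' @param seeds Integer vector of split seeds (default 10 trials).
#' @param config A [pipeline_config()].
#' @return An object of class `metrics_report`: `per_trial` data frame,
#'   `mean` and `se` named vectors.
#' @export
run_trials <- function(cohort, mode = "Full", seeds = 1:10,
                       config = pipeline_config()) {
  labels <- as.integer(cohort$y) - 1L
  rows <- lapply(seq_along(seeds), function(t) {
    seed <- seeds[t]
    res <- tryCatch({
      split <- trial_split(nrow(cohort$data), seed, f = config$f, y = cohort$y)
      feats <- prepare_trial(cohort, split, config, seed * 1000L,
                             need_graph = mode != "MLP",
                             need_cl = mode %in% c("Graph+CL", "Full"))
      cm <- classify_mode(feats, mode, labels, split, config, seed * 1000L)
      cbind(data.frame(trial = t, seed = seed),
            .trial_metrics(labels[split$test], cm$scores, cm$label))
    }, error = function(e)
      stop("trial ", t, " (seed ", seed, ") failed: ", conditionMessage(e),
           call. = FALSE))
    res
  })
  metrics_report(do.call(rbind, rows))
}

#' Build a metrics report from per-trial rows
#' @param per_trial Data frame of per-trial metric rows.
#' @return An object of class `metrics_report` with `per_trial`, `mean`,
#'   `se` (standard error, `sd / sqrt(trials)`).
#' @export
metrics_report <- function(per_trial) {
  num <- per_trial[, !(names(per_trial) %in% c("trial", "seed", "mode")),
                   drop = FALSE]
  structure(list(per_trial = per_trial,
                 mean = colMeans(num),
                 se = apply(num, 2, stats::sd) / sqrt(nrow(num))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", nrow(x$per_trial), " trials\n", sep = "")
  out <- data.frame(mean = round(x$mean, 4), se = round(x$se, 4))
  print(out)
  invisible(x)
}

#' Stratified k-fold cross-validation over a hyperparameter grid
#'
#' For every grid point, fits with `fit_fun` on k-1 folds and scores the
#' held-out fold; the point with the highest mean validation macro one-vs-
#' rest AUC wins, ties resolving to the earliest grid entry.
#'
#' @param X Input matrix.
#' @param labels Integer labels in `{0, 1, 2}`.
#' @param grid Nonempty list of hyperparameter settings.
#' @param k Number of folds.
#' @param fit_fun `function(X, labels, par)` returning a model.
#' @param score_fun `function(model, X)` returning an n x 3 score matrix.
#' @param seed Integer seed for fold assignment.
#' @return List: `best` (the winning grid entry), `best_index`, `auc`
#'   (mean validation AUC per grid point), `folds` (fold id per row).
#' @export
cross_validate <- function(X, labels, grid, k = 5L,
                           fit_fun = function(X, labels, par) {
                             cfg <- do.call(loss_config, par)
                             fit_mlp_classifier(X, labels, 3L, cfg)
                           },
                           score_fun = predict_mlp_classifier,
                           seed = 1L) {
  if (length(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n, k >= 2)
  folds <- with_seed(seed, {
    f <- integer(n)
    for (c in unique(labels)) {
      idx <- sample(which(labels == c))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  auc <- vapply(grid, function(par) {
    mean(vapply(seq_len(k), function(fold) {
      tr <- folds != fold
      model <- fit_fun(X[tr, , drop = FALSE], labels[tr], par)
      sc <- score_fun(model, X[!tr, , drop = FALSE])
      ovr_auc(labels[!tr], sc)$macro
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(auc)        # ties -> first in grid order
  list(best = grid[[best]], best_index = best, auc = auc, folds = folds)
}

#' Ablation study over the four method variants
#'
#' Runs `MLP` (preprocessed dense input), `Graph` (+ graph embeddings),
#' `Graph+CL` (+ contrastive embeddings) and `Full` (complete two-stage
#' method) on identical split seeds, reusing each trial's graphs and
#' embeddings across modes so the comparison is paired.
#'
#' @param cohort A [cohort_table()].
#' @param modes Subset of the four mode names.
#' @param seeds Split seeds (one trial per seed).
#' @param config A [pipeline_config()].
#' @return Data frame: one row per mode with mean and SE of macro AUC;
#'   attribute `"per_trial"` holds the trial x mode AUC matrix for paired
#'   tests, attribute `"reports"` the full [metrics_report()] per mode.
#' @export
ablation_study <- function(cohort,
                           modes = c("MLP", "Graph", "Graph+CL", "Full"),
                           seeds = 1:5, config = pipeline_config()) {
  stopifnot(all(modes %in% c("MLP", "Graph", "Graph+CL", "Full")))
  labels <- as.integer(cohort$y) - 1L
  need_graph <- any(modes != "MLP")
  need_cl <- any(modes %in% c("Graph+CL", "Full"))
  per_mode <- stats::setNames(vector("list", length(modes)), modes)
  for (t in seq_along(seeds)) {
    seed <- seeds[t]
    split <- trial_split(nrow(cohort$data), seed, f = config$f, y = cohort$y)
    feats <- prepare_trial(cohort, split, config, seed * 1000L,
                           need_graph = need_graph, need_cl = need_cl)
    for (mode in modes) {
      cm <- classify_mode(feats, mode, labels, split, config, seed * 1000L)
      per_mode[[mode]][[t]] <- cbind(
        data.frame(trial = t, seed = seed, mode = mode),
        .trial_metrics(labels[split$test], cm$scores, cm$label))
    }
  }
  reports <- lapply(per_mode, function(rows)
    metrics_report(do.call(rbind, rows)))
  out <- do.call(rbind, lapply(modes, function(m)
    data.frame(mode = m,
               auc_mean = reports[[m]]$mean["macro_auc"],
               auc_se = reports[[m]]$se["macro_auc"],
               row.names = NULL)))
  attr(out, "per_trial") <- vapply(modes, function(m)
    reports[[m]]$per_trial$macro_auc, numeric(length(seeds)))
  attr(out, "reports") <- reports
  out
}
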