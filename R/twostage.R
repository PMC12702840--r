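#' Compose the two-stage class distribution
#'
#' Stage 1 yields `p = P(any MAFLD)`; stage 2 yields a distribution over the
#' H phenotypes. The overall (1+H)-class distribution is
#' `(1 - p, p * yb_1, ..., p * yb_H)`, which sums to 1 by construction.
#'
#' @param p Stage-1 MAFLD probability in `[0, 1]`.
#' @param yb Stage-2 phenotype distribution (nonnegative, sums to 1 within
#'   1e-9).
#' @return Numeric vector of length `1 + length(yb)`.
#' @export
compose_probabilities <- function(p, yb) {
  stopifnot(p >= 0, p <= 1, all(yb >= 0))
  if (abs(sum(yb) - 1) > 1e-9)
    stop("stage-2 distribution must sum to 1", call. = FALSE)
  c(1 - p, p * yb)
}

#' Two-stage loss configuration
#'
#' @param gamma,lambda Nonnegative trade-off weights on the stage-1 and
#'   stage-2 loss terms.
#' @param hidden Width of the two shared trunk layers.
#' @param epochs,lr Optimiser settings (full-batch Adam).
#' @param l2 L2 weight-decay strength on all weight matrices (not biases);
#'   the heads otherwise memorise small imbalanced training sets.
#' @param seed Integer seed.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(gamma = 1.0, lambda = 1.0, hidden = 64L,
                        epochs = 300L, lr = 3e-3, l2 = 0.1, seed = 1L) {
  stopifnot(gamma >= 0, lambda >= 0, l2 >= 0)
  structure(list(gamma = gamma, lambda = lambda, hidden = as.integer(hidden),
                 epochs = as.integer(epochs), lr = lr, l2 = l2,
                 seed = as.integer(seed)),
            class = "loss_config")
}

# add l2 * W to every weight-matrix gradient in a nested grads list
.add_l2 <- function(grads, params, l2) {
  if (l2 == 0) return(grads)
  for (i in seq_along(params)) {
    if (is.list(params[[i]]) && !is.null(params[[i]]$W))
      grads[[i]]$W <- grads[[i]]$W + l2 * params[[i]]$W
    else if (is.list(params[[i]]))
      grads[[i]] <- .add_l2(grads[[i]], params[[i]], l2)
  }
  grads
}

# Clamp probabilities away from 0 before log; warn when clamping occurs.
.clamp_log <- function(p) {
  if (any(p < 1e-12)) {
    warning("probability clamped at 1e-12 before log", call. = FALSE)
    p <- pmax(p, 1e-12)
  }
  log(p)
}

#' Joint two-stage training loss
#'
#' Three summed terms: (1) class-weighted negative log-likelihood of the
#' composed 3-class distribution against the true label; (2) `gamma` times
#' the weighted binary cross-entropy of the stage-1 distribution against
#' any-MAFLD membership; (3) `lambda` times the weighted cross-entropy of
#' the stage-2 distribution against the phenotype, summed over true-MAFLD
#' rows only (teacher forcing).
#'
#' @param pred List with `p` (stage-1 probabilities, length n) and `yb`
#'   (n x 2 phenotype distribution matrix).
#' @param labels Integer labels in `{0, 1, 2}` (0 = non-MAFLD).
#' @param config A [loss_config()].
#' @param w3,wbin,wph Class-weight vectors for the three terms (3-class,
#'   binary, phenotype); default all ones.
#' @return Scalar total loss; attribute `"terms"` holds the three summands.
#' @export
two_stage_loss <- function(pred, labels, config = loss_config(),
                           w3 = rep(1, 3), wbin = rep(1, 2),
                           wph = rep(1, 2)) {
  p <- pred$p
  yb <- as.matrix(pred$yb)
  n <- length(labels)
  stopifnot(length(p) == n, nrow(yb) == n, all(labels %in% 0:2))
  comp <- cbind(1 - p, p * yb[, 1], p * yb[, 2])
  term1 <- -sum(w3[labels + 1L] * .clamp_log(comp[cbind(seq_len(n),
                                                        labels + 1L)]))
  is_m <- labels > 0L
  pa <- ifelse(is_m, p, 1 - p)
  term2 <- config$gamma * -sum(wbin[1L + is_m] * .clamp_log(pa))
  m <- which(is_m)
  term3 <- if (length(m))
    config$lambda * -sum(wph[labels[m]] *
                           .clamp_log(yb[cbind(m, labels[m])]))
  else 0
  total <- term1 + term2 + term3
  attr(total, "terms") <- c(composed_nll = term1, stage1 = unname(term2),
                            stage2 = unname(term3))
  total
}

# hard 0-based label: argmax with ties broken toward the lower class index
.hard_label <- function(composed) {
  max.col(composed, ties.method = "first") - 1L
}

# forward pass of trunk + two heads; returns caches for backprop
.ts_forward <- function(params, X) {
  ft <- mlp_forward(params$trunk, X)
  Tr <- relu(ft$out)
  fa <- mlp_forward(params$head_a, Tr)
  fb <- mlp_forward(params$head_b, Tr)
  list(ft = ft, Tr = Tr, fa = fa, fb = fb,
       Pa = row_softmax(fa$out), Pb = row_softmax(fb$out))
}

#' Fit the two-stage risk estimator
#'
#' Two softmax heads (any-MAFLD; phenotype) over a shared 2-layer trunk,
#' trained full-batch with Adam to minimise [two_stage_loss()] with
#' inverse-frequency class weights in every term. The stage-2 term is
#' evaluated on true-MAFLD rows (teacher forcing).
#'
#' @param X Numeric input matrix (preprocessed demographics + clinical
#'   features concatenated with the contrastive view embeddings).
#' @param labels Integer labels in `{0, 1, 2}`; at least one MAFLD row.
#' @param config A [loss_config()].
#' @return An object of class `two_stage_model` with a `loss` history.
#' @export
fit_two_stage <- function(X, labels, config = loss_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n, all(labels %in% 0:2))
  if (!any(labels > 0))
    stop("no MAFLD rows: stage-2 loss undefined", call. = FALSE)
  w3 <- as.numeric(compute_class_weights(factor(labels, levels = 0:2)))
  wbin <- as.numeric(compute_class_weights(factor(labels > 0,
                                                  levels = c(FALSE, TRUE))))
  mafld <- labels[labels > 0]
  wph <- if (length(unique(mafld)) == 2)
    as.numeric(compute_class_weights(factor(mafld, levels = 1:2)))
  else c(1, 1)

  is_m <- labels > 0L
  ta <- 1L + is_m                        # stage-1 target column
  wa <- w3[labels + 1L] + config$gamma * wbin[ta]
  wb <- ifelse(is_m, w3[labels + 1L] + config$lambda * wph[pmax(labels, 1L)],
               0)
  Ya <- matrix(0, n, 2); Ya[cbind(seq_len(n), ta)] <- 1
  Yb <- matrix(0, n, 2)
  Yb[cbind(which(is_m), labels[is_m])] <- 1

  with_seed(config$seed, {
    params <- list(trunk = mlp_init(c(ncol(X), config$hidden, config$hidden)),
                   head_a = mlp_init(c(config$hidden, 2L)),
                   head_b = mlp_init(c(config$hidden, 2L)))
    opt <- adam_init(params)
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      fw <- .ts_forward(params, X)
      losses[ep] <- as.numeric(two_stage_loss(
        list(p = fw$Pa[, 2], yb = fw$Pb), labels, config,
        w3 = w3, wbin = wbin, wph = wph))
      if (!is.finite(losses[ep]))
        stop("non-finite two-stage loss at epoch ", ep, call. = FALSE)
      Ga <- wa * (fw$Pa - Ya) / n
      Gb <- wb * (fw$Pb - Yb) / n
      ba <- mlp_backward(params$head_a, fw$fa, Ga)
      bb <- mlp_backward(params$head_b, fw$fb, Gb)
      Gt <- (ba$dX + bb$dX) * (fw$ft$out > 0)
      bt <- mlp_backward(params$trunk, fw$ft, Gt)
      grads <- .add_l2(list(trunk = bt$grads, head_a = ba$grads,
                            head_b = bb$grads), params, config$l2)
      step <- adam_step(params, grads, opt, lr = config$lr)
      params <- step$params
      opt <- step$state
    }
    structure(list(params = params, config = config, d_in = ncol(X),
                   weights = list(w3 = w3, wbin = wbin, wph = wph),
                   loss = losses),
              class = "two_stage_model")
  })
}

#' Predict with a fitted two-stage model
#'
#' @param model A [fit_two_stage()] result.
#' @param X Input matrix with the fitted number of columns.
#' @return An object of class `two_stage_prediction`: list with `p`
#'   (stage-1 MAFLD probability), `yb` (n x 2 phenotype distribution),
#'   `composed` (n x 3 overall distribution) and `label` (hard 0/1/2 label;
#'   ties break toward the lower class index).
#' @export
predict_two_stage <- function(model, X) {
  stopifnot(inherits(model, "two_stage_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d_in)
    stop("input has ", ncol(X), " columns; model expects ", model$d_in,
         call. = FALSE)
  fw <- .ts_forward(model$params, X)
  p <- fw$Pa[, 2]
  composed <- cbind(1 - p, p * fw$Pb[, 1], p * fw$Pb[, 2])
  colnames(composed) <- mafld_classes()
  label <- .hard_label(composed)
  structure(list(p = p, yb = fw$Pb, composed = composed, label = label),
            class = "two_stage_prediction")
}

#' Stage-1 precision/recall across decision thresholds
#'
#' For each threshold `t`, rows with `p >= t` are flagged as high risk;
#' precision is reported as `NA` (absent) when nothing is flagged, never as
#' zero.
#'
#' @param p Stage-1 probabilities in `[0, 1]`.
#' @param ybin Logical (or 0/1) any-MAFLD membership.
#' @param thresholds Nonempty numeric vector of thresholds.
#' @return Data frame with columns `threshold`, `flagged`, `precision`,
#'   `recall`; `flagged` and `recall` are non-increasing in the threshold.
#' @export
threshold_report <- function(p, ybin, thresholds) {
  if (length(thresholds) == 0)
    stop("empty threshold list", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1), length(p) == length(ybin))
  ybin <- as.logical(ybin)
  pos <- sum(ybin)
  rows <- lapply(sort(thresholds), function(t) {
    fl <- p >= t
    tp <- sum(fl & ybin)
    data.frame(threshold = t, flagged = sum(fl),
               precision = if (any(fl)) tp / sum(fl) else NA_real_,
               recall = if (pos > 0) tp / pos else NA_real_)
  })
  do.call(rbind, rows)
}

#' Fit the plain MLP multiclass baseline
#'
#' Single-softmax classifier over the same trunk architecture as the
#' two-stage model, trained with inverse-frequency class-weighted
#' cross-entropy. Serves as the ablation baseline and as the classifier for
#' the embedding-concatenation ablation modes.
#'
#' @param X Numeric input matrix.
#' @param labels Integer labels in `{0, ..., K-1}`.
#' @param n_class Number of classes K.
#' @param config A [loss_config()] (only `hidden`, `epochs`, `lr`, `seed`
#'   are used).
#' @return An object of class `mlp_model`.
#' @export
fit_mlp_classifier <- function(X, labels, n_class = 3L,
                               config = loss_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n, all(labels %in% (seq_len(n_class) - 1L)))
  w <- as.numeric(compute_class_weights(
    factor(labels, levels = seq_len(n_class) - 1L)))
  wi <- w[labels + 1L]
  Y <- matrix(0, n, n_class); Y[cbind(seq_len(n), labels + 1L)] <- 1
  with_seed(config$seed, {
    params <- list(trunk = mlp_init(c(ncol(X), config$hidden, config$hidden)),
                   head = mlp_init(c(config$hidden, n_class)))
    opt <- adam_init(params)
    for (ep in seq_len(config$epochs)) {
      ft <- mlp_forward(params$trunk, X)
      Tr <- relu(ft$out)
      fh <- mlp_forward(params$head, Tr)
      P <- row_softmax(fh$out)
      G <- wi * (P - Y) / n
      bh <- mlp_backward(params$head, fh, G)
      Gt <- bh$dX * (ft$out > 0)
      bt <- mlp_backward(params$trunk, ft, Gt)
      grads <- .add_l2(list(trunk = bt$grads, head = bh$grads), params,
                       config$l2)
      step <- adam_step(params, grads, opt, lr = config$lr)
      params <- step$params
      opt <- step$state
    }
    structure(list(params = params, d_in = ncol(X),
                   n_class = as.integer(n_class)), class = "mlp_model")
  })
}

#' Class probabilities from the MLP baseline
#' @param model A [fit_mlp_classifier()] result.
#' @param X Input matrix.
#' @return n x K matrix of class probabilities.
#' @export
predict_mlp_classifier <- function(model, X) {
  stopifnot(inherits(model, "mlp_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d_in)
    stop("input has ", ncol(X), " columns; model expects ", model$d_in,
         call. = FALSE)
  ft <- mlp_forward(model$params$trunk, X)
  row_softmax(mlp_forward(model$params$head, relu(ft$out))$out)
}
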