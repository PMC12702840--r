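#' Contrastive pretraining configuration
#'
#' @param d_z Embedding dimension of all three views.
#' @param hidden Hidden width of the encoders.
#' @param batch Mini-batch size.
#' @param epochs Learner training epochs.
#' @param teacher_epochs Autoencoder pretraining epochs for the teacher.
#' @param lr Adam learning rate.
#' @param tau_min Temperature floor added to the softplus output of the
#'   adaptive temperature network, keeping the InfoNCE temperature strictly
#'   positive.
#' @param freeze_teacher Keep the clinical teacher fixed while the learners
#'   train (the teacher anchors the alignment); set `FALSE` to fine-tune it
#'   jointly.
#' @param seed Integer seed.
#' @return An object of class `contrastive_config`.
#' @export
contrastive_config <- function(d_z = 32L, hidden = 64L, batch = 256L,
                               epochs = 100L, teacher_epochs = 200L,
                               lr = 1e-3, tau_min = 0.05,
                               freeze_teacher = TRUE, seed = 1L) {
  stopifnot(d_z >= 2, batch >= 1, epochs >= 1, tau_min > 0)
  structure(list(d_z = as.integer(d_z), hidden = as.integer(hidden),
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 teacher_epochs = as.integer(teacher_epochs), lr = lr,
                 tau_min = tau_min, freeze_teacher = freeze_teacher,
                 seed = as.integer(seed)),
            class = "contrastive_config")
}

#' Pretrain the clinical teacher autoencoder
#'
#' The teacher view is the encoder half of an autoencoder trained with Adam
#' to minimise mean squared reconstruction error on the (complete,
#' standardised) clinical matrix. Its bottleneck output `z_b` anchors the
#' contrastive alignment of the survey learners.
#'
#' @param X Complete numeric clinical matrix (training rows).
#' @param d_z Bottleneck dimension.
#' @param hidden Hidden width.
#' @param epochs Training epochs (full batch).
#' @param lr Adam learning rate.
#' @param activation Hidden activation; `"linear"` reduces the autoencoder
#'   to its PCA-like limit.
#' @param seed Integer seed.
#' @return An object of class `teacher_encoder` with the encoder layers and
#'   a `loss` history (first element = error before any update).
#' @export
pretrain_teacher <- function(X, d_z = 32L, hidden = 64L, epochs = 200L,
                             lr = 1e-3, activation = c("relu", "linear"),
                             seed = 1L) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  stopifnot(!anyNA(X))
  p <- ncol(X)
  with_seed(seed, {
    enc <- mlp_init(c(p, hidden, d_z))
    dec <- mlp_init(c(d_z, hidden, p))
    params <- list(enc = enc, dec = dec)
    opt <- adam_init(params)
    losses <- numeric(epochs + 1L)
    for (ep in seq_len(epochs + 1L)) {
      fe <- mlp_forward(params$enc, X, activation)
      fd <- mlp_forward(params$dec, fe$out, activation)
      R <- fd$out - X
      losses[ep] <- mean(R^2)
      if (!is.finite(losses[ep]))
        stop("non-finite reconstruction loss at epoch ", ep, call. = FALSE)
      if (ep > epochs) break
      G <- 2 * R / length(R)
      bd <- mlp_backward(params$dec, fd, G)
      be <- mlp_backward(params$enc, fe, bd$dX)
      step <- adam_step(params, list(enc = be$grads, dec = bd$grads), opt,
                        lr = lr)
      params <- step$params
      opt <- step$state
    }
    structure(list(enc = params$enc, activation = activation,
                   d_z = as.integer(d_z), loss = losses),
              class = "teacher_encoder")
  })
}

#' Encode clinical rows with a pretrained teacher
#' @param teacher A [pretrain_teacher()] result.
#' @param X Clinical matrix with the fitted number of columns.
#' @return N x `d_z` matrix `z_b`.
#' @export
encode_teacher <- function(teacher, X) {
  stopifnot(inherits(teacher, "teacher_encoder"))
  mlp_forward(teacher$enc, as.matrix(X), teacher$activation)$out
}

#' Batch-adaptive InfoNCE temperature
#'
#' The adaptive temperature network maps the batch mean of the teacher
#' embeddings through a ReLU and a linear map `W`, then through a softplus
#' plus the floor `tau_min`, yielding one strictly positive temperature per
#' batch.
#'
#' @param z_b Teacher embedding batch (n x d_z).
#' @param W Numeric weight vector of length d_z.
#' @param tau_min Temperature floor (`> 0`).
#' @return Scalar temperature `> 0`.
#' @export
batch_temperature <- function(z_b, W, tau_min = 0.05) {
  z_b <- as.matrix(z_b)
  stopifnot(nrow(z_b) >= 1, length(W) == ncol(z_b), tau_min > 0)
  pre <- sum(W * relu(colMeans(z_b)))
  softplus <- if (pre > 30) pre else log1p(exp(pre))
  softplus + tau_min
}

#' InfoNCE loss between a learner batch and the teacher batch
#'
#' Row `i` of each view is a positive pair; every other teacher row in the
#' batch is a negative. With cosine similarity `sim` and temperature `tau`,
#' the loss is the mean over rows of
#' `-log( exp(sim_ii / tau) / sum_k exp(sim_ik / tau) )`.
#'
#' @param z_x Learner embedding batch (n x d).
#' @param z_b Teacher embedding batch (n x d).
#' @param tau Temperature, `> 0`.
#' @return Scalar loss (`>= 0`; equals `log(n)` when all similarities are
#'   equal; 0 when n = 1).
#' @export
infonce_loss <- function(z_x, z_b, tau) {
  z_x <- as.matrix(z_x); z_b <- as.matrix(z_b)
  stopifnot(nrow(z_x) == nrow(z_b), ncol(z_x) == ncol(z_b), tau > 0)
  U <- l2_normalize_rows(z_x, "learner")
  V <- l2_normalize_rows(z_b, "teacher")
  S <- tcrossprod(U, V) / tau
  mean(row_logsumexp(S) - diag(S))
}

#' Combined multiview contrastive loss
#'
#' Sum of the lifestyle-vs-clinical and genetics-vs-clinical InfoNCE terms,
#' both anchored on the teacher view under the same batch temperature.
#'
#' @param z_a,z_b,z_c Lifestyle, clinical (teacher) and genetics embedding
#'   batches, row-aligned.
#' @param tau Temperature, `> 0`.
#' @return Scalar loss.
#' @export
multiview_loss <- function(z_a, z_b, z_c, tau) {
  infonce_loss(z_a, z_b, tau) + infonce_loss(z_c, z_b, tau)
}

# Gradient of one InfoNCE term wrt the learner batch and the temperature.
# Returns list(dZ, dtau, loss).
.infonce_grad <- function(z_x, z_b_unit, tau) {
  n <- nrow(z_x)
  nrm <- sqrt(rowSums(z_x^2))
  if (any(nrm == 0))
    stop("zero-norm learner embedding row", call. = FALSE)
  U <- z_x / nrm
  S <- tcrossprod(U, z_b_unit)
  P <- row_softmax(S / tau)
  loss <- mean(row_logsumexp(S / tau) - diag(S) / tau)
  Gu <- (P - diag(n)) %*% z_b_unit / (n * tau)
  dZ <- (Gu - U * rowSums(Gu * U)) / nrm
  dtau <- sum(diag(S) - rowSums(P * S)) / (n * tau^2)
  list(dZ = dZ, dtau = dtau, loss = loss)
}

#' Train the survey learners against the frozen clinical teacher
#'
#' The lifestyle and genetics learners (two identical 3-layer MLPs over the
#' graph embeddings) and the adaptive temperature network are trained
#' jointly with Adam to minimise [multiview_loss()] over mini-batches; the
#' teacher is pretrained (or supplied) and by default frozen, anchoring the
#' alignment.
#'
#' @param A_lif,A_gen Person graph embeddings from
#'   [train_graph_encoder()], row-aligned with `clinical`.
#' @param clinical Complete standardised clinical matrix (all rows).
#' @param config A [contrastive_config()].
#' @param teacher Optional pre-fitted [pretrain_teacher()] result; fitted on
#'   `train_idx` rows when `NULL`.
#' @param train_idx Rows used for training (default all rows).
#' @return List of class `mvc_model`: `stack` (encoders `enc_a`, `enc_c`,
#'   `teacher`, ATN weights `W`, `config`) and `embeddings` (`z_a`, `z_b`,
#'   `z_c` for all rows). Attributes `align_before`/`align_after` record the
#'   mean positive-pair cosine of the lifestyle view on the training rows.
#' @export
train_learners <- function(A_lif, A_gen, clinical,
                           config = contrastive_config(),
                           teacher = NULL, train_idx = NULL) {
  A_lif <- as.matrix(A_lif); A_gen <- as.matrix(A_gen)
  clinical <- as.matrix(clinical)
  stopifnot(nrow(A_lif) == nrow(clinical), nrow(A_gen) == nrow(clinical))
  if (is.null(train_idx)) train_idx <- seq_len(nrow(clinical))
  if (is.null(teacher))
    teacher <- pretrain_teacher(clinical[train_idx, , drop = FALSE],
                                d_z = config$d_z, hidden = config$hidden,
                                epochs = config$teacher_epochs,
                                lr = config$lr, seed = config$seed)
  zb_all <- encode_teacher(teacher, clinical)
  zb_unit_all <- l2_normalize_rows(zb_all, "teacher")

  with_seed(config$seed + 1L, {
    params <- list(
      enc_a = mlp_init(c(ncol(A_lif), config$hidden, config$hidden,
                         config$d_z)),
      enc_c = mlp_init(c(ncol(A_gen), config$hidden, config$hidden,
                         config$d_z)),
      W = stats::rnorm(config$d_z, sd = 0.1)
    )
    opt <- adam_init(params)

    mean_pos_cos <- function(enc, A) {
      z <- mlp_forward(enc, A[train_idx, , drop = FALSE])$out
      mean(rowSums(l2_normalize_rows(z) * zb_unit_all[train_idx, ,
                                                      drop = FALSE]))
    }
    align_before <- mean_pos_cos(params$enc_a, A_lif)

    n_tr <- length(train_idx)
    for (ep in seq_len(config$epochs)) {
      ord <- train_idx[sample.int(n_tr)]
      starts <- seq(1L, n_tr, by = config$batch)
      for (s in starts) {
        b <- ord[s:min(s + config$batch - 1L, n_tr)]
        zb <- zb_all[b, , drop = FALSE]
        zbu <- zb_unit_all[b, , drop = FALSE]
        Vb <- relu(colMeans(zb))
        pre <- sum(params$W * Vb)
        tau <- (if (pre > 30) pre else log1p(exp(pre))) + config$tau_min

        fa <- mlp_forward(params$enc_a, A_lif[b, , drop = FALSE])
        fc <- mlp_forward(params$enc_c, A_gen[b, , drop = FALSE])
        ga <- .infonce_grad(fa$out, zbu, tau)
        gc <- .infonce_grad(fc$out, zbu, tau)
        if (!is.finite(ga$loss + gc$loss))
          stop("non-finite contrastive loss at epoch ", ep, call. = FALSE)
        ba <- mlp_backward(params$enc_a, fa, ga$dZ)
        bc <- mlp_backward(params$enc_c, fc, gc$dZ)
        dW <- (ga$dtau + gc$dtau) * stats::plogis(pre) * Vb
        step <- adam_step(params,
                          list(enc_a = ba$grads, enc_c = bc$grads, W = dW),
                          opt, lr = config$lr)
        params <- step$params
        opt <- step$state
      }
    }
    align_after <- mean_pos_cos(params$enc_a, A_lif)

    z_a <- mlp_forward(params$enc_a, A_lif)$out
    z_c <- mlp_forward(params$enc_c, A_gen)$out
    out <- structure(
      list(stack = list(enc_a = params$enc_a, enc_c = params$enc_c,
                        teacher = teacher, W = params$W, config = config),
           embeddings = list(z_a = z_a, z_b = zb_all, z_c = z_c)),
      class = "mvc_model")
    attr(out, "align_before") <- align_before
    attr(out, "align_after") <- align_after
    out
  })
}
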