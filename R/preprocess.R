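#' Fit the dense-path preprocessor on training rows
#'
#' Learns, from training rows only, the statistics later applied to any
#' conforming table: per numeric feature the training mean and population
#' (divide-by-n) standard deviation for z-scoring; per categorical feature
#' the declared-level one-hot map. A zero-variance numeric feature gets its
#' standard deviation replaced by 1 with a warning, so its transform is
#' identically zero.
#'
#' @param train A [cohort_table()] of training rows.
#' @param groups Feature groups to include (default all four).
#' @param k Neighbour count stored for downstream kNN imputation.
#' @return An object of class `preprocess_state`.
#' @export
fit_preprocessor <- function(train, groups = c("D", "C", "S_lif", "S_gen"),
                             k = 5L) {
  stopifnot(inherits(train, "cohort_table"), nrow(train$data) > 0)
  sch <- train$schema
  feats <- sch$features[sch$features$group %in% groups, , drop = FALSE]
  num_stats <- list()
  for (i in which(feats$kind == "numeric")) {
    nm <- feats$name[i]
    v <- train$data[[nm]][!train$mask[, nm]]
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    if (!is.finite(sd_pop) || sd_pop == 0) {
      warning("zero-variance numeric feature '", nm,
              "': sd replaced by 1", call. = FALSE)
      sd_pop <- 1
    }
    num_stats[[nm]] <- c(mean = mu, sd = sd_pop)
  }
  structure(list(features = feats, levels = sch$levels[
                   feats$name[feats$kind == "categorical"]],
                 num_stats = num_stats, k = as.integer(k)),
            class = "preprocess_state")
}

#' Transform a cohort table to a dense numeric matrix
#'
#' Numeric cells are z-scored with the stored training statistics;
#' categorical cells are one-hot encoded in declared level order. Missing
#' cells propagate as `NA` across their whole column block (imputation is a
#' separate step, [knn_impute()]). A level unseen by the fitted state maps to
#' an all-zero block with a warning.
#'
#' @param state A [fit_preprocessor()] result.
#' @param table A [cohort_table()] conforming to the fitted schema.
#' @return Numeric matrix, one row per person, with a `blocks` attribute
#'   (list of per-feature column indices and type) used by [knn_impute()].
#' @export
transform_cohort <- function(state, table) {
  stopifnot(inherits(state, "preprocess_state"), inherits(table, "cohort_table"))
  n <- nrow(table$data)
  cols <- list()
  blocks <- list()
  for (i in seq_len(nrow(state$features))) {
    nm <- state$features$name[i]
    if (!nm %in% colnames(table$data))
      stop("table lacks fitted feature '", nm, "'", call. = FALSE)
    miss <- table$mask[, nm]
    if (state$features$kind[i] == "numeric") {
      st <- state$num_stats[[nm]]
      z <- (as.numeric(table$data[[nm]]) - st["mean"]) / st["sd"]
      z[miss] <- NA
      block <- matrix(z, n, 1, dimnames = list(NULL, nm))
      type <- "numeric"
    } else {
      lv <- state$levels[[nm]]
      vals <- as.character(table$data[[nm]])
      unseen <- !is.na(vals) & !(vals %in% lv)
      if (any(unseen)) {
        warning("unseen level '", vals[unseen][1], "' for '", nm,
                "': encoded as all-zero block", call. = FALSE)
      }
      block <- matrix(0, n, length(lv),
                      dimnames = list(NULL, paste0(nm, "=", lv)))
      hit <- match(vals, lv)
      ok <- !is.na(hit)
      block[cbind(which(ok), hit[ok])] <- 1
      block[miss, ] <- NA
      type <- "onehot"
    }
    blocks[[nm]] <- list(type = type)
    cols[[nm]] <- block
  }
  M <- do.call(cbind, cols)
  at <- 0L
  for (nm in names(cols)) {
    blocks[[nm]]$cols <- at + seq_len(ncol(cols[[nm]]))
    at <- at + ncol(cols[[nm]])
  }
  attr(M, "blocks") <- blocks
  M
}

#' k-nearest-neighbour imputation of a dense matrix
#'
#' Each missing cell is replaced using the `k` donor rows nearest by
#' (unscaled) Euclidean distance over the features observed in both rows,
#' restricted to donors that observe the target cell: numeric cells take the
#' donor mean, one-hot blocks take the donor mode re-encoded as a valid
#' indicator. Ties in distance resolve toward earlier donor rows.
#'
#' @param M Numeric matrix with `NA` holes (a [transform_cohort()] output).
#' @param k Neighbour count, `>= 1`.
#' @param blocks Optional block structure; defaults to `attr(M, "blocks")`,
#'   else every column is its own numeric block.
#' @param donors Donor matrix with identical columns (default `M` itself);
#'   pass the training matrix to impute test rows from training rows.
#' @return A complete matrix of the same shape as `M`.
#' @export
knn_impute <- function(M, k = 5L, blocks = NULL, donors = M) {
  stopifnot(k >= 1, ncol(M) == ncol(donors))
  if (is.null(blocks)) blocks <- attr(M, "blocks")
  if (is.null(blocks))
    blocks <- stats::setNames(lapply(seq_len(ncol(M)), function(j)
      list(cols = j, type = "numeric")),
      colnames(M) %||% paste0("V", seq_len(ncol(M))))
  if (!anyNA(M)) return(M)
  obs_m <- !is.na(M)
  if (any(rowSums(obs_m) == 0))
    stop("a row has all features missing: cannot impute", call. = FALSE)
  obs_d <- !is.na(donors)
  Mz <- M; Mz[!obs_m] <- 0
  Dz <- donors; Dz[!obs_d] <- 0
  need <- which(rowSums(obs_m) < ncol(M))
  # squared distance over mutually observed features, all pairs at once
  D2 <- (Mz[need, , drop = FALSE]^2) %*% t(obs_d) +
    obs_m[need, , drop = FALSE] %*% t(Dz^2) -
    2 * Mz[need, , drop = FALSE] %*% t(Dz)
  D2[D2 < 0] <- 0
  out <- M
  for (r in seq_along(need)) {
    i <- need[r]
    ord <- order(D2[r, ])
    for (nm in names(blocks)) {
      bc <- blocks[[nm]]$cols
      if (!anyNA(M[i, bc])) next
      donors_ok <- ord[obs_d[ord, bc[1]]]
      if (identical(donors, M)) donors_ok <- setdiff(donors_ok, i)
      if (length(donors_ok) < k)
        stop("fewer than k=", k, " donor rows observe feature '", nm, "'",
             call. = FALSE)
      nb <- donors_ok[seq_len(k)]
      if (blocks[[nm]]$type == "numeric") {
        out[i, bc] <- mean(donors[nb, bc])
      } else {
        freq <- colSums(donors[nb, bc, drop = FALSE])
        ind <- rep(0, length(bc))
        ind[which.max(freq)] <- 1
        out[i, bc] <- ind
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse-frequency class weights
#'
#' The standard balanced scheme `w_c = N / (K * n_c)` with `K` the number of
#' classes, so that the weighted class frequencies satisfy
#' `sum_c w_c * n_c = N`.
#'
#' @param labels Factor or vector of class labels.
#' @param classes Optional explicit class set; every class must be present in
#'   `labels`.
#' @return Named numeric vector of weights, one per class.
#' @export
compute_class_weights <- function(labels, classes = NULL) {
  labels <- as.factor(labels)
  if (is.null(classes)) classes <- levels(labels)
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0))
    stop("class absent from labels: '",
         names(counts)[counts == 0][1], "'", call. = FALSE)
  N <- length(labels)
  K <- length(classes)
  stats::setNames(as.numeric(N / (K * counts)), classes)
}
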