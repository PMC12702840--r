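#' Build a person-feature bipartite graph for one survey view
#'
#' Persons form one node set; every coded value (feature, level) of the
#' group's features forms the other. A person is linked to the feature-value
#' node matching their observed value; missing cells create no edge, so a
#' fully missing person is an isolated node (retained -- the triplet sampler
#' then uses the node itself as its positive). Numeric survey features are
#' quantile-binned into `numeric_bins` categories first, so every
#' feature-value node is a coded category; all edge weights are 1.
#'
#' @param table A [cohort_table()].
#' @param group `"S_lif"` or `"S_gen"`.
#' @param numeric_bins Number of quantile bins for numeric survey features.
#' @return An object of class `bipartite_graph`: `n_person`, `fv` (data
#'   frame: feature, level), `edges` (person, fv, weight), `group`.
#' @export
build_graph <- function(table, group = c("S_lif", "S_gen"),
                        numeric_bins = 4L) {
  stopifnot(inherits(table, "cohort_table"))
  group <- match.arg(group)
  sch <- table$schema
  feats <- sch$features[sch$features$group == group, , drop = FALSE]
  if (nrow(feats) == 0) stop("empty feature group: ", group, call. = FALSE)
  n <- nrow(table$data)
  fv_rows <- list()
  edge_rows <- list()
  at <- 0L
  for (i in seq_len(nrow(feats))) {
    nm <- feats$name[i]
    if (feats$kind[i] == "categorical") {
      lv <- sch$levels[[nm]]
      code <- as.integer(table$data[[nm]])     # NA for missing
    } else {
      v <- as.numeric(table$data[[nm]])
      br <- unique(stats::quantile(v, probs = seq(0, 1, length.out =
        numeric_bins + 1), na.rm = TRUE, names = FALSE))
      if (length(br) < 2) br <- c(br, br + 1)
      code <- as.integer(cut(v, breaks = br, include.lowest = TRUE))
      lv <- paste0("bin", seq_len(length(br) - 1L))
    }
    J <- length(lv)
    fv_rows[[nm]] <- data.frame(feature = nm, level = lv,
                                stringsAsFactors = FALSE)
    ok <- which(!is.na(code))
    edge_rows[[nm]] <- data.frame(person = ok, fv = at + code[ok], weight = 1)
    at <- at + J
  }
  structure(list(n_person = n,
                 fv = do.call(rbind, c(fv_rows, make.row.names = FALSE)),
                 edges = do.call(rbind, c(edge_rows, make.row.names = FALSE)),
                 group = group),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("<bipartite_graph ", x$group, "> ", x$n_person, " persons, ",
      nrow(x$fv), " feature-value nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

# Node indexing: persons 1..N, then feature-value nodes N+1..N+F.
graph_n_nodes <- function(graph) graph$n_person + nrow(graph$fv)

# Sparse symmetric adjacency over the full node set, then row-normalised so
# that A %*% H is weighted mean aggregation over neighbours.
graph_adjacency <- function(graph) {
  n_nodes <- graph_n_nodes(graph)
  i <- c(graph$edges$person, graph$edges$fv + graph$n_person)
  j <- c(graph$edges$fv + graph$n_person, graph$edges$person)
  A <- Matrix::sparseMatrix(i = i, j = j, x = rep(graph$edges$weight, 2),
                            dims = c(n_nodes, n_nodes))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / pmax(deg, 1)) %*% A
}

# Person -> neighbour (feature-value node) list, global node indices.
graph_neighbors <- function(graph) {
  nb <- split(graph$edges$fv + graph$n_person, graph$edges$person)
  out <- vector("list", graph$n_person)
  out[as.integer(names(nb))] <- nb
  out
}

#' Sample an (anchor, positive, negative) triplet
#'
#' The positive is a uniform draw from the anchor's neighbours, or the
#' anchor itself if it has none; the negative is a uniform draw from all
#' nodes that are neither the anchor nor one of its neighbours.
#'
#' @param graph A [build_graph()] result.
#' @param anchor Person node index (1-based).
#' @return Integer vector `c(a, p, n)` of global node indices. Draws come
#'   from the current RNG stream.
#' @export
sample_triplet <- function(graph, anchor) {
  stopifnot(anchor >= 1, anchor <= graph$n_person)
  nbrs <- graph$edges$fv[graph$edges$person == anchor] + graph$n_person
  p <- if (length(nbrs) == 0) anchor else nbrs[sample.int(length(nbrs), 1)]
  n_nodes <- graph_n_nodes(graph)
  forbidden <- c(anchor, nbrs)
  if (length(forbidden) >= n_nodes)
    stop("no valid negative: anchor neighbours every other node",
         call. = FALSE)
  repeat {
    neg <- sample.int(n_nodes, 1)
    if (!neg %in% forbidden) break
  }
  c(a = anchor, p = p, n = neg)
}

#' Triplet margin loss
#'
#' `max(0, d(f_a, f_p) - d(f_a, f_n) + alpha)` with Euclidean `d`: the
#' anchor is pulled within margin `alpha` closer to the positive than to the
#' negative.
#'
#' @param f_a,f_p,f_n Embedding vectors of equal length.
#' @param alpha Margin, `> 0`.
#' @return Scalar loss.
#' @export
triplet_loss <- function(f_a, f_p, f_n, alpha = 0.5) {
  if (length(f_a) != length(f_p) || length(f_a) != length(f_n))
    stop("triplet embedding dimensions differ", call. = FALSE)
  stopifnot(alpha > 0)
  max(0, sqrt(sum((f_a - f_p)^2)) - sqrt(sum((f_a - f_n)^2)) + alpha)
}

#' Graph encoder configuration
#'
#' @param d_g Embedding dimension (`>= 2`).
#' @param alpha Triplet margin (`> 0`).
#' @param epochs Training epochs.
#' @param negatives Negative samples per anchor per epoch.
#' @param lr Adam learning rate.
#' @param seed Integer seed.
#' @return An object of class `triplet_config`.
#' @export
triplet_config <- function(d_g = 32L, alpha = 0.5, epochs = 50L,
                           negatives = 1L, lr = 1e-2, seed = 1L) {
  stopifnot(d_g >= 2, alpha > 0, epochs >= 1, negatives >= 1)
  structure(list(d_g = as.integer(d_g), alpha = alpha,
                 epochs = as.integer(epochs), negatives = as.integer(negatives),
                 lr = lr, seed = as.integer(seed)),
            class = "triplet_config")
}

# Initial node features: each feature-value node carries its own identity
# one-hot (injective over coded values, so two levels of the same feature
# stay distinguishable through aggregation -- a person's first-layer
# neighbourhood mean is then exactly their observed level distribution);
# person nodes carry a single normalised-degree summary column.
graph_node_features <- function(graph) {
  n_fv <- nrow(graph$fv)
  n_feat <- length(unique(graph$fv$feature))
  X <- matrix(0, graph_n_nodes(graph), n_fv + 1L)
  X[cbind(graph$n_person + seq_len(n_fv), seq_len(n_fv))] <- 1
  deg <- tabulate(graph$edges$person, graph$n_person)
  X[seq_len(graph$n_person), n_fv + 1L] <- deg / n_feat
  X
}

#' Train the neighbourhood-aggregating graph encoder
#'
#' A 2-layer mean-aggregation encoder in the GraphSAGE style: each layer
#' concatenates a node's representation with the weighted mean of its
#' neighbours' and applies a dense map (ReLU after the first layer). Trained
#' full-batch with Adam to minimise the mean [triplet_loss()] over one
#' sampled triplet set per person per epoch.
#'
#' @param graph A [build_graph()] result.
#' @param config A [triplet_config()].
#' @return N x `d_g` matrix of person embeddings, row-aligned with the
#'   cohort; attribute `"loss"` holds the per-epoch mean triplet loss and
#'   attribute `"fv_embeddings"` the feature-value node embeddings.
#' @export
train_graph_encoder <- function(graph, config = triplet_config()) {
  stopifnot(inherits(graph, "bipartite_graph"),
            inherits(config, "triplet_config"))
  A <- graph_adjacency(graph)
  X <- graph_node_features(graph)
  n_nodes <- nrow(X)
  N <- graph$n_person
  nbrs <- graph_neighbors(graph)
  d_in <- ncol(X)
  d_h <- max(config$d_g, 16L)

  with_seed(config$seed, {
    layers <- list(
      l1 = mlp_init(c(2L * d_in, d_h))[[1]],
      l2 = mlp_init(c(2L * d_h, config$d_g))[[1]]
    )
    opt <- adam_init(layers)
    losses <- numeric(config$epochs)
    AX <- as.matrix(A %*% X)

    sample_epoch <- function() {
      # vectorised triplet draws: one positive + `negatives` negatives/anchor
      pos <- vapply(seq_len(N), function(i) {
        nb <- nbrs[[i]]
        if (is.null(nb) || length(nb) == 0) i
        else nb[sample.int(length(nb), 1)]
      }, 1L)
      anc <- rep(seq_len(N), config$negatives)
      pos <- rep(pos, config$negatives)
      neg <- sample.int(n_nodes, length(anc), replace = TRUE)
      for (t in seq_along(anc)) {
        while (neg[t] == anc[t] || neg[t] %in% nbrs[[anc[t]]])
          neg[t] <- sample.int(n_nodes, 1)
      }
      cbind(anc, pos, neg)
    }

    for (ep in seq_len(config$epochs)) {
      In1 <- cbind(X, AX)
      P1 <- In1 %*% layers$l1$W
      P1 <- sweep(P1, 2, layers$l1$b, "+")
      H1 <- relu(P1)
      AH1 <- as.matrix(A %*% H1)
      In2 <- cbind(H1, AH1)
      Z <- In2 %*% layers$l2$W
      Z <- sweep(Z, 2, layers$l2$b, "+")

      tri <- sample_epoch()
      m <- nrow(tri)
      dap_v <- Z[tri[, 1], , drop = FALSE] - Z[tri[, 2], , drop = FALSE]
      dan_v <- Z[tri[, 1], , drop = FALSE] - Z[tri[, 3], , drop = FALSE]
      dap <- sqrt(rowSums(dap_v^2))
      dan <- sqrt(rowSums(dan_v^2))
      viol <- dap - dan + config$alpha
      losses[ep] <- mean(pmax(0, viol))
      if (!is.finite(losses[ep]))
        stop("non-finite triplet loss at epoch ", ep, call. = FALSE)
      act <- which(viol > 0)
      G <- matrix(0, n_nodes, config$d_g)
      if (length(act)) {
        uap <- dap_v[act, , drop = FALSE] / pmax(dap[act], 1e-12)
        uan <- dan_v[act, , drop = FALSE] / pmax(dan[act], 1e-12)
        contrib <- rbind(uap - uan, -uap, uan) / m
        idx <- c(tri[act, 1], tri[act, 2], tri[act, 3])
        agg <- rowsum(contrib, idx)
        G[as.integer(rownames(agg)), ] <- G[as.integer(rownames(agg)), ] + agg
      }
      # backprop: Z = [H1, A H1] W2 + b2
      gW2 <- crossprod(In2, G)
      gb2 <- colSums(G)
      GH1 <- tcrossprod(G, layers$l2$W[seq_len(d_h), , drop = FALSE]) +
        as.matrix(Matrix::crossprod(A,
          tcrossprod(G, layers$l2$W[d_h + seq_len(d_h), , drop = FALSE])))
      GH1 <- GH1 * (P1 > 0)
      gW1 <- crossprod(In1, GH1)
      gb1 <- colSums(GH1)
      step <- adam_step(layers,
                        list(l1 = list(W = gW1, b = gb1),
                             l2 = list(W = gW2, b = gb2)),
                        opt, lr = config$lr)
      layers <- step$params
      opt <- step$state
    }
    # final forward
    In1 <- cbind(X, AX)
    H1 <- relu(sweep(In1 %*% layers$l1$W, 2, layers$l1$b, "+"))
    In2 <- cbind(H1, as.matrix(A %*% H1))
    Z <- sweep(In2 %*% layers$l2$W, 2, layers$l2$b, "+")
    emb <- Z[seq_len(N), , drop = FALSE]
    attr(emb, "loss") <- losses
    attr(emb, "fv_embeddings") <- Z[N + seq_len(nrow(graph$fv)), ,
                                    drop = FALSE]
    emb
  })
}

#' Export a graph as an edge-list TSV
#'
#' Columns: `person_id`, `feature`, `level`, `weight`.
#'
#' @param graph A [build_graph()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(graph, path) {
  out <- data.frame(person_id = graph$edges$person,
                    feature = graph$fv$feature[graph$edges$fv],
                    level = graph$fv$level[graph$edges$fv],
                    weight = graph$edges$weight)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
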