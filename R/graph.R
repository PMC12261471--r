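#' Build the heterogeneous drug-target interaction graph
#'
#' Nodes are drugs and targets; message-passing edges are the positive
#' *training* interactions only, so validation and test supervision edges
#' never influence propagation (no label leakage). Supervision edges are the
#' labeled pairs partitioned into train/val/test.
#'
#' @param pairs Data frame with columns `drug_id`, `target_id`, `label`
#'   (0/1) and `partition` (`"train"`, `"val"`, `"test"`).
#' @param drug_ids,target_ids Character vectors of all node ids (defaults:
#'   the ids appearing in `pairs`).
#' @return A `dti_graph`: node id vectors, the message-edge data frame, the
#'   supervision partitions, and row-normalized neighbor-mean operators
#'   `M_dt` (drugs x targets) and `M_td` (targets x drugs). Isolated nodes
#'   have all-zero rows (their neighbor mean is the zero vector).
#' @export
build_graph <- function(pairs, drug_ids = NULL, target_ids = NULL) {
  need <- c("drug_id", "target_id", "label", "partition")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  pairs <- pairs[pairs$partition != "unused", , drop = FALSE]
  if (!all(pairs$partition %in% c("train", "val", "test"))) {
    stop("partition must be train/val/test (or unused)", call. = FALSE)
  }
  if (is.null(drug_ids)) drug_ids <- sort(unique(pairs$drug_id))
  if (is.null(target_ids)) target_ids <- sort(unique(pairs$target_id))
  dangling_d <- setdiff(pairs$drug_id, drug_ids)
  dangling_t <- setdiff(pairs$target_id, target_ids)
  if (length(dangling_d) || length(dangling_t)) {
    stop("supervision edges reference unknown ids: ",
         paste(utils::head(c(dangling_d, dangling_t), 5), collapse = ", "),
         call. = FALSE)
  }
  msg <- pairs[pairs$partition == "train" & pairs$label == 1,
               c("drug_id", "target_id"), drop = FALSE]
  nd <- length(drug_ids); nt <- length(target_ids)
  A <- matrix(0, nd, nt, dimnames = list(drug_ids, target_ids))
  if (nrow(msg)) A[cbind(match(msg$drug_id, drug_ids),
                         match(msg$target_id, target_ids))] <- 1
  deg_d <- rowSums(A); deg_t <- colSums(A)
  M_dt <- A / ifelse(deg_d > 0, deg_d, 1); M_dt[deg_d == 0, ] <- 0
  M_td <- t(A) / ifelse(deg_t > 0, deg_t, 1); M_td[deg_t == 0, ] <- 0
  structure(list(
    drug_ids = drug_ids, target_ids = target_ids,
    message_edges = msg,
    supervision = split(pairs, pairs$partition),
    M_dt = M_dt, M_td = M_td
  ), class = "dti_graph")
}

#' @export
print.dti_graph <- function(x, ...) {
  sizes <- vapply(x$supervision, nrow, integer(1))
  cat(sprintf(paste0("Heterogeneous DTI graph: %d drugs, %d targets, ",
                     "%d message edges\n"),
              length(x$drug_ids), length(x$target_ids), nrow(x$message_edges)))
  cat("supervision edges:", paste(names(sizes), sizes, collapse = ", "), "\n")
  invisible(x)
}

# ---- parameter initialization ----------------------------------------------

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

sage_layer_params <- function(nin, nout) {
  list(W_self = glorot(nin, nout), W_nbr = glorot(nin, nout),
       b = numeric(nout),
       bn_gamma = rep(1, nout), bn_beta = numeric(nout))
}

init_model_params <- function(dims, seed) {
  withr::with_seed(seed, {
    latent <- dims$latent
    list(
      head_dl = projection_head(dims$drug_llm, latent, latent,
                                seed = sample.int(1e8, 1)),
      head_dt = projection_head(dims$drug_topo, latent, latent,
                                seed = sample.int(1e8, 1)),
      head_tl = projection_head(dims$target_llm, latent, latent,
                                seed = sample.int(1e8, 1)),
      head_tt = projection_head(dims$target_topo, latent, latent,
                                seed = sample.int(1e8, 1)),
      gate_d = fusion_gate(latent),
      gate_t = fusion_gate(latent),
      gnn = list(
        d1 = sage_layer_params(latent, dims$gnn[1]),
        t1 = sage_layer_params(latent, dims$gnn[1]),
        d2 = sage_layer_params(dims$gnn[1], dims$gnn[2]),
        t2 = sage_layer_params(dims$gnn[1], dims$gnn[2])
      ),
      mlp = list(W1 = glorot(2 * dims$gnn[2], dims$mlp),
                 b1 = numeric(dims$mlp),
                 W2 = glorot(dims$mlp, 1L), b2 = numeric(1))
    )
  })
}

init_bn_state <- function(dims) {
  z <- function(w) list(mean = numeric(w), var = rep(1, w))
  list(d1 = z(dims$gnn[1]), t1 = z(dims$gnn[1]),
       d2 = z(dims$gnn[2]), t2 = z(dims$gnn[2]))
}

# ---- forward / backward pieces ---------------------------------------------

head_forward <- function(x, head) {
  z1 <- sweep(x %*% head$W1, 2, head$b1, "+")
  h1 <- relu(z1)
  z2 <- sweep(h1 %*% head$W2, 2, head$b2, "+")
  list(out = relu(z2), x = x, z1 = z1, h1 = h1, z2 = z2)
}

head_backward <- function(dout, cache, head) {
  dz2 <- dout * (cache$z2 > 0)
  dW2 <- crossprod(cache$h1, dz2); db2 <- colSums(dz2)
  dh1 <- dz2 %*% t(head$W2)
  dz1 <- dh1 * (cache$z1 > 0)
  dW1 <- crossprod(cache$x, dz1); db1 <- colSums(dz1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dx = dz1 %*% t(head$W1))
}

bn_forward <- function(x, gamma, beta, state, train, momentum, eps) {
  if (train && nrow(x) > 1) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
  }
  xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, var = v, state = state,
       batch = train && nrow(x) > 1)
}

bn_backward <- function(dout, cache, gamma, eps) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  inv_sd <- 1 / sqrt(cache$var + eps)
  if (cache$batch) {
    n <- nrow(dout)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dx <- sweep(t1 - t2, 2, inv_sd, "*")
  } else {
    dx <- sweep(dxhat, 2, inv_sd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

sage_forward <- function(h_self, h_other, M, lp, bn_state, train, control,
                         drop_mask = NULL) {
  m <- M %*% h_other
  z <- sweep(h_self %*% lp$W_self + m %*% lp$W_nbr, 2, lp$b, "+")
  bn <- bn_forward(z, lp$bn_gamma, lp$bn_beta, bn_state, train,
                   control$bn_momentum, control$bn_eps)
  a <- relu(bn$out)
  if (train && control$dropout > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(stats::runif(length(a)) >= control$dropout,
                          nrow(a), ncol(a))
    }
    out <- a * drop_mask / (1 - control$dropout)
  } else {
    drop_mask <- NULL
    out <- a
  }
  list(out = out, h_self = h_self, h_other = h_other, m = m, bn = bn,
       bn_out = bn$out, a = a, drop_mask = drop_mask, state = bn$state)
}

sage_backward <- function(dout, cache, lp, M, control) {
  if (!is.null(cache$drop_mask)) {
    dout <- dout * cache$drop_mask / (1 - control$dropout)
  }
  dbn_out <- dout * (cache$bn_out > 0)
  bnb <- bn_backward(dbn_out, cache$bn, lp$bn_gamma, control$bn_eps)
  dz <- bnb$dx
  g <- list(W_self = crossprod(cache$h_self, dz),
            W_nbr = crossprod(cache$m, dz),
            b = colSums(dz),
            bn_gamma = bnb$dgamma, bn_beta = bnb$dbeta)
  dm <- dz %*% t(lp$W_nbr)
  list(grads = g,
       dh_self = dz %*% t(lp$W_self),
       dh_other = crossprod(M, dm))
}

#' Two-layer heterogeneous mean-aggregation GNN forward pass
#'
#' Each layer computes, per node type, `relu(BN(h W_self + mean_nbr W_nbr +
#' b))` with separate weights for the drug-to-target and target-to-drug
#' directions, followed by dropout in training mode. Isolated nodes see a
#' zero neighbor mean and depend only on their own features. Evaluation mode
#' uses the running batch-norm statistics and is deterministic.
#'
#' @param graph A `dti_graph`.
#' @param params Model parameter list (element `gnn`) from the trained model
#'   or [init_model_params()] internals.
#' @param features List with `drug` and `target` feature matrices (rows in
#'   the graph's node order).
#' @param bn_state Batch-norm running statistics (defaults to fresh state).
#' @param train_mode Logical; enables batch statistics and dropout.
#' @param control Hyperparameters from [topofuse_control()].
#' @return List with embedding matrices `drug`, `target` (and caches/state,
#'   used internally).
#' @export
gnn_forward <- function(graph, params, features, bn_state = NULL,
                        train_mode = FALSE, control = topofuse_control()) {
  if (is.null(bn_state)) {
    dims <- list(gnn = c(ncol(params$d1$W_self), ncol(params$d2$W_self)))
    bn_state <- init_bn_state(dims)
  }
  c1d <- sage_forward(features$drug, features$target, graph$M_dt, params$d1,
                      bn_state$d1, train_mode, control)
  c1t <- sage_forward(features$target, features$drug, graph$M_td, params$t1,
                      bn_state$t1, train_mode, control)
  c2d <- sage_forward(c1d$out, c1t$out, graph$M_dt, params$d2,
                      bn_state$d2, train_mode, control)
  c2t <- sage_forward(c1t$out, c1d$out, graph$M_td, params$t2,
                      bn_state$t2, train_mode, control)
  bn_state <- list(d1 = c1d$state, t1 = c1t$state,
                   d2 = c2d$state, t2 = c2t$state)
  list(drug = c2d$out, target = c2t$out,
       cache = list(c1d = c1d, c1t = c1t, c2d = c2d, c2t = c2t),
       bn_state = bn_state)
}

#' Score drug-target pairs with the MLP head
#'
#' Concatenates each pair's drug and target embeddings and applies the
#' two-layer MLP with a logistic output, returning interaction
#' probabilities strictly inside (0, 1).
#'
#' @param embeddings List with matrices `drug`, `target` (rownames = ids).
#' @param pairs Data frame with `drug_id`, `target_id`.
#' @param classifier MLP weights (`W1`, `b1`, `W2`, `b2`).
#' @return Numeric vector of probabilities, one per pair.
#' @export
predict_pairs <- function(embeddings, pairs, classifier) {
  di <- match(pairs$drug_id, rownames(embeddings$drug))
  ti <- match(pairs$target_id, rownames(embeddings$target))
  if (anyNA(di) || anyNA(ti)) {
    bad <- unique(c(pairs$drug_id[is.na(di)], pairs$target_id[is.na(ti)]))
    stop("unknown ids in pairs: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- cbind(embeddings$drug[di, , drop = FALSE],
             embeddings$target[ti, , drop = FALSE])
  z1 <- relu(sweep(x %*% classifier$W1, 2, classifier$b1, "+"))
  unname(drop(sigmoid(sweep(z1 %*% classifier$W2, 2, classifier$b2, "+"))))
}
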