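#' Training hyperparameters
#'
#' @param latent Shared latent width after projection (default 512).
#' @param gnn_hidden Widths of the two GNN layers (default `c(256, 128)`).
#' @param mlp_hidden Hidden width of the pair classifier (default 64).
#' @param dropout Dropout rate applied after each GNN layer in training
#'   mode (default 0.2).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Supervision-edge minibatch size (default 512). Each
#'   epoch is one shuffled pass over the training pairs in batches of this
#'   size, with a full-graph forward and one Adam step per batch;
#'   `Inf` gives single-step full-batch epochs.
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience: training stops once the
#'   validation loss has failed to improve for this many consecutive epochs
#'   (default 5); the best-validation parameters are restored.
#' @param bn_momentum,bn_eps Batch-norm running-statistics momentum and
#'   numerical epsilon. Training is full-graph (one batch = all nodes of a
#'   type), so the default momentum of 1 stores the statistics of the
#'   latest training pass for evaluation; values below 1 blend in earlier
#'   passes, which lags the current parameters and distorts early
#'   validation losses.
#' @param threshold Classification threshold used for sensitivity and
#'   specificity (default 0.5).
#' @param verbose Print a line per epoch.
#' @return List of settings, class `topofuse_control`.
#' @export
topofuse_control <- function(latent = 512L, gnn_hidden = c(256L, 128L),
                             mlp_hidden = 64L, dropout = 0.2, lr = 1e-3,
                             batch_size = 512L,
                             max_epochs = 100L, patience = 5L,
                             bn_momentum = 1, bn_eps = 1e-5,
                             threshold = 0.5, verbose = FALSE) {
  stopifnot(dropout >= 0, dropout < 1, length(gnn_hidden) == 2)
  structure(list(latent = as.integer(latent),
                 gnn_hidden = as.integer(gnn_hidden),
                 mlp_hidden = as.integer(mlp_hidden),
                 dropout = dropout, lr = lr, batch_size = batch_size,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 threshold = threshold, verbose = verbose),
            class = "topofuse_control")
}

# early-stopping controller: feed one validation loss per epoch
es_init <- function(patience) {
  list(best = Inf, best_epoch = 0L, wait = 0L, patience = patience,
       stop = FALSE)
}

es_update <- function(state, loss) {
  if (loss < state$best) {
    state$best <- loss
    state$best_epoch <- state$best_epoch + state$wait + 1L
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

# ---- whole-model forward/backward ------------------------------------------

# X: list(drug_llm, drug_topo, target_llm, target_topo) matrices
model_forward <- function(params, X, graph, pairs, control, bn_state,
                          train_mode, fusion = "dynamic") {
  hd_l <- head_forward(X$drug_llm, params$head_dl)
  hd_t <- head_forward(X$drug_topo, params$head_dt)
  ht_l <- head_forward(X$target_llm, params$head_tl)
  ht_t <- head_forward(X$target_topo, params$head_tt)
  fuse_one <- function(fl, ft, gate) {
    switch(fusion,
           dynamic = fuse(fl, ft, gate),
           static_half = list(alpha = NULL, fused = (fl + ft) / 2),
           top_only = list(alpha = NULL, fused = ft),
           llm_only = list(alpha = NULL, fused = fl),
           stop("unknown fusion mode: ", fusion, call. = FALSE))
  }
  fd <- fuse_one(hd_l$out, hd_t$out, params$gate_d)
  ft <- fuse_one(ht_l$out, ht_t$out, params$gate_t)
  feats <- list(drug = fd$fused, target = ft$fused)
  g <- gnn_forward(graph, params$gnn, feats, bn_state, train_mode, control)
  emb <- list(drug = g$drug, target = g$target)
  rownames(emb$drug) <- graph$drug_ids
  rownames(emb$target) <- graph$target_ids
  di <- match(pairs$drug_id, graph$drug_ids)
  ti <- match(pairs$target_id, graph$target_ids)
  xc <- cbind(g$drug[di, , drop = FALSE], g$target[ti, , drop = FALSE])
  z1 <- sweep(xc %*% params$mlp$W1, 2, params$mlp$b1, "+")
  a1 <- relu(z1)
  logit <- drop(sweep(a1 %*% params$mlp$W2, 2, params$mlp$b2, "+"))
  prob <- sigmoid(logit)
  y <- pairs$label
  eps <- 1e-12
  loss <- -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
  list(prob = prob, loss = loss, emb = emb, bn_state = g$bn_state,
       cache = list(hd_l = hd_l, hd_t = hd_t, ht_l = ht_l, ht_t = ht_t,
                    fd = fd, ft = ft, gnn = g$cache, xc = xc, z1 = z1,
                    a1 = a1, di = di, ti = ti, y = y))
}

model_backward <- function(params, fwd, graph, control, fusion = "dynamic") {
  ca <- fwd$cache
  n <- length(fwd$prob)
  dlogit <- (fwd$prob - ca$y) / n
  dW2 <- crossprod(ca$a1, matrix(dlogit)); db2 <- sum(dlogit)
  da1 <- matrix(dlogit) %*% t(params$mlp$W2)
  dz1 <- da1 * (ca$z1 > 0)
  dW1 <- crossprod(ca$xc, dz1); db1 <- colSums(dz1)
  dxc <- dz1 %*% t(params$mlp$W1)
  k <- ncol(dxc) / 2
  nd <- length(graph$drug_ids); nt <- length(graph$target_ids)
  dEd <- matrix(0, nd, k); dEt <- matrix(0, nt, k)
  dd <- rowsum(dxc[, 1:k, drop = FALSE], ca$di)
  dEd[as.integer(rownames(dd)), ] <- dd
  dt_ <- rowsum(dxc[, (k + 1):(2 * k), drop = FALSE], ca$ti)
  dEt[as.integer(rownames(dt_)), ] <- dt_

  gc2d <- sage_backward(dEd, ca$gnn$c2d, params$gnn$d2, graph$M_dt, control)
  gc2t <- sage_backward(dEt, ca$gnn$c2t, params$gnn$t2, graph$M_td, control)
  dh1d <- gc2d$dh_self + gc2t$dh_other
  dh1t <- gc2t$dh_self + gc2d$dh_other
  gc1d <- sage_backward(dh1d, ca$gnn$c1d, params$gnn$d1, graph$M_dt, control)
  gc1t <- sage_backward(dh1t, ca$gnn$c1t, params$gnn$t1, graph$M_td, control)
  dfd <- gc1d$dh_self + gc1t$dh_other
  dft <- gc1t$dh_self + gc1d$dh_other

  back_gate <- function(df, cache_f, fl, ft, gate) {
    if (fusion == "dynamic") {
      alpha <- cache_f$alpha
      dalpha <- df * (fl$out - ft$out)
      dpre <- dalpha * alpha * (1 - alpha)
      conc <- cbind(fl$out, ft$out)
      gW <- crossprod(conc, dpre); gb <- colSums(dpre)
      dconc <- dpre %*% t(gate$W)
      w <- ncol(fl$out)
      dfl <- df * alpha + dconc[, 1:w, drop = FALSE]
      dftda <- df * (1 - alpha) + dconc[, (w + 1):(2 * w), drop = FALSE]
      list(gate = list(W = gW, b = gb), dfl = dfl, dft = dftda)
    } else if (fusion == "static_half") {
      list(gate = list(W = gate$W * 0, b = gate$b * 0),
           dfl = df / 2, dft = df / 2)
    } else if (fusion == "top_only") {
      list(gate = list(W = gate$W * 0, b = gate$b * 0),
           dfl = df * 0, dft = df)
    } else {
      list(gate = list(W = gate$W * 0, b = gate$b * 0),
           dfl = df, dft = df * 0)
    }
  }
  bg_d <- back_gate(dfd, ca$fd, ca$hd_l, ca$hd_t, params$gate_d)
  bg_t <- back_gate(dft, ca$ft, ca$ht_l, ca$ht_t, params$gate_t)

  hb_dl <- head_backward(bg_d$dfl, ca$hd_l, params$head_dl)
  hb_dt <- head_backward(bg_d$dft, ca$hd_t, params$head_dt)
  hb_tl <- head_backward(bg_t$dfl, ca$ht_l, params$head_tl)
  hb_tt <- head_backward(bg_t$dft, ca$ht_t, params$head_tt)

  list(head_dl = hb_dl$grads, head_dt = hb_dt$grads,
       head_tl = hb_tl$grads, head_tt = hb_tt$grads,
       gate_d = bg_d$gate, gate_t = bg_t$gate,
       gnn = list(d1 = gc1d$grads, t1 = gc1t$grads,
                  d2 = gc2d$grads, t2 = gc2t$grads),
       mlp = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- Adam over nested parameter lists --------------------------------------

adam_init <- function(params) {
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else x * 0
  }
  list(m = walk(params), v = walk(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# ---- training --------------------------------------------------------------

#' Train the fused-feature GNN link classifier
#'
#' Full-batch training of the end-to-end model (projection heads, fusion
#' gates, two-layer heterogeneous GNN, MLP pair classifier) with binary
#' cross-entropy loss and the Adam optimizer. Validation loss is monitored
#' each epoch; training stops early once it has not improved for
#' `control$patience` consecutive epochs and the best-validation checkpoint
#' is restored. With a fixed seed the loss history is reproducible.
#'
#' @param graph A `dti_graph` from [build_graph()].
#' @param X Feature list: `drug_llm`, `drug_topo`, `target_llm`,
#'   `target_topo` matrices with rows in graph node order.
#' @param control [topofuse_control()] settings.
#' @param fusion Fusion mode: `"dynamic"`, `"static_half"`, `"top_only"` or
#'   `"llm_only"`.
#' @param seed Integer seed covering initialization and dropout.
#' @return List with trained `params`, batch-norm `bn_state`, `history`
#'   data frame (epoch, train/val loss, mean fusion weights) and
#'   `best_epoch`.
#' @export
train_model <- function(graph, X, control = topofuse_control(),
                        fusion = "dynamic", seed = 1L) {
  train_pairs <- graph$supervision$train
  if (is.null(train_pairs) || nrow(train_pairs) == 0) {
    stop("empty training split", call. = FALSE)
  }
  val_pairs <- graph$supervision$val
  dims <- list(drug_llm = ncol(X$drug_llm), drug_topo = ncol(X$drug_topo),
               target_llm = ncol(X$target_llm),
               target_topo = ncol(X$target_topo),
               latent = control$latent, gnn = control$gnn_hidden,
               mlp = control$mlp_hidden)
  params <- init_model_params(dims, seed)
  bn_state <- init_bn_state(dims)
  opt <- adam_init(params)
  es <- es_init(control$patience)
  best <- list(params = params, bn_state = bn_state, epoch = 0L)
  hist <- NULL
  set.seed(seed + 1L)  # dropout + shuffling stream
  n_train <- nrow(train_pairs)
  bs <- if (is.finite(control$batch_size)) {
    max(1L, min(as.integer(control$batch_size), n_train))
  } else n_train
  for (epoch in seq_len(control$max_epochs)) {
    # one epoch = one shuffled pass over the training pairs; every batch
    # does a full-graph forward supervised on that batch of edges
    perm <- sample.int(n_train)
    starts <- seq(1L, n_train, by = bs)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + bs - 1L, n_train)]
      fwd <- model_forward(params, X, graph, train_pairs[idx, , drop = FALSE],
                           control, bn_state, train_mode = TRUE,
                           fusion = fusion)
      bn_state <- fwd$bn_state
      grads <- model_backward(params, fwd, graph, control, fusion = fusion)
      st <- adam_step(params, grads, opt, control$lr)
      params <- st$params; opt <- st$state
      epoch_loss <- epoch_loss + fwd$loss * length(idx)
    }
    epoch_loss <- epoch_loss / n_train
    mean_ad <- if (fusion == "dynamic") mean(fwd$cache$fd$alpha) else 0.5
    mean_at <- if (fusion == "dynamic") mean(fwd$cache$ft$alpha) else 0.5
    if (!is.null(val_pairs) && nrow(val_pairs) > 0) {
      vfwd <- model_forward(params, X, graph, val_pairs, control, bn_state,
                            train_mode = FALSE, fusion = fusion)
      vloss <- vfwd$loss
    } else {
      vloss <- NA_real_
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = epoch_loss,
                                   val_loss = vloss,
                                   mean_alpha_drug = mean_ad,
                                   mean_alpha_target = mean_at))
    if (control$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch, epoch_loss,
                      formatC(vloss, format = "f", digits = 4)))
    }
    if (!is.na(vloss)) {
      improved <- vloss < es$best
      es <- es_update(es, vloss)
      if (improved) {
        best <- list(params = params, bn_state = bn_state, epoch = epoch)
      }
      if (es$stop) break
    }
  }
  if (is.null(val_pairs) || nrow(val_pairs) == 0) {
    best <- list(params = params, bn_state = bn_state,
                 epoch = nrow(hist))
  }
  list(params = best$params, bn_state = best$bn_state, history = hist,
       best_epoch = best$epoch, control = control, fusion = fusion)
}
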