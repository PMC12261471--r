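test_that("message edges are the positive training edges only", {
  g <- build_graph(toy_pairs())
  expect_equal(nrow(g$message_edges), 1L)
  expect_equal(g$message_edges$drug_id, "d1")
  # val/test edges are supervision-only: removing them leaves propagation
  # operators untouched
  g2 <- build_graph(toy_pairs()[1:2, ], drug_ids = c("d1", "d2"),
                    target_ids = c("t1", "t2"))
  expect_equal(g$M_dt, g2$M_dt)
  expect_equal(g$M_td, g2$M_td)
  # no supervision edge in val/test contributes a message edge
  sup_eval <- rbind(g$supervision$val, g$supervision$test)
  keys_eval <- paste(sup_eval$drug_id, sup_eval$target_id)
  keys_msg <- paste(g$message_edges$drug_id, g$message_edges$target_id)
  expect_length(intersect(keys_msg, keys_eval), 0L)
})

test_that("dangling ids are reported", {
  p <- toy_pairs()
  expect_error(build_graph(p, drug_ids = "d1", target_ids = c("t1", "t2")),
               "d2")
})

test_that("cold-split graphs leave held-out nodes isolated", {
  d <- tiny_dataset()
  sp <- cold_split(d$pairs, "unseen_targets", 0.2, seed = 4)
  g <- build_graph(sp, rownames(d$drug_llm), rownames(d$target_llm))
  held <- unique(sp$target_id[sp$partition == "test"])
  expect_true(all(colSums(g$M_td[held, , drop = FALSE] > 0) == 0))
  expect_true(all(rowSums(g$M_td[held, , drop = FALSE]) == 0))
})

test_that("gnn forward on an edgeless graph depends only on self features", {
  p <- toy_pairs(); p$label <- 0L   # no positive edges anywhere
  g <- build_graph(p)
  ctrl <- tiny_control()
  dims <- list(drug_llm = 8, drug_topo = 8, target_llm = 8, target_topo = 8,
               latent = 4L, gnn = c(3L, 2L), mlp = 2L)
  params <- topofuse:::init_model_params(dims, seed = 1)
  f <- list(drug = matrix(rnorm(8), 2, 4), target = matrix(rnorm(8), 2, 4))
  out1 <- gnn_forward(g, params$gnn, f, train_mode = FALSE, control = ctrl)
  # perturbing target features does not change drug embeddings (no edges)
  f2 <- f; f2$target <- f2$target + 100
  out2 <- gnn_forward(g, params$gnn, f2, train_mode = FALSE, control = ctrl)
  expect_equal(out1$drug, out2$drug)
})

test_that("neighbor mean equals the shared vector for identical neighbors", {
  p <- data.frame(drug_id = c("d1", "d1"), target_id = c("t1", "t2"),
                  label = 1L, partition = "train")
  g <- build_graph(p)
  v <- rnorm(4)
  f <- list(drug = matrix(rnorm(4), 1, 4),
            target = rbind(v, v))
  expect_equal(drop(g$M_dt %*% f$target), v)
  # permuting neighbor order leaves the aggregation unchanged
  p2 <- p[2:1, ]
  g2 <- build_graph(p2)
  expect_equal(g2$M_dt %*% f$target, g$M_dt %*% f$target)
})

test_that("pair classifier outputs probabilities; zero weights give 0.5", {
  emb <- list(drug = matrix(rnorm(8), 2, 4, dimnames = list(c("d1", "d2"))),
              target = matrix(rnorm(8), 2, 4, dimnames = list(c("t1", "t2"))))
  clf0 <- list(W1 = matrix(0, 8, 3), b1 = numeric(3),
               W2 = matrix(0, 3, 1), b2 = 0)
  pairs <- data.frame(drug_id = c("d1", "d2"), target_id = c("t2", "t1"))
  expect_equal(predict_pairs(emb, pairs, clf0), c(0.5, 0.5))
  set.seed(8)
  clf <- list(W1 = matrix(rnorm(24), 8, 3), b1 = rnorm(3),
              W2 = matrix(rnorm(3), 3, 1), b2 = 1)
  pr <- predict_pairs(emb, pairs, clf)
  expect_true(all(pr > 0 & pr < 1))
  # hand-computed toy with 1-D embeddings
  emb1 <- list(drug = matrix(2, 1, 1, dimnames = list("d1")),
               target = matrix(3, 1, 1, dimnames = list("t1")))
  clf1 <- list(W1 = matrix(c(1, -1), 2, 1), b1 = 0,
               W2 = matrix(2, 1, 1), b2 = -1)
  # concat (2,3) -> relu(2-3) = 0 -> logit -1 -> sigmoid
  expect_equal(predict_pairs(emb1, data.frame(drug_id = "d1",
                                              target_id = "t1"), clf1),
               1 / (1 + exp(1)))
  expect_error(predict_pairs(emb, data.frame(drug_id = "dX",
                                             target_id = "t1"), clf),
               "dX")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(21)
  d <- gen_dti_dataset(n_drugs = 6, n_targets = 5, latent_dim = 2,
                       density = 0.2, seed = 9)
  sp <- random_split(d$pairs, seed = 2)
  g <- build_graph(sp, rownames(d$drug_llm), rownames(d$target_llm))
  ctrl <- topofuse_control(latent = 6L, gnn_hidden = c(5L, 4L),
                           mlp_hidden = 3L, dropout = 0)  # no dropout noise
  X <- list(drug_llm = d$drug_llm, drug_topo = d$drug_topo,
            target_llm = d$target_llm, target_topo = d$target_topo)
  dims <- list(drug_llm = 768, drug_topo = 1200, target_llm = 1024,
               target_topo = 1200, latent = 6L, gnn = c(5L, 4L), mlp = 3L)
  params <- topofuse:::init_model_params(dims, seed = 5)
  # non-zero gate so gate gradients are exercised away from the symmetric
  # starting point
  params$gate_d$W <- params$gate_d$W + 0.01
  params$gate_d$b <- params$gate_d$b + 0.1
  bn <- topofuse:::init_bn_state(dims)
  train <- g$supervision$train
  loss_at <- function(p) {
    topofuse:::model_forward(p, X, g, train, ctrl, bn,
                             train_mode = TRUE)$loss
  }
  fwd <- topofuse:::model_forward(params, X, g, train, ctrl, bn,
                                  train_mode = TRUE)
  grads <- topofuse:::model_backward(params, fwd, g, ctrl)
  eps <- 1e-5
  check <- function(path, idx) {
    p1 <- params; p2 <- params
    p1[[path[1]]][[path[2]]][idx] <- p1[[path[1]]][[path[2]]][idx] + eps
    p2[[path[1]]][[path[2]]][idx] <- p2[[path[1]]][[path[2]]][idx] - eps
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    ana <- grads[[path[1]]][[path[2]]][idx]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste(paste(path, collapse = "$"), idx))
  }
  check(c("mlp", "W1"), 3); check(c("mlp", "b2"), 1)
  check(c("gate_d", "b"), 2); check(c("gate_d", "W"), 10)
  check(c("head_dl", "W1"), 5); check(c("head_tt", "b2"), 4)
  # GNN layer params are nested one level deeper
  for (leaf in list(c("d1", "W_self"), c("t1", "W_nbr"),
                    c("d2", "bn_gamma"), c("t2", "b"))) {
    p1 <- params; p2 <- params
    p1$gnn[[leaf[1]]][[leaf[2]]][2] <- p1$gnn[[leaf[1]]][[leaf[2]]][2] + eps
    p2$gnn[[leaf[1]]][[leaf[2]]][2] <- p2$gnn[[leaf[1]]][[leaf[2]]][2] - eps
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    ana <- grads$gnn[[leaf[1]]][[leaf[2]]][2]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste("gnn", leaf[1], leaf[2]))
  }
})
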