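#' Fit the topological-fusion drug-target interaction model
#'
#' The main model fitter. Projects sequence embeddings and topological
#' feature vectors of every drug and target into a shared latent space,
#' fuses the two modalities per entity through a learnable sigmoid gate,
#' propagates the fused node features through a two-layer heterogeneous
#' mean-aggregation GNN over the positive training interactions, and scores
#' candidate pairs with an MLP. Trained end-to-end with binary
#' cross-entropy, Adam, and validation-loss early stopping.
#'
#' @param data A dataset list as produced by [gen_dti_dataset()] or
#'   assembled from the readers: elements `pairs` (data frame `drug_id`,
#'   `target_id`, `label`), `drug_llm`, `target_llm` (sequence embedding
#'   matrices, rownames = ids), `drug_topo`, `target_topo` (topological
#'   feature matrices, rownames = ids).
#' @param split `data$pairs` with a `partition` column, from
#'   [random_split()] or [cold_split()]. Defaults to a seeded random
#'   70/10/20 split.
#' @param fusion Fusion mode, see [fuse_variant()].
#' @param control Hyperparameters from [topofuse_control()].
#' @param seed Integer seed for initialization and dropout.
#' @return An object of class `topofuse` with the trained parameters,
#'   training history (losses and mean fusion weights per epoch), the
#'   evaluation-mode node embeddings, and test-set predictions and metrics.
#' @seealso [predict.topofuse()], [alpha_trace()], [run_experiment()]
#' @export
topofuse <- function(data, split = NULL, fusion = "dynamic",
                     control = topofuse_control(), seed = 1L) {
  data <- validate_dti_data(data)
  if (is.null(split)) split <- random_split(data$pairs, seed = seed)
  drug_ids <- rownames(data$drug_llm)
  target_ids <- rownames(data$target_llm)
  graph <- build_graph(split, drug_ids, target_ids)
  X <- list(drug_llm = data$drug_llm,
            drug_topo = data$drug_topo[drug_ids, , drop = FALSE],
            target_llm = data$target_llm,
            target_topo = data$target_topo[target_ids, , drop = FALSE])
  tr <- train_model(graph, X, control = control, fusion = fusion,
                    seed = seed)
  # evaluation-mode embeddings and test metrics from the restored checkpoint
  test_pairs <- graph$supervision$test
  eval_pairs <- if (!is.null(test_pairs) && nrow(test_pairs)) test_pairs
                else graph$supervision$train
  fwd <- model_forward(tr$params, X, graph, eval_pairs, control,
                       tr$bn_state, train_mode = FALSE, fusion = fusion)
  metrics <- if (length(unique(eval_pairs$label)) == 2L) {
    compute_metrics(fwd$prob, eval_pairs$label, control$threshold)
  } else NULL
  trainfwd <- model_forward(tr$params, X, graph, graph$supervision$train,
                            control, tr$bn_state, train_mode = FALSE,
                            fusion = fusion)
  structure(list(
    params = tr$params, bn_state = tr$bn_state, history = tr$history,
    best_epoch = tr$best_epoch, control = control, fusion = fusion,
    seed = seed, graph = graph, X = X,
    embeddings = fwd$emb,
    test_predictions = data.frame(eval_pairs[, c("drug_id", "target_id")],
                                  probability = fwd$prob,
                                  label = eval_pairs$label),
    test_metrics = metrics,
    fitted_train = data.frame(graph$supervision$train[, c("drug_id",
                                                          "target_id")],
                              probability = trainfwd$prob,
                              label = graph$supervision$train$label)
  ), class = "topofuse")
}

validate_dti_data <- function(data) {
  need <- c("pairs", "drug_llm", "target_llm", "drug_topo", "target_topo")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset missing elements: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (nm in need[-1]) {
    if (is.null(rownames(data[[nm]]))) {
      stop(nm, " must have entity ids as rownames", call. = FALSE)
    }
  }
  bad_d <- setdiff(data$pairs$drug_id, rownames(data$drug_llm))
  bad_t <- setdiff(data$pairs$target_id, rownames(data$target_llm))
  if (length(bad_d) || length(bad_t)) {
    stop("pairs reference entities without features: ",
         paste(utils::head(c(bad_d, bad_t), 5), collapse = ", "),
         call. = FALSE)
  }
  data
}

#' @export
print.topofuse <- function(x, ...) {
  cat("Fused topological/sequence DTI model\n")
  cat(sprintf("  fusion mode: %s; trained %d epoch(s), best at %d\n",
              x$fusion, nrow(x$history), x$best_epoch))
  cat(sprintf("  %d drugs, %d targets, %d message edges\n",
              length(x$graph$drug_ids), length(x$graph$target_ids),
              nrow(x$graph$message_edges)))
  if (!is.null(x$test_metrics)) {
    cat(sprintf("  test AUROC %.3f, AUPRC %.3f\n",
                x$test_metrics$auroc, x$test_metrics$auprc))
  }
  invisible(x)
}

#' @export
summary.topofuse <- function(object, ...) {
  h <- object$history
  cat("Fused topological/sequence DTI model\n\n")
  cat(sprintf("fusion: %s   seed: %d   epochs: %d (best %d)\n",
              object$fusion, object$seed, nrow(h), object$best_epoch))
  cat(sprintf("final train loss %.4f, best val loss %.4f\n",
              h$train_loss[nrow(h)], min(h$val_loss, na.rm = TRUE)))
  if (object$fusion == "dynamic") {
    cat(sprintf("final mean gate weight alpha: drugs %.3f, targets %.3f\n",
                h$mean_alpha_drug[nrow(h)], h$mean_alpha_target[nrow(h)]))
  }
  if (!is.null(object$test_metrics)) {
    m <- object$test_metrics
    cat(sprintf(paste0("test metrics: AUROC %.4f  AUPRC %.4f  ",
                       "sensitivity %.4f  specificity %.4f\n"),
                m$auroc, m$auprc, m$sensitivity, m$specificity))
  }
  invisible(object)
}

#' Predict interaction probabilities for drug-target pairs
#'
#' Scores pairs with the fitted model in evaluation mode (deterministic:
#' running batch-norm statistics, no dropout). Both endpoints must be nodes
#' the model was fitted with.
#'
#' @param object A fitted `topofuse` model.
#' @param pairs Data frame with `drug_id`, `target_id`; defaults to the
#'   test partition.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.topofuse <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) pairs <- object$graph$supervision$test
  predict_pairs(object$embeddings, pairs, object$params$mlp)
}

#' @export
fitted.topofuse <- function(object, ...) {
  object$fitted_train$probability
}

#' @export
residuals.topofuse <- function(object, ...) {
  object$fitted_train$label - object$fitted_train$probability
}

#' @export
coef.topofuse <- function(object, ...) {
  object$params
}

#' Plot training history of a fitted model
#'
#' Left panel: training and validation loss per epoch with the restored
#' best epoch marked. Right panel (dynamic fusion): mean gate weight alpha
#' per epoch for drugs and targets; alpha above 0.5 means the model leans
#' on sequence embeddings over topological features.
#'
#' @param x A fitted `topofuse` model.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.topofuse <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = if (x$fusion == "dynamic") c(1, 2) else c(1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  if (x$fusion == "dynamic") {
    graphics::matplot(h$epoch, cbind(h$mean_alpha_drug, h$mean_alpha_target),
                      type = "l", lty = 1, col = c("steelblue", "darkorange"),
                      ylim = c(0, 1), xlab = "epoch", ylab = "mean alpha")
    graphics::abline(h = 0.5, lty = 3)
    graphics::legend("bottomright", c("drugs", "targets"), lty = 1,
                     col = c("steelblue", "darkorange"), bty = "n")
  }
  invisible(x)
}
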