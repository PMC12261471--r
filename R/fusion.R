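sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create a gated fusion module
#'
#' The gate computes an elementwise weight vector
#' `alpha = sigmoid(W [f_seq ; f_topo] + b)` from the concatenation of the
#' sequence and topological latent vectors and fuses them as
#' `f = alpha * f_seq + (1 - alpha) * f_topo`. Weights and bias are
#' zero-initialized so an untrained gate starts at the static
#' `alpha = 0.5` baseline; they are learned during model training.
#'
#' @param width Latent width of each input (default 512).
#' @return List with `W` (`2*width x width` matrix, input-concatenation by
#'   output orientation) and `b` (length-`width` bias).
#' @export
fusion_gate <- function(width = 512L) {
  list(W = matrix(0, 2L * width, width), b = numeric(width))
}

#' Fuse sequence and topological embeddings through the sigmoid gate
#'
#' @param f_llm Sequence-derived latent vector(s): length-`width` vector or
#'   `n x width` matrix.
#' @param f_tda Topology-derived latent vector(s), same shape.
#' @param gate Gate from [fusion_gate()].
#' @return List with `alpha` (gate weights in (0, 1)) and `fused` (the convex
#'   elementwise combination), each shaped like the inputs.
#' @export
#' @examples
#' g <- fusion_gate(4)
#' fuse(c(1, 0, 2, 3), c(0, 1, 2, -1), g)$alpha  # all 0.5 at zero init
fuse <- function(f_llm, f_tda, gate) {
  vec <- is.null(dim(f_llm))
  a <- if (vec) matrix(f_llm, 1) else as.matrix(f_llm)
  t <- if (vec) matrix(f_tda, 1) else as.matrix(f_tda)
  if (!all(dim(a) == dim(t))) {
    stop("sequence and topological embeddings must have identical shape",
         call. = FALSE)
  }
  if (nrow(gate$W) != 2L * ncol(a) || ncol(gate$W) != ncol(a)) {
    stop(sprintf("gate shaped for width %d, inputs have width %d",
                 ncol(gate$W), ncol(a)), call. = FALSE)
  }
  pre <- sweep(cbind(a, t) %*% gate$W, 2, gate$b, "+")
  alpha <- sigmoid(pre)
  fused <- alpha * a + (1 - alpha) * t
  if (vec) list(alpha = drop(alpha), fused = drop(fused))
  else list(alpha = alpha, fused = fused)
}

#' Fusion ablation variants
#'
#' Besides the learned dynamic gate, the ablation grid uses: `top_only`
#' (topological latent alone), `llm_only` (sequence latent alone) and
#' `static_half` (fixed alpha = 0.5, the elementwise mean). The Betti-only
#' and landscape-only ablations are realized upstream by restricting the
#' topological feature vector with [topo_blocks()] before projection.
#'
#' @param f_llm,f_tda Latent vectors or matrices of identical shape.
#' @param mode One of `"dynamic"`, `"static_half"`, `"top_only"`,
#'   `"llm_only"`.
#' @param gate Gate, required for `"dynamic"`.
#' @return Fused vector/matrix (for `"dynamic"`, the `fused` element).
#' @export
fuse_variant <- function(f_llm, f_tda,
                         mode = c("dynamic", "static_half", "top_only",
                                  "llm_only"),
                         gate = NULL) {
  mode <- match.arg(mode)
  switch(mode,
         top_only = f_tda,
         llm_only = f_llm,
         static_half = (f_llm + f_tda) / 2,
         dynamic = {
           if (is.null(gate)) stop("dynamic fusion needs a gate", call. = FALSE)
           fuse(f_llm, f_tda, gate)$fused
         })
}

#' Per-epoch mean gate weights of a fitted model
#'
#' Extracts the epoch-wise mean of the dynamically assigned fusion weights
#' (alpha) for drugs and for targets, recorded during training. Values near
#' 1 mean the model leans on sequence embeddings, near 0 on topological
#' features.
#'
#' @param fit A fitted `topofuse` model (or its `history`).
#' @return Data frame with columns `epoch`, `mean_alpha_drug`,
#'   `mean_alpha_target`.
#' @export
alpha_trace <- function(fit) {
  h <- if (inherits(fit, "topofuse")) fit$history else fit
  out <- h[, c("epoch", "mean_alpha_drug", "mean_alpha_target")]
  rownames(out) <- NULL
  out
}

#' Write an alpha trace as CSV
#'
#' @param trace Data frame from [alpha_trace()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alpha_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
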