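#' Generate an image with planted topology
#'
#' Draws `n_blobs` filled disks and `n_rings` annuli as dark foreground
#' (value near 0) on a light background (255), optionally adding clipped
#' Gaussian pixel noise. Dark-on-light matches the sublevel filtration,
#' which activates low values first, so at a mid-range threshold the
#' noiseless foreground has exactly `beta0 = n_blobs + n_rings` components
#' and `beta1 = n_rings` loops. Shapes are placed on a seeded rejection
#' sampler; an error is raised if they cannot be placed disjointly.
#'
#' @param n_blobs Number of filled components.
#' @param n_rings Number of annuli.
#' @param size Canvas edge in pixels (default 64).
#' @param noise_sd Pixel noise standard deviation (default 0; noise is
#'   clipped to \[0, 255\] after addition).
#' @param seed Integer seed.
#' @return List with `image` (`size x size x 3` array), `beta0`, `beta1`.
#' @export
gen_topo_image <- function(n_blobs = 1L, n_rings = 0L, size = 64L,
                           noise_sd = 0, seed = 1L) {
  stopifnot(n_blobs >= 0, n_rings >= 0, n_blobs + n_rings >= 1, size >= 16)
  withr::with_seed(seed, {
    n_shapes <- n_blobs + n_rings
    # guaranteed-disjoint placement: one shape per cell of a k x k grid,
    # jittered within the cell
    k <- ceiling(sqrt(n_shapes))
    cell <- size / k
    r_out <- floor(cell * 0.3)
    if (r_out < 3) {
      stop(sprintf("cannot place %d disjoint shapes on a %dx%d canvas",
                   n_shapes, size, size), call. = FALSE)
    }
    slots <- expand.grid(ci = seq_len(k), cj = seq_len(k))[seq_len(n_shapes), ]
    jit <- matrix(stats::runif(2 * n_shapes, -0.08 * cell, 0.08 * cell),
                  n_shapes, 2)
    centers <- cbind((slots$ci - 0.5) * cell, (slots$cj - 0.5) * cell) + jit
    gx <- matrix(rep(seq_len(size) - 0.5, size), size, size)
    gy <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)
    canvas <- matrix(255, size, size)
    for (i in seq_len(n_shapes)) {
      d2 <- (gx - centers[i, 1])^2 + (gy - centers[i, 2])^2
      if (i <= n_blobs) {
        canvas[d2 <= r_out^2] <- 0
      } else {
        canvas[d2 <= r_out^2 & d2 >= (r_out / 2)^2] <- 0
      }
    }
    if (noise_sd > 0) {
      canvas <- canvas + stats::rnorm(length(canvas), sd = noise_sd)
      canvas <- pmin(pmax(canvas, 0), 255)
    }
    canvas <- floor(canvas + 0.5)
    list(image = array(rep(canvas, 3), c(size, size, 3)),
         beta0 = as.integer(n_blobs + n_rings), beta1 = as.integer(n_rings))
  })
}

# small pool of parseable SMILES for synthetic drug records
synthetic_smiles_pool <- c("c1ccccc1", "C1CCCCC1", "CCO", "CC(=O)O",
                           "c1ccncc1", "C1CCC1", "CCCCCC", "CC(C)CC",
                           "c1ccc2ccccc2c1", "OCC1CCCCC1")

#' Generate a drug-target interaction dataset with planted structure
#'
#' Draws latent vectors for every drug and target; a pair is a positive
#' interaction when its noisy latent inner product exceeds the
#' `1 - density` quantile over all pairs. Negative pairs are sampled
#' uniformly from the non-interacting pairs, count-matched to the
#' positives, giving a balanced labeled set. Mock sequence embeddings are
#' noisy linear images of the latent vectors (signal-bearing); topological
#' feature vectors are either signal-bearing as well or pure noise
#' (`topo_signal = FALSE`), which is useful for checking that the fusion
#' gate learns to favor the informative modality. Fully deterministic per
#' seed.
#'
#' @param n_drugs,n_targets Entity counts (defaults 200 and 150).
#' @param latent_dim Latent dimension (default 8).
#' @param density Positive-pair fraction (default 0.05).
#' @param noise_sd Noise level for the interaction scores and feature maps
#'   (default 0.5).
#' @param topo_signal Should topological vectors carry the latent signal?
#' @param seed Integer seed.
#' @return Dataset list for [topofuse()]: `records`, `pairs`, `drug_llm`
#'   (768 columns), `target_llm` (1024), `drug_topo`, `target_topo` (1200),
#'   `latent` (the generating vectors).
#' @export
gen_dti_dataset <- function(n_drugs = 200L, n_targets = 150L,
                            latent_dim = 8L, density = 0.05,
                            noise_sd = 0.5, topo_signal = TRUE, seed = 1L) {
  stopifnot(n_drugs >= 2, n_targets >= 2, latent_dim >= 1,
            density > 0, density < 1)
  withr::with_seed(seed, {
    drug_ids <- sprintf("d%03d", seq_len(n_drugs))
    target_ids <- sprintf("t%03d", seq_len(n_targets))
    U <- matrix(stats::rnorm(n_drugs * latent_dim), n_drugs, latent_dim)
    V <- matrix(stats::rnorm(n_targets * latent_dim), n_targets, latent_dim)
    S <- U %*% t(V) + noise_sd * stats::rnorm(n_drugs * n_targets)
    cutoff <- stats::quantile(S, 1 - density)
    pos <- which(S > cutoff, arr.ind = TRUE)
    if (nrow(pos) < 1) stop("degenerate spec: no positive pairs", call. = FALSE)
    neg_pool <- which(S <= cutoff)
    n_neg <- min(nrow(pos), length(neg_pool))
    if (n_neg < 1) stop("degenerate spec: no negative pairs", call. = FALSE)
    neg_lin <- sample(neg_pool, n_neg)
    neg <- cbind(((neg_lin - 1) %% n_drugs) + 1,
                 ((neg_lin - 1) %/% n_drugs) + 1)
    pairs <- data.frame(
      drug_id = drug_ids[c(pos[, 1], neg[, 1])],
      target_id = target_ids[c(pos[, 2], neg[, 2])],
      label = rep(c(1L, 0L), c(nrow(pos), n_neg)))
    lin_map <- function(L, out_dim) {
      P <- matrix(stats::rnorm(ncol(L) * out_dim), ncol(L), out_dim)
      out <- L %*% P + noise_sd * stats::rnorm(nrow(L) * out_dim)
      colnames(out) <- paste0("e", seq_len(out_dim))
      out
    }
    noise_mat <- function(n, out_dim) {
      matrix(stats::rnorm(n * out_dim), n, out_dim,
             dimnames = list(NULL, paste0("e", seq_len(out_dim))))
    }
    drug_llm <- lin_map(U, 768L); rownames(drug_llm) <- drug_ids
    target_llm <- lin_map(V, 1024L); rownames(target_llm) <- target_ids
    if (topo_signal) {
      drug_topo <- lin_map(U, 1200L)
      target_topo <- lin_map(V, 1200L)
    } else {
      drug_topo <- noise_mat(n_drugs, 1200L)
      target_topo <- noise_mat(n_targets, 1200L)
    }
    rownames(drug_topo) <- drug_ids; rownames(target_topo) <- target_ids
    records <- data.frame(
      id = c(drug_ids, target_ids),
      kind = rep(c("drug", "target"), c(n_drugs, n_targets)),
      sequence = c(sample(synthetic_smiles_pool, n_drugs, replace = TRUE),
                   vapply(seq_len(n_targets), function(i) {
                     paste(sample(c("A", "C", "D", "E", "G", "K", "L"),
                                  30, replace = TRUE), collapse = "")
                   }, character(1))))
    list(records = records, pairs = pairs,
         drug_llm = drug_llm, target_llm = target_llm,
         drug_topo = drug_topo, target_topo = target_topo,
         latent = list(U = U, V = V, cutoff = unname(cutoff)))
  })
}

#' Write a generated dataset in the formats the readers consume
#'
#' Writes `pairs.tsv`, the four embedding/feature tables and `records.tsv`
#' into a directory, so generated fixtures double as format documentation.
#'
#' @param data Dataset from [gen_dti_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dti_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data$records, file.path(dir, "records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_embedding_table(data$drug_llm, file.path(dir, "drug_llm.tsv"))
  write_embedding_table(data$target_llm, file.path(dir, "target_llm.tsv"))
  write_feature_table(data$drug_topo, file.path(dir, "drug_topo.tsv"))
  write_feature_table(data$target_topo, file.path(dir, "target_topo.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dti_dataset()]
#'
#' @param dir Dataset directory.
#' @return Dataset list for [topofuse()].
#' @export
read_dti_dataset <- function(dir) {
  list(
    records = utils::read.delim(file.path(dir, "records.tsv"),
                                stringsAsFactors = FALSE),
    pairs = utils::read.delim(file.path(dir, "pairs.tsv"),
                              stringsAsFactors = FALSE),
    drug_llm = load_embedding_table(file.path(dir, "drug_llm.tsv"), "drug"),
    target_llm = load_embedding_table(file.path(dir, "target_llm.tsv"),
                                      "target"),
    drug_topo = read_feature_table(file.path(dir, "drug_topo.tsv")),
    target_topo = read_feature_table(file.path(dir, "target_topo.tsv"))
  )
}
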