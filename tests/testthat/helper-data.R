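# small dataset + control used across model tests
tiny_control <- function(max_epochs = 25L, ...) {
  topofuse_control(latent = 16L, gnn_hidden = c(8L, 4L), mlp_hidden = 4L,
                   max_epochs = max_epochs, ...)
}

tiny_dataset <- function(seed = 3, ...) {
  gen_dti_dataset(n_drugs = 30L, n_targets = 20L, latent_dim = 4L,
                  density = 0.1, seed = seed, ...)
}

toy_pairs <- function() {
  data.frame(
    drug_id = c("d1", "d1", "d2", "d2"),
    target_id = c("t1", "t2", "t1", "t2"),
    label = c(1L, 0L, 1L, 1L),
    partition = c("train", "train", "val", "test"))
}
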