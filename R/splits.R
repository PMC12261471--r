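#' Random train/validation/test split of labeled pairs
#'
#' Partitions the pairs uniformly at random into train/val/test at the
#' given fractions (70/10/20 by default). Counts are `floor(n * ratio)`
#' for train and validation with the remainder in test, so divisible inputs
#' split exactly.
#'
#' @param pairs Data frame with `drug_id`, `target_id`, `label`.
#' @param ratios Length-3 numeric summing to 1 (train, val, test).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return `pairs` with a `partition` column (`train`/`val`/`test`).
#' @export
random_split <- function(pairs, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8 || any(ratios < 0)) {
    stop("ratios must be three non-negative fractions summing to 1",
         call. = FALSE)
  }
  n <- nrow(pairs)
  n_train <- floor(n * ratios[1])
  n_val <- floor(n * ratios[2])
  if (n_train < 1 || n - n_train - n_val < 1) {
    stop("too few pairs for a non-empty train and test partition",
         call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  part <- character(n)
  part[perm[seq_len(n_train)]] <- "train"
  part[perm[n_train + seq_len(n_val)]] <- "val"
  part[part == ""] <- "test"
  out <- pairs
  out$partition <- part
  out
}

#' Cold split with unseen drugs and/or targets
#'
#' Holds out a fraction of the entities (drugs, targets, or both) and sends
#' *every* interaction involving a held-out entity to the test set, so held-
#' out entities never overlap the training set. The remaining pairs are
#' divided 7/8 train and 1/8 validation. In `cold_both` mode the entity
#' universe itself is partitioned (test entities, then 1/8 of the remainder
#' for validation) and only within-group pairs are kept, so every drug and
#' target seen in validation or test is entirely absent from training;
#' cross-group pairs get partition `"unused"` and are excluded from
#' supervision.
#'
#' @param pairs Data frame with `drug_id`, `target_id`, `label`.
#' @param mode `"unseen_targets"`, `"unseen_drugs"` or `"cold_both"`.
#' @param holdout_fraction Fraction of entities held out for test
#'   (default 0.2).
#' @param seed Integer seed.
#' @return `pairs` with a `partition` column.
#' @export
cold_split <- function(pairs, mode = c("unseen_targets", "unseen_drugs",
                                       "cold_both"),
                       holdout_fraction = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0, 1)", call. = FALSE)
  }
  out <- pairs
  out$partition <- NA_character_
  pick <- function(ids, frac, s) {
    k <- max(1L, round(length(ids) * frac))
    withr::with_seed(s, sample(ids, k))
  }
  if (mode == "cold_both") {
    # partition the entity universe; keep only within-group pairs so every
    # entity seen in validation or test is entirely absent from training
    # (cross-group pairs are marked "unused" and excluded from supervision)
    d_test <- pick(unique(pairs$drug_id), holdout_fraction, seed)
    t_test <- pick(unique(pairs$target_id), holdout_fraction, seed + 1L)
    d_val <- pick(setdiff(unique(pairs$drug_id), d_test), 1 / 8, seed + 2L)
    t_val <- pick(setdiff(unique(pairs$target_id), t_test), 1 / 8, seed + 3L)
    dgrp <- ifelse(pairs$drug_id %in% d_test, "test",
                   ifelse(pairs$drug_id %in% d_val, "val", "train"))
    tgrp <- ifelse(pairs$target_id %in% t_test, "test",
                   ifelse(pairs$target_id %in% t_val, "val", "train"))
    out$partition <- ifelse(dgrp == tgrp, dgrp, "unused")
  } else {
    col <- if (mode == "unseen_targets") "target_id" else "drug_id"
    held <- pick(unique(pairs[[col]]), holdout_fraction, seed)
    is_test <- pairs[[col]] %in% held
    rest <- which(!is_test)
    n_rest <- length(rest)
    n_train <- floor(n_rest * 7 / 8)
    perm <- withr::with_seed(seed + 1L, sample(rest))
    out$partition[is_test] <- "test"
    out$partition[perm[seq_len(n_train)]] <- "train"
    out$partition[perm[-seq_len(n_train)]] <- "val"
  }
  if (!any(out$partition == "train" & out$label == 1)) {
    stop("holdout removes all positive pairs from the training set",
         call. = FALSE)
  }
  out
}

#' Write a split as TSV
#'
#' @param pairs Data frame with `drug_id`, `target_id`, `label`,
#'   `partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_split <- function(pairs, path) {
  utils::write.table(pairs[, c("drug_id", "target_id", "label", "partition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a split TSV written by [write_split()]
#'
#' @param path Input file.
#' @return Data frame with the four split columns.
#' @export
read_split <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(drug_id = "character",
                                   target_id = "character"))
}
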