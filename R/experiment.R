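#' Repeat-run evaluation of the DTI model
#'
#' Trains and evaluates the model once per seed on a fixed split and
#' aggregates test metrics as mean and standard deviation over runs (the
#' repeat-run protocol; five seeds by default).
#'
#' @param data Dataset list (see [topofuse()]).
#' @param split Partitioned pairs; defaults to a random 70/10/20 split
#'   generated with `split_seed`.
#' @param seeds Integer vector of model seeds (default `1:5`).
#' @param fusion Fusion mode.
#' @param control [topofuse_control()] settings.
#' @param split_seed Seed for the default random split.
#' @return A `metric_report` with one row per run (including the final mean
#'   fusion weights) plus mean/sd; the per-run fits are attached as the
#'   `fits` attribute.
#' @export
run_experiment <- function(data, split = NULL, seeds = 1:5,
                           fusion = "dynamic",
                           control = topofuse_control(),
                           split_seed = 1L) {
  data <- validate_dti_data(data)
  if (is.null(split)) split <- random_split(data$pairs, seed = split_seed)
  fits <- lapply(seeds, function(s) {
    topofuse(data, split = split, fusion = fusion, control = control,
             seed = s)
  })
  runs <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    f <- fits[[i]]
    h <- f$history
    data.frame(seed = seeds[i],
               auroc = f$test_metrics$auroc,
               auprc = f$test_metrics$auprc,
               sensitivity = f$test_metrics$sensitivity,
               specificity = f$test_metrics$specificity,
               final_alpha_drug = h$mean_alpha_drug[nrow(h)],
               final_alpha_target = h$mean_alpha_target[nrow(h)],
               epochs = nrow(h))
  }))
  rep <- metric_report(runs)
  attr(rep, "fits") <- fits
  rep
}

#' Training-set size sweep
#'
#' Re-runs the repeat-run evaluation with the training partition randomly
#' subsampled to each requested fraction, keeping validation and test
#' fixed, to chart how performance degrades with less supervision.
#' Fraction 1 reproduces [run_experiment()] exactly under the same seeds.
#'
#' @param data Dataset list.
#' @param split Partitioned pairs (defaults to a random split).
#' @param fractions Numeric vector of train fractions in (0, 1\].
#' @param seeds Model seeds per fraction.
#' @param fusion,control,split_seed As in [run_experiment()].
#' @return Named list of `metric_report`s, one per fraction. Fractions whose
#'   subsample has fewer than 2 pairs or a single class are skipped with a
#'   warning.
#' @export
training_fraction_sweep <- function(data, split = NULL,
                                    fractions = c(1, 0.3, 0.05),
                                    seeds = 1:3, fusion = "dynamic",
                                    control = topofuse_control(),
                                    split_seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  data <- validate_dti_data(data)
  if (is.null(split)) split <- random_split(data$pairs, seed = split_seed)
  train_idx <- which(split$partition == "train")
  out <- list()
  for (frac in fractions) {
    sub <- split
    if (frac < 1) {
      keep <- withr::with_seed(
        split_seed + round(1e6 * frac),
        sample(train_idx, max(1L, floor(length(train_idx) * frac))))
      drop_idx <- setdiff(train_idx, keep)
      if (length(drop_idx)) sub <- split[-drop_idx, , drop = FALSE]
    }
    kept_train <- sub[sub$partition == "train", ]
    if (nrow(kept_train) < 2 || length(unique(kept_train$label)) < 2) {
      warning(sprintf("fraction %.3g leaves a degenerate training set; skipped",
                      frac))
      next
    }
    out[[sprintf("%g", frac)]] <-
      run_experiment(data, split = sub, seeds = seeds, fusion = fusion,
                     control = control)
  }
  out
}

#' Write a metric report as JSON and CSV
#'
#' @param report A `metric_report`.
#' @param path Output path without extension; writes `<path>.json` and
#'   `<path>.csv`.
#' @return The JSON path, invisibly.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report$runs, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(mean = as.list(report$mean),
                            sd = as.list(report$sd),
                            n_runs = report$n_runs,
                            runs = report$runs),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, ".json"))
}
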