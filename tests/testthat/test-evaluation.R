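test_that("random split gives exact counts, conservation, reproducibility", {
  pairs <- data.frame(drug_id = sprintf("d%02d", rep(1:10, 10)),
                      target_id = sprintf("t%02d", rep(1:10, each = 10)),
                      label = rep_len(c(1L, 0L), 100))
  sp <- random_split(pairs, seed = 3)
  expect_equal(as.vector(table(sp$partition)[c("train", "val", "test")]),
               c(70L, 10L, 20L))
  # conservation: partitions recover the input multiset
  expect_equal(sp[, 1:3], pairs)
  expect_identical(sp, random_split(pairs, seed = 3))
  expect_false(identical(sp$partition, random_split(pairs, seed = 4)$partition))
  expect_error(random_split(pairs[1, , drop = FALSE]), "too few")
  expect_error(random_split(pairs, ratios = c(0.5, 0.5, 0.5)), "summing")
})

test_that("cold splits hold out entities with provably empty overlap", {
  set.seed(10)
  pairs <- data.frame(drug_id = sample(sprintf("d%02d", 1:15), 100, TRUE),
                      target_id = sample(sprintf("t%02d", 1:10), 100, TRUE),
                      label = rep_len(c(1L, 0L), 100))
  sp <- cold_split(pairs, "unseen_targets", 0.2, seed = 1)
  held <- unique(sp$target_id[sp$partition == "test"])
  expect_length(intersect(held, sp$target_id[sp$partition != "test"]), 0)
  expect_equal(length(unique(pairs$target_id[pairs$target_id %in% held])), 2L)
  # remaining pairs split 7/8 train, 1/8 val
  n_rest <- sum(sp$partition != "test")
  expect_equal(sum(sp$partition == "train"), floor(n_rest * 7 / 8))
  # unseen drugs: every test drug absent from train and val
  spd <- cold_split(pairs, "unseen_drugs", 0.2, seed = 2)
  test_drugs <- unique(spd$drug_id[spd$partition == "test"])
  expect_length(intersect(test_drugs,
                          spd$drug_id[spd$partition %in% c("train", "val")]),
                0)
  # cold_both: val and test entities never appear in training
  spb <- cold_split(pairs, "cold_both", 0.2, seed = 3)
  train_d <- unique(spb$drug_id[spb$partition == "train"])
  train_t <- unique(spb$target_id[spb$partition == "train"])
  for (part in c("val", "test")) {
    expect_length(intersect(unique(spb$drug_id[spb$partition == part]),
                            train_d), 0)
    expect_length(intersect(unique(spb$target_id[spb$partition == part]),
                            train_t), 0)
  }
  # every pair gets a partition, deterministically per seed; only cold_both
  # may mark cross-group pairs unused
  for (m in c("unseen_targets", "unseen_drugs", "cold_both")) {
    s1 <- cold_split(pairs, m, 0.2, seed = 5)
    expect_false(any(is.na(s1$partition)))
    if (m != "cold_both") expect_false(any(s1$partition == "unused"))
    expect_identical(s1, cold_split(pairs, m, 0.2, seed = 5))
  }
  expect_error(cold_split(pairs, "unseen_targets", 1.2), "holdout_fraction")
})

test_that("an exact 7/8 vs 1/8 division falls out on divisible remainders", {
  pairs <- data.frame(drug_id = sprintf("d%d", rep(1:10, each = 10)),
                      target_id = sprintf("t%d", rep(1:10, 10)),
                      label = 1L)
  # 10 targets, fraction 0.2 -> 2 held out -> 80 remaining -> 70/10
  sp <- cold_split(pairs, "unseen_targets", 0.2, seed = 9)
  expect_equal(sum(sp$partition == "test"), 20L)
  expect_equal(sum(sp$partition == "train"), 70L)
  expect_equal(sum(sp$partition == "val"), 10L)
})

test_that("metrics match closed forms and an independent implementation", {
  m <- compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auroc, 1); expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1); expect_equal(m$auprc, 1)
  # 3 of 4 positive-negative pairs correctly ordered
  expect_equal(compute_metrics(c(0.9, 0.8, 0.4, 0.3),
                               c(1, 0, 1, 0))$auroc, 0.75)
  # all-tied scores give half credit
  expect_equal(compute_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auroc, 0.5)
  # reversal identity
  set.seed(31)
  sc <- runif(50); lb <- rbinom(50, 1, 0.4)
  expect_equal(compute_metrics(1 - sc, lb)$auroc,
               1 - compute_metrics(sc, lb)$auroc)
  # cross-check against pROC on random scores
  skip_if_not_installed("pROC")
  for (i in 1:5) {
    sc <- runif(40); lb <- rbinom(40, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(compute_metrics(sc, lb)$auroc,
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                levels = c(0, 1),
                                                direction = "<"))))
  }
  expect_error(compute_metrics(c(0.1, 0.9), c(1, 1)), "both classes")
  expect_error(compute_metrics(1, c(0, 1)), "equal length")
})

test_that("sensitivity and specificity respect the threshold", {
  m <- compute_metrics(c(0.6, 0.4, 0.6, 0.4), c(1, 1, 0, 0), threshold = 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  m2 <- compute_metrics(c(0.6, 0.4, 0.6, 0.4), c(1, 1, 0, 0), threshold = 0.3)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
})

test_that("run_experiment aggregates per-seed runs reproducibly", {
  d <- tiny_dataset()
  ctrl <- tiny_control(max_epochs = 6L)
  rep1 <- run_experiment(d, seeds = 1:3, control = ctrl)
  expect_s3_class(rep1, "metric_report")
  expect_equal(rep1$n_runs, 3L)
  expect_equal(nrow(rep1$runs), 3L)
  expect_true(all(rep1$mean >= 0 & rep1$mean <= 1))
  expect_gte(rep1$mean["auroc"], min(rep1$runs$auroc))
  expect_lte(rep1$mean["auroc"], max(rep1$runs$auroc))
  rep2 <- run_experiment(d, seeds = 1:3, control = ctrl)
  expect_identical(rep1$runs, rep2$runs)
  # report files
  path <- withr::local_tempfile()
  write_metric_report(rep1, path)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$n_runs, 3L)
  expect_equal(length(js$runs), 3L)
})

test_that("training-fraction sweep: identity at 1 and degradation trend", {
  d <- tiny_dataset()
  ctrl <- tiny_control(max_epochs = 6L)
  sp <- random_split(d$pairs, seed = 2)
  full <- run_experiment(d, split = sp, seeds = 1:2, control = ctrl)
  sw <- training_fraction_sweep(d, split = sp, fractions = c(1, 0.25),
                                seeds = 1:2, control = ctrl)
  expect_named(sw, c("1", "0.25"))
  expect_identical(sw[["1"]]$runs, full$runs)
  # tiny fractions that destroy the train set are skipped with a warning
  expect_warning(
    sw2 <- training_fraction_sweep(d, split = sp, fractions = 0.01,
                                   seeds = 1, control = ctrl),
    "degenerate")
  expect_length(sw2, 0)
})

test_that("split TSVs round-trip", {
  d <- tiny_dataset()
  sp <- random_split(d$pairs, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, path)
  back <- read_split(path)
  expect_equal(back, sp[, c("drug_id", "target_id", "label", "partition")])
})
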