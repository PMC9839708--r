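smoke_config <- function(seed = 5L) {
  protocol_config(
    label_budget = 3L,
    train_fraction = 0.6,   # small smoke runs need a validation pool >= N per class
    ae = ae_config(embedding_dim = 8L, gru_hidden = 16L, epochs = 2L,
                   batch_size = 32L),
    seed = seed
  )
}

test_that("stratified folds are exact for balanced data, disjoint and seeded", {
  manifest <- data.frame(segment_id = sprintf("s%02d", 1:40),
                         label = rep(0:3, each = 10))
  plan <- make_folds(manifest, k = 10, seed = 3)
  per_fold <- table(plan$fold, plan$label)
  expect_true(all(per_fold == 1))

  set.seed(21)
  for (trial in 1:5) {
    n <- sample(40:120, 1)
    m <- data.frame(segment_id = sprintf("r%03d", 1:n),
                    label = sample(0:3, n, replace = TRUE, prob = c(.1, .2, .3, .4)))
    if (any(table(m$label) < 4)) next
    pl <- make_folds(m, k = 4, seed = trial)
    expect_setequal(pl$segment_id, m$segment_id)
    expect_true(all(pl$fold %in% 1:4))
    # per-fold class counts within +/- 1 of an even split
    tab <- table(pl$fold, pl$label)
    expect_true(all(abs(tab - rep(colMeans(tab), each = 4)) <= 1))
  }

  p1 <- make_folds(manifest, k = 10, seed = 9)
  p2 <- make_folds(manifest, k = 10, seed = 9)
  expect_identical(p1, p2)

  expect_error(make_folds(data.frame(segment_id = c("a", "b"), label = c(0, 1)),
                          k = 3), class = "ieegsift_too_few")
})

test_that("the k-fold protocol runs end to end with clean label hygiene", {
  segs <- make_small_dataset(per_class = 30, seed = 61)  # 120 segments
  manifest <- data.frame(segment_id = vapply(segs, `[[`, character(1), "segment_id"),
                         label = vapply(segs, `[[`, integer(1), "label"))
  plan <- make_folds(manifest, k = 3, seed = 2)
  cfg <- smoke_config(seed = 5L)
  rep1 <- run_protocol(segs, plan, cfg)

  expect_s3_class(rep1, "metrics_report")
  expect_equal(nrow(rep1$per_fold), 3)
  expect_gt(rep1$mean[["macro_auroc"]], 0.5)
  expect_true(all(rep1$per_fold$macro_auroc >= 0 & rep1$per_fold$macro_auroc <= 1))
  expect_equal(sum(rep1$confusion), length(segs))

  # audit: labels were read only for the VS draw and test scoring, never for
  # autoencoder training data
  log <- audit_entries(rep1$audit)
  expect_setequal(unique(log$purpose), c("vs_draw", "test_scoring"))
  test_ids <- log$segment_id[log$purpose == "test_scoring"]
  vs_ids <- log$segment_id[log$purpose == "vs_draw"]
  expect_setequal(test_ids, manifest$segment_id)          # every fold scored once
  expect_length(test_ids, length(segs))
  trs_ids <- setdiff(manifest$segment_id, union(test_ids, vs_ids))
  expect_false(any(trs_ids %in% log$segment_id))

  rep2 <- run_protocol(segs, plan, cfg)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_identical(rep1$confusion, rep2$confusion)
})

test_that("a budget shortfall in the validation pool is a labeled error", {
  segs <- make_small_dataset(per_class = 12, seed = 62)
  manifest <- data.frame(segment_id = vapply(segs, `[[`, character(1), "segment_id"),
                         label = vapply(segs, `[[`, integer(1), "label"))
  plan <- make_folds(manifest, k = 3, seed = 1)
  cfg <- smoke_config()
  cfg$label_budget <- 50L
  expect_error(run_protocol(segs, plan, cfg),
               class = "ieegsift_budget_shortfall")
})

test_that("run_split scores an explicit train/val/test division", {
  parts <- split_dataset(make_small_dataset(per_class = 40, seed = 71),
                         n_train = 20, n_val = 12, n_test = 8)
  train <- parts$train; val <- parts$val; test <- parts$test
  cfg <- smoke_config(seed = 6L)
  res <- run_split(train, val, test, cfg)
  expect_length(res$metrics$auroc$per_class, 4)
  expect_equal(sum(res$metrics$f1$confusion), length(test))
  expect_s3_class(res$model, "ae_model")
  log <- audit_entries(res$audit)
  train_ids <- vapply(train, `[[`, character(1), "segment_id")
  expect_false(any(log$segment_id %in% train_ids))
})

test_that("pseudo-prospective scoring flags injected high-amplitude discharges", {
  parts <- split_dataset(make_small_dataset(per_class = 36, seed = 81),
                         n_train = 20, n_val = 12, n_test = 4)
  cfg <- smoke_config(seed = 7L)
  res <- run_split(parts$train, parts$val, parts$test, cfg)

  rec <- generate_recording(240, 0.15, generator_params(), seed = 9)
  pp <- pseudo_prospective_eval(res$model, res$classifier, rec)
  expect_length(pp$scores, length(rec))
  expect_true(pp$auroc >= 0 && pp$auroc <= 1)
  # internal consistency: reported F1 equals f1_scores on thresholded scores
  labs <- vapply(rec, `[[`, integer(1), "label")
  ref <- f1_scores(as.integer(pp$scores >= 0.5), labs, classes = c(0L, 1L))
  expect_equal(pp$macro_f1, ref$macro_f1)
  expect_equal(pp$weighted_f1, ref$weighted_f1)

  bad <- rec
  bad[[1]]$label <- 3L
  expect_error(pseudo_prospective_eval(res$model, res$classifier, bad),
               class = "ieegsift_bad_label")
})
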