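# Training protocol: learning-rate schedule, fold construction, confusion
# metrics, cross-validated evaluation.

test_that("the learning-rate schedule hits its anchors and is unimodal", {
  cfg <- train_config()
  expect_identical(lr_at(cfg, 0), 5e-5)
  expect_identical(lr_at(cfg, 20), 1e-3)
  expect_identical(lr_at(cfg, 200), 5e-4)
  lrs <- lr_at(cfg, 0:200)
  expect_true(all(diff(lrs[1:21]) > 0))            # warmup strictly increases
  expect_true(all(diff(lrs[21:201]) <= 0))         # decay never increases
  # continuity at the warmup boundary
  expect_lt(abs(lr_at(cfg, 20) - lr_at(cfg, 20 - 1e-9)), 1e-9)
  expect_error(lr_at(cfg, -1), "epoch")
  expect_error(lr_at(cfg, 201), "epoch")
  expect_error(train_config(lr_init = 2e-3), "lr_init")
  expect_error(train_config(warmup_epochs = 200), "warmup")
})

test_that("epoch-level folds partition the data with class stratification", {
  ep <- make_epochs(100, rep(c("DD", "HC"), c(60, 40)))
  cfg <- train_config(n_folds = 5, seed = 3)
  folds <- kfold_split(ep, cfg)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)         # union covers everything
  expect_equal(lengths(tests), rep(20L, 5))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    tb <- table(ep$labels[f$test])
    expect_lte(abs(tb[["DD"]] - 12), 1)
    expect_lte(abs(tb[["HC"]] - 8), 1)
  }
})

test_that("subject-level folds never split a subject across train and test", {
  ep <- make_epochs(100, rep(rep(c("DD", "HC"), each = 5), 10)[1:100],
                    subject_ids = rep(paste0("s", 1:10), each = 10))
  # relabel consistently per subject
  ep$labels <- ifelse(as.integer(sub("s", "", ep$subject_ids)) %% 2 == 0,
                      "DD", "HC")
  cfg <- train_config(n_folds = 5, fold_unit = "subject_level", seed = 1)
  folds <- kfold_split(ep, cfg)
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:100)
  for (f in folds) {
    expect_length(intersect(unique(ep$subject_ids[f$train]),
                            unique(ep$subject_ids[f$test])), 0)
    expect_length(unique(ep$subject_ids[f$test]), 2)
  }
})

test_that("confusion counts follow the declared positive class", {
  cc <- confusion(c("DD", "DD", "HC", "HC"), c("DD", "HC", "DD", "HC"), "DD")
  expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]),
               c(TP = 1, FP = 1, FN = 1, TN = 1))
  # swapping the positive class swaps TP<->TN and FP<->FN
  cs <- confusion(c("DD", "DD", "HC", "HC"), c("DD", "HC", "DD", "HC"), "HC")
  expect_equal(cs$TP, cc$TN); expect_equal(cs$FP, cc$FN)
  # perfect prediction has no off-diagonal mass
  cp <- confusion(rep("DD", 5), rep("DD", 5))
  expect_equal(cp$FP + cp$FN, 0)
  expect_error(confusion("DD", c("DD", "HC")), "length")
  expect_error(confusion("XX", "DD"), "XX")
})

test_that("metric formulas give the worked example and handle empty denominators", {
  cc <- structure(list(TP = 3, FP = 1, FN = 2, TN = 4, positive_class = "DD"),
                  class = "confusion_counts")
  m <- metrics(cc)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.6)
  expect_equal(unname(m["f1"]), 2 * 3 / (2 * 3 + 1 + 2), tolerance = 1e-12)
  # perfect classifier
  mp <- metrics(confusion(rep(c("DD", "HC"), 50), rep(c("DD", "HC"), 50)))
  expect_equal(as.numeric(mp), rep(1, 4))
  # nothing predicted positive: sentinel 0 with a warning
  cz <- confusion(rep("HC", 4), c("DD", "DD", "HC", "HC"))
  expect_warning(mz <- metrics(cz), "sentinel")
  expect_equal(unname(mz["precision"]), 0)
  expect_true("precision" %in% attr(mz, "undefined"))
})

test_that("metrics agree with a brute-force recount over random label pairs", {
  set.seed(42)
  for (r in 1:50) {
    n <- sample(5:200, 1)
    pred <- sample(c("DD", "HC"), n, replace = TRUE)
    act <- sample(c("DD", "HC"), n, replace = TRUE)
    cc <- confusion(pred, act, "DD")
    m <- suppressWarnings(metrics(cc))
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_len(n)) {
      if (pred[i] == "DD" && act[i] == "DD") tp <- tp + 1
      else if (pred[i] == "DD") fp <- fp + 1
      else if (act[i] == "DD") fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]),
                 c(TP = tp, FP = fp, FN = fn, TN = tn))
    expect_equal(unname(m["accuracy"]), (tp + tn) / n)
    if (tp + fp > 0) expect_equal(unname(m["precision"]), tp / (tp + fp))
    if (tp + fn > 0) expect_equal(unname(m["recall"]), tp / (tp + fn))
    # F1 is the harmonic mean of precision and recall whenever both defined
    if (tp > 0) {
      pr <- tp / (tp + fp); rc <- tp / (tp + fn)
      expect_equal(unname(m["f1"]), 2 * pr * rc / (pr + rc), tolerance = 1e-12)
    }
  }
})

test_that("the training loop follows the schedule and records its trace", {
  ep <- make_epochs(24, rep(c("DD", "HC"), 12), Tt = 24)
  cfg <- train_config(batch_size = 8, max_epochs = 6, warmup_epochs = 2,
                      seed = 4)
  m <- train_model(build_model(micro_spec("mrcnn_rse"), 1), ep, cfg)
  expect_length(m$trace$loss, 6)
  expect_equal(m$trace$lr, lr_at(cfg, 0:5))
  expect_true(all(is.finite(m$trace$loss)))
  expect_error(train_model(build_model(micro_spec("mrcnn_rse"), 1),
                           make_epochs(4, rep(NA_character_, 4), Tt = 24),
                           cfg),
               "label")
})

test_that("a majority-class stub on 60/40 data scores 0.6 with zero spread", {
  ep <- make_epochs(100, rep(c("DD", "HC"), c(60, 40)))
  majority_trainer <- function(train_set, config, seed) {
    cls <- names(which.max(table(train_set$labels)))
    function(test_set) rep(cls, length(test_set$labels))
  }
  rep_ <- cross_validate(ep, NULL, train_config(n_folds = 5, seed = 2),
                         trainer = majority_trainer)
  expect_equal(unname(rep_$mean["accuracy"]), 0.6)
  expect_equal(unname(rep_$sd["accuracy"]), 0)
  # fold accounting: the test confusions sum to the dataset size
  expect_equal(sum(vapply(rep_$confusions,
                          function(cc) cc$TP + cc$FP + cc$FN + cc$TN,
                          numeric(1))), 100)
})

test_that("cross-validation is reproducible for a fixed seed", {
  ep <- make_epochs(40, rep(c("DD", "HC"), 20), Tt = 24)
  cfg <- train_config(batch_size = 8, max_epochs = 3, warmup_epochs = 1,
                      n_folds = 2, seed = 11)
  r1 <- cross_validate(ep, micro_spec("mrcnn_rse"), cfg)
  r2 <- cross_validate(ep, micro_spec("mrcnn_rse"), cfg)
  expect_identical(r1$per_fold, r2$per_fold)
})

test_that("report tables render one mean +/- SD row per band", {
  ep <- make_epochs(40, rep(c("DD", "HC"), 20))
  maj <- function(train_set, config, seed) {
    cls <- names(which.max(table(train_set$labels)))
    function(test_set) rep(cls, length(test_set$labels))
  }
  r <- cross_validate(ep, NULL, train_config(n_folds = 2, seed = 1),
                      trainer = maj)
  tab <- report_table(list(Beta = r, Theta = r))
  expect_equal(rownames(tab), c("Beta", "Theta"))
  expect_match(tab$Accuracy[1], "%")
})
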