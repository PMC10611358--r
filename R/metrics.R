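# Confusion-matrix metric suite: accuracy, precision, recall, F1 with
# respect to an explicit positive class, aggregated as mean +/- SD across
# cross-validation folds.

#' Confusion counts
#'
#' Tabulates TP/FP/FN/TN of predicted vs actual labels with respect to a
#' declared positive class.
#'
#' @param pred,actual equal-length label vectors over `{"DD", "HC"}`.
#' @param positive_class the class counted as positive (default `"DD"`).
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `FN`, `TN` and `positive_class`.
#' @export
confusion <- function(pred, actual, positive_class = "DD") {
  if (length(pred) != length(actual))
    stopf("`pred` [%d] and `actual` [%d] differ in length",
          length(pred), length(actual))
  classes <- c("DD", "HC")
  bad <- setdiff(unique(c(pred, actual)), classes)
  if (length(bad))
    stopf("label(s) outside {DD, HC}: %s", paste(bad, collapse = ", "))
  if (!positive_class %in% classes)
    stopf("`positive_class` must be \"DD\" or \"HC\"")
  pos <- positive_class
  structure(list(TP = sum(pred == pos & actual == pos),
                 FP = sum(pred == pos & actual != pos),
                 FN = sum(pred != pos & actual == pos),
                 TN = sum(pred != pos & actual != pos),
                 positive_class = pos),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> positive = %s\n", x$positive_class))
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(predicted = c("pos", "neg"),
                              actual = c("pos", "neg")))
  print(t(m)[c(1, 2), ])
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2TP/(2TP+FP+FN). A zero denominator yields the sentinel 0 with the
#' affected metric recorded in the `undefined` attribute and a warning.
#'
#' @param cc a [confusion()] result.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`;
#'   attribute `undefined` names any zero-denominator metrics.
#' @export
metrics <- function(cc) {
  if (!inherits(cc, "confusion_counts")) stopf("`cc` must be confusion_counts")
  total <- cc$TP + cc$FP + cc$FN + cc$TN
  if (total == 0) stopf("all confusion counts are zero")
  undef <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); 0 } else num / den
  }
  out <- c(accuracy = (cc$TP + cc$TN) / total,
           precision = div(cc$TP, cc$TP + cc$FP, "precision"),
           recall = div(cc$TP, cc$TP + cc$FN, "recall"),
           f1 = div(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN, "f1"))
  if (length(undef))
    warnf("zero denominator for %s; sentinel 0 returned",
          paste(undef, collapse = ", "))
  attr(out, "undefined") <- undef
  out
}

#' Cross-validated training and evaluation
#'
#' Splits the dataset with [kfold_split()], trains one model per fold on
#' the train side and evaluates on the held-out side, and reports per-fold
#' accuracy/precision/recall/F1 plus their mean and standard deviation
#' (population SD, `n_folds` denominator) across folds.
#'
#' @param dataset a labeled [epoch_set()].
#' @param spec a [model_spec()] (ignored when `trainer` is given).
#' @param config a [train_config()].
#' @param n_epochs training epochs per fold (default `config$max_epochs`).
#' @param positive_class positive class for the metrics (default `"DD"`).
#' @param trainer optional custom trainer
#'   `function(train_set, config, seed)` returning a function that maps an
#'   epoch set to predicted labels (used for stub models and comparisons).
#' @param verbose print per-fold progress.
#' @return An object of class `cv_report`: `per_fold` (folds x metrics
#'   matrix), `mean`, `sd`, `confusions`, `band`, `config`.
#' @export
cross_validate <- function(dataset, spec, config = train_config(),
                           n_epochs = config$max_epochs,
                           positive_class = "DD", trainer = NULL,
                           verbose = FALSE) {
  if (config$fold_unit == "epoch_level" &&
      length(unique(dataset$subject_ids)) > 1)
    message("epoch_level folds: epochs of one subject may occur in both train and test (no subject-level leakage guard)")
  folds <- kfold_split(dataset, config)
  per <- matrix(NA_real_, length(folds), 4,
                dimnames = list(NULL, c("accuracy", "precision", "recall", "f1")))
  confs <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- epochs_subset(dataset, folds[[f]]$train)
    te <- epochs_subset(dataset, folds[[f]]$test)
    pred_fun <- if (is.null(trainer)) {
      mod <- build_model(spec, seed = derive_seed(config$seed, f))
      mod <- train_model(mod, tr, config, n_epochs = n_epochs)
      function(ep) predict_labels(mod, ep)
    } else {
      trainer(tr, config, derive_seed(config$seed, f))
    }
    cc <- confusion(pred_fun(te), te$labels, positive_class)
    confs[[f]] <- cc
    per[f, ] <- suppressWarnings(metrics(cc))
    if (verbose)
      message(sprintf("fold %d/%d: acc %.3f", f, length(folds), per[f, 1]))
  }
  structure(list(per_fold = per,
                 mean = colMeans(per),
                 sd = apply(per, 2, sd_pop),
                 confusions = confs,
                 band = dataset$band,
                 n = dim(dataset$data)[1],
                 positive_class = positive_class,
                 config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  bd <- if (inherits(x$band, "band_spec"))
    sprintf("%g-%g Hz", x$band$low_hz, x$band$high_hz) else as.character(x$band)
  cat(sprintf("<cv_report> %d epochs, band %s, %d folds (%s), positive = %s\n",
              x$n, bd, nrow(x$per_fold), x$config$fold_unit, x$positive_class))
  line <- paste(sprintf("%s %.2f +/- %.2f%%",
                        c("Accuracy", "F1", "Precision", "Recall"),
                        100 * x$mean[c("accuracy", "f1", "precision", "recall")],
                        100 * x$sd[c("accuracy", "f1", "precision", "recall")]),
                collapse = " | ")
  cat(" ", line, "\n")
  invisible(x)
}

#' Format cross-validation reports as a band-by-metric table
#'
#' Renders one row per report in the layout mean +/- SD percent for
#' Accuracy, F1, Precision and Recall.
#'
#' @param reports named list of `cv_report`s (names become row labels).
#' @return A data.frame of formatted strings.
#' @export
report_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    v <- sprintf("%.2f ± %.2f%%",
                 100 * r$mean[c("accuracy", "f1", "precision", "recall")],
                 100 * r$sd[c("accuracy", "f1", "precision", "recall")])
    stats::setNames(as.list(v), c("Accuracy", "F1_Score", "Precision", "Recall"))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(df) <- names(reports)
  df
}

#' Paired t-test across seed replicates
#'
#' Utility for comparing two models (or two bands) run over the same set of
#' seeds: a paired two-sided t-test on per-replicate accuracies.
#'
#' @param acc_a,acc_b equal-length accuracy vectors, one entry per seed.
#' @return `htest` object from [stats::t.test()].
#' @export
replicate_ttest <- function(acc_a, acc_b) {
  stats::t.test(acc_a, acc_b, paired = TRUE)
}
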