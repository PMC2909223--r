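#' Confusion-count metrics
#'
#' Computes TPR = TP/(TP+FN) (recall/sensitivity), FPR = FP/(FP+TN),
#' precision = TP/(TP+FP), and accuracy = (TP+TN)/total. A ratio with a
#' zero denominator is reported as `NA` (undefined), which is distinct
#' from 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`,
#'   `precision`, `accuracy`.
#' @examples
#' confusion_metrics(tp = 25, fp = 16, tn = 46, fn = 2)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = ratio(tp, tp + fn),
    fpr = ratio(fp, fp + tn),
    precision = ratio(tp, tp + fp),
    accuracy = (tp + tn) / total
  )
}

#' Multi-class accuracy from per-class counts
#'
#' @param correct,total Equal-length numeric vectors of per-class correct
#'   and total counts.
#' @return `sum(correct) / sum(total)`.
#' @examples
#' multiclass_accuracy(c(43, 16, 19), c(45, 20, 21))
#' @export
multiclass_accuracy <- function(correct, total) {
  if (length(correct) == 0L || length(correct) != length(total)) {
    stop("correct and total must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(total <= 0) || any(correct < 0) || any(correct > total)) {
    stop("need 0 <= correct <= total with total > 0", call. = FALSE)
  }
  sum(correct) / sum(total)
}

.check_binary_scores <- function(scores, labels, positive) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  labels <- as.character(labels)
  if (is.null(positive)) {
    positive <- if ("binding" %in% labels) "binding" else
      sort(unique(labels))[1L]
  }
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  list(is_pos = is_pos, positive = positive)
}

# Threshold sweep shared by roc_curve / pr_curve: instances sorted by
# decreasing score, tied scores grouped into one threshold.
.sweep_counts <- function(scores, is_pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- is_pos[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tie group
  tibble::tibble(
    threshold = s[keep],
    cum_tp = cumsum(p)[keep],
    cum_fp = cumsum(!p)[keep]
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values (tied
#' scores grouped), yielding points monotone in both axes from (0, 0) to
#' (1, 1). The AUC is the trapezoidal area, which equals the Mann-Whitney
#' probability that a random positive outscores a random negative, with
#' half credit for ties.
#'
#' @param scores Numeric vector, higher = more positive.
#' @param labels Class labels (two classes present).
#' @param positive The positive-class label; defaults to `"binding"` when
#'   present, else the alphabetically first label.
#' @return A `pdz_roc` object: list with `points` (tibble of `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_curve(c(.9, .8, .4, .3), c("+", "-", "+", "-"), positive = "+")$auc
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  chk <- .check_binary_scores(scores, labels, positive)
  P <- sum(chk$is_pos)
  N <- sum(!chk$is_pos)
  sw <- .sweep_counts(scores, chk$is_pos)
  pts <- tibble::tibble(
    threshold = c(Inf, sw$threshold),
    fpr = c(0, sw$cum_fp / N),
    tpr = c(0, sw$cum_tp / P)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, positive = chk$positive),
            class = "pdz_roc")
}

#' @export
print.pdz_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f (positive = %s)\n",
              nrow(x$points), x$auc, x$positive))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pdz_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr,
                                              y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Precision-recall curve
#'
#' Same threshold sweep as [roc_curve()]; recall is non-decreasing along
#' the sweep. With all scores tied the curve collapses to the single point
#' (recall 1, precision = prevalence).
#'
#' @inheritParams roc_curve
#' @return Tibble of `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels, positive = NULL) {
  chk <- .check_binary_scores(scores, labels, positive)
  P <- sum(chk$is_pos)
  sw <- .sweep_counts(scores, chk$is_pos)
  tibble::tibble(
    threshold = sw$threshold,
    recall = sw$cum_tp / P,
    precision = sw$cum_tp / (sw$cum_tp + sw$cum_fp)
  )
}

#' Plot a precision-recall curve
#' @param pr Tibble from [pr_curve()].
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(pr) {
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$recall,
                                   y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

# Deterministic stratified fold assignment: within each class, a seeded
# shuffle of rep(1:k). Proportions per fold stay within one instance of
# the global class proportions.
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in levels(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the forest model
#'
#' Instances are assigned to folds stratified by label (deterministic given
#' `seed`); each instance is tested exactly once. Confusion counts are
#' pooled across folds before metrics are computed (micro aggregation);
#' per-fold reports are also returned. Stratified resampling with
#' replacement can be applied inside each training fold (default), before
#' the split (which duplicates instances across folds and thereby leaks
#' test information — kept available for fidelity with pre-processing
#' pipelines that resample first), or not at all.
#'
#' @param data Modelling tibble (label column + numeric features).
#' @param label Name of the label column.
#' @param k Number of folds (default 10); every class needs at least `k`
#'   instances.
#' @param params A [forest_params()]; per-fold seeds are derived from
#'   `params$seed`.
#' @param seed Integer seed for the fold assignment.
#' @param resample One of `"within-folds"`, `"none"`, `"before-cv"`.
#' @param positive Positive-class label for binary tasks (see
#'   [roc_curve()]).
#' @return A `pdz_cv` object: `task` ("binary" or "multiclass"),
#'   `metrics` (pooled, one row), `fold_metrics`, `confusion`,
#'   `predictions`, `roc`, `pr`, `auc`, and for multi-class tasks
#'   `per_class` counts. `auc` for multi-class is the class-size-weighted
#'   mean of one-vs-rest AUCs.
#' @export
cross_validate <- function(data, label = "label", k = 10,
                           params = forest_params(), seed = 1L,
                           resample = c("within-folds", "none",
                                        "before-cv"),
                           positive = NULL) {
  resample <- match.arg(resample)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (resample == "before-cv") {
    data <- resample_stratified(data, label, seed = seed)
  }
  y <- droplevels(factor(data[[label]]))
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  loo <- k == nrow(data)  # leave-one-out needs no stratification
  if (!loo) {
    small <- table(y)[table(y) < k]
    if (length(small) > 0L) {
      stop(sprintf(
        "class '%s' has only %d instance(s), fewer than k = %d; use a smaller k",
        names(small)[1L], small[1L], k), call. = FALSE)
    }
  }
  data[[label]] <- y
  fold <- if (loo) seq_len(nrow(data)) else .stratified_folds(y, k, seed)

  preds <- purrr::map(seq_len(k), function(i) {
    train <- data[fold != i, , drop = FALSE]
    if (resample == "within-folds") {
      train <- resample_stratified(train, label,
                                   seed = as.integer(seed) + i)
    }
    fit <- train_forest(train, label,
                        forest_params(params$numTree, params$numFeature,
                                      seed = params$seed + i))
    test <- data[fold == i, , drop = FALSE]
    sc <- predict_score(fit, test)
    sc$.row <- which(fold == i)
    sc$.fold <- i
    sc$.truth <- test[[label]]
    sc
  }) |> purrr::list_rbind()
  preds <- dplyr::arrange(preds, .data$.row)

  classes <- levels(y)
  fold_metrics <- preds |>
    dplyr::group_by(fold = .data$.fold) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = mean(.data$.pred_class == .data$.truth),
                     .groups = "drop")

  if (length(classes) == 2L) {
    pos <- if (is.null(positive)) {
      if ("binding" %in% classes) "binding" else classes[1L]
    } else positive
    scores <- preds[[paste0(".vote_", pos)]]
    truth_pos <- preds$.truth == pos
    pred_pos <- preds$.pred_class == pos
    metrics <- confusion_metrics(
      tp = sum(pred_pos & truth_pos), fp = sum(pred_pos & !truth_pos),
      tn = sum(!pred_pos & !truth_pos), fn = sum(!pred_pos & truth_pos)
    )
    roc <- roc_curve(scores, preds$.truth, positive = pos)
    out <- list(
      task = "binary", k = k, positive = pos, classes = classes,
      metrics = metrics, fold_metrics = fold_metrics,
      confusion = metrics[c("tp", "fp", "tn", "fn")],
      predictions = preds, roc = roc,
      pr = pr_curve(scores, preds$.truth, positive = pos),
      auc = roc$auc, params = params, seed = as.integer(seed),
      resample = resample
    )
  } else {
    per_class <- preds |>
      dplyr::group_by(class = .data$.truth) |>
      dplyr::summarise(correct = sum(.data$.pred_class == .data$.truth),
                       total = dplyr::n(), .groups = "drop")
    ovr <- purrr::map_dbl(classes, function(cl) {
      roc_curve(preds[[paste0(".vote_", cl)]],
                ifelse(preds$.truth == cl, cl, "rest"),
                positive = cl)$auc
    })
    wts <- as.numeric(table(y)[classes])
    acc <- multiclass_accuracy(per_class$correct, per_class$total)
    out <- list(
      task = "multiclass", k = k, classes = classes,
      metrics = tibble::tibble(accuracy = acc,
                               auc = sum(ovr * wts) / sum(wts)),
      fold_metrics = fold_metrics,
      per_class = per_class,
      confusion = as.data.frame(table(truth = preds$.truth,
                                      predicted = preds$.pred_class)),
      predictions = preds,
      ovr_auc = stats::setNames(ovr, classes),
      auc = sum(ovr * wts) / sum(wts),
      params = params, seed = as.integer(seed), resample = resample
    )
  }
  structure(out, class = "pdz_cv")
}

#' Evaluate a trained forest on an independent dataset
#'
#' Applies the model to a held-out table (for example an unseen validation
#' set) and reports the same confusion metrics, ROC and PR summaries as
#' [cross_validate()].
#'
#' @param model A `pdz_forest`.
#' @param data Modelling tibble with the model's feature columns and a
#'   label column.
#' @param label Name of the label column.
#' @param positive Positive-class label (binary tasks).
#' @return A `pdz_eval` list: `metrics`, `confusion`, `roc`, `pr`, `auc`,
#'   `predictions` (binary), or `metrics`, `per_class`, `confusion`
#'   (multi-class).
#' @export
evaluate_model <- function(model, data, label = "label", positive = NULL) {
  sc <- predict_score(model, data)
  truth <- factor(as.character(data[[label]]), levels = model$classes)
  if (anyNA(truth)) stop("labels outside the model's class list",
                         call. = FALSE)
  if (length(model$classes) == 2L) {
    pos <- if (is.null(positive)) {
      if ("binding" %in% model$classes) "binding" else model$classes[1L]
    } else positive
    scores <- sc[[paste0(".vote_", pos)]]
    pred_pos <- sc$.pred_class == pos
    truth_pos <- truth == pos
    metrics <- confusion_metrics(
      tp = sum(pred_pos & truth_pos), fp = sum(pred_pos & !truth_pos),
      tn = sum(!pred_pos & !truth_pos), fn = sum(!pred_pos & truth_pos)
    )
    roc <- roc_curve(scores, truth, positive = pos)
    structure(list(task = "binary", positive = pos, metrics = metrics,
                   confusion = metrics[c("tp", "fp", "tn", "fn")],
                   roc = roc, pr = pr_curve(scores, truth, positive = pos),
                   auc = roc$auc,
                   predictions = dplyr::mutate(sc, .truth = truth)),
              class = "pdz_eval")
  } else {
    per_class <- tibble::tibble(class = model$classes) |>
      dplyr::rowwise() |>
      dplyr::mutate(correct = sum(sc$.pred_class == .data$class &
                                    truth == .data$class),
                    total = sum(truth == .data$class)) |>
      dplyr::ungroup()
    structure(list(
      task = "multiclass",
      metrics = tibble::tibble(
        accuracy = multiclass_accuracy(per_class$correct,
                                       per_class$total)),
      per_class = per_class,
      confusion = as.data.frame(table(truth = truth,
                                      predicted = sc$.pred_class)),
      predictions = dplyr::mutate(sc, .truth = truth)
    ), class = "pdz_eval")
  }
}

#' @export
print.pdz_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (%s task)\n", x$k,
              x$task))
  print(x$metrics)
  cat(sprintf("AUC: %.4f\n", x$auc))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pdz_cv <- function(x, ...) {
  m <- x$metrics
  if (!"auc" %in% names(m)) m$auc <- x$auc
  m$k <- x$k
  m$task <- x$task
  m
}

#' @exportS3Method generics::tidy
tidy.pdz_cv <- function(x, ...) {
  x$fold_metrics
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.pdz_cv <- function(object, ...) {
  if (object$task == "binary") {
    autoplot.pdz_roc(object$roc)
  } else {
    df <- object$confusion
    ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                     fill = .data$Freq)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
      ggplot2::labs(x = "Predicted class", y = "True class") +
      ggplot2::theme_minimal()
  }
}
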