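#' Random Forest parameters
#'
#' `numTree` is the number of trees in the ensemble and `numFeature` the
#' number of randomly chosen candidate features per split. The defaults
#' (200 trees, 30 features) are the OOB-optimal setting for the trigram
#' interaction model; `numFeature` should stay well below the feature
#' dimension.
#'
#' @param numTree Positive integer, number of trees.
#' @param numFeature Positive integer, candidate features per split.
#' @param seed Integer seed making training deterministic.
#' @return A `forest_params` list.
#' @export
forest_params <- function(numTree = 200, numFeature = 30, seed = 1L) {
  if (numTree < 1 || numFeature < 1) {
    stop("numTree and numFeature must be positive", call. = FALSE)
  }
  structure(list(numTree = as.integer(numTree),
                 numFeature = as.integer(numFeature),
                 seed = as.integer(seed)),
            class = "forest_params")
}

# Feature columns of a modelling table: all numeric columns except the label.
.feature_cols <- function(data, label) {
  num <- vapply(data, is.numeric, logical(1))
  setdiff(names(data)[num], label)
}

#' Stratified resampling with replacement
#'
#' Draws a bootstrap sample of the same size as the input, stratified by
#' label so that per-class counts are preserved exactly (the class
#' distribution is left as-is). Used to stabilize training on imbalanced
#' interaction tables.
#'
#' @param data Modelling tibble containing `label`.
#' @param label Name of the label column.
#' @param seed Integer seed.
#' @return Tibble of the same size and class composition, rows drawn with
#'   replacement.
#' @export
resample_stratified <- function(data, label = "label", seed = 1L) {
  if (nrow(data) == 0L) stop("cannot resample an empty dataset",
                             call. = FALSE)
  y <- data[[label]]
  idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(nrow(data)), y, drop = TRUE), function(i) {
      sample(i, length(i), replace = TRUE)
    }), use.names = FALSE)
  })
  data[sort(idx), , drop = FALSE]
}

#' Train a Random Forest on an encoded dataset
#'
#' Grows `numTree` trees, each on a bootstrap sample of the data,
#' considering `numFeature` random candidate features at every split, and
#' records the out-of-bag (OOB) error: each tree is tested on the instances
#' left out of its bootstrap sample, giving an internal error estimate
#' without a held-out set.
#'
#' @param data Modelling tibble: a label column plus numeric feature
#'   columns (id columns are ignored).
#' @param label Name of the label column (factor or character with >= 2
#'   observed classes).
#' @param params A [forest_params()].
#' @return A `pdz_forest` object with elements `rf` (the fitted ensemble),
#'   `features`, `classes`, `oob_error`, `params`.
#' @export
train_forest <- function(data, label = "label", params = forest_params()) {
  feats <- .feature_cols(data, label)
  if (length(feats) == 0L) stop("no numeric feature columns found",
                                call. = FALSE)
  y <- droplevels(factor(data[[label]]))
  if (nlevels(y) < 2L) {
    stop("training data contains a single class; need at least 2",
         call. = FALSE)
  }
  if (params$numFeature > length(feats)) {
    stop(sprintf("numFeature (%d) exceeds feature dimension (%d)",
                 params$numFeature, length(feats)), call. = FALSE)
  }
  x <- as.matrix(data[feats])
  if (anyNA(x)) stop("feature matrix contains NA", call. = FALSE)
  rf <- withr::with_seed(params$seed, {
    randomForest::randomForest(
      x = x, y = y,
      ntree = params$numTree, mtry = params$numFeature
    )
  })
  structure(list(
    rf = rf,
    features = feats,
    classes = levels(y),
    oob_error = unname(rf$err.rate[params$numTree, "OOB"]),
    params = params
  ), class = "pdz_forest")
}

#' Predict class-vote scores with a trained forest
#'
#' Scores are the fraction of trees voting for each class, so each row sums
#' to 1; the predicted label is the argmax, with ties broken toward the
#' class listed first in the model's class list.
#'
#' @param model A `pdz_forest`.
#' @param newdata Tibble containing the model's feature columns.
#' @return Tibble with one `.vote_<class>` column per class and
#'   `.pred_class`; for binary models the first class's vote fraction is
#'   the natural ROC score.
#' @export
predict_score <- function(model, newdata) {
  miss <- setdiff(model$features, names(newdata))
  if (length(miss) > 0L) {
    stop("newdata is missing ", length(miss), " model feature(s), e.g. ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[model$features])
  votes <- stats::predict(model$rf, x, type = "vote", norm.votes = TRUE)
  votes <- votes[, model$classes, drop = FALSE]
  # argmax with ties toward the first-listed class
  pred <- model$classes[apply(votes, 1L, which.max)]
  out <- tibble::as_tibble(as.data.frame(votes))
  names(out) <- paste0(".vote_", model$classes)
  out$.pred_class <- factor(pred, levels = model$classes)
  out
}

#' OOB grid search over forest parameters
#'
#' Trains one forest per (numTree, numFeature) grid point and returns the
#' pair with minimal OOB error; ties are broken toward the smaller
#' numFeature, then the smaller numTree. The full OOB table is returned for
#' reporting the error surface.
#'
#' @param data,label As in [train_forest()].
#' @param tree_grid,feature_grid Candidate values; the defaults bracket the
#'   200-tree / 30-feature optimum of the trigram interaction model.
#' @param seed Integer seed shared by all grid points.
#' @return List with `best` (a [forest_params()]) and `table` (tibble of
#'   numTree, numFeature, oob_error).
#' @export
grid_search_oob <- function(data, label = "label",
                            tree_grid = c(10, 50, 100, 200, 500),
                            feature_grid = c(5, 10, 20, 30, 50, 100),
                            seed = 1L) {
  if (length(tree_grid) == 0L || length(feature_grid) == 0L) {
    stop("parameter grids must be non-empty", call. = FALSE)
  }
  grid <- tidyr::expand_grid(numTree = as.integer(tree_grid),
                             numFeature = as.integer(feature_grid))
  grid$oob_error <- purrr::map2_dbl(grid$numTree, grid$numFeature,
    function(nt, nf) {
      train_forest(data, label,
                   forest_params(nt, nf, seed = seed))$oob_error
    })
  best <- grid |>
    dplyr::arrange(.data$oob_error, .data$numFeature, .data$numTree) |>
    dplyr::slice(1L)
  list(best = forest_params(best$numTree, best$numFeature, seed = seed),
       table = grid)
}

#' Save / load a trained forest
#'
#' The file carries a documented header (feature-naming convention, gram
#' length implied by the feature names, parameters and class list) so that
#' models are portable across sessions.
#'
#' @param model A `pdz_forest`.
#' @param path File path.
#' @return `save_forest` returns `path` invisibly; `load_forest` the model.
#' @export
save_forest <- function(model, path) {
  stopifnot(inherits(model, "pdz_forest"))
  payload <- list(
    format = "pdzgram-forest-1",
    feature_convention = "lexicographic gram order, <block>_<tg|bg>_<gram>",
    classes = model$classes,
    params = unclass(model$params),
    model = model
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "pdzgram-forest-1")) {
    stop("not a pdzgram forest file: ", path, call. = FALSE)
  }
  payload$model
}

#' @export
print.pdz_forest <- function(x, ...) {
  cat(sprintf(
    "Random forest: %d trees, %d candidate features/split, %d features\n",
    x$params$numTree, x$params$numFeature, length(x$features)))
  cat("Classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("OOB error: %.4f\n", x$oob_error))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @exportS3Method generics::glance
glance.pdz_forest <- function(x, ...) {
  tibble::tibble(
    numTree = x$params$numTree,
    numFeature = x$params$numFeature,
    n_features = length(x$features),
    n_classes = length(x$classes),
    oob_error = x$oob_error
  )
}

#' @exportS3Method generics::tidy
tidy.pdz_forest <- function(x, ...) {
  imp <- randomForest::importance(x$rf)
  tibble::tibble(
    feature = rownames(imp),
    importance = as.numeric(imp[, 1L])
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
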