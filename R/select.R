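#' Feature-class correlation
#'
#' For binary labels this is the absolute point-biserial (Pearson)
#' correlation between the feature column and the 0/1 label; for more than
#' two classes it is the multiple correlation of the column with the
#' one-hot-encoded label, i.e. `sqrt(SS_between / SS_total)` from the
#' one-way decomposition. Both lie in [0, 1] and coincide for two classes.
#' A zero-variance column is defined to have correlation 0.
#'
#' @param column Numeric feature column.
#' @param labels Class labels (2 or more classes).
#' @return Correlation in [0, 1].
#' @export
feature_class_correlation <- function(column, labels) {
  labels <- factor(labels)
  if (length(column) != length(labels)) {
    stop("column and labels must have equal length", call. = FALSE)
  }
  sst <- sum((column - mean(column))^2)
  if (sst == 0) return(0)
  mu <- tapply(column, labels, mean)
  nc <- tapply(column, labels, length)
  ssb <- sum(nc * (mu - mean(column))^2, na.rm = TRUE)
  sqrt(max(0, min(1, ssb / sst)))
}

# Precomputed correlation structure so searches do not recompute Pearson
# correlations per candidate subset.
.cfs_precompute <- function(X, labels) {
  X <- as.matrix(X)
  rcf <- apply(X, 2L, feature_class_correlation, labels = labels)
  sds <- apply(X, 2L, stats::sd)
  rff <- suppressWarnings(abs(stats::cor(X)))
  rff[!is.finite(rff)] <- 0  # zero-variance columns
  diag(rff) <- 1
  list(rcf = rcf, rff = rff, p = ncol(X), sds = sds)
}

.merit_from_pre <- function(subset, pre) {
  k <- length(subset)
  if (k == 0L) return(0)
  rcf_bar <- mean(pre$rcf[subset])
  if (k == 1L) return(rcf_bar)
  sub_rff <- pre$rff[subset, subset]
  rff_bar <- mean(sub_rff[upper.tri(sub_rff)])
  denom <- sqrt(k + k * (k - 1) * rff_bar)
  if (denom == 0) return(0)
  k * rcf_bar / denom
}

#' CFS merit of a feature subset
#'
#' The correlation-based feature selection (CFS) heuristic scores a subset
#' of k features as
#' `merit = k * mean(r_cf) / sqrt(k + k (k - 1) * mean(r_ff))`,
#' where `r_cf` are the feature-class correlations of the members and
#' `r_ff` the absolute pairwise Pearson correlations among them. Good
#' subsets correlate with the label but not with each other; a duplicated
#' feature raises `mean(r_ff)` and is penalized. For k = 1 the merit
#' reduces to the feature's own `r_cf`.
#'
#' @param subset Integer vector of feature column positions in `X`.
#' @param X Numeric feature matrix or data frame (columns = features).
#' @param labels Class labels.
#' @return The merit (a finite number, 0 for degenerate subsets).
#' @export
cfs_merit <- function(subset, X, labels) {
  subset <- unique(as.integer(subset))
  if (length(subset) == 0L) stop("subset must be non-empty", call. = FALSE)
  X <- as.matrix(X)
  if (any(subset < 1L | subset > ncol(X))) {
    stop("subset indices out of range", call. = FALSE)
  }
  .merit_from_pre(subset, .cfs_precompute(X, labels))
}

# key for visited-state bookkeeping ("0" = the empty state)
.subset_key <- function(s) {
  if (length(s) == 0L) "0" else paste(sort(s), collapse = ",")
}

#' Search for a high-merit feature subset
#'
#' Two deterministic search strategies over the CFS merit landscape.
#' `greedy-forward` adds the single best feature (lowest index on ties)
#' until the merit stops improving. `best-first` keeps an open list of
#' states ordered by merit, repeatedly expands the best unexpanded state by
#' adding or removing one feature, and stops after `stall_limit`
#' consecutive expansions that fail to improve the best merit seen; it
#' explores a superset of the greedy frontier and never returns a worse
#' subset.
#'
#' @param X Numeric feature matrix or data frame.
#' @param labels Class labels.
#' @param strategy `"best-first"` or `"greedy-forward"`.
#' @param seed Integer recorded as provenance (the searches themselves are
#'   deterministic).
#' @param stall_limit Consecutive non-improving best-first expansions
#'   allowed before stopping.
#' @return A `feature_subset` list: `indices` (sorted), `features`
#'   (column names, if any), `merit`, `strategy`, `seed`.
#' @export
cfs_search <- function(X, labels, strategy = c("best-first",
                                               "greedy-forward"),
                       seed = 1L, stall_limit = 5L) {
  strategy <- match.arg(strategy)
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("need at least one feature", call. = FALSE)
  pre <- .cfs_precompute(X, labels)
  best <- switch(strategy,
                 "greedy-forward" = .greedy_forward(pre),
                 "best-first" = .best_first(pre, stall_limit))
  structure(list(
    indices = sort(best$subset),
    features = if (!is.null(colnames(X))) colnames(X)[sort(best$subset)],
    merit = best$merit,
    strategy = strategy,
    seed = as.integer(seed)
  ), class = "feature_subset")
}

.greedy_forward <- function(pre) {
  current <- integer(0)
  current_merit <- 0
  repeat {
    cands <- setdiff(seq_len(pre$p), current)
    if (length(cands) == 0L) break
    merits <- vapply(cands, function(f) .merit_from_pre(c(current, f), pre),
                     numeric(1))
    best_i <- which.max(merits)  # which.max takes the first (lowest index)
    if (merits[best_i] > current_merit) {
      current <- c(current, cands[best_i])
      current_merit <- merits[best_i]
    } else break
  }
  if (length(current) == 0L) {  # no single feature beats merit 0
    current <- which.max(pre$rcf)
    current_merit <- .merit_from_pre(current, pre)
  }
  list(subset = current, merit = current_merit)
}

.best_first <- function(pre, stall_limit) {
  # states are integer subsets; open list ordered by merit, ties by
  # insertion order; successors add or remove one feature
  open <- list(list(subset = integer(0), merit = 0))
  visited <- new.env(parent = emptyenv())
  assign(.subset_key(integer(0)), TRUE, envir = visited)
  best_subset <- integer(0)
  best_merit <- 0
  stall <- 0L
  while (length(open) > 0L && stall < stall_limit) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    i <- which.max(merits)
    state <- open[[i]]
    open[[i]] <- NULL
    improved <- FALSE
    succ_sets <- c(
      lapply(setdiff(seq_len(pre$p), state$subset),
             function(f) c(state$subset, f)),
      if (length(state$subset) > 1L)
        lapply(seq_along(state$subset),
               function(j) state$subset[-j])
    )
    for (s in succ_sets) {
      key <- .subset_key(s)
      if (!is.null(visited[[key]])) next
      assign(key, TRUE, envir = visited)
      m <- .merit_from_pre(s, pre)
      open[[length(open) + 1L]] <- list(subset = s, merit = m)
      if (m > best_merit) {
        best_merit <- m
        best_subset <- s
        improved <- TRUE
      }
    }
    stall <- if (improved) 0L else stall + 1L
  }
  if (length(best_subset) == 0L) {
    best_subset <- which.max(pre$rcf)
    best_merit <- .merit_from_pre(best_subset, pre)
  }
  list(subset = best_subset, merit = best_merit)
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("CFS subset (%s): %d feature(s), merit %.4f\n",
              x$strategy, length(x$indices), x$merit))
  if (!is.null(x$features)) {
    cat(" ", paste(utils::head(x$features, 12), collapse = ", "),
        if (length(x$features) > 12) "...", "\n")
  }
  invisible(x)
}

#' Run CFS selection on an encoded dataset
#'
#' Convenience wrapper over [cfs_search()] for modelling tables produced
#' by [build_interaction_dataset()] or [build_class_dataset()]. For
#' interaction tables the domain block (`pdz_*` columns) and the peptide
#' block (`pep_*` columns) are searched separately, mirroring the
#' domain/peptide reporting convention. All configured strategies are run
#' and their subsets combined (union by default; intersection optionally).
#'
#' @param data Modelling tibble.
#' @param label Name of the label column.
#' @param strategies Character vector of [cfs_search()] strategies to run.
#' @param combine `"union"` or `"intersection"` of the per-strategy
#'   subsets.
#' @param seed Integer provenance seed.
#' @param stall_limit Passed to [cfs_search()].
#' @return Tibble with one row per selected feature: `feature`, `block`
#'   (`pdz` / `pep`), `gram`, `merit` (of the selecting subset),
#'   `strategy` (comma-joined strategies that selected it).
#' @export
select_features <- function(data, label = "label",
                            strategies = c("best-first",
                                           "greedy-forward"),
                            combine = c("union", "intersection"),
                            seed = 1L, stall_limit = 5L) {
  combine <- match.arg(combine)
  feats <- .feature_cols(data, label)
  blocks <- split(feats, sub("_.*$", "", feats))
  res <- purrr::map(blocks, function(cols) {
    X <- as.matrix(data[cols])
    per_strat <- purrr::map(strategies, function(st) {
      fs <- cfs_search(X, data[[label]], strategy = st, seed = seed,
                       stall_limit = stall_limit)
      tibble::tibble(feature = cols[fs$indices], merit = fs$merit,
                     strategy = st)
    }) |> purrr::list_rbind()
    keep <- if (combine == "union") {
      unique(per_strat$feature)
    } else {
      Reduce(intersect, split(per_strat$feature, per_strat$strategy))
    }
    per_strat |>
      dplyr::filter(.data$feature %in% keep) |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(merit = max(.data$merit),
                       strategy = paste(sort(unique(.data$strategy)),
                                        collapse = ","),
                       .groups = "drop")
  }) |> purrr::list_rbind()
  res |>
    dplyr::mutate(
      block = sub("_.*$", "", .data$feature),
      gram = sub("^[a-z]+_[tb]g_", "", .data$feature)
    ) |>
    dplyr::select("feature", "block", "gram", "merit", "strategy") |>
    dplyr::arrange(dplyr::desc(.data$merit), .data$feature)
}

#' Bigrams contained in selected trigrams
#'
#' The consensus step of motif extraction: a selected bigram is retained
#' when it occurs as a substring of at least one selected trigram, the
#' observation being that conserved bigrams are parts of the conserved
#' trigrams.
#'
#' @param trigrams Character vector of selected trigram labels (digits
#'   1..7).
#' @param bigrams Character vector of selected bigram labels.
#' @return Tibble with `bigram` and `hosts` (comma-joined host trigrams);
#'   empty if the sets are disjoint.
#' @examples
#' consensus_features(c("125", "612"), c("12", "25", "34"))
#' @export
consensus_features <- function(trigrams, bigrams) {
  for (g in c(trigrams, bigrams)) .check_gram(g)
  bigrams <- unique(bigrams)
  trigrams <- unique(trigrams)
  rows <- purrr::map(bigrams, function(b) {
    hosts <- trigrams[vapply(trigrams, function(t) grepl(b, t, fixed = TRUE),
                             logical(1))]
    if (length(hosts) == 0L) return(NULL)
    tibble::tibble(bigram = b, hosts = paste(hosts, collapse = ","))
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0L) {
    tibble::tibble(bigram = character(0), hosts = character(0))
  } else out
}
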