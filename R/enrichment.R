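#' Per-bin principal-loop anchor participation counts
#'
#' Counts, for each bin, how many specific principal-loop complexes use it as
#' an anchor — the quantity whose sorted profile drives the elbow labeling.
#'
#' @param calls A `manybody_calls` tibble.
#' @param n_bins Number of bins in the locus.
#' @param specific_only Count only specific complexes (default `TRUE`).
#' @return Integer vector of length `n_bins`.
#' @export
anchor_participation <- function(calls, n_bins, specific_only = TRUE) {
  calls <- tibble::as_tibble(as.data.frame(calls))
  if (specific_only && "specific" %in% names(calls)) {
    calls <- dplyr::filter(calls, .data$specific)
  }
  counts <- integer(n_bins)
  for (b in c(calls$anchor1, calls$anchor2)) counts[b] <- counts[b] + 1L
  counts
}

#' Elbow-rule enrichment labels
#'
#' Bins are sorted by participation count (descending); the elbow is the
#' rank maximizing the perpendicular distance to the line joining the first
#' and last sorted points. Bins strictly above the elbow are candidates, of
#' which the top `top_fraction` (by count) are labeled `enriched` and the
#' rest `discarded` (ambiguous); all bins at or below the elbow are
#' `not_enriched`. Constant or monotone-linear profiles have no elbow and
#' raise an error.
#'
#' @param counts Per-bin participation counts (numeric vector).
#' @param top_fraction Fraction of above-elbow bins kept as enriched
#'   (default 0.2).
#' @return An `enrichment_labels` tibble: `bin`, `count`, `rank`, `label`;
#'   `attr(, "elbow_rank")` stores the elbow position.
#' @export
elbow_label <- function(counts, top_fraction = 0.2) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  n <- length(counts)
  if (n < 3) abort("Need at least 3 bins to locate an elbow.")
  if (max(counts) == min(counts)) {
    abort("Constant counts: no elbow exists.")
  }
  ord <- order(counts, decreasing = TRUE)
  y <- counts[ord]
  x <- seq_len(n)
  # perpendicular distance from each sorted point to the chord (1,y1)-(n,yn)
  dx <- n - 1
  dy <- y[n] - y[1]
  dist_perp <- abs(dy * (x - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  elbow <- which.max(dist_perp)
  if (elbow == 1) {
    abort("Elbow falls at the profile end (monotone/linear counts).")
  }
  above <- seq_len(elbow - 1)
  n_keep <- max(1L, ceiling(top_fraction * length(above)))
  label <- rep("not_enriched", n)
  label[above] <- "discarded"
  label[above[seq_len(n_keep)]] <- "enriched"
  out <- tibble::tibble(
    bin = ord, count = y, rank = x, label = label
  )
  out <- dplyr::arrange(out, .data$bin)
  structure(out,
    elbow_rank = elbow,
    class = c("enrichment_labels", class(out))
  )
}

rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

prepare_features <- function(features) {
  x <- if (is.data.frame(features)) {
    as.matrix(features[setdiff(names(features), "bin")])
  } else {
    as.matrix(features)
  }
  storage.mode(x) <- "double"
  x
}

#' Train the principal-loop enrichment random forest
#'
#' A 500-tree random forest with stratified (balanced) per-tree bootstrap:
#' each tree sees equal numbers of positive and negative samples so the
#' heavy class imbalance of enriched-vs-not bins cannot collapse the vote to
#' the majority class. Features are z-scored before training. The out-of-bag
#' error is class-balanced (macro-averaged over the two per-class error
#' rates); it and two feature-importance measures (mean decrease in accuracy via
#' out-of-bag permutation, and total Gini decrease) are computed during
#' training. `discarded` labels are excluded.
#'
#' @param features Bin-by-track table (tibble with optional `bin` column, or
#'   matrix).
#' @param labels An `enrichment_labels` tibble, or a vector of
#'   `enriched` / `not_enriched` / `discarded` strings (or 0/1).
#' @param n_trees Number of trees (default 500).
#' @param seed RNG seed.
#' @param min_node Minimum node size for splitting (default 5).
#' @return A `chromfold_rf` model.
#' @export
train_enrichment_classifier <- function(features, labels, n_trees = 500,
                                        seed = 1, min_node = 5) {
  x <- prepare_features(features)
  lab <- if (is.data.frame(labels)) labels$label else labels
  if (is.numeric(lab)) lab <- ifelse(lab == 1, "enriched", "not_enriched")
  keep <- lab != "discarded"
  x <- x[keep, , drop = FALSE]
  y <- as.integer(lab[keep] == "enriched")
  if (length(unique(y)) < 2) abort("Need both classes to train.")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  xz <- sweep(sweep(x, 2, center), 2, scale_, "/")
  mtry <- max(1L, floor(sqrt(ncol(xz))))
  fit <- rf_train_cpp(xz, y, as.integer(n_trees), mtry, as.integer(min_node),
    as.numeric(seed)
  )
  feats <- colnames(x) %||% paste0("feature_", seq_len(ncol(x)))
  structure(
    list(
      trees = fit$trees, oob_error = fit$oob_error,
      importance = tibble::tibble(
        feature = feats,
        mean_decrease_accuracy = as.numeric(fit$importance_mda),
        gini_decrease = as.numeric(fit$importance_gini)
      ),
      center = center, scale = scale_, features = feats,
      n_trees = n_trees, mtry = mtry, seed = seed, n_pos = sum(y),
      n_neg = sum(y == 0)
    ),
    class = "chromfold_rf"
  )
}

#' @export
print.chromfold_rf <- function(x, ...) {
  cat(sprintf(
    "<chromfold_rf> %d trees, %d features, OOB error %.3f (%d pos / %d neg)\n",
    x$n_trees, length(x$features), x$oob_error, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Predicted enrichment probability
#'
#' @param object A `chromfold_rf`.
#' @param newdata Feature table on the original (un-z-scored) scale.
#' @param ... Unused.
#' @return Vector of class-1 (enriched) vote fractions.
#' @export
predict.chromfold_rf <- function(object, newdata, ...) {
  x <- prepare_features(newdata)
  xz <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.numeric(rf_predict_cpp(object$trees, xz))
}

#' Dual feature-importance table
#'
#' @param model A `chromfold_rf`.
#' @return Tibble sorted by mean decrease in accuracy, with Gini decrease
#'   alongside.
#' @export
feature_importance <- function(model) {
  dplyr::arrange(model$importance, dplyr::desc(.data$mean_decrease_accuracy))
}

#' @export
tidy.chromfold_rf <- function(x, ...) feature_importance(x)

#' @export
glance.chromfold_rf <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees, oob_error = x$oob_error,
    n_pos = x$n_pos, n_neg = x$n_neg, mtry = x$mtry
  )
}

#' Cross-validated ROC AUC of the enrichment classifier
#'
#' Stratified k-fold (default 5) cross-validation; z-scoring is fitted on
#' each training fold only and applied to its held-out fold (leakage guard).
#' Per-fold AUC is the rank (Mann-Whitney) statistic of the held-out vote
#' fractions.
#'
#' @inheritParams train_enrichment_classifier
#' @param k_folds Number of folds (default 5).
#' @return List: `mean_auc` and a per-fold tibble.
#' @export
evaluate_classifier <- function(features, labels, k_folds = 5, n_trees = 500,
                                seed = 1, min_node = 5) {
  x <- prepare_features(features)
  lab <- if (is.data.frame(labels)) labels$label else labels
  if (is.numeric(lab)) lab <- ifelse(lab == 1, "enriched", "not_enriched")
  keep <- lab != "discarded"
  x <- x[keep, , drop = FALSE]
  y <- as.integer(lab[keep] == "enriched")
  if (sum(y) < k_folds || sum(y == 0) < k_folds) {
    abort("Too few samples in a class to stratify the requested folds.")
  }
  withr::local_seed(seed)
  fold <- integer(length(y))
  fold[y == 1] <- sample(rep(seq_len(k_folds), length.out = sum(y)))
  fold[y == 0] <- sample(rep(seq_len(k_folds), length.out = sum(y == 0)))
  aucs <- vapply(seq_len(k_folds), function(f) {
    tr <- fold != f
    fit <- train_enrichment_classifier(
      x[tr, , drop = FALSE], y[tr],
      n_trees = n_trees, seed = seed + f, min_node = min_node
    )
    scores <- predict(fit, x[!tr, , drop = FALSE])
    rank_auc(scores, y[!tr])
  }, numeric(1))
  list(
    mean_auc = mean(aucs),
    folds = tibble::tibble(fold = seq_len(k_folds), auc = aucs)
  )
}

#' Marker-difference tests between enriched and not-enriched bins
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature track, with
#' Benjamini-Hochberg correction — the reporting companion to the
#' classifier's importances.
#'
#' @inheritParams train_enrichment_classifier
#' @return Tibble: `feature`, `statistic`, `p_value`, `q_value`,
#'   `median_enriched`, `median_not`.
#' @export
marker_enrichment_tests <- function(features, labels) {
  x <- prepare_features(features)
  lab <- if (is.data.frame(labels)) labels$label else labels
  keep <- lab != "discarded"
  x <- x[keep, , drop = FALSE]
  y <- lab[keep] == "enriched"
  feats <- colnames(x) %||% paste0("feature_", seq_len(ncol(x)))
  rows <- lapply(seq_len(ncol(x)), function(j) {
    wt <- wilcox.test(x[y, j], x[!y, j], exact = FALSE)
    tibble::tibble(
      feature = feats[j], statistic = unname(wt$statistic),
      p_value = wt$p.value,
      median_enriched = median(x[y, j]), median_not = median(x[!y, j])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[, c(
    "feature", "statistic", "p_value", "q_value", "median_enriched",
    "median_not"
  )]
}
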