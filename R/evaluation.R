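#' Random fold assignment for k-fold cross-validation
#'
#' Records are randomly split into folds of (near) equal size: sizes differ by
#' at most one and every record lands in exactly one fold. Splitting is
#' unstratified by default, matching a plain random split; stratified
#' assignment (per-class balancing) is available behind a flag.
#'
#' @param m Number of records (must be at least `n_folds`).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the same seed reproduces the same assignment.
#' @param labels Optional 0/1 labels, required when `stratify = TRUE`.
#' @param stratify Balance class proportions across folds?
#' @return An integer vector of fold indices in `1:n_folds`, length `m`.
#' @examples
#' table(make_folds(2299, seed = 1))
#' @export
make_folds <- function(m, n_folds = 10, seed = 1, labels = NULL,
                       stratify = FALSE) {
  if (m < n_folds) abort("Need at least as many records as folds.")
  withr::with_seed(seed, {
    if (stratify) {
      if (is.null(labels) || length(labels) != m) {
        abort("`labels` of length m are required for stratified folds.")
      }
      fold <- integer(m)
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
      }
      fold
    } else {
      sample(rep(seq_len(n_folds), length.out = m))
    }
  })
}

#' Screening metrics: AUC, average precision, sensitivity, specificity
#'
#' AUC is the probability that a randomly chosen high-risk record outscores a
#' randomly chosen normal record, with ties counted one half (the
#' Mann-Whitney mid-rank form). Average precision summarises the
#' precision-recall curve as the sum over score thresholds of precision
#' weighted by the increase in recall. Sensitivity is the recall of the
#' high-risk class and specificity the recall of the normal class, computed
#' from the thresholded class calls.
#'
#' @param labels Binary 0/1 ground truth; both classes must be present.
#' @param scores Continuous high-risk scores (any monotone scale).
#' @param classes Optional 0/1 class calls; defaults to
#'   `scores >= threshold`.
#' @param threshold Probability cut used when `classes` is not given.
#' @return A one-row tibble: `auc`, `ap`, `sensitivity`, `specificity`.
#' @examples
#' screening_metrics(c(0, 0, 1, 1), c(.1, .4, .35, .8))
#' @export
screening_metrics <- function(labels, scores, classes = NULL,
                              threshold = 0.5) {
  if (length(labels) != length(scores)) abort("labels/scores lengths differ.")
  if (length(unique(labels)) < 2) {
    abort("AUC and AP are undefined for single-class labels.")
  }
  if (is.null(classes)) classes <- as.integer(scores >= threshold)
  tp <- sum(classes == 1 & labels == 1)
  fn <- sum(classes == 0 & labels == 1)
  tn <- sum(classes == 0 & labels == 0)
  fp <- sum(classes == 1 & labels == 0)
  tibble::tibble(
    auc = auc_score(labels, scores),
    ap = average_precision(labels, scores),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

auc_score <- function(labels, scores) {
  r <- rank(scores)  # mid-ranks: ties contribute 1/2
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

average_precision <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate precision/recall at each distinct score threshold
  last_of_value <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last_of_value] / (tp[last_of_value] + fp[last_of_value])
  rec <- tp[last_of_value] / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Cross-validate an algorithm grid on a health-record table
#'
#' Runs the full experiment loop: optionally impute the table once up front
#' (the study's step order: imputation before the splits), assign records to
#' folds, and for each fold train every requested algorithm on the remaining
#' nine folds and score the held-out fold. All algorithms share the same fold
#' assignment within a run, so comparisons are paired by construction. When a
#' random split leaves a test fold single-class, the split is resampled with
#' a fresh derived seed (recorded in the result's `resampled` attribute).
#'
#' `leak_free = TRUE` instead fits the imputation inside each training fold
#' and completes the test fold against the training records only.
#'
#' @param data Tibble of numeric features (`NA` allowed when an imputation
#'   method is requested).
#' @param groups Tibble from [feature_groups()].
#' @param labels Integer 0/1 vector.
#' @param algorithms A subset of [baseline_grid()] (default: the full grid).
#' @param n_folds Number of folds (default 10).
#' @param seed Seed controlling folds and per-fold model seeds.
#' @param imputation `"none"`, `"mean"`, or `"knn"`.
#' @param k,metric KNN imputation parameters.
#' @param leak_free Fit imputation inside training folds only?
#' @param net_config [dualnet_config()] used for the DNN/SNN entries.
#' @param threshold Class-call threshold for probabilistic scores.
#' @param stratify Stratify the folds by class?
#' @return A tibble of class `cv_result` with one row per algorithm x fold
#'   and columns `label`, `algorithm`, `cost_sensitive`, `fold`, `auc`, `ap`,
#'   `sensitivity`, `specificity`. Attributes: `folds`, `seed`,
#'   `imputation`, `resampled`.
#' @export
cross_validate <- function(data, groups, labels,
                           algorithms = baseline_grid(), n_folds = 10,
                           seed = 1, imputation = c("none", "mean", "knn"),
                           k = 5, metric = "euclidean", leak_free = FALSE,
                           net_config = dualnet_config(), threshold = 0.5,
                           stratify = FALSE) {
  imputation <- match.arg(imputation)
  m <- nrow(data)
  if (imputation == "none") check_complete(data, "Cross-validation without imputation")
  if (!leak_free && imputation != "none") {
    data <- switch(imputation,
      mean = impute_mean(data),
      knn = impute_knn(data, groups, k = k, metric = metric)
    )
  }
  fold <- make_folds(m, n_folds, seed = derive_seed(seed, "folds"),
                     labels = labels, stratify = stratify)
  resampled <- 0L
  while (any(vapply(
    seq_len(n_folds),
    function(f) length(unique(labels[fold == f])) < 2, logical(1)
  ))) {
    resampled <- resampled + 1L
    if (resampled > 50) abort("Could not find folds with both classes present.")
    fold <- make_folds(m, n_folds,
                       seed = derive_seed(seed + resampled * 1000L, "folds"),
                       labels = labels, stratify = stratify)
  }
  results <- list()
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    if (leak_free && imputation != "none") {
      sp <- impute_split(data[tr, ], data[te, ], groups,
                         method = imputation, k = k, metric = metric)
      d_tr <- sp$train
      d_te <- sp$test
    } else {
      d_tr <- data[tr, ]
      d_te <- data[te, ]
    }
    for (a in seq_len(nrow(algorithms))) {
      fit <- fit_baseline(
        d_tr, groups, labels[tr],
        algorithm = algorithms$algorithm[a],
        cost_sensitive = algorithms$cost_sensitive[a],
        seed = derive_seed(seed + f, "train"),
        net_config = net_config
      )
      pred <- predict(fit, d_te, threshold = threshold)
      met <- screening_metrics(labels[te], pred$.score, pred$.class)
      results[[length(results) + 1]] <- dplyr::bind_cols(
        tibble::tibble(
          label = algorithms$label[a],
          algorithm = algorithms$algorithm[a],
          cost_sensitive = algorithms$cost_sensitive[a],
          fold = f
        ),
        met
      )
    }
  }
  out <- dplyr::bind_rows(results)
  structure(
    out,
    class = c("cv_result", class(out)),
    folds = fold, seed = seed, imputation = imputation, resampled = resampled
  )
}

#' Summarise a cross-validation result per algorithm
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A tibble with mean and SD of each metric over the folds, one row
#'   per algorithm.
#' @export
summary.cv_result <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      c("auc", "ap", "sensitivity", "specificity"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$label, .data$algorithm, .data$cost_sensitive,
                    .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop"
    )
}

#' @export
tidy.cv_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_algorithms = dplyr::n_distinct(x$label),
    n_folds = dplyr::n_distinct(x$fold),
    imputation = attr(x, "imputation"),
    seed = attr(x, "seed"),
    resampled_splits = attr(x, "resampled")
  )
}

#' Compare every algorithm against a reference with one-sided t-tests
#'
#' For each metric, the reference algorithm's per-fold values are compared
#' with each competitor's by a one-sided t-test with the alternative that the
#' reference exceeds the competitor. Folds are shared across algorithms, so
#' the test is paired by fold (an unpaired variant is available). When the
#' fold-wise differences have zero variance the t statistic is undefined; the
#' row is flagged `degenerate` and the p-value is `NA`.
#'
#' @param cv A `cv_result`.
#' @param reference The reference algorithm label (default `"DNN+CSL"`).
#' @param paired Pair by fold (default) or compare fold means unpaired?
#' @return A tibble: `label`, `metric`, `p_value`, `degenerate`.
#' @export
compare_to_reference <- function(cv, reference = "DNN+CSL", paired = TRUE) {
  if (!reference %in% cv$label) {
    abort(paste0("Reference algorithm `", reference, "` not in the result."))
  }
  metrics <- c("auc", "ap", "sensitivity", "specificity")
  ref <- dplyr::filter(tibble::as_tibble(cv), .data$label == reference) |>
    dplyr::arrange(.data$fold)
  others <- setdiff(unique(cv$label), reference)
  purrr::map_dfr(others, function(lbl) {
    comp <- dplyr::filter(tibble::as_tibble(cv), .data$label == lbl) |>
      dplyr::arrange(.data$fold)
    purrr::map_dfr(metrics, function(met) {
      x <- ref[[met]]
      y <- comp[[met]]
      degenerate <- if (paired) stats::sd(x - y) == 0 else
        (stats::sd(x) == 0 && stats::sd(y) == 0)
      p <- if (degenerate) NA_real_ else {
        t.test(x, y, paired = paired, alternative = "greater")$p.value
      }
      tibble::tibble(label = lbl, metric = met, p_value = p,
                     degenerate = degenerate)
    })
  })
}

#' Per-fold metric distribution across algorithms
#'
#' @param object A `cv_result`.
#' @param metric Which metric to plot (default `"auc"`).
#' @param ... Unused.
#' @return A ggplot: per-fold values as boxplots by algorithm.
#' @export
autoplot.cv_result <- function(object,
                               metric = c("auc", "ap", "sensitivity",
                                          "specificity"), ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data[[metric]], FUN = stats::median),
      y = .data[[metric]], fill = .data$cost_sensitive
    )
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = toupper(metric), fill = "Cost-sensitive") +
    ggplot2::theme_minimal()
}
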