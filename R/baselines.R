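#' The 16-algorithm benchmark grid
#'
#' Eight learners — logistic regression, decision tree, random forest, three
#' SVM kernels, the single neural network, and the dual neural network — each
#' with and without cost-sensitive class weighting.
#'
#' @return A 16-row tibble with columns `label` (e.g. `"RF+CSL"`),
#'   `algorithm`, and `cost_sensitive`.
#' @examples
#' baseline_grid()
#' @export
baseline_grid <- function() {
  algos <- c("LR", "DT", "RF", "SVM_linear", "SVM_poly", "SVM_rbf",
             "SNN", "DNN")
  tidyr::expand_grid(
    algorithm = algos,
    cost_sensitive = c(FALSE, TRUE)
  ) |>
    dplyr::mutate(
      label = paste0(.data$algorithm, ifelse(.data$cost_sensitive, "+CSL", ""))
    ) |>
    dplyr::select("label", "algorithm", "cost_sensitive")
}

#' Fit one algorithm of the benchmark grid
#'
#' All learners consume the full (imputed) feature table and expose a
#' continuous high-risk score usable for AUC/AP plus a thresholded class
#' call. Cost-sensitive variants weight the high-risk class by the
#' normal-to-high-risk count ratio of the training labels: per-sample loss
#' weights for LR and DT, `class.weights` for the SVMs and random forest, the
#' cost-sensitive cross-entropy for the neural models.
#'
#' Fixed hyperparameters mirror the screening study: the random forest uses
#' 100 trees of maximum depth 3; SVMs use the `e1071` kernel defaults; LR is
#' an unpenalised binomial GLM; neural models are configured through
#' `net_config`.
#'
#' @param data Fully observed tibble of numeric features.
#' @param groups Tibble from [feature_groups()].
#' @param labels Integer 0/1 vector.
#' @param algorithm One of `"LR"`, `"DT"`, `"RF"`, `"SVM_linear"`,
#'   `"SVM_poly"`, `"SVM_rbf"`, `"SNN"`, `"DNN"`.
#' @param cost_sensitive Apply class weighting?
#' @param seed Integer seed for the stochastic learners.
#' @param net_config Optional [dualnet_config()] for the neural models,
#'   interpreted as per-branch dimensions; the SNN doubles `d1`/`d2` so its
#'   final representation matches the dual network's concatenated one.
#' @return An object of class `screening_fit` with a `predict()` method
#'   returning a tibble of `.score` and `.class`.
#' @export
fit_baseline <- function(data, groups, labels, algorithm,
                         cost_sensitive = FALSE, seed = 1,
                         net_config = NULL) {
  check_complete(data, "Model fitting")
  if (length(unique(labels)) < 2) abort("Training labels are single-class.")
  algorithm <- match.arg(
    algorithm,
    c("LR", "DT", "RF", "SVM_linear", "SVM_poly", "SVM_rbf", "SNN", "DNN")
  )
  feat_cols <- groups$column
  counts <- c(n0 = sum(labels == 0), n1 = sum(labels == 1))
  ratio <- counts[["n0"]] / counts[["n1"]]
  # Syntactic internal names keep formula interfaces happy with arbitrary
  # feature identifiers.
  name_map <- stats::setNames(paste0("f", seq_along(feat_cols)), feat_cols)
  df <- as.data.frame(feature_matrix(data, feat_cols))
  names(df) <- unname(name_map)
  yf <- factor(labels, levels = c("0", "1"))
  w <- if (cost_sensitive) ifelse(labels == 1, ratio, 1) else rep(1, length(labels))
  model <- withr::with_seed(seed, switch(algorithm,
    LR = suppressWarnings(stats::glm(
      y ~ ., data = cbind(df, y = yf), family = stats::binomial(),
      weights = w
    )),
    DT = rpart::rpart(
      y ~ ., data = cbind(df, y = yf), weights = w, method = "class"
    ),
    # class weighting enters through the per-sample weights: weighted
    # bootstrap sampling shifts the leaf class frequencies (and hence the
    # probability estimates), unlike split-rule-only class weights
    RF = ranger::ranger(
      y = yf, x = df, num.trees = 100, max.depth = 3, probability = TRUE,
      case.weights = w, num.threads = 1, seed = seed
    ),
    SVM_linear = ,
    SVM_poly = ,
    SVM_rbf = e1071::svm(
      x = df, y = yf,
      kernel = switch(algorithm, SVM_linear = "linear",
                      SVM_poly = "polynomial", SVM_rbf = "radial"),
      class.weights = if (cost_sensitive) c("0" = 1, "1" = ratio) else NULL
    ),
    SNN = {
      cfg <- snn_scaled_config(net_config %||% dualnet_config())
      cfg$cost_sensitive <- cost_sensitive
      cfg$seed <- seed
      fit_snn(data, groups, labels, cfg)
    },
    DNN = {
      cfg <- net_config %||% dualnet_config()
      cfg$cost_sensitive <- cost_sensitive
      cfg$seed <- seed
      fit_dualnet(data, groups, labels, cfg)
    }
  ))
  structure(
    list(
      algorithm = algorithm, cost_sensitive = cost_sensitive,
      model = model, name_map = name_map, feat_cols = feat_cols,
      class_counts = counts, seed = seed,
      defaults = baseline_defaults(algorithm)
    ),
    class = "screening_fit"
  )
}

# The SNN matches the dual network's concatenated representation size by
# doubling both hidden widths relative to the per-branch dims: with the
# defaults d1 = 128, d2 = 32 the single branch gets 256 and 64 and its final
# representation has the same dimension as the concatenated dual one.
snn_scaled_config <- function(cfg) {
  cfg$d1 <- 2 * cfg$d1
  cfg$d2 <- 2 * cfg$d2
  if (cfg$extra_layers > 0) cfg$extra_dims <- as.integer(cfg$extra_dims)
  cfg
}

baseline_defaults <- function(algorithm) {
  switch(algorithm,
    LR = "stats::glm binomial, unpenalised MLE",
    DT = "rpart defaults (cp = 0.01, minsplit = 20)",
    RF = "ranger, 100 trees, max depth 3",
    SVM_linear = "e1071::svm linear kernel, cost = 1",
    SVM_poly = "e1071::svm polynomial kernel, degree 3, cost = 1",
    SVM_rbf = "e1071::svm radial kernel, gamma = 1/n, cost = 1",
    SNN = "single branch, d1 = 256, d2 = 64, SGD momentum 0.9",
    DNN = "dual branches, d1 = 128, d2 = 32, SGD momentum 0.9"
  )
}

#' Score new records with a fitted benchmark model
#'
#' `.score` is a continuous high-risk score: a probability for LR, DT, RF and
#' the neural models, and the (suitably oriented) decision value for the
#' SVMs, whose class calls use the decision-function sign as is standard.
#'
#' @param object A `screening_fit`.
#' @param new_data Fully observed feature tibble.
#' @param threshold Probability threshold for probabilistic models
#'   (default 0.5).
#' @param ... Unused.
#' @return A tibble with columns `.score` and `.class`.
#' @export
predict.screening_fit <- function(object, new_data, threshold = 0.5, ...) {
  check_complete(new_data, "Prediction")
  if (object$algorithm %in% c("SNN", "DNN")) {
    prob <- predict(object$model, new_data, type = "prob")
    return(tibble::tibble(
      .score = prob,
      .class = as.integer(prob >= threshold)
    ))
  }
  df <- as.data.frame(feature_matrix(new_data, object$feat_cols))
  names(df) <- unname(object$name_map)
  if (object$algorithm == "LR") {
    prob <- unname(predict(object$model, newdata = df, type = "response"))
    return(tibble::tibble(.score = prob, .class = as.integer(prob >= threshold)))
  }
  if (object$algorithm == "DT") {
    prob <- unname(predict(object$model, newdata = df, type = "prob")[, "1"])
    return(tibble::tibble(.score = prob, .class = as.integer(prob >= threshold)))
  }
  if (object$algorithm == "RF") {
    prob <- unname(predict(object$model, data = df,
                           num.threads = 1)$predictions[, "1"])
    return(tibble::tibble(.score = prob, .class = as.integer(prob >= threshold)))
  }
  # SVMs: rank by decision value, classify by its sign (via predicted label).
  pred <- predict(object$model, newdata = df, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- dv[, 1]
  # e1071 orients the decision value toward the first class named in the
  # column header; flip so larger = more likely high risk ("1").
  if (startsWith(colnames(dv)[1], "0/")) score <- -score
  tibble::tibble(
    .score = unname(score),
    .class = as.integer(as.character(pred) == "1")
  )
}

#' @export
print.screening_fit <- function(x, ...) {
  cat(sprintf(
    "<screening_fit: %s%s>\n  %s\n",
    x$algorithm, if (x$cost_sensitive) "+CSL" else "", x$defaults
  ))
  invisible(x)
}
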