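#' Training configuration for the dual and single neural networks
#'
#' Defaults follow the screening model: hidden widths `d1 = 128`, `d2 = 32`
#' per branch, stochastic gradient descent with momentum 0.9, and a
#' cost-sensitive loss that up-weights high-risk samples by the ratio of
#' normal to high-risk training counts. Learning rate, epoch budget and batch
#' size are tunable; training runs a fixed epoch budget unless
#' `early_stopping` is enabled (plateau of the training loss, `patience`
#' epochs within `tol`).
#'
#' @param d1,d2 Widths of the first and second hidden layer of each branch.
#' @param learning_rate SGD step size.
#' @param momentum Momentum rate in `[0, 1)`.
#' @param epochs Number of passes over the training data; 0 returns the
#'   initialisation unchanged.
#' @param batch_size Mini-batch size.
#' @param cost_sensitive Use the class-imbalance cost ratio in the loss?
#' @param threshold Probability cut for classifying a record as high risk.
#' @param extra_layers Number of extra fully connected ReLU layers (0, 1 or 2)
#'   inserted between the concatenated representation and the risk head.
#' @param extra_dims Widths of the extra layers; defaults to `2 * d2` each.
#' @param normalize Min-max scale each feature to `[0, 1]` before training
#'   (off by default; raw features are used as-is).
#' @param early_stopping,patience,tol Optional plateau-based stop.
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @return A list of class `dualnet_config`.
#' @export
dualnet_config <- function(d1 = 128, d2 = 32, learning_rate = 0.01,
                           momentum = 0.9, epochs = 200, batch_size = 64,
                           cost_sensitive = TRUE, threshold = 0.5,
                           extra_layers = 0, extra_dims = NULL,
                           normalize = FALSE, early_stopping = FALSE,
                           patience = 20, tol = 1e-5, seed = 1) {
  if (!extra_layers %in% 0:2) abort("`extra_layers` must be 0, 1 or 2.")
  if (is.null(extra_dims)) extra_dims <- rep(2 * d2, extra_layers)
  if (length(extra_dims) != extra_layers) {
    abort("`extra_dims` must have length `extra_layers`.")
  }
  if (momentum < 0 || momentum >= 1) abort("`momentum` must be in [0, 1).")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(
    list(
      d1 = d1, d2 = d2, learning_rate = learning_rate, momentum = momentum,
      epochs = epochs, batch_size = batch_size,
      cost_sensitive = cost_sensitive, threshold = threshold,
      extra_layers = extra_layers, extra_dims = as.integer(extra_dims),
      normalize = normalize, early_stopping = early_stopping,
      patience = patience, tol = tol, seed = seed
    ),
    class = "dualnet_config"
  )
}

#' Cost-sensitive binary cross-entropy loss
#'
#' The supervised loss is the mean over samples of
#' `-(w_i * y_i * log(p_i) + (1 - y_i) * log(1 - p_i))`, with `w_i` the cost
#' ratio (normal count / high-risk count) for high-risk samples and 1
#' otherwise. With `cost_sensitive = FALSE` (or balanced counts) all weights
#' are 1 and the loss reduces to plain cross-entropy. Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param prob Predicted high-risk probabilities in `(0, 1)`.
#' @param labels Binary 0/1 labels.
#' @param cost_sensitive Apply the cost ratio to high-risk terms?
#' @param class_counts Optional `c(n_normal, n_high_risk)` pair; defaults to
#'   the counts in `labels` (training-set counts should be supplied when
#'   scoring held-out data).
#' @return A single nonnegative number.
#' @export
dualnet_loss <- function(prob, labels, cost_sensitive = TRUE,
                         class_counts = NULL) {
  if (length(prob) != length(labels)) abort("prob and labels lengths differ.")
  w <- net_sample_weights(labels, cost_sensitive, class_counts)
  net_loss(prob, labels, w)
}

#' Fit the dual neural network risk model
#'
#' Two parallel branches, each with two ReLU hidden layers, learn latent
#' representations of the profile features and the assessment features
#' separately; the two deepest representations are concatenated and fed to a
#' sigmoid unit that outputs the probability of a high-risk case. Training
#' minimises the (optionally cost-sensitive) cross-entropy by mini-batch SGD
#' with momentum; the run is fully reproducible from `config$seed`.
#'
#' @param data A fully observed tibble of numeric features (impute first).
#' @param groups Tibble from [feature_groups()] defining the profile /
#'   assessment split.
#' @param labels Integer 0/1 vector (1 = high risk).
#' @param config A [dualnet_config()].
#' @return An object of class `dualnet` with `predict()`, [tidy()],
#'   [glance()], [augment()] and [autoplot()] methods.
#' @examples
#' cfg <- synth_config(m = 120, n_p = 6, n_q = 10, n_complete = 4, seed = 7)
#' d <- generate_health_data(cfg)
#' full <- impute_mean(d$data)
#' fit <- fit_dualnet(full, d$groups, d$labels,
#'                    dualnet_config(d1 = 16, d2 = 8, epochs = 20))
#' head(predict(fit, full))
#' @export
fit_dualnet <- function(data, groups, labels, config = dualnet_config()) {
  fit_branched(data, groups, labels, config, architecture = "dual")
}

#' Fit the single-network (SNN) baseline
#'
#' Consumes all features in one branch. To match the dual network's
#' concatenated representation size, its hidden widths default to twice the
#' dual defaults (`d1 = 256`, `d2 = 64`), so the final representation has the
#' same dimension `2 * 32 = 64`. Shares every line of layer arithmetic with
#' [fit_dualnet()].
#'
#' @inheritParams fit_dualnet
#' @param config A [dualnet_config()]; if omitted, dual defaults doubled.
#' @export
fit_snn <- function(data, groups, labels, config = NULL) {
  if (is.null(config)) config <- dualnet_config(d1 = 256, d2 = 64)
  fit_branched(data, groups, labels, config, architecture = "single")
}

fit_branched <- function(data, groups, labels, config, architecture) {
  check_complete(data, "Network training")
  if (length(labels) != nrow(data)) abort("labels length must match rows.")
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary 0/1.")
  if (config$cost_sensitive && length(unique(labels)) < 2) {
    abort("Cost-sensitive training needs both classes present.")
  }
  branch_cols <- branch_columns(groups, architecture)
  norm <- NULL
  if (config$normalize) {
    norm <- normalization_stats(data)
    data <- apply_normalization(data, norm)
  }
  x_list <- lapply(branch_cols, function(cols) feature_matrix(data, cols))
  params <- net_init(
    vapply(x_list, ncol, integer(1)),
    config$d1, config$d2, config$extra_dims,
    seed = derive_seed(config$seed, "init")
  )
  trained <- net_train(params, x_list, labels, config)
  counts <- c(n_normal = sum(labels == 0), n_high_risk = sum(labels == 1))
  structure(
    list(
      params = trained$params,
      config = config,
      architecture = architecture,
      branch_columns = branch_cols,
      class_counts = counts,
      loss_history = trained$loss_history,
      n_parameters = length(net_flatten(trained$params)),
      normalization = norm
    ),
    class = "dualnet"
  )
}

branch_columns <- function(groups, architecture) {
  p_cols <- groups$column[groups$group == "profile"]
  q_cols <- groups$column[groups$group == "assessment"]
  if (architecture == "dual") {
    if (length(p_cols) == 0 || length(q_cols) == 0) {
      abort("Dual architecture needs both profile and assessment columns.")
    }
    list(profile = p_cols, assessment = q_cols)
  } else {
    list(all = c(p_cols, q_cols))
  }
}

normalization_stats <- function(data) {
  x <- feature_matrix(data)
  rng <- apply(x, 2, range)
  list(min = rng[1, ], span = pmax(rng[2, ] - rng[1, ], 1e-12))
}

apply_normalization <- function(data, norm) {
  x <- feature_matrix(data)
  x <- sweep(sweep(x, 2, norm$min, "-"), 2, norm$span, "/")
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- names(data)
  out
}

#' Predict high-risk probabilities or classes
#'
#' @param object A fitted `dualnet`.
#' @param new_data Fully observed tibble holding at least the feature columns
#'   seen at fit time.
#' @param type `"prob"` (default) for the sigmoid probabilities, `"class"` for
#'   0/1 calls at `threshold`.
#' @param threshold Probability cut; defaults to the fit configuration's.
#' @param ... Unused.
#' @return A numeric (prob) or integer (class) vector, one entry per row.
#' @export
predict.dualnet <- function(object, new_data, type = c("prob", "class"),
                            threshold = NULL, ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$config$threshold
  if (!is.null(object$normalization)) {
    new_data <- apply_normalization(new_data, object$normalization)
  }
  x_list <- lapply(object$branch_columns, function(cols) {
    x <- feature_matrix(new_data, cols)
    if (anyNA(x) || any(!is.finite(x))) abort("new_data must be finite and complete.")
    x
  })
  prob <- net_forward(object$params, x_list)$prob
  if (type == "prob") prob else as.integer(prob >= threshold)
}

#' @export
print.dualnet <- function(x, ...) {
  cat(sprintf(
    "<dualnet: %s architecture, %d parameters>\n",
    x$architecture, x$n_parameters
  ))
  cat(sprintf(
    "  branches: %s\n",
    paste(sprintf("%s(%d)", names(x$branch_columns),
                  lengths(x$branch_columns)), collapse = ", ")
  ))
  cat(sprintf(
    "  d1 = %d, d2 = %d, extra layers = %d, cost-sensitive = %s\n",
    x$config$d1, x$config$d2, x$config$extra_layers,
    x$config$cost_sensitive
  ))
  if (length(x$loss_history) > 0) {
    cat(sprintf("  trained %d epochs, final training loss %.4f\n",
                length(x$loss_history),
                x$loss_history[length(x$loss_history)]))
  }
  invisible(x)
}

#' Tidy a fitted network into a per-layer summary
#'
#' @param x A fitted `dualnet`.
#' @param ... Unused.
#' @return A tibble with one row per weight matrix or bias vector: `component`
#'   (branch/extra/head), `layer`, `parameter`, `rows`, `cols`, `norm`.
#' @export
tidy.dualnet <- function(x, ...) {
  rows <- list()
  push <- function(component, layer, parameter, value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      component = component, layer = layer, parameter = parameter,
      rows = NROW(value), cols = NCOL(value),
      norm = sqrt(sum(value^2))
    )
  }
  for (g in seq_along(x$params$branches)) {
    nm <- names(x$branch_columns)[g]
    br <- x$params$branches[[g]]
    push(nm, 1L, "weight", br$W1); push(nm, 1L, "bias", br$b1)
    push(nm, 2L, "weight", br$W2); push(nm, 2L, "bias", br$b2)
  }
  for (e in seq_along(x$params$extras)) {
    ex <- x$params$extras[[e]]
    push("extra", e, "weight", ex$W); push("extra", e, "bias", ex$b)
  }
  push("head", 1L, "weight", x$params$head$W)
  push("head", 1L, "bias", x$params$head$b)
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted network
#'
#' @inheritParams tidy.dualnet
#' @return A one-row tibble: architecture, parameter count, epochs run, final
#'   training loss, cost ratio used.
#' @export
glance.dualnet <- function(x, ...) {
  tibble::tibble(
    architecture = x$architecture,
    n_parameters = x$n_parameters,
    epochs = length(x$loss_history),
    final_loss = if (length(x$loss_history) > 0) {
      x$loss_history[length(x$loss_history)]
    } else NA_real_,
    cost_sensitive = x$config$cost_sensitive,
    cost_ratio = unname(x$class_counts[1] / x$class_counts[2])
  )
}

#' Attach predictions to a data frame
#'
#' @param x A fitted `dualnet`.
#' @param data Fully observed tibble of features.
#' @param ... Passed to `predict()`.
#' @return `data` with `.pred_prob` and `.pred_class` columns appended.
#' @export
augment.dualnet <- function(x, data, ...) {
  prob <- predict(x, data, type = "prob", ...)
  dplyr::mutate(
    tibble::as_tibble(data),
    .pred_prob = prob,
    .pred_class = as.integer(prob >= x$config$threshold)
  )
}

#' Training-loss curve
#'
#' @param object A fitted `dualnet`.
#' @param ... Unused.
#' @return A ggplot of mean training loss per epoch.
#' @export
autoplot.dualnet <- function(object, ...) {
  df <- tibble::tibble(
    epoch = seq_along(object$loss_history),
    loss = object$loss_history
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Epoch", y = "Mean training loss",
      title = sprintf("%s network training loss", object$architecture)
    ) +
    ggplot2::theme_minimal()
}

#' Serialize a fitted network to a versioned JSON container
#'
#' All weight matrices, biases, the training configuration and branch column
#' lists are written as plain JSON so models survive as text.
#'
#' @param object A fitted `dualnet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dualnet <- function(object, path) {
  payload <- list(
    format = "dualscreen-model",
    version = 1L,
    architecture = object$architecture,
    config = unclass(object$config),
    branch_columns = object$branch_columns,
    class_counts = as.list(object$class_counts),
    loss_history = object$loss_history,
    theta = net_flatten(object$params),
    shapes = list(
      input_dims = object$params$input_dims,
      d1 = object$params$d1, d2 = object$params$d2,
      extra_dims = object$params$extra_dims
    ),
    normalization = object$normalization
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fitted network written by [write_dualnet()]
#'
#' @param path Path to the JSON model file.
#' @return A `dualnet` object.
#' @export
read_dualnet <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "dualscreen-model")) {
    abort("Not a dualscreen model file.")
  }
  shp <- payload$shapes
  input_dims <- as.integer(shp$input_dims)
  # Rebuild the parameter skeleton from the stored shapes, then restore the
  # flattened weight vector into it.
  params <- net_init(input_dims, shp$d1, shp$d2, as.integer(shp$extra_dims),
                     seed = 1)
  restored <- net_unflatten(params, as.numeric(payload$theta))
  cfg <- payload$config
  config <- dualnet_config(
    d1 = cfg$d1, d2 = cfg$d2, learning_rate = cfg$learning_rate,
    momentum = cfg$momentum, epochs = cfg$epochs, batch_size = cfg$batch_size,
    cost_sensitive = cfg$cost_sensitive, threshold = cfg$threshold,
    extra_layers = cfg$extra_layers, extra_dims = cfg$extra_dims,
    normalize = cfg$normalize, early_stopping = cfg$early_stopping,
    patience = cfg$patience, tol = cfg$tol, seed = cfg$seed
  )
  norm <- payload$normalization
  norm <- if (!is.null(norm) && length(norm$min) > 0) {
    list(min = as.numeric(norm$min), span = as.numeric(norm$span))
  } else NULL
  structure(
    list(
      params = restored,
      config = config,
      architecture = payload$architecture,
      branch_columns = lapply(payload$branch_columns, as.character),
      class_counts = unlist(payload$class_counts),
      loss_history = as.numeric(payload$loss_history),
      n_parameters = length(net_flatten(restored)),
      normalization = norm
    ),
    class = "dualnet"
  )
}
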