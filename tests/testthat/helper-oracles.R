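# Independent brute-force oracles used to pin down the package's numerics.
# These deliberately avoid the package's own code paths: plain double loops
# and direct summation only.

oracle_distance <- function(x, metric = "euclidean") {
  m <- nrow(x)
  d <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      a <- x[i, ]
      b <- x[j, ]
      d[i, j] <- switch(metric,
        euclidean = sqrt(sum((a - b)^2)),
        cityblock = sum(abs(a - b)),
        cosine = {
          na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
          if (na == 0 || nb == 0) if (i == j) 0 else 1
          else 1 - sum(a * b) / (na * nb)
        }
      )
    }
  }
  diag(d) <- 0
  d
}

oracle_mean_impute <- function(x) {
  out <- x
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j], na.rm = TRUE)
    out[is.na(x[, j]), j] <- mu
  }
  out
}

# Sort every other record by complete-feature distance, take the k nearest
# that observe the target cell, and apply the inverse-distance weights.
oracle_knn_impute <- function(x, complete_idx, k) {
  m <- nrow(x)
  xc <- x[, complete_idx, drop = FALSE]
  out <- x
  for (i in seq_len(m)) {
    d <- vapply(seq_len(m),
                function(r) sqrt(sum((xc[i, ] - xc[r, ])^2)), numeric(1))
    ord <- order(d, seq_len(m))
    ord <- ord[ord != i]
    for (j in seq_len(ncol(x))) {
      if (!is.na(x[i, j])) next
      cand <- ord[!is.na(x[ord, j])]
      sel <- utils::head(cand, k)
      if (length(sel) == 0) {
        out[i, j] <- mean(x[, j], na.rm = TRUE)
      } else {
        w <- 1 / (d[sel] + 1e-8)
        w <- w / sum(w)
        out[i, j] <- sum(w * x[sel, j])
      }
    }
  }
  out
}

# AUC by exhaustive positive-negative pair counting, ties worth one half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# AP by sweeping every distinct score as a threshold, in increasing recall.
oracle_ap <- function(labels, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / sum(labels == 1)
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# Cost-sensitive cross-entropy by direct term-by-term summation.
oracle_loss <- function(prob, y, cost_sensitive, n_normal, n_high) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  total <- 0
  for (i in seq_along(y)) {
    w <- if (cost_sensitive && y[i] == 1) n_normal / n_high else 1
    total <- total - (w * y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  }
  total / length(y)
}

# Central finite differences of a scalar function of a parameter vector.
numeric_gradient <- function(f, theta, eps = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}

# --- fixtures -------------------------------------------------------------

# Random masked table: numeric values, MCAR mask, first `n_complete` columns
# kept fully observed so distances are defined.
random_masked_table <- function(m, n, n_complete, miss_rate = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(m * n), m, n)
    for (j in (n_complete + 1):n) {
      mask <- runif(m) < miss_rate
      # keep at least one observed value per column
      if (all(mask)) mask[sample.int(m, 1)] <- FALSE
      x[mask, j] <- NA
    }
    colnames(x) <- sprintf("v%02d", seq_len(n))
    data <- tibble::as_tibble(as.data.frame(x))
    assignment <- stats::setNames(
      rep(c("profile", "assessment"), length.out = n), colnames(x)
    )
    list(data = data, groups = feature_groups(data, assignment))
  })
}

# Linearly separable two-group toy: class decides the sign of every feature.
separable_data <- function(m = 40, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = m)
    sgn <- ifelse(y == 1, 1, -1)
    x <- cbind(
      p1 = sgn * 2 + rnorm(m, sd = 0.1),
      p2 = sgn * 1.5 + rnorm(m, sd = 0.1),
      a1 = sgn * 2.5 + rnorm(m, sd = 0.1),
      a2 = sgn * 1 + rnorm(m, sd = 0.1)
    )
    data <- tibble::as_tibble(as.data.frame(x))
    groups <- feature_groups(
      data, c(p1 = "profile", p2 = "profile",
              a1 = "assessment", a2 = "assessment")
    )
    list(data = data, groups = groups, labels = y)
  })
}

# Small fast net config for tests; overrides replace the fast defaults.
test_net_config <- function(...) {
  defaults <- list(d1 = 8, d2 = 4, epochs = 30, batch_size = 16,
                   learning_rate = 0.05)
  do.call(dualnet_config, utils::modifyList(defaults, list(...)))
}
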