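ns <- asNamespace("dualscreen")

# hand-buildable parameter container for the internal branched net
toy_params <- function() {
  list(
    branches = list(
      list(W1 = matrix(c(1, 0, -1, 2), 2, 2), b1 = c(0.5, -0.5),
           W2 = matrix(c(1, 1, 0, -1), 2, 2), b2 = c(0, 0.25)),
      list(W1 = matrix(c(0.5, 0.5, 1, -1), 2, 2), b1 = c(0, 0),
           W2 = matrix(c(-1, 2, 1, 0), 2, 2), b2 = c(0.1, -0.1))
    ),
    extras = list(),
    head = list(W = matrix(c(1, -1, 0.5, 2), 4, 1), b = -0.2),
    input_dims = c(2L, 2L), d1 = 2L, d2 = 2L, extra_dims = integer(0)
  )
}

test_that("the forward pass matches hand-computed scalar arithmetic", {
  params <- toy_params()
  p_in <- c(1, 2)
  q_in <- c(-1, 0.5)
  # branch 1, layer 1: z = p W1 + b1
  z1 <- c(1 * 1 + 2 * 0 + 0.5, 1 * (-1) + 2 * 2 - 0.5)
  h1 <- pmax(z1, 0)
  z2 <- c(h1[1] * 1 + h1[2] * 1 + 0, h1[1] * 0 + h1[2] * (-1) + 0.25)
  h2p <- pmax(z2, 0)
  # branch 2
  z1q <- c(-1 * 0.5 + 0.5 * 0.5, -1 * 1 + 0.5 * (-1))
  h1q <- pmax(z1q, 0)
  z2q <- c(h1q[1] * (-1) + h1q[2] * 2 + 0.1, h1q[1] * 1 + h1q[2] * 0 - 0.1)
  h2q <- pmax(z2q, 0)
  h <- c(h2p, h2q)
  z <- sum(h * c(1, -1, 0.5, 2)) - 0.2
  want <- 1 / (1 + exp(-z))

  fwd <- ns$net_forward(params, list(matrix(p_in, 1), matrix(q_in, 1)))
  expect_equal(drop(fwd$rep), h, tolerance = 1e-15)
  expect_equal(fwd$prob, want, tolerance = 1e-15)
})

test_that("all-zero parameters give probability one half; ReLU kills negatives", {
  params <- toy_params()
  zero <- ns$net_unflatten(params, rep(0, length(ns$net_flatten(params))))
  fwd <- ns$net_forward(zero, list(matrix(c(3, -2), 1), matrix(c(1, 1), 1)))
  expect_equal(fwd$prob, 0.5)
  expect_equal(drop(fwd$rep), rep(0, 4))

  # a strongly negative pre-activation is exactly zero after ReLU
  params$branches[[1]]$b1 <- c(-100, -100)
  fwd2 <- ns$net_forward(params, list(matrix(c(0.1, 0.1), 1), matrix(c(0, 0), 1)),
                         keep_cache = TRUE)
  expect_equal(drop(fwd2$cache$branches[[1]]$h1), c(0, 0))
})

test_that("the cost-sensitive loss reduces to plain cross-entropy at w = 1", {
  withr::with_seed(1, {
    prob <- runif(10, 0.05, 0.95)
    y <- rep(c(0L, 1L), 5)
  })
  plain <- dualnet_loss(prob, y, cost_sensitive = FALSE)
  balanced <- dualnet_loss(prob, y, cost_sensitive = TRUE,
                           class_counts = c(50, 50))
  expect_identical(plain, balanced)
})

test_that("the loss matches direct summation and vanishes for perfect predictions", {
  withr::with_seed(2, {
    prob <- runif(8, 0.01, 0.99)
    y <- c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L)
  })
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  expect_equal(
    dualnet_loss(prob, y, cost_sensitive = TRUE),
    oracle_loss(prob, y, TRUE, n0, n1),
    tolerance = 1e-14
  )
  expect_equal(
    dualnet_loss(prob, y, cost_sensitive = FALSE),
    oracle_loss(prob, y, FALSE, n0, n1),
    tolerance = 1e-14
  )
  # near-perfect predictions give a near-zero loss
  eps_prob <- ifelse(y == 1, 1 - 1e-9, 1e-9)
  expect_lt(dualnet_loss(eps_prob, y, cost_sensitive = TRUE), 1e-5)
})

test_that("the imbalance of the study gives a cost ratio of about 4.4", {
  y <- c(rep(0L, 1872), rep(1L, 427))
  w <- ns$net_sample_weights(y, cost_sensitive = TRUE)
  expect_true(all(w[y == 0] == 1))              # normal cases weigh 1
  expect_equal(round(unique(w[y == 1]), 1), 4.4)
})

test_that("single-class labels make the cost ratio undefined", {
  expect_error(ns$net_sample_weights(rep(0L, 5), TRUE), "undefined")
  d <- separable_data(20)
  expect_error(
    fit_dualnet(d$data, d$groups, rep(0L, 20), test_net_config()),
    "both classes"
  )
})

test_that("analytic gradients agree with central finite differences", {
  for (case in list(
    list(extra = integer(0), cs = TRUE, seed = 3),
    list(extra = c(4L), cs = TRUE, seed = 4),
    list(extra = c(4L, 3L), cs = FALSE, seed = 5)
  )) {
    withr::with_seed(case$seed, {
      xp <- matrix(rnorm(6 * 3), 6, 3)
      xq <- matrix(rnorm(6 * 4), 6, 4)
      y <- c(1L, 0L, 1L, 0L, 0L, 1L)
    })
    params <- ns$net_init(c(3L, 4L), d1 = 3, d2 = 2,
                          extra_dims = case$extra, seed = case$seed)
    # evaluate at a generic point: jittering all parameters (biases start at
    # exactly zero) keeps every ReLU away from its kink, where analytic
    # subgradients and central differences legitimately differ
    withr::with_seed(case$seed + 1000, {
      theta0 <- ns$net_flatten(params) +
        runif(length(ns$net_flatten(params)), -0.2, 0.2)
    })
    params <- ns$net_unflatten(params, theta0)
    w <- ns$net_sample_weights(y, case$cs)
    loss_at <- function(theta) {
      p <- ns$net_unflatten(params, theta)
      fwd <- ns$net_forward(p, list(xp, xq))
      ns$net_loss(fwd$prob, y, w)
    }
    fwd <- ns$net_forward(params, list(xp, xq), keep_cache = TRUE)
    analytic <- ns$net_flatten(ns$net_backward(params, fwd, y, w))
    numeric <- numeric_gradient(loss_at, theta0)
    rel_err <- sqrt(sum((analytic - numeric)^2)) /
      max(sqrt(sum(numeric^2)), 1e-12)
    expect_lt(rel_err, 1e-5)
  }
})

test_that("branches are isolated: assessment inputs never touch the profile path", {
  params <- ns$net_init(c(3L, 4L), d1 = 3, d2 = 2, seed = 10)
  withr::with_seed(11, {
    xp <- matrix(rnorm(5 * 3), 5, 3)
    xq <- matrix(rnorm(5 * 4), 5, 4)
  })
  a <- ns$net_forward(params, list(xp, xq))
  b <- ns$net_forward(params, list(xp, matrix(0, 5, 4)))
  expect_identical(a$rep[, 1:2], b$rep[, 1:2])     # profile block unchanged
  expect_false(isTRUE(all.equal(a$rep[, 3:4], b$rep[, 3:4])))
})

test_that("training is reproducible, skippable, and solves a separable toy", {
  d <- separable_data(40, seed = 21)
  cfg0 <- test_net_config(epochs = 0, seed = 9)
  init_only <- fit_dualnet(d$data, d$groups, d$labels, cfg0)
  expect_identical(
    ns$net_flatten(init_only$params),
    ns$net_flatten(ns$net_init(c(2L, 2L), 8, 4,
                               seed = ns$derive_seed(9, "init")))
  )
  expect_length(init_only$loss_history, 0)

  cfg <- test_net_config(epochs = 60, seed = 9)
  fit1 <- fit_dualnet(d$data, d$groups, d$labels, cfg)
  fit2 <- fit_dualnet(d$data, d$groups, d$labels, cfg)
  expect_identical(ns$net_flatten(fit1$params), ns$net_flatten(fit2$params))

  acc <- mean(predict(fit1, d$data, type = "class") == d$labels)
  expect_equal(acc, 1.0)
  # training loss trends down (up to batch noise): compare ends
  expect_lt(fit1$loss_history[length(fit1$loss_history)],
            fit1$loss_history[1])
})

test_that("degenerate thresholds and row-wise forward consistency hold", {
  d <- separable_data(20, seed = 31)
  fit <- fit_dualnet(d$data, d$groups, d$labels, test_net_config(seed = 2))
  prob <- predict(fit, d$data, type = "prob")
  expect_true(all(prob > 0 & prob < 1))
  expect_true(all(predict(fit, d$data, type = "class", threshold = 0) == 1L))
  expect_true(all(predict(fit, d$data, type = "class", threshold = 1 + 1e-9) == 0L))
  # probabilities equal a row-by-row forward pass
  row_probs <- vapply(seq_len(nrow(d$data)), function(i) {
    ns$net_forward(fit$params, list(
      matrix(as.numeric(d$data[i, c("p1", "p2")]), 1),
      matrix(as.numeric(d$data[i, c("a1", "a2")]), 1)
    ))$prob
  }, numeric(1))
  expect_equal(prob, row_probs, tolerance = 1e-12)
})

test_that("raising the cost ratio does not reduce predicted positives", {
  positives <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    cfg <- synth_config(m = 160, n_p = 6, n_q = 10, n_complete = 4,
                        seed = 100 + s)
    d <- generate_health_data(cfg)
    full <- impute_mean(d$data)
    for (cs in c(FALSE, TRUE)) {
      fit <- fit_dualnet(full, d$groups, d$labels,
                         test_net_config(cost_sensitive = cs, seed = s))
      positives[s, cs + 1] <- sum(predict(fit, full, type = "class"))
    }
  }
  expect_gte(mean(positives[, 2]), mean(positives[, 1]))
})

test_that("the single-network baseline matches the dual net's representation size", {
  d <- separable_data(20, seed = 41)
  dual <- fit_dualnet(d$data, d$groups, d$labels,
                      test_net_config(epochs = 0))
  snn <- fit_snn(d$data, d$groups, d$labels,
                 test_net_config(d1 = 16, d2 = 8, epochs = 0))
  expect_identical(length(snn$branch_columns), 1L)
  expect_identical(length(snn$branch_columns$all), 4L)  # consumes all inputs
  # head input dims: 2 * d2 for the dual net, d2_snn = 2 * d2 for the SNN
  expect_identical(nrow(dual$params$head$W), 8L)
  expect_identical(nrow(snn$params$head$W), 8L)
})

test_that("extra fully connected layers extend the head as configured", {
  d <- separable_data(20, seed = 51)
  cfg <- test_net_config(extra_layers = 2, seed = 3)
  expect_identical(cfg$extra_dims, c(8L, 8L))  # defaults to 2 * d2 each
  fit <- fit_dualnet(d$data, d$groups, d$labels, cfg)
  expect_length(fit$params$extras, 2)
  expect_true(all(is.finite(predict(fit, d$data))))
  expect_error(dualnet_config(extra_layers = 3), "0, 1 or 2")
})

test_that("a fitted model survives JSON serialization byte-for-byte in behaviour", {
  d <- separable_data(24, seed = 61)
  fit <- fit_dualnet(d$data, d$groups, d$labels, test_net_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_dualnet(fit, path)
  back <- read_dualnet(path)
  expect_equal(predict(back, d$data), predict(fit, d$data), tolerance = 1e-12)
  expect_identical(back$architecture, fit$architecture)
  expect_identical(back$branch_columns, fit$branch_columns)

  g <- glance(fit)
  expect_identical(g$architecture, "dual")
  td <- tidy(fit)
  expect_true(all(c("component", "layer", "parameter") %in% names(td)))
  aug <- augment(fit, d$data)
  expect_true(all(c(".pred_prob", ".pred_class") %in% names(aug)))
})
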