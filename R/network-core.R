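# Internal branched multilayer perceptron.
#
# Architecture: each branch g sees its own input block X_g and applies two
# ReLU hidden layers (widths d1, d2). The deepest branch representations are
# concatenated; optional extra fully connected ReLU layers may follow; a
# single sigmoid unit produces the high-risk probability. Parameters are
# plain R matrices so analytic gradients can be checked against finite
# differences directly.

net_init <- function(input_dims, d1, d2, extra_dims = integer(0), seed = 1) {
  he_unif <- function(n_in, n_out) {
    lim <- sqrt(6 / n_in)
    matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  withr::with_seed(seed, {
    branches <- lapply(input_dims, function(n_in) {
      list(
        W1 = he_unif(n_in, d1), b1 = rep(0, d1),
        W2 = he_unif(d1, d2), b2 = rep(0, d2)
      )
    })
    rep_dim <- length(input_dims) * d2
    extras <- list()
    dim_in <- rep_dim
    for (dd in extra_dims) {
      extras[[length(extras) + 1]] <- list(W = he_unif(dim_in, dd), b = rep(0, dd))
      dim_in <- dd
    }
    head <- list(W = he_unif(dim_in, 1), b = 0)
    list(branches = branches, extras = extras, head = head,
         input_dims = input_dims, d1 = d1, d2 = d2, extra_dims = extra_dims)
  })
}

add_bias <- function(z, b) sweep(z, 2, b, "+")

# Forward pass over a list of input matrices (one per branch, rows aligned).
# Returns probabilities, the concatenated representation, and the cache
# needed for backpropagation.
net_forward <- function(params, x_list, keep_cache = FALSE) {
  stopifnot(length(x_list) == length(params$branches))
  branch_caches <- vector("list", length(x_list))
  h2s <- vector("list", length(x_list))
  for (g in seq_along(x_list)) {
    br <- params$branches[[g]]
    x <- x_list[[g]]
    z1 <- add_bias(x %*% br$W1, br$b1)
    h1 <- relu(z1)
    z2 <- add_bias(h1 %*% br$W2, br$b2)
    h2 <- relu(z2)
    h2s[[g]] <- h2
    if (keep_cache) branch_caches[[g]] <- list(x = x, z1 = z1, h1 = h1, z2 = z2, h2 = h2)
  }
  rep_mat <- do.call(cbind, h2s)
  a <- rep_mat
  extra_caches <- vector("list", length(params$extras))
  for (e in seq_along(params$extras)) {
    ex <- params$extras[[e]]
    ze <- add_bias(a %*% ex$W, ex$b)
    he <- relu(ze)
    if (keep_cache) extra_caches[[e]] <- list(input = a, z = ze)
    a <- he
  }
  z <- as.vector(a %*% params$head$W) + params$head$b
  prob <- sigmoid(z)
  out <- list(prob = prob, rep = rep_mat)
  if (keep_cache) {
    out$cache <- list(branches = branch_caches, extras = extra_caches,
                      head_input = a)
  }
  out
}

# Cost-sensitive binary cross-entropy: mean over samples of
# -[w_i y_i log p_i + (1 - y_i) log(1 - p_i)], with w_i = m_n / m_d for
# high-risk samples when cost-sensitive, else 1.
net_sample_weights <- function(y, cost_sensitive, class_counts = NULL) {
  if (!cost_sensitive) return(rep(1, length(y)))
  if (is.null(class_counts)) {
    class_counts <- c(n_normal = sum(y == 0), n_high_risk = sum(y == 1))
  }
  if (class_counts[[2]] == 0) {
    abort("Cost ratio undefined: no high-risk samples in the training labels.")
  }
  w <- class_counts[[1]] / class_counts[[2]]
  ifelse(y == 1, w, 1)
}

net_loss <- function(prob, y, weights) {
  p <- clamp_prob(prob)
  mean(-(weights * y * log(p) + (1 - y) * log(1 - p)))
}

# Analytic gradients of net_loss wrt all parameters, for one batch.
net_backward <- function(params, fwd, y, weights) {
  n <- length(y)
  p <- clamp_prob(fwd$prob)
  # d loss / d z_head; the clamp is inactive in the interior, where training
  # lives, so the unclamped derivative is used.
  dz <- (weights * y * (p - 1) + (1 - y) * p) / n
  dz <- matrix(dz, ncol = 1)
  cache <- fwd$cache
  grads <- list(branches = vector("list", length(params$branches)),
                extras = vector("list", length(params$extras)),
                head = NULL)
  a <- cache$head_input
  grads$head <- list(W = crossprod(a, dz), b = sum(dz))
  da <- dz %*% t(params$head$W)
  for (e in rev(seq_along(params$extras))) {
    ec <- cache$extras[[e]]
    dze <- da * (ec$z > 0)
    grads$extras[[e]] <- list(W = crossprod(ec$input, dze), b = colSums(dze))
    da <- dze %*% t(params$extras[[e]]$W)
  }
  d2 <- params$d2
  for (g in seq_along(params$branches)) {
    bc <- cache$branches[[g]]
    cols <- ((g - 1) * d2 + 1):(g * d2)
    dh2 <- da[, cols, drop = FALSE]
    dz2 <- dh2 * (bc$z2 > 0)
    dh1 <- dz2 %*% t(params$branches[[g]]$W2)
    dz1 <- dh1 * (bc$z1 > 0)
    grads$branches[[g]] <- list(
      W1 = crossprod(bc$x, dz1), b1 = colSums(dz1),
      W2 = crossprod(bc$h1, dz2), b2 = colSums(dz2)
    )
  }
  grads
}

# Flatten parameters (or gradients of the same shape) to a numeric vector and
# back; used by the finite-difference gradient checks.
net_flatten <- function(params) {
  unlist(lapply(params$branches, function(b) c(b$W1, b$b1, b$W2, b$b2))) |>
    c(unlist(lapply(params$extras, function(e) c(e$W, e$b)))) |>
    c(c(params$head$W, params$head$b)) |>
    unname()
}

net_unflatten <- function(params, theta) {
  pos <- 1
  take <- function(n) {
    out <- theta[pos:(pos + n - 1)]
    pos <<- pos + n
    out
  }
  for (g in seq_along(params$branches)) {
    b <- params$branches[[g]]
    params$branches[[g]]$W1 <- matrix(take(length(b$W1)), nrow(b$W1), ncol(b$W1))
    params$branches[[g]]$b1 <- take(length(b$b1))
    params$branches[[g]]$W2 <- matrix(take(length(b$W2)), nrow(b$W2), ncol(b$W2))
    params$branches[[g]]$b2 <- take(length(b$b2))
  }
  for (e in seq_along(params$extras)) {
    ex <- params$extras[[e]]
    params$extras[[e]]$W <- matrix(take(length(ex$W)), nrow(ex$W), ncol(ex$W))
    params$extras[[e]]$b <- take(length(ex$b))
  }
  params$head$W <- matrix(take(length(params$head$W)), length(params$head$W), 1)
  params$head$b <- take(1)
  stopifnot(pos == length(theta) + 1)
  params
}

# Mini-batch SGD with classical momentum: v <- mom * v - lr * g; theta += v.
net_train <- function(params, x_list, y, cfg) {
  weights_full <- net_sample_weights(y, cfg$cost_sensitive)
  m <- length(y)
  theta <- net_flatten(params)
  vel <- numeric(length(theta))
  loss_history <- numeric(0)
  if (cfg$epochs > 0) {
    withr::with_seed(derive_seed(cfg$seed, "train"), {
      best <- Inf
      wait <- 0
      for (epoch in seq_len(cfg$epochs)) {
        idx <- sample.int(m)
        batch_starts <- seq(1, m, by = cfg$batch_size)
        epoch_loss <- 0
        for (s in batch_starts) {
          rows <- idx[s:min(s + cfg$batch_size - 1, m)]
          xb <- lapply(x_list, function(x) x[rows, , drop = FALSE])
          yb <- y[rows]
          wb <- weights_full[rows]
          params <- net_unflatten(params, theta)
          fwd <- net_forward(params, xb, keep_cache = TRUE)
          grads <- net_backward(params, fwd, yb, wb)
          g <- net_flatten(grads)
          vel <- cfg$momentum * vel - cfg$learning_rate * g
          theta <- theta + vel
          epoch_loss <- epoch_loss + net_loss(fwd$prob, yb, wb) * length(rows)
        }
        loss_history <- c(loss_history, epoch_loss / m)
        if (cfg$early_stopping) {
          cur <- loss_history[length(loss_history)]
          if (cur < best - cfg$tol) {
            best <- cur
            wait <- 0
          } else {
            wait <- wait + 1
            if (wait >= cfg$patience) break
          }
        }
      }
    })
  }
  list(params = net_unflatten(params, theta), loss_history = loss_history)
}
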