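#' Pairwise record distances over the complete features
#'
#' Similarity between client records is measured on the complete columns only,
#' since those are the only entries guaranteed to be observed for every
#' record. The resulting matrix anchors k-nearest-neighbour imputation.
#'
#' @param data Tibble of numeric feature columns (`NA` = missing).
#' @param groups Tibble from [feature_groups()]; its `complete` column selects
#'   the distance features.
#' @param metric One of `"euclidean"` (default), `"cityblock"`, `"cosine"`.
#' @return An m x m symmetric matrix with zero diagonal, with attributes
#'   `metric` and class `record_dist`.
#' @export
record_distances <- function(data, groups,
                             metric = c("euclidean", "cityblock", "cosine")) {
  metric <- match.arg(metric)
  complete_cols <- groups$column[groups$complete]
  if (length(complete_cols) == 0) {
    abort("No complete columns: record distances are undefined.")
  }
  x <- feature_matrix(data, complete_cols)
  if (anyNA(x)) abort("Columns marked complete contain missing values.")
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(x, method = "euclidean")),
    cityblock = as.matrix(stats::dist(x, method = "manhattan")),
    cosine = cosine_distance(x)
  )
  dimnames(d) <- NULL
  diag(d) <- 0
  structure(d, metric = metric, class = c("record_dist", "matrix", "array"))
}

# 1 - cosine similarity; zero-norm rows get similarity 0 to any other row.
cosine_distance <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  s <- tcrossprod(x)
  denom <- outer(nrm, nrm)
  sim <- ifelse(denom > 0, s / denom, 0)
  d <- 1 - sim
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Mean imputation
#'
#' Each missing entry is replaced by the mean of the observed entries in its
#' column. Observed entries are never altered.
#'
#' @param data Tibble of numeric feature columns (`NA` = missing).
#' @return The completed tibble. The fill bookkeeping is attached as attribute
#'   `"imputation_report"`; read it with [imputation_report()].
#' @export
impute_mean <- function(data) {
  x <- feature_matrix(data)
  n_missing <- sum(is.na(x))
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    abort(paste0(
      "Column(s) with no observed values cannot be mean-imputed: ",
      paste(colnames(x)[all_na], collapse = ", ")
    ))
  }
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mu[j]
  }
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- names(data)
  attr(out, "imputation_report") <- tibble::tibble(
    method = "mean", k = NA_integer_, metric = NA_character_,
    filled_cell_count = n_missing, fallback_cell_count = 0L
  )
  out
}

#' K-nearest-neighbour imputation anchored on complete features
#'
#' Record-to-record distances are computed over the complete columns; each
#' missing entry of record i in column b is then filled with a weighted
#' average of the observed values of b over the k records nearest to i *among
#' those that observe b*. Weights decrease with distance
#' (`w = 1 / (d + 1e-8)`, normalised), so more similar neighbours count more;
#' exact duplicates dominate through the epsilon regulariser. Equidistant
#' neighbours are broken by row order for determinism. A cell with no
#' eligible neighbour at all falls back to the column's observed mean and is
#' counted in the report's `fallback_cell_count`.
#'
#' @inheritParams record_distances
#' @param k Number of neighbours (default 5). Must satisfy `1 <= k < m`.
#' @return The completed tibble with attribute `"imputation_report"`.
#' @export
impute_knn <- function(data, groups, k = 5,
                       metric = c("euclidean", "cityblock", "cosine")) {
  metric <- match.arg(metric)
  m <- nrow(data)
  if (k < 1) abort("`k` must be at least 1.")
  if (k >= m) abort("`k` must be smaller than the number of records.")
  x <- feature_matrix(data)
  if (!anyNA(x)) {
    out <- tibble::as_tibble(data)
    attr(out, "imputation_report") <- tibble::tibble(
      method = "knn", k = as.integer(k), metric = metric,
      filled_cell_count = 0L, fallback_cell_count = 0L
    )
    return(out)
  }
  d <- record_distances(data, groups, metric)
  filled <- knn_fill(x, x, d, k)
  out <- tibble::as_tibble(as.data.frame(filled$values))
  names(out) <- names(data)
  attr(out, "imputation_report") <- tibble::tibble(
    method = "knn", k = as.integer(k), metric = metric,
    filled_cell_count = filled$filled, fallback_cell_count = filled$fallback
  )
  out
}

# Fill the missing cells of `target` using candidate donor rows in `pool`.
# `d` is the target-row x pool-row distance matrix. When target and pool are
# the same table, a row is never its own donor.
knn_fill <- function(target, pool, d, k) {
  self_pool <- nrow(target) == nrow(pool) && identical(target, pool)
  n_filled <- 0L
  n_fallback <- 0L
  col_means <- colMeans(pool, na.rm = TRUE)
  out <- target
  for (j in seq_len(ncol(target))) {
    miss_rows <- which(is.na(target[, j]))
    if (length(miss_rows) == 0) next
    donor_rows <- which(!is.na(pool[, j]))
    vals <- pool[donor_rows, j]
    for (i in miss_rows) {
      donors <- donor_rows
      dvals <- vals
      if (self_pool) {
        keep <- donors != i
        donors <- donors[keep]
        dvals <- dvals[keep]
      }
      if (length(donors) == 0) {
        fill <- col_means[j]
        if (is.nan(fill)) {
          abort(paste0(
            "Column ", j, " has no observed values; cannot impute."
          ))
        }
        n_fallback <- n_fallback + 1L
      } else {
        di <- d[i, donors]
        ord <- order(di, donors)       # stable tie-break by row index
        sel <- ord[seq_len(min(k, length(ord)))]
        w <- 1 / (di[sel] + 1e-8)
        w <- w / sum(w)
        fill <- sum(w * dvals[sel])
      }
      out[i, j] <- fill
      n_filled <- n_filled + 1L
    }
  }
  list(values = out, filled = n_filled, fallback = n_fallback)
}

#' Retrieve the imputation report attached to a completed table
#'
#' @param data A tibble returned by [impute_mean()] or [impute_knn()].
#' @return A one-row tibble: `method`, `k`, `metric`, `filled_cell_count`,
#'   `fallback_cell_count`.
#' @export
imputation_report <- function(data) {
  rep <- attr(data, "imputation_report")
  if (is.null(rep)) abort("No imputation report attached to this table.")
  rep
}

# Leak-free split imputation: statistics/donors come from the training rows
# only; test rows are completed against the training pool.
impute_split <- function(train, test, groups, method = c("mean", "knn"),
                         k = 5, metric = "euclidean") {
  method <- match.arg(method)
  if (method == "mean") {
    x_tr <- feature_matrix(train)
    mu <- colMeans(x_tr, na.rm = TRUE)
    if (anyNA(mu) || any(is.nan(mu))) {
      abort("A column has no observed training values; cannot impute.")
    }
    fill_with <- function(tbl) {
      x <- feature_matrix(tbl)
      for (j in seq_len(ncol(x))) {
        miss <- is.na(x[, j])
        if (any(miss)) x[miss, j] <- mu[j]
      }
      out <- tibble::as_tibble(as.data.frame(x))
      names(out) <- names(tbl)
      out
    }
    return(list(train = fill_with(train), test = fill_with(test)))
  }
  complete_cols <- groups$column[groups$complete]
  if (length(complete_cols) == 0) abort("No complete columns for distances.")
  x_tr <- feature_matrix(train)
  x_te <- feature_matrix(test)
  d_tr <- record_distances(train, groups, metric)
  tr_filled <- knn_fill(x_tr, x_tr, d_tr, k)
  ct <- match(complete_cols, names(train))
  d_cross <- cross_distances(x_te[, ct, drop = FALSE],
                             x_tr[, ct, drop = FALSE], metric)
  te_filled <- knn_fill(x_te, x_tr, d_cross, k)
  wrap <- function(x, nms) {
    out <- tibble::as_tibble(as.data.frame(x))
    names(out) <- nms
    out
  }
  list(
    train = wrap(tr_filled$values, names(train)),
    test = wrap(te_filled$values, names(test))
  )
}

cross_distances <- function(a, b, metric) {
  if (metric == "euclidean") {
    aa <- rowSums(a^2)
    bb <- rowSums(b^2)
    d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else if (metric == "cityblock") {
    d <- matrix(0, nrow(a), nrow(b))
    for (i in seq_len(nrow(a))) {
      d[i, ] <- colSums(abs(t(b) - a[i, ]))
    }
    d
  } else {
    na <- sqrt(rowSums(a^2))
    nb <- sqrt(rowSums(b^2))
    denom <- outer(na, nb)
    sim <- ifelse(denom > 0, tcrossprod(a, b) / denom, 0)
    d <- 1 - sim
    d[d < 0] <- 0
    d
  }
}
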