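sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Fan a top-level seed out to per-stage seeds without correlated streams.
# Kept below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    synth = 104729, folds = 224737, init = 350377,
    train = 479909, impute = 611953, study = 746773
  )
  off <- offsets[[stage]]
  as.integer((abs(seed) * 2654435761 + off) %% 2147483647L)
}

# Matrix view of the feature columns of a data frame, in a fixed column order.
feature_matrix <- function(data, columns = NULL) {
  if (is.null(columns)) columns <- names(data)
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Columns absent from data: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as.matrix(data[columns])
  if (!is.numeric(x)) abort("All feature columns must be numeric.")
  x
}

check_complete <- function(data, what = "This operation") {
  if (anyNA(data)) {
    abort(paste0(
      what, " requires a fully observed table; impute missing values first ",
      "(see impute_mean() or impute_knn())."
    ))
  }
  invisible(data)
}
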