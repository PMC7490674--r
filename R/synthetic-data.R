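#' Default column-wise missingness profile
#'
#' Bins of per-feature missing-data rates with the number of features falling
#' in each bin, mirroring the structure of a community health dataset in
#' which 96 of 567 features are fully observed and the rest range up to
#' nearly 70% missing.
#'
#' @return A tibble with columns `lower`, `upper` (rate bounds as
#'   proportions) and `count`.
#' @export
default_missing_bins <- function() {
  tibble::tibble(
    lower = c(0, 0.01, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60),
    upper = c(0, 0.09, 0.19, 0.29, 0.39, 0.49, 0.59, 0.69),
    count = c(96L, 49L, 22L, 6L, 97L, 5L, 152L, 140L)
  )
}

# Rescale the default bin counts to a smaller feature space, keeping the
# complete-bin count pinned and distributing the incomplete counts
# proportionally (largest-remainder rounding).
scale_missing_bins <- function(n, n_complete) {
  bins <- default_missing_bins()
  inc <- bins[-1, ]
  target <- n - n_complete
  raw <- inc$count / sum(inc$count) * target
  cnt <- floor(raw)
  rem <- target - sum(cnt)
  if (rem > 0) {
    topup <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[topup] <- cnt[topup] + 1L
  }
  bins$count <- as.integer(c(n_complete, cnt))
  bins
}

#' Configuration for the synthetic health-data generator
#'
#' Defaults emulate the structure the screening method assumes: 2299 records
#' with 132 profile and 435 assessment features (567 total), 96 fully
#' observed columns (all in the profile group), a heavy-tailed column-wise
#' missingness profile, and 427 high-risk versus 1872 normal cases (a 1:4.4
#' class imbalance). Each feature group is driven by its own class-conditional
#' latent factors, so both groups carry independent ("complementary")
#' predictive signal.
#'
#' When `n_p`/`n_q`/`n_complete` are changed and `missing_bins` is not given,
#' the default bin counts are rescaled proportionally to the new feature
#' count.
#'
#' @param m Number of records.
#' @param n_p,n_q Number of profile / assessment features.
#' @param n_complete Number of fully observed features; must not exceed
#'   `n_p` (complete columns live in the profile group).
#' @param missing_bins Tibble `lower`/`upper`/`count`; counts must sum to
#'   `n_p + n_q` with the first bin equal to `n_complete` at rate 0.
#' @param minority_count Number of high-risk records (must be < `m`). The
#'   default preserves the 427 / 2299 prevalence (the 1:4.4 imbalance) at any
#'   `m`: 427 when `m = 2299`, else `round(m * 427 / 2299)`.
#' @param latent_dim Latent factors per feature group.
#' @param signal_profile,signal_assessment Class separation (latent-space
#'   Mahalanobis shift) carried by each group; 0 removes all signal.
#' @param noise_sd Feature-level Gaussian noise SD.
#' @param binary_fraction Fraction of assessment columns binarised to emulate
#'   yes/no questionnaire items.
#' @param scale_profile,scale_assessment Numeric scale of each group's
#'   continuous features. The defaults (1 and 8) emulate the heterogeneity of
#'   raw community health records: profile variables on standardised
#'   measurement-like scales versus assessment questionnaire scores spanning
#'   wider raw ranges. Since no input normalisation is applied by default,
#'   this scale mismatch is part of what a single undivided network must cope
#'   with. Binarised items always stay 0/1.
#' @param mechanism Missingness mechanism: `"mcar"` (default) masks cells
#'   completely at random at each column's target rate; `"mar"` ties the
#'   masking probability to the first complete profile feature.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(m = 2299, n_p = 132, n_q = 435, n_complete = 96,
                         missing_bins = NULL, minority_count = NULL,
                         latent_dim = 3, signal_profile = 1.2,
                         signal_assessment = 1.2, noise_sd = 1,
                         binary_fraction = 0.3,
                         scale_profile = 1, scale_assessment = 8,
                         mechanism = c("mcar", "mar"), seed = 1) {
  mechanism <- match.arg(mechanism)
  n <- n_p + n_q
  if (is.null(minority_count)) minority_count <- max(1L, round(m * 427 / 2299))
  if (n_complete > n_p) {
    abort("`n_complete` must not exceed `n_p`: complete columns live in the profile group.")
  }
  if (minority_count >= m) abort("`minority_count` must be smaller than `m`.")
  if (minority_count < 1) abort("`minority_count` must be at least 1.")
  if (is.null(missing_bins)) {
    missing_bins <- if (n == 567 && n_complete == 96) {
      default_missing_bins()
    } else {
      scale_missing_bins(n, n_complete)
    }
  }
  if (sum(missing_bins$count) != n) {
    abort("`missing_bins` counts must sum to the total feature count.")
  }
  if (missing_bins$count[1] != n_complete || missing_bins$upper[1] != 0) {
    abort("The first missingness bin must hold the complete features at rate 0.")
  }
  if (signal_profile < 0 || signal_assessment < 0 || noise_sd <= 0) {
    abort("Signal strengths must be nonnegative and `noise_sd` positive.")
  }
  structure(
    list(
      m = m, n_p = n_p, n_q = n_q, n_complete = n_complete,
      missing_bins = missing_bins, minority_count = minority_count,
      latent_dim = latent_dim, signal_profile = signal_profile,
      signal_assessment = signal_assessment, noise_sd = noise_sd,
      binary_fraction = binary_fraction, scale_profile = scale_profile,
      scale_assessment = scale_assessment, mechanism = mechanism, seed = seed
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic grouped health-record dataset
#'
#' Labels are drawn to hit the configured high-risk count exactly. Each group
#' g has its own latent factors `U_g ~ N(0, I)` whose mean is shifted for
#' high-risk records by `signal_g / sqrt(latent_dim)` in every latent
#' dimension (a latent Mahalanobis separation of `signal_g`); features are
#' linear loadings of the latents plus Gaussian noise, with a configurable
#' fraction of assessment columns thresholded to 0/1. Each incomplete
#' column's target missing rate is drawn uniformly within its bin and cells
#' are masked completely at random at that rate (missingness is independent
#' of the label). Incomplete profile columns take the lowest nonzero-rate
#' bins; assessment columns take the remainder, so every assessment column
#' has missing data.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_health_data`: `data` (tibble with `NA`
#'   missing cells), `groups` ([feature_groups()] tibble), `labels` (integer
#'   0/1), and `truth` (latents, loadings, per-column target rates, and the
#'   config).
#' @examples
#' d <- generate_health_data(synth_config(m = 50, n_p = 6, n_q = 10,
#'                                        n_complete = 4, seed = 1))
#' dim(d$data)
#' @export
generate_health_data <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(derive_seed(cfg$seed, "synth"), {
    m <- cfg$m
    n <- cfg$n_p + cfg$n_q
    y <- integer(m)
    y[sample.int(m, cfg$minority_count)] <- 1L

    draw_group <- function(n_feat, signal, n_binary, scale) {
      u <- matrix(rnorm(m * cfg$latent_dim), m, cfg$latent_dim)
      shift <- signal / sqrt(cfg$latent_dim)
      u[y == 1, ] <- u[y == 1, ] + shift
      a <- matrix(rnorm(cfg$latent_dim * n_feat), cfg$latent_dim, n_feat) /
        sqrt(cfg$latent_dim)
      x <- u %*% a + cfg$noise_sd * matrix(rnorm(m * n_feat), m, n_feat)
      x <- x * scale
      if (n_binary > 0) {
        # first columns binarised; yes/no items stay on the 0/1 scale
        bcols <- seq_len(n_binary)
        x[, bcols] <- (x[, bcols] > 0) * 1
      }
      list(u = u, a = a, x = x)
    }
    gp <- draw_group(cfg$n_p, cfg$signal_profile, 0L, cfg$scale_profile)
    gq <- draw_group(cfg$n_q, cfg$signal_assessment,
                     as.integer(round(cfg$binary_fraction * cfg$n_q)),
                     cfg$scale_assessment)

    x <- cbind(gp$x, gq$x)
    colnames(x) <- c(sprintf("p%03d", seq_len(cfg$n_p)),
                     sprintf("a%03d", seq_len(cfg$n_q)))

    # Per-column target rates: complete bin -> profile; lowest nonzero bins ->
    # remaining profile columns; everything else -> assessment columns.
    bins <- cfg$missing_bins
    inc_bins <- bins[-1, ][order(bins$lower[-1]), ]
    rates <- numeric(0)
    for (b in seq_len(nrow(inc_bins))) {
      rates <- c(rates, runif(inc_bins$count[b], inc_bins$lower[b],
                              inc_bins$upper[b]))
    }
    n_inc_profile <- cfg$n_p - cfg$n_complete
    col_rate <- c(
      rep(0, cfg$n_complete),
      rates[seq_len(n_inc_profile)],
      if (length(rates) > n_inc_profile) rates[(n_inc_profile + 1):length(rates)]
    )

    mar_driver <- if (cfg$mechanism == "mar") rank(x[, 1]) / m else NULL
    for (j in seq_len(n)) {
      r <- col_rate[j]
      if (r <= 0) next
      if (cfg$mechanism == "mcar") {
        mask <- runif(m) < r
      } else {
        # masking probability increases with the first complete profile
        # feature; mean masking rate stays at the column target
        p <- r * 2 * mar_driver
        mask <- runif(m) < pmin(p, 1)
      }
      x[mask, j] <- NA_real_
    }

    data <- tibble::as_tibble(as.data.frame(x))
    assignment <- stats::setNames(
      c(rep("profile", cfg$n_p), rep("assessment", cfg$n_q)),
      colnames(x)
    )
    groups <- feature_groups(data, assignment)
    list2 <- list(
      data = data,
      groups = groups,
      labels = y,
      truth = list(
        latents = list(profile = gp$u, assessment = gq$u),
        loadings = list(profile = gp$a, assessment = gq$a),
        target_rates = tibble::tibble(column = colnames(x), rate = col_rate),
        config = cfg
      )
    )
    structure(list2, class = "synth_health_data")
  })
}

#' @export
print.synth_health_data <- function(x, ...) {
  cnt <- group_counts(x$groups)
  cat(sprintf(
    "<synth_health_data: %d records x %d features (%d profile, %d assessment)>\n",
    nrow(x$data), cnt$n, cnt$n_profile, cnt$n_assessment
  ))
  cat(sprintf(
    "  complete columns: %d; high-risk: %d / %d\n",
    cnt$n_complete, sum(x$labels), length(x$labels)
  ))
  invisible(x)
}

#' Draw MMSE scores consistent with binary risk labels
#'
#' Scores are drawn uniformly on the integers 24-30 for normal records and
#' 0-23 for high-risk records, so [derive_labels()] inverts the draw exactly.
#'
#' @param labels Integer 0/1 vector.
#' @param seed Integer seed.
#' @return Integer vector of MMSE scores in `[0, 30]`.
#' @export
mmse_scores_from_labels <- function(labels, seed = 1) {
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary 0/1.")
  withr::with_seed(seed, {
    scores <- integer(length(labels))
    n1 <- sum(labels == 1)
    n0 <- sum(labels == 0)
    scores[labels == 1] <- sample(0:23, n1, replace = TRUE)
    scores[labels == 0] <- sample(24:30, n0, replace = TRUE)
    scores
  })
}
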