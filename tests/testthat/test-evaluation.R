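test_that("fold assignment gives near-equal folds covering every record", {
  f20 <- make_folds(20, seed = 1)
  expect_equal(unname(table(f20)), rep(2L, 10), ignore_attr = TRUE)

  f <- make_folds(2299, seed = 3)
  sizes <- as.integer(table(f))
  expect_true(all(sizes %in% c(229L, 230L)))
  expect_equal(sum(sizes), 2299)
  expect_length(f, 2299)                     # every record in exactly one fold
  expect_identical(make_folds(2299, seed = 3), f)   # determinism
  expect_false(identical(make_folds(2299, seed = 4), f))
  expect_error(make_folds(8, n_folds = 10), "at least as many records")
})

test_that("stratified folds balance the classes", {
  y <- rep(c(0L, 1L), c(80, 20))
  f <- make_folds(100, seed = 2, labels = y, stratify = TRUE)
  per_fold_pos <- tapply(y, f, sum)
  expect_true(all(per_fold_pos == 2))
})

test_that("metric edge cases behave as the definitions demand", {
  y <- c(0, 0, 1, 1)
  perfect <- screening_metrics(y, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$ap, 1)

  all_pos <- screening_metrics(y, c(0.9, 0.9, 0.9, 0.9),
                               classes = c(1L, 1L, 1L, 1L))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)

  expect_error(screening_metrics(c(1, 1, 1), c(0.1, 0.2, 0.3)),
               "single-class")
})

test_that("AUC and AP match exhaustive oracles, including ties", {
  withr::with_seed(10, {
    for (rep in 1:30) {
      n <- sample(4:12, 1)
      y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
      m <- screening_metrics(y, scores)
      expect_equal(m$auc, oracle_auc(y, scores), tolerance = 1e-12)
      expect_equal(m$ap, oracle_ap(y, scores), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an established implementation", {
  withr::with_seed(11, {
    y <- sample(0:1, 50, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    s <- rnorm(50) + y
  })
  got <- screening_metrics(y, s)$auc
  want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("ranking metrics are invariant to strictly monotone transforms", {
  withr::with_seed(12, {
    y <- rep(c(0L, 1L), c(14, 6))
    s <- rnorm(20)
  })
  base <- screening_metrics(y, s)
  for (f in list(function(x) exp(x), function(x) 5 * x - 3,
                 function(x) atan(x))) {
    tr <- screening_metrics(y, f(s))
    expect_equal(tr$auc, base$auc, tolerance = 1e-12)
    expect_equal(tr$ap, base$ap, tolerance = 1e-12)
  }
})

test_that("one-sided paired comparisons point the right way", {
  cvtbl <- function(ref_vals, comp_vals) {
    df <- dplyr::bind_rows(
      tibble::tibble(label = "DNN+CSL", algorithm = "DNN",
                     cost_sensitive = TRUE, fold = 1:10,
                     auc = ref_vals, ap = ref_vals,
                     sensitivity = ref_vals, specificity = ref_vals),
      tibble::tibble(label = "LR", algorithm = "LR",
                     cost_sensitive = FALSE, fold = 1:10,
                     auc = comp_vals, ap = comp_vals,
                     sensitivity = comp_vals, specificity = comp_vals)
    )
    structure(df, class = c("cv_result", class(df)))
  }
  withr::with_seed(13, {
    base <- runif(10, 0.6, 0.8)
  })
  noise <- rep(c(-1e-3, 1e-3), 5)   # exactly zero-mean perturbation
  # reference clearly above: small p
  up <- compare_to_reference(cvtbl(base + 0.1 + noise, base))
  expect_true(all(up$p_value < 0.01))
  # reference clearly below: p near 1
  down <- compare_to_reference(cvtbl(base - 0.1 + noise, base))
  expect_true(all(down$p_value > 0.99))
  # identical folds: zero-variance differences are flagged, not tested
  same <- compare_to_reference(cvtbl(base, base))
  expect_true(all(same$degenerate))
  expect_true(all(is.na(same$p_value)))
  # exactly zero mean difference: the one-sided p sits at one half
  null <- compare_to_reference(cvtbl(base + noise, base))
  expect_equal(unique(null$p_value), 0.5, tolerance = 1e-12)
  expect_error(compare_to_reference(cvtbl(base, base), reference = "nope"),
               "not in the result")
})

test_that("cross-validation pairs all algorithms on shared folds", {
  cfg <- synth_config(m = 120, n_p = 6, n_q = 10, n_complete = 4, seed = 14)
  d <- generate_health_data(cfg)
  algos <- dplyr::filter(baseline_grid(), label %in% c("LR", "LR+CSL", "DT"))
  cv <- cross_validate(d$data, d$groups, d$labels, algorithms = algos,
                       n_folds = 4, seed = 5, imputation = "mean")
  expect_equal(nrow(cv), 3 * 4)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  expect_true(all(cv$ap >= 0 & cv$ap <= 1))
  fold_attr <- attr(cv, "folds")
  expect_length(fold_attr, 120)

  # identical seed reproduces the whole result table
  cv2 <- cross_validate(d$data, d$groups, d$labels, algorithms = algos,
                        n_folds = 4, seed = 5, imputation = "mean")
  expect_equal(tibble::as_tibble(cv), tibble::as_tibble(cv2))

  smry <- summary(cv)
  expect_equal(nrow(smry), 3 * 4)  # 3 algorithms x 4 metrics
  expect_true(all(c("mean", "sd") %in% names(smry)))
  g <- glance(cv)
  expect_equal(g$n_folds, 4)
})

test_that("leak-free imputation mode runs and stays honest on metrics", {
  cfg <- synth_config(m = 90, n_p = 6, n_q = 8, n_complete = 4, seed = 15)
  d <- generate_health_data(cfg)
  algos <- dplyr::filter(baseline_grid(), label == "LR")
  cv <- cross_validate(d$data, d$groups, d$labels, algorithms = algos,
                       n_folds = 3, seed = 6, imputation = "knn", k = 3,
                       leak_free = TRUE)
  expect_equal(nrow(cv), 3)
  expect_true(all(is.finite(cv$auc)))
})
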