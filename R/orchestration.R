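#' Run a full screening experiment from a configuration
#'
#' Reproduces the experiment shape end to end: obtain data (either load a
#' delimited file plus group config, or generate a synthetic dataset), impute
#' missing entries once, cross-validate the requested algorithm grid on
#' shared folds, summarise the four metrics, and test every algorithm against
#' the reference with one-sided paired t-tests. A run manifest captures the
#' configuration snapshot, the derived per-stage seeds, and a hash of the
#' fold assignment so a completed run can be reproduced exactly.
#'
#' The configuration is a named list (or a YAML file path) with entries:
#' \describe{
#'   \item{data, group_config}{paths to a data file and group config, or}
#'   \item{synth}{a list of [synth_config()] arguments for synthetic data;}
#'   \item{imputation}{`"mean"` (default), `"knn"`, or `"none"`; plus
#'     optional `k`, `metric`, `leak_free`;}
#'   \item{grid}{`"full"` (default) or a character vector of grid labels,
#'     e.g. `c("DNN", "DNN+CSL")`;}
#'   \item{n_folds}{default 10;}
#'   \item{net}{a list of [dualnet_config()] overrides;}
#'   \item{reference}{reference algorithm for the t-tests, default
#'     `"DNN+CSL"` when present in the grid;}
#'   \item{seed}{top-level seed, fanned out to the stages.}
#' }
#'
#' @param config A named list or path to a YAML file.
#' @param out_dir Optional directory; when given, writes `report.csv` (means
#'   and SDs rounded to 2 decimals), `report_full.csv` (per-fold values at
#'   full precision), and `manifest.json`.
#' @return A list of class `experiment_result`: `cv` (the [cross_validate()]
#'   result), `summary`, `comparison` (or `NULL` when the grid has a single
#'   entry), and `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  seed <- config$seed %||% 1L

  if (!is.null(config$data)) {
    loaded <- read_health_table(config$data, config$group_config)
    if (is.null(loaded$labels)) abort("The data config must include a label column.")
    data <- loaded$data
    groups <- loaded$groups
    labels <- loaded$labels
    source_desc <- config$data
  } else {
    synth_args <- config$synth %||% list()
    synth_args$seed <- synth_args$seed %||% derive_seed(seed, "synth")
    scfg <- do.call(synth_config, synth_args)
    d <- generate_health_data(scfg)
    data <- d$data
    groups <- d$groups
    labels <- d$labels
    source_desc <- "synthetic"
  }

  grid <- baseline_grid()
  if (!is.null(config$grid) && !identical(config$grid, "full")) {
    unknown <- setdiff(config$grid, grid$label)
    if (length(unknown) > 0) {
      abort(paste0("Unknown grid entries: ", paste(unknown, collapse = ", ")))
    }
    grid <- grid[grid$label %in% config$grid, ]
  }

  net_args <- config$net %||% list()
  net_cfg <- do.call(dualnet_config, net_args)
  imputation <- config$imputation %||% "mean"

  cv <- cross_validate(
    data, groups, labels,
    algorithms = grid,
    n_folds = config$n_folds %||% 10,
    seed = seed,
    imputation = imputation,
    k = config$k %||% 5,
    metric = config$metric %||% "euclidean",
    leak_free = isTRUE(config$leak_free),
    net_config = net_cfg,
    threshold = config$threshold %||% 0.5,
    stratify = isTRUE(config$stratify)
  )
  smry <- summary(cv)

  reference <- config$reference %||%
    (if ("DNN+CSL" %in% grid$label) "DNN+CSL" else grid$label[nrow(grid)])
  comparison <- if (nrow(grid) > 1 && reference %in% grid$label) {
    compare_to_reference(cv, reference = reference)
  } else NULL

  manifest <- list(
    tool = "dualscreen",
    version = as.character(utils::packageVersion("dualscreen")),
    config = config,
    data_source = source_desc,
    n_records = nrow(data),
    n_features = nrow(groups),
    class_counts = list(normal = sum(labels == 0), high_risk = sum(labels == 1)),
    imputation = imputation,
    grid = grid$label,
    seed = seed,
    stage_seeds = list(
      synth = derive_seed(seed, "synth"),
      folds = derive_seed(seed, "folds"),
      train = derive_seed(seed, "train")
    ),
    fold_hash = rlang::hash(attr(cv, "folds")),
    resampled_splits = attr(cv, "resampled"),
    reference = reference,
    baseline_defaults = purrr::map_chr(unique(grid$algorithm), baseline_defaults)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    human <- smry |>
      dplyr::mutate(cell = sprintf("%.2f (%.2f)", .data$mean, .data$sd)) |>
      dplyr::select("label", "metric", "cell") |>
      tidyr::pivot_wider(names_from = "metric", values_from = "cell")
    readr::write_csv(human, file.path(out_dir, "report.csv"))
    readr::write_csv(tibble::as_tibble(cv), file.path(out_dir, "report_full.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(cv = cv, summary = smry, comparison = comparison, manifest = manifest),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result: %d algorithms x %d folds, imputation = %s>\n",
    length(x$manifest$grid), dplyr::n_distinct(x$cv$fold),
    x$manifest$imputation
  ))
  wide <- x$summary |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f)", .data$mean, .data$sd)) |>
    dplyr::select("label", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
  print(wide, n = Inf)
  invisible(x)
}

#' Sensitivity study over an imputation or architecture parameter
#'
#' Re-runs the cross-validated reference model (`DNN+CSL` by default) for each
#' value of one tunable parameter — the number of imputation neighbours `k`,
#' or the hidden widths `d1` / `d2` — and reports mean AUC and AP per value,
#' the tabular counterpart of a parameter-sweep curve.
#'
#' @param config Experiment configuration (list or YAML path), as in
#'   [run_experiment()]; its `grid` is ignored.
#' @param parameter One of `"k"`, `"d1"`, `"d2"`.
#' @param values Numeric vector of parameter values (nonempty).
#' @param algorithm Grid label to sweep (default `"DNN+CSL"`).
#' @return A tibble: `parameter`, `value`, `auc`, `ap` (means over folds).
#' @export
run_sensitivity_study <- function(config, parameter = c("k", "d1", "d2"),
                                  values, algorithm = "DNN+CSL") {
  parameter <- match.arg(parameter)
  if (length(values) == 0) abort("`values` must be nonempty.")
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config$grid <- algorithm
  purrr::map_dfr(values, function(v) {
    cfg <- config
    if (parameter == "k") {
      cfg$imputation <- "knn"
      cfg$k <- v
    } else {
      cfg$net <- cfg$net %||% list()
      cfg$net[[parameter]] <- v
    }
    res <- run_experiment(cfg)
    s <- res$summary
    tibble::tibble(
      parameter = parameter,
      value = v,
      auc = s$mean[s$metric == "auc"],
      ap = s$mean[s$metric == "ap"]
    )
  })
}
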