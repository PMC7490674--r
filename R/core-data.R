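#' Partition feature columns into groups and completeness sets
#'
#' Community health records carry two kinds of features: client *profile*
#' variables (demographics, bio-measurements, medical history) and *assessment*
#' variables from health questionnaires. Independently of that partition, each
#' column is either *complete* (observed for every record) or *incomplete*
#' (at least one missing entry); distances for k-nearest-neighbour imputation
#' are computed over the complete columns only.
#'
#' @param data A data frame of numeric feature columns; `NA` marks a missing
#'   entry.
#' @param assignment Group assignment for every feature column: either a named
#'   character vector (`c(age = "profile", gds_1 = "assessment", ...)`) or a
#'   two-column data frame with columns `column` and `group`. Groups must be
#'   `"profile"` or `"assessment"`.
#' @return A tibble with one row per feature column and columns `column`,
#'   `group` (factor: profile/assessment), `complete` (logical, fully
#'   observed), and `missing_rate` (fraction of records with the entry
#'   missing).
#' @examples
#' d <- tibble::tibble(age = c(70, 81, 65), gds = c(4, NA, 9))
#' feature_groups(d, c(age = "profile", gds = "assessment"))
#' @export
feature_groups <- function(data, assignment) {
  if (is.data.frame(assignment)) {
    if (!all(c("column", "group") %in% names(assignment))) {
      abort("`assignment` data frame needs columns `column` and `group`.")
    }
    asg <- stats::setNames(as.character(assignment$group), assignment$column)
  } else {
    asg <- assignment
  }
  if (is.null(names(asg)) || any(names(asg) == "")) {
    abort("`assignment` must name every column.")
  }
  bad_groups <- setdiff(unique(asg), c("profile", "assessment"))
  if (length(bad_groups) > 0) {
    abort(paste0("Unknown feature group(s): ", paste(bad_groups, collapse = ", ")))
  }
  unknown <- setdiff(names(asg), names(data))
  if (length(unknown) > 0) {
    abort(paste0(
      "Assignment names column(s) absent from data: ",
      paste(unknown, collapse = ", ")
    ))
  }
  unassigned <- setdiff(names(data), names(asg))
  if (length(unassigned) > 0) {
    abort(paste0(
      "Data column(s) missing from assignment: ",
      paste(unassigned, collapse = ", ")
    ))
  }
  x <- feature_matrix(data)
  miss <- colMeans(is.na(x))
  tibble::tibble(
    column = names(data),
    group = factor(asg[names(data)], levels = c("profile", "assessment")),
    complete = unname(miss == 0),
    missing_rate = unname(miss)
  )
}

#' Summary counts of a feature-group partition
#'
#' @param groups A tibble as returned by [feature_groups()].
#' @return A one-row tibble with `n`, `n_profile`, `n_assessment`,
#'   `n_complete`, `n_incomplete`.
#' @export
group_counts <- function(groups) {
  tibble::tibble(
    n = nrow(groups),
    n_profile = sum(groups$group == "profile"),
    n_assessment = sum(groups$group == "assessment"),
    n_complete = sum(groups$complete),
    n_incomplete = sum(!groups$complete)
  )
}

#' Read a delimited health-record table with a group configuration
#'
#' Reads one record per row from a CSV/TSV file with a header. Empty cells (or
#' a configurable sentinel) encode missing entries. A group configuration file
#' maps every column to `profile`, `assessment`, or `label`; the label column
#' (if any) is split off as the binary outcome.
#'
#' The configuration file is either a YAML mapping (`column: group`, for
#' `.yml`/`.yaml` files) or a two-column delimited file with header
#' `column,group`.
#'
#' @param path Path to the data file (`.csv` or `.tsv`, by extension).
#' @param config Path to the group configuration file.
#' @param na Sentinel string(s) treated as missing, in addition to truly empty
#'   cells. Default `""`.
#' @return A list with elements `data` (tibble of numeric feature columns,
#'   `NA` = missing), `groups` (tibble from [feature_groups()]), and `labels`
#'   (integer 0/1 vector, or `NULL` when the config declares no label column).
#' @export
read_health_table <- function(path, config, na = "") {
  asg <- read_group_config(config)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim, na = na, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  unknown <- setdiff(names(asg), names(raw))
  if (length(unknown) > 0) {
    abort(paste0(
      "Config names column(s) absent from the data file: ",
      paste(unknown, collapse = ", ")
    ))
  }
  unassigned <- setdiff(names(raw), names(asg))
  if (length(unassigned) > 0) {
    abort(paste0(
      "Data column(s) missing from the config: ",
      paste(unassigned, collapse = ", ")
    ))
  }
  parsed <- purrr::imap(raw, function(col, nm) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(out) & !is.na(col))
    if (length(bad) > 0) {
      abort(paste0(
        "Non-numeric, non-empty cell in column `", nm, "` (first at row ",
        bad[1], "): \"", col[bad[1]], "\""
      ))
    }
    out
  })
  data <- tibble::as_tibble(parsed)
  label_cols <- names(asg)[asg == "label"]
  if (length(label_cols) > 1) abort("Config declares more than one label column.")
  labels <- NULL
  if (length(label_cols) == 1) {
    labels <- data[[label_cols]]
    if (anyNA(labels)) abort("Label column contains missing values.")
    if (!all(labels %in% c(0, 1))) abort("Label column must be binary 0/1.")
    labels <- as.integer(labels)
    data[[label_cols]] <- NULL
    asg <- asg[names(asg) != label_cols]
  }
  list(
    data = data,
    groups = feature_groups(data, asg),
    labels = labels
  )
}

read_group_config <- function(config) {
  if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
    cfg <- yaml::read_yaml(config)
    asg <- unlist(cfg)
  } else {
    delim <- if (grepl("\\.tsv$", config, ignore.case = TRUE)) "\t" else ","
    cfg <- readr::read_delim(
      config,
      delim = delim, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    if (!all(c("column", "group") %in% names(cfg))) {
      abort("Group config file needs columns `column` and `group`.")
    }
    asg <- stats::setNames(cfg$group, cfg$column)
  }
  bad <- setdiff(unique(asg), c("profile", "assessment", "label"))
  if (length(bad) > 0) {
    abort(paste0("Unknown group(s) in config: ", paste(bad, collapse = ", ")))
  }
  asg
}

#' Write a health-record table and its group configuration
#'
#' Missing entries are written as empty cells, so [read_health_table()] on the
#' output round-trips values, missingness mask, and group assignment.
#'
#' @param data Tibble of numeric feature columns (`NA` = missing).
#' @param path Output data file (`.csv` or `.tsv` by extension).
#' @param groups Tibble from [feature_groups()] (or `NULL` to skip the config).
#' @param labels Optional integer 0/1 vector, written as column `label`.
#' @param config Optional path for the group configuration file.
#' @return `path`, invisibly.
#' @export
write_health_table <- function(data, path, groups = NULL, labels = NULL,
                               config = NULL) {
  out <- data
  if (!is.null(labels)) {
    if (length(labels) != nrow(data)) abort("labels length must match rows.")
    out$label <- as.integer(labels)
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  if (!is.null(config)) {
    if (is.null(groups)) abort("`groups` is required to write a config file.")
    cfg <- tibble::tibble(
      column = c(groups$column, if (!is.null(labels)) "label"),
      group = c(as.character(groups$group), if (!is.null(labels)) "label")
    )
    cdelim <- if (grepl("\\.tsv$", config, ignore.case = TRUE)) "\t" else ","
    readr::write_delim(cfg, config, delim = cdelim)
  }
  invisible(path)
}

#' Derive binary high-risk labels from MMSE scores
#'
#' The Mini-Mental State Examination is scored 0-30; a score of 24 or above
#' indicates normal cognition, while a score below 24 suggests impairment and
#' defines the high-risk class.
#'
#' @param mmse Numeric vector of MMSE scores in \[0, 30\].
#' @return Integer vector: 1 (high risk) where `mmse < 24`, else 0.
#' @examples
#' derive_labels(c(30, 24, 23, 0))
#' @export
derive_labels <- function(mmse) {
  if (!is.numeric(mmse)) abort("`mmse` must be numeric.")
  if (anyNA(mmse) || any(mmse < 0 | mmse > 30)) {
    abort("MMSE scores must be in [0, 30] with no missing values.")
  }
  as.integer(mmse < 24)
}
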