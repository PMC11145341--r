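# Delimited-text I/O for feature tables and the end-to-end scale
# workflow. Tables on disk are wide: first column the feature
# identifier, remaining columns one per sample. Group labels come from a
# named vector or a two-column sidecar file (sample_id, group).

#' Read a wide feature table from delimited text
#'
#' @param path CSV or TSV file; the delimiter is inferred from the
#'   extension (`.csv` = comma, otherwise tab) unless `delim` is given.
#' @param groups Optional group assignment: a named character vector
#'   (`c(sample1 = "control", ...)`) or the path to a two-column
#'   delimited file with columns `sample_id` and `group`. Samples left
#'   unassigned get `NA`.
#' @param delim Field delimiter override.
#' @return Long tibble with columns `feature_id`, `sample_id`, `group`,
#'   `value`. Non-numeric cells become `NA` with one warning giving the
#'   count.
#' @export
read_feature_table <- function(path, groups = NULL, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort("table must have a feature column and at least one sample column.")
  }
  names(raw)[1] <- "feature_id"
  if (anyDuplicated(raw$feature_id)) {
    abort("duplicate feature identifiers in the first column.")
  }
  long <- raw |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "raw_value")
  value <- suppressWarnings(as.numeric(long$raw_value))
  n_bad <- sum(is.na(value) & !is.na(long$raw_value) &
                 long$raw_value != "NA")
  if (n_bad > 0) {
    warn(sprintf("%d non-numeric cell(s) set to NA.", n_bad))
  }
  long$value <- value
  long$raw_value <- NULL

  group_map <- resolve_groups(groups, delim)
  long$group <- if (is.null(group_map)) {
    NA_character_
  } else {
    unname(group_map[long$sample_id])
  }
  long[, c("feature_id", "sample_id", "group", "value")]
}

resolve_groups <- function(groups, delim = "\t") {
  if (is.null(groups)) return(NULL)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gdelim <- if (grepl("\\.csv$", groups, ignore.case = TRUE)) "," else "\t"
    tbl <- readr::read_delim(groups, delim = gdelim, col_types = "cc",
                             progress = FALSE)
    require_columns(tbl, c("sample_id", "group"))
    return(setNames(tbl$group, tbl$sample_id))
  }
  if (is.null(names(groups))) abort("`groups` must be named by sample_id.")
  groups
}

#' Write a long feature table as wide delimited text
#'
#' @param data Long tibble (`feature_id`, `sample_id`, `value`).
#' @param path Output path; `.csv` writes comma-separated, else tab.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  require_columns(data, c("feature_id", "sample_id", "value"))
  wide <- tidyr::pivot_wider(data[, c("feature_id", "sample_id", "value")],
                             names_from = "sample_id",
                             values_from = "value")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(wide, path)
  } else {
    readr::write_tsv(wide, path)
  }
  invisible(path)
}

#' Run the table-scaling workflow end to end
#'
#' Reads (or accepts) a feature table, converts intensities to per-donor
#' log2 abundance ratios against the control cohort if needed, derives
#' effect-size thresholds, applies the per-feature scaling transform, and
#' categorises every feature on the volcano plane. Results and a JSON
#' run summary are written to `out_dir` (when given) and returned.
#'
#' Thresholds come from the pseudo-control distribution when a control
#' cohort is present, and otherwise from the central quantiles of the
#' per-feature effects themselves.
#'
#' All randomness flows from `seed`; each randomised stage uses its own
#' derived substream (`seed + 1` for the pseudo-control permutation) so
#' adding a stage never perturbs another stage's draws.
#'
#' @param input Path to a delimited table or a long tibble as returned by
#'   [read_feature_table()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing. Files: `scaled.tsv` (feature_id, n, m1, p, s, V, category)
#'   and `summary.json`.
#' @param value_space `"log2_ratio"` (default; values are already
#'   per-donor log2 effects), `"ratio"` (log2 is taken first), or
#'   `"intensity"` (ratios computed against the control-cohort mean).
#' @param m0 Hypothetical mean on the log2 scale; default 0.
#' @param penalty Penalty factor `F`, or `"auto"` (10 x replicate count).
#' @param alpha Significance level; default 0.05.
#' @param coverage Threshold coverage; default 0.90.
#' @param seed Integer master seed.
#' @param groups Group assignment (see [read_feature_table()]); only
#'   needed for intensity-space input or when `input` is a path.
#' @param digits Significant digits for the written table; `Inf` writes
#'   full precision.
#' @param verbose Log resolved parameters to stderr.
#' @return (Invisibly) a list with `result` (per-feature tibble),
#'   `thresholds`, and `summary` (the JSON payload as a list).
#' @export
run_scale_workflow <- function(input, out_dir = NULL,
                               value_space = c("log2_ratio", "ratio",
                                               "intensity"),
                               m0 = 0, penalty = "auto", alpha = 0.05,
                               coverage = 0.90, seed = 1, groups = NULL,
                               digits = 6, verbose = FALSE) {
  value_space <- match.arg(value_space)
  data <- if (is.character(input)) {
    read_feature_table(input, groups = groups)
  } else {
    input
  }
  require_columns(data, c("feature_id", "sample_id", "value"))
  if (!"group" %in% names(data) && !is.null(groups)) {
    gm <- resolve_groups(groups)
    data$group <- unname(gm[data$sample_id])
  }

  if (value_space == "intensity") {
    if (!"group" %in% names(data) || !any(data$group %in% "control")) {
      abort("intensity-space input needs control samples (see `groups`).")
    }
    thresholds <- pseudo_control_thresholds(
      dplyr::filter(data, .data$group == "control"),
      coverage = coverage, alpha = alpha, seed = seed + 1
    )
    ratios <- abundance_ratios(data)
  } else {
    ratios <- data |>
      dplyr::mutate(log2_ratio = if (value_space == "ratio") {
        log2(.data$value)
      } else {
        .data$value
      }) |>
      dplyr::select("feature_id", "sample_id", "log2_ratio")
    thresholds <- NULL
  }

  scaled <- percept_table(ratios, m0 = m0, penalty = penalty)
  if (is.null(thresholds)) {
    thresholds <- percentile_thresholds(scaled$m1, coverage = coverage,
                                        alpha = alpha)
  }
  scaled$category <- categorize_features(scaled$m1, scaled$p, thresholds)

  counts <- table(scaled$category, useNA = "no")
  resolved_F <- if (identical(penalty, "auto")) {
    sort(unique(10 * scaled$n[scaled$n >= 2]))
  } else {
    penalty
  }
  summary <- list(
    n_features = nrow(scaled),
    n_flagged = sum(!is.na(scaled$note)),
    m0 = m0,
    penalty = if (identical(penalty, "auto")) "auto" else penalty,
    resolved_penalty = resolved_F,
    alpha = alpha,
    coverage = coverage,
    seed = seed,
    thresholds = list(lower = thresholds$lower, upper = thresholds$upper),
    category_counts = as.list(counts),
    category_percent = as.list(round(100 * counts / sum(counts), 2))
  )
  if (verbose) {
    message(sprintf(
      "scaled %d features: m0=%g, F=%s, alpha=%g, thresholds=[%.4g, %.4g], seed=%d",
      nrow(scaled), m0, paste(resolved_F, collapse = "/"), alpha,
      thresholds$lower, thresholds$upper, seed
    ))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- scaled
    if (is.finite(digits)) {
      num <- vapply(out, is.numeric, logical(1))
      out[num] <- lapply(out[num], signif, digits = digits)
    }
    readr::write_tsv(out, file.path(out_dir, "scaled.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(result = scaled, thresholds = thresholds, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
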