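# Cohort-level operations: abundance ratios against a control cohort,
# data-driven effect-size thresholds, volcano categorisation, and
# table-wide application of the scaling transform.
#
# Tables are tidy (long) tibbles with columns:
#   feature_id : feature identifier (opaque string)
#   sample_id  : donor / replicate identifier
#   group      : "control" or "case" (where relevant)
#   value      : measurement (intensity or log2 ratio, per function)

#' Construct effect-size thresholds
#'
#' Bundles the lower/upper log2 effect bounds and the significance level
#' that together define the quadrants of a volcano plot. Bounds need not
#' be symmetric: data-driven thresholds usually are not.
#'
#' @param lower,upper Log2-scale effect bounds, `lower < upper` (equality
#'   allowed for degenerate, variability-free data).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return An `effect_thresholds` object.
#' @examples
#' effect_thresholds(-0.058, 0.077)
#' @export
effect_thresholds <- function(lower, upper, alpha = 0.05) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower > upper) {
    abort("`lower` must be <= `upper`.")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  structure(
    list(lower = lower, upper = upper, alpha = alpha),
    class = "effect_thresholds"
  )
}

#' @export
print.effect_thresholds <- function(x, ...) {
  cat(sprintf(
    "Effect thresholds: log2 effect < %.4g or > %.4g; alpha = %g\n",
    x$lower, x$upper, x$alpha
  ))
  if (!is.null(attr(x, "n_pseudo"))) {
    cat(sprintf("  (from %d pseudo-control ratios, coverage %g)\n",
                attr(x, "n_pseudo"), attr(x, "coverage")))
  }
  invisible(x)
}

#' @rdname effect_thresholds
#' @param x An `effect_thresholds` object.
#' @param ... Unused.
#' @method tidy effect_thresholds
#' @export
tidy.effect_thresholds <- function(x, ...) {
  tibble::tibble(lower = x$lower, upper = x$upper, alpha = x$alpha)
}

#' Per-donor abundance ratios against the control cohort mean
#'
#' For each feature, divides every case donor's intensity by the mean
#' intensity of that feature in the control cohort, and returns the result
#' on the log2 scale. This converts raw intensities into per-donor effect
#' sizes with a natural null at 0.
#'
#' Features whose control mean is non-positive or undefined (all control
#' values missing) yield `NA` ratios and are flagged in the `note` column
#' rather than aborting the run.
#'
#' @param data Long tibble with columns `feature_id`, `sample_id`,
#'   `group` (`"control"`/`"case"`) and `value` (positive intensities).
#' @return Tibble with columns `feature_id`, `sample_id`, `log2_ratio`,
#'   `note` (NA or a flag string), one row per case donor and feature.
#' @examples
#' tbl <- tibble::tibble(
#'   feature_id = "P1",
#'   sample_id = c("c1", "c2", "d1"),
#'   group = c("control", "control", "case"),
#'   value = c(10, 10, 20)
#' )
#' abundance_ratios(tbl) # log2 ratio 1: the case donor doubled
#' @export
abundance_ratios <- function(data) {
  require_columns(data, c("feature_id", "sample_id", "group", "value"))
  if (!any(data$group == "control") || !any(data$group == "case")) {
    abort("`data` must contain both control and case samples.")
  }
  ctrl <- data |>
    dplyr::filter(.data$group == "control", is.finite(.data$value)) |>
    dplyr::summarise(ctrl_mean = mean(.data$value), .by = "feature_id")
  data |>
    dplyr::filter(.data$group == "case") |>
    dplyr::left_join(ctrl, by = "feature_id") |>
    dplyr::mutate(
      note = dplyr::case_when(
        is.na(.data$ctrl_mean) ~ "no control values",
        .data$ctrl_mean <= 0 ~ "non-positive control mean",
        TRUE ~ NA_character_
      ),
      log2_ratio = dplyr::if_else(
        is.na(.data$note), log2(.data$value / .data$ctrl_mean), NA_real_
      )
    ) |>
    dplyr::select("feature_id", "sample_id", "log2_ratio", "note")
}

#' Pseudo-control ratios from a label-randomised control cohort
#'
#' Compares the control cohort against a randomised version of itself:
#' for each feature independently the donor labels are permuted (seeded),
#' and each control donor's value is divided by the mean of the permuted
#' cohort's values for that feature. The pooled log2 ratios capture the
#' inherent experimental variability among controls without any disease
#' signal.
#'
#' @param data Long tibble with columns `feature_id`, `sample_id`,
#'   `value`; if a `group` column is present only `"control"` rows are
#'   used. At least 2 control samples are required.
#' @param seed Integer seed for the label permutation.
#' @return Tibble with columns `feature_id`, `sample_id`, `log2_ratio`.
#' @seealso [pseudo_control_thresholds()]
#' @export
pseudo_control_ratios <- function(data, seed) {
  if ("group" %in% names(data)) {
    data <- dplyr::filter(data, .data$group == "control")
  }
  require_columns(data, c("feature_id", "sample_id", "value"))
  if (dplyr::n_distinct(data$sample_id) < 2L) {
    abort("need at least 2 control samples.")
  }
  withr::local_seed(seed)
  data |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(
      permuted = sample(.data$value),
      log2_ratio = log2(.data$value / mean(.data$permuted)),
      .by = "feature_id"
    ) |>
    dplyr::select("feature_id", "sample_id", "log2_ratio")
}

#' Data-driven effect thresholds from a pseudo-control distribution
#'
#' Builds the pseudo-control log2-ratio distribution with
#' [pseudo_control_ratios()], pools the ratios across features and donors,
#' and returns the central quantiles that encompass `coverage` of the
#' distribution (the 5th and 95th percentiles at the default coverage of
#' 0.90). These bounds delineate the minimum abundance ratio considered
#' biologically interesting, replacing an arbitrary fixed fold-change
#' cutoff. Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7). The bounds are not forced symmetric.
#'
#' @inheritParams pseudo_control_ratios
#' @param coverage Fraction of the pseudo-control distribution the
#'   thresholds must encompass; default 0.90.
#' @param alpha Significance level stored alongside the bounds.
#' @return An [effect_thresholds()] object with attributes `n_pseudo` and
#'   `coverage`.
#' @export
pseudo_control_thresholds <- function(data, coverage = 0.90, alpha = 0.05,
                                      seed) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1) {
    abort("`coverage` must lie in (0, 1).")
  }
  ratios <- pseudo_control_ratios(data, seed = seed)
  x <- ratios$log2_ratio[is.finite(ratios$log2_ratio)]
  if (length(x) == 0L) abort("no finite pseudo-control ratios.")
  tail <- (1 - coverage) / 2
  q <- quantile(x, probs = c(tail, 1 - tail), names = FALSE, type = 7)
  th <- effect_thresholds(q[1], q[2], alpha = alpha)
  attr(th, "n_pseudo") <- length(x)
  attr(th, "coverage") <- coverage
  th
}

#' Percentile-based effect thresholds
#'
#' Effect bounds taken directly as the central-quantile cut of a set of
#' observed effects (the 5th and 95th percentiles at the default
#' coverage), for tables where no control cohort is available to build a
#' pseudo-control distribution.
#'
#' @param effects Numeric per-feature effects (mean log2 ratios).
#' @inheritParams pseudo_control_thresholds
#' @return An [effect_thresholds()] object.
#' @export
percentile_thresholds <- function(effects, coverage = 0.90, alpha = 0.05) {
  effects <- effects[is.finite(effects)]
  if (length(effects) == 0L) abort("no finite effects.")
  tail <- (1 - coverage) / 2
  q <- quantile(effects, probs = c(tail, 1 - tail), names = FALSE, type = 7)
  effect_thresholds(q[1], q[2], alpha = alpha)
}

#' Volcano-plot categories
#'
#' Crosses the two volcano-plot booleans — *significant* (`p < alpha`,
#' i.e. `-log10(p) > 1.3` at `alpha = 0.05`) and *affected*
#' (`effect > upper` or `effect < lower`, strict) — into four categories:
#'
#' * `S/A`  — significant and affected
#' * `NS/A` — non-significant but affected (the points binary
#'   thresholding discards despite large effect sizes)
#' * `NS/NA` — non-significant, non-affected
#' * `S/NA` — significant but inside the effect window (kept as its own
#'   label so the four categories partition the plane)
#'
#' @param effect Numeric effect sizes (mean log2 ratios).
#' @param p P-values in `[0, 1]`.
#' @param thresholds An [effect_thresholds()] object.
#' @return Factor with levels `S/A`, `NS/A`, `NS/NA`, `S/NA`; `NA` where
#'   `effect` or `p` is missing.
#' @examples
#' th <- effect_thresholds(-0.058, 0.077)
#' categorize_features(c(0.10, 0, -0.2), c(0.01, 0.5, 0.9), th)
#' @export
categorize_features <- function(effect, p, thresholds) {
  stopifnot(inherits(thresholds, "effect_thresholds"))
  check_pvalue(p)
  affected <- effect > thresholds$upper | effect < thresholds$lower
  significant <- p < thresholds$alpha
  out <- dplyr::case_when(
    significant & affected ~ "S/A",
    !significant & affected ~ "NS/A",
    !significant & !affected ~ "NS/NA",
    significant & !affected ~ "S/NA"
  )
  factor(out, levels = c("S/A", "NS/A", "NS/NA", "S/NA"))
}

#' Apply the scaling transform to every feature of a table
#'
#' Per-feature composition of the one-sample t-test and the scaling
#' transform: for each feature the replicate values (e.g. per-donor log2
#' ratios) are tested against `m0`, and the replicate mean is scaled by
#' `F^(-p)`. Features left with fewer than 2 finite values are returned
#' with `NA` results and a `note` flag instead of aborting the table.
#'
#' @param data Long tibble with columns `feature_id` and the value column.
#' @param value Column holding the replicate measurements (tidy-eval);
#'   defaults to `log2_ratio` as produced by [abundance_ratios()].
#' @param m0 Hypothetical mean; 0 for log2 ratios.
#' @param penalty Penalty factor `F`, or `"auto"` for
#'   [default_penalty()] of each feature's replicate count.
#' @param alternative Sidedness of the t-test.
#' @return Tibble with one row per feature, in input order: `feature_id`,
#'   `n`, `m1`, `p`, `s`, `V`, `note`.
#' @examples
#' tbl <- tibble::tibble(feature_id = "P1", log2_ratio = c(1, 2, 3))
#' percept_table(tbl, m0 = 0, penalty = 30)
#' @export
percept_table <- function(data, value = log2_ratio, m0 = 0, penalty = "auto",
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  require_columns(data, "feature_id")
  val <- rlang::enquo(value)
  auto <- identical(penalty, "auto")
  if (!auto) check_penalty(penalty)

  stats_tbl <- data |>
    dplyr::mutate(.value = !!val) |>
    dplyr::mutate(feature_id = factor(.data$feature_id,
                                      levels = unique(.data$feature_id))) |>
    dplyr::summarise(
      n = sum(is.finite(.data$.value)),
      m1 = mean(.data$.value[is.finite(.data$.value)]),
      sd = sd(.data$.value[is.finite(.data$.value)]),
      .by = "feature_id"
    )

  F <- if (auto) 10 * pmax(stats_tbl$n, 2L) else penalty
  tstat <- (stats_tbl$m1 - m0) / (stats_tbl$sd / sqrt(stats_tbl$n))
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(tstat), df = stats_tbl$n - 1),
    greater   = pt(tstat, df = stats_tbl$n - 1, lower.tail = FALSE),
    less      = pt(tstat, df = stats_tbl$n - 1)
  )
  # degenerate variance: continuous limit of the test (see one_sample_t_pvalue)
  zero_sd <- !is.na(stats_tbl$sd) & stats_tbl$sd == 0
  p[zero_sd] <- ifelse(stats_tbl$m1[zero_sd] == m0,
    switch(alternative, two.sided = 1, greater = 1, less = 1),
    switch(alternative,
      two.sided = 0,
      greater = ifelse(stats_tbl$m1[zero_sd] > m0, 0, 1),
      less = ifelse(stats_tbl$m1[zero_sd] < m0, 0, 1)
    )
  )
  too_few <- stats_tbl$n < 2L
  p[too_few] <- NA_real_

  stats_tbl |>
    dplyr::mutate(
      feature_id = as.character(.data$feature_id),
      m1 = dplyr::if_else(.data$n >= 1L, .data$m1, NA_real_),
      p = p,
      s = exp(-p * log(F)),
      V = m0 + (.data$m1 - m0) * .data$s,
      note = dplyr::if_else(too_few, "fewer than 2 finite values",
                            NA_character_)
    ) |>
    dplyr::select("feature_id", "n", "m1", "p", "s", "V", "note")
}

#' Symmetric max-absolute normalisation
#'
#' Divides every value by the table-wide maximum absolute value, so the
#' data are symmetrically scaled to a maximum range of -1 to 1 without
#' disrupting the centre at 0. Used to put datasets from different
#' technologies on a shared scale before compilation.
#'
#' @param data Tibble; or a bare numeric vector.
#' @param value Column to normalise (tidy-eval); default `log2_ratio`.
#' @return Same shape as the input with the value column rescaled.
#' @export
normalize_symmetric <- function(data, value = log2_ratio) {
  if (is.numeric(data)) {
    if (!any(is.finite(data))) abort("no finite values.")
    m <- max(abs(data[is.finite(data)]))
    if (m == 0) return(data)
    return(data / m)
  }
  val <- rlang::enquo(value)
  x <- dplyr::pull(data, !!val)
  if (!any(is.finite(x))) abort("no finite values.")
  m <- max(abs(x[is.finite(x)]))
  if (m == 0) m <- 1
  dplyr::mutate(data, !!rlang::quo_get_expr(val) := !!val / m)
}

require_columns <- function(data, cols) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  invisible(data)
}
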