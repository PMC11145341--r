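# Quantitative evaluation machinery: donor subsampling, distance to the
# population, interpolated cumulative distributions, Bland-Altman
# agreement, and cross-dataset correlation.

#' Mean absolute distance to the population
#'
#' The single-number summary used throughout the evaluation: the mean
#' over features of the absolute difference between a small-n summary and
#' the population (large-n or ground-truth) value. Pairs with a missing
#' value on either side are dropped.
#'
#' @param values Named or positional numeric vector of per-feature values.
#' @param population Numeric vector of matched per-feature population
#'   values (same order).
#' @return Non-negative scalar.
#' @examples
#' distance_to_population(c(1, 2), c(0, 0)) # 1.5
#' @export
distance_to_population <- function(values, population) {
  if (length(values) != length(population)) {
    abort("`values` and `population` must have the same length.")
  }
  ok <- is.finite(values) & is.finite(population)
  if (!any(ok)) abort("no overlapping finite feature pairs.")
  mean(abs(values[ok] - population[ok]))
}

#' Subsample donors and score raw versus scaled summaries
#'
#' Emulates low-replicate studies by repeatedly drawing `k` donors
#' without replacement from a cohort of per-donor log2 ratios. For every
#' trial the per-feature raw mean and the scaled value (one-sample t-test
#' against `m0`, penalty `F`) are computed and their mean absolute
#' distances to the full-cohort population mean recorded.
#'
#' Features with fewer than 2 finite values in a draw cannot be tested
#' and are excluded from both distances, keeping the raw and scaled
#' comparisons on the same feature set.
#'
#' @param data Long tibble of per-donor effects with columns `feature_id`,
#'   `sample_id` and the value column (default `log2_ratio`), e.g. the
#'   output of [abundance_ratios()].
#' @param k Donors per trial, `2 <= k <=` cohort size (a full-cohort
#'   draw reproduces the population means exactly).
#' @param trials Number of repeated draws; default 100.
#' @param penalty Penalty factor `F` for the scaling; default 20.
#' @param m0 Hypothetical mean; default 0 (log2 ratios).
#' @param seed Integer seed governing all draws.
#' @param value Value column (tidy-eval).
#' @return Tibble of class `percept_trials`, one row per trial:
#'   `trial`, `donors` (list column), `raw_means` and `scaled_values`
#'   (list columns of named per-feature vectors), `raw_distance`,
#'   `scaled_distance`.
#' @export
subsample_donors <- function(data, k = 5, trials = 100, penalty = 20,
                             m0 = 0, seed, value = log2_ratio) {
  require_columns(data, c("feature_id", "sample_id"))
  val <- rlang::enquo(value)
  check_penalty(penalty)
  wide <- data |>
    dplyr::mutate(.value = !!val) |>
    tidyr::pivot_wider(id_cols = "feature_id", names_from = "sample_id",
                       values_from = ".value") |>
    tibble::column_to_rownames("feature_id") |>
    as.matrix()
  donors <- colnames(wide)
  if (k > length(donors)) abort("`k` must not exceed the donor count.")
  if (k < 2L) abort("`k` must be at least 2.")
  if (trials < 1L) abort("`trials` must be at least 1.")
  population <- rowMeans(wide, na.rm = TRUE)

  draws <- withr::with_seed(
    seed,
    replicate(trials, sample(donors, k), simplify = FALSE)
  )
  rows <- purrr::imap(draws, function(ids, i) {
    sub <- wide[, ids, drop = FALSE]
    fin <- is.finite(sub)
    n <- rowSums(fin)
    m1 <- rowSums(ifelse(fin, sub, 0)) / n
    ss <- rowSums(ifelse(fin, sub^2, 0))
    s2 <- (ss - n * m1^2) / (n - 1)
    s2 <- pmax(s2, 0)  # guard tiny negative round-off
    tstat <- (m1 - m0) / sqrt(s2 / n)
    p <- 2 * pt(-abs(tstat), df = n - 1)
    zero <- !is.na(s2) & s2 == 0 & n >= 2
    p[zero] <- ifelse(m1[zero] == m0, 1, 0)
    usable <- n >= 2
    p[!usable] <- NA_real_
    V <- m0 + (m1 - m0) * exp(-p * log(penalty))
    m1[!usable] <- NA_real_
    tibble::tibble(
      trial = i,
      donors = list(ids),
      raw_means = list(m1),
      scaled_values = list(V),
      raw_distance = distance_to_population(m1, population),
      scaled_distance = distance_to_population(V, population)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "population") <- population
  attr(out, "k") <- k
  attr(out, "penalty") <- penalty
  class(out) <- c("percept_trials", class(out))
  out
}

#' Normalise trial distances to the mean raw distance
#'
#' Divides every raw and scaled distance by the mean raw distance across
#' trials, so the mean normalised raw distance is exactly 1 and scaled
#' distances read directly as a fraction of the raw baseline. Applying
#' the normalisation twice equals applying it once.
#'
#' @param trials Output of [subsample_donors()] (any tibble with
#'   `raw_distance` and `scaled_distance` columns works).
#' @return The input with both distance columns rescaled.
#' @export
normalize_distances <- function(trials) {
  require_columns(trials, c("raw_distance", "scaled_distance"))
  baseline <- mean(trials$raw_distance)
  if (!is.finite(baseline) || baseline == 0) {
    abort("mean raw distance is zero or undefined; cannot normalise.")
  }
  dplyr::mutate(
    trials,
    raw_distance = .data$raw_distance / baseline,
    scaled_distance = .data$scaled_distance / baseline
  )
}

#' Interpolate an empirical CDF at fixed increments
#'
#' Computes the empirical cumulative distribution of `values` (position
#' of the i-th order statistic = i/n, so the maximum sits at 1) and, at
#' each of `increments` equidistant targets from 0 to 1 (0, 0.01, ...,
#' 0.99, 1 by default), returns the value whose cumulative position is
#' nearest to the target, ties broken toward the lower position. A fixed
#' grid makes cumulative distributions from different trials averageable
#' point-wise (mean +/- SD bands).
#'
#' @param values Numeric vector; non-finite entries dropped.
#' @param increments Number of grid points including both ends;
#'   default 101.
#' @return Tibble with columns `position` (the grid) and `value`
#'   (non-decreasing, bounded by the data range).
#' @examples
#' interpolate_cdf(c(1, 2, 3, 4), increments = 11)
#' @export
interpolate_cdf <- function(values, increments = 101) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) abort("no finite values.")
  if (increments < 2L) abort("`increments` must be at least 2.")
  v <- sort(values)
  n <- length(v)
  pos <- seq_len(n) / n
  targets <- seq(0, 1, length.out = increments)
  idx <- vapply(targets, function(t) which.min(abs(pos - t)), integer(1))
  tibble::tibble(position = targets, value = v[idx])
}

#' Bland-Altman agreement between two paired measures
#'
#' Summarises agreement as the mean of the pairwise differences
#' `d = a - b` together with the classical 95% limits of agreement,
#' `mean(d) +/- 1.96 * sd(d)` (n - 1 denominator). A mean difference
#' near zero with narrow limits indicates the two measures agree.
#'
#' @param a,b Paired numeric vectors (same length, matched order);
#'   pairs with a missing side are dropped. At least 2 complete pairs.
#' @return A one-row tibble of class `percept_agreement`:
#'   `mean_difference`, `loa_low`, `loa_high`, `n`.
#' @examples
#' bland_altman(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2L) abort("need at least 2 complete pairs.")
  m <- mean(d)
  half <- 1.96 * sd(d)
  out <- tibble::tibble(
    mean_difference = m,
    loa_low = m - half,
    loa_high = m + half,
    n = length(d)
  )
  class(out) <- c("percept_agreement", class(out))
  out
}

#' @method tidy percept_agreement
#' @export
tidy.percept_agreement <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance percept_agreement
#' @export
glance.percept_agreement <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Pairwise Pearson correlation between datasets
#'
#' Correlates every unordered pair of per-feature summary tables on their
#' shared features (pairwise-complete) and tags each pair as `inside`
#' (same disease / group label) or `outside` (different labels). Pairs
#' from the same underlying biology should correlate more strongly,
#' especially after scaling; `outside` pairs act as a negative control.
#'
#' @param tables Named list of tibbles, each with columns `feature_id`
#'   and `value` (the raw or scaled per-feature summary).
#' @param groups Character vector of group labels, one per table (same
#'   order or same names as `tables`).
#' @return Tibble with one row per unordered pair: `table_a`, `table_b`,
#'   `relation` (`"inside"`/`"outside"`), `n_shared`, `r`. Pairs sharing
#'   fewer than 3 features get `r = NA`.
#' @export
pairwise_correlation <- function(tables, groups) {
  if (!is.list(tables) || length(tables) < 2L) {
    abort("`tables` must be a list of at least 2 tibbles.")
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("table", seq_along(tables))
  }
  if (length(groups) != length(tables)) {
    abort("`groups` must have one label per table.")
  }
  if (!is.null(names(groups))) groups <- groups[names(tables)]
  purrr::walk(tables, require_columns, cols = c("feature_id", "value"))

  pairs <- utils::combn(seq_along(tables), 2)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    merged <- dplyr::inner_join(
      tables[[i1]][, c("feature_id", "value")],
      tables[[i2]][, c("feature_id", "value")],
      by = "feature_id", suffix = c("_a", "_b")
    )
    ok <- is.finite(merged$value_a) & is.finite(merged$value_b)
    n_shared <- sum(ok)
    r <- if (n_shared >= 3L) {
      stats::cor(merged$value_a[ok], merged$value_b[ok], method = "pearson")
    } else {
      NA_real_
    }
    tibble::tibble(
      table_a = names(tables)[i1],
      table_b = names(tables)[i2],
      relation = if (groups[i1] == groups[i2]) "inside" else "outside",
      n_shared = n_shared,
      r = r
    )
  }) |>
    dplyr::bind_rows()
}
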