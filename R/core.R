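# Core transform: a p-value becomes an inverse scaling factor F^(-p) that
# pulls a measured mean toward a hypothetical mean. All functions here are
# pure and vectorised; table- and image-level wrappers live elsewhere.

check_penalty <- function(F) {
  if (!is.numeric(F) || anyNA(F) || any(!is.finite(F))) {
    abort("`F` must be finite and numeric.")
  }
  if (any(F <= 0)) {
    abort("`F` must be strictly positive.")
  }
  if (any(F <= 1)) {
    warn(paste0(
      "penalty factor F <= 1: the scaling factor F^(-p) is >= 1, so ",
      "low-confidence effects are amplified rather than suppressed."
    ))
  }
  invisible(F)
}

check_pvalue <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- !is.na(p) & (p < 0 | p > 1 | !is.finite(p))
  if (any(bad)) abort("`p` must lie in [0, 1].")
  invisible(p)
}

#' Scaling factor derived from a p-value
#'
#' Converts a p-value into the multiplicative scaling factor `F^(-p)`
#' applied to the deviation of a measured mean from the hypothetical mean.
#' At `p = 0` the factor is 1 (the measurement is fully preserved); as `p`
#' approaches 1 the factor approaches `1/F` (maximal suppression). Even a
#' very large penalty leaves significant measurements nearly intact: at
#' `p = 0.05` and `F = 500` the factor is still about 0.73.
#'
#' Evaluated as `exp(-p * log(F))` for numerical stability at large `F`.
#'
#' @param p P-value(s) in `[0, 1]`. `NA` propagates.
#' @param F Penalty factor, strictly positive. Values `<= 1` trigger a
#'   warning because they invert the intent of the method. A reasonable
#'   starting point is `default_penalty(n) = 10 * n`.
#' @return Numeric vector of scaling factors in `(0, 1]` when `F >= 1`.
#' @examples
#' scaling_factor(0.05, 500) # ~0.733: significant values barely move
#' scaling_factor(0.5, 30)   # ~0.183: noisy values strongly suppressed
#' @seealso [percept_scale()], [default_penalty()]
#' @export
scaling_factor <- function(p, F) {
  check_pvalue(p)
  check_penalty(F)
  exp(-p * log(F))
}

#' Scale a measured mean toward a hypothetical mean
#'
#' The central transform of the package: given a replicate mean `m1`, a
#' hypothetical (ground-truth or null) mean `m0`, a p-value `p` for the
#' difference, and a penalty factor `F`, returns
#'
#' \deqn{V = m_0 + (m_1 - m_0)\,F^{-p}.}
#'
#' High-confidence effects (small `p`) are preserved almost exactly, while
#' low-confidence effects are pulled toward `m0`. `V` always lies on the
#' segment between `m0` and `m1` when `F >= 1`.
#'
#' @param m1 Measured replicate mean(s); finite numeric.
#' @param m0 Hypothetical mean(s), in the same units as `m1`. Use 0 for
#'   log2 ratios, 1 for raw ratios.
#' @inheritParams scaling_factor
#' @return Numeric vector of scaled values.
#' @examples
#' # A noisy measurement (p = 0.5) is pulled close to the ground truth:
#' percept_scale(m1 = 400, m0 = 600, p = 0.5, F = 30)   # ~563
#' # A confident measurement (p = 0.02) is mostly preserved:
#' percept_scale(m1 = 400, m0 = 600, p = 0.02, F = 30)  # ~413
#' @export
percept_scale <- function(m1, m0, p, F) {
  if (!is.numeric(m1) || !is.numeric(m0)) {
    abort("`m1` and `m0` must be numeric.")
  }
  if (any(!is.finite(m1) & !is.na(m1)) || any(!is.finite(m0) & !is.na(m0))) {
    abort("`m1` and `m0` must be finite.")
  }
  m0 + (m1 - m0) * scaling_factor(p, F)
}

#' Default penalty factor for a given replicate number
#'
#' Returns `10 * n`, the recommended starting point for tuning the penalty
#' factor. Scaling the penalty with `n` offsets the natural decrease of
#' p-values with sample size, so datasets of different size are penalised
#' comparably. Always overridable: `F` is a free parameter everywhere.
#'
#' @param n Number of replicates, integer `>= 2`.
#' @return `10 * n`.
#' @examples
#' default_penalty(3) # 30
#' @export
default_penalty <- function(n) {
  if (!is.numeric(n) || anyNA(n) || any(n < 2) || any(n != round(n))) {
    abort("`n` must be an integer >= 2.")
  }
  10 * n
}

#' One-sample t-test p-value
#'
#' P-value of a one-sample t-test of `values` against the hypothetical
#' mean `m0`, with the sample standard deviation computed with the `n - 1`
#' denominator. Two-sided by default.
#'
#' Zero sample variance is handled as the continuous limit of the test
#' rather than returning `NaN`: identical replicates that differ from `m0`
#' give `p = 0` (the deviation is perfectly consistent, so it is fully
#' preserved downstream), and identical replicates equal to `m0` give
#' `p = 1`.
#'
#' @param values Numeric replicate measurements; `NA`s are dropped. At
#'   least 2 finite values are required.
#' @param m0 Hypothetical mean to test against.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return A single p-value in `[0, 1]`.
#' @examples
#' one_sample_t_pvalue(c(1, 2, 3), m0 = 2) # 1: mean equals m0
#' one_sample_t_pvalue(c(1, 2, 3), m0 = 0) # ~0.074
#' @export
one_sample_t_pvalue <- function(values, m0,
                                alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(values)) abort("`values` must be numeric.")
  if (length(m0) != 1L || !is.finite(m0)) abort("`m0` must be a single finite number.")
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) abort("need at least 2 finite replicate values for a t-test.")
  m1 <- mean(values)
  s <- sd(values)
  if (s == 0) {
    # degenerate variance: continuous limit of the test
    return(switch(alternative,
      two.sided = if (m1 == m0) 1 else 0,
      greater   = if (m1 > m0) 0 else 1,
      less      = if (m1 < m0) 0 else 1
    ))
  }
  tstat <- (m1 - m0) / (s / sqrt(n))
  switch(alternative,
    two.sided = 2 * pt(-abs(tstat), df = n - 1),
    greater   = pt(tstat, df = n - 1, lower.tail = FALSE),
    less      = pt(tstat, df = n - 1)
  )
}

#' Scale one feature's replicate measurements
#'
#' Composes [one_sample_t_pvalue()] and [percept_scale()] for a single
#' replicate vector: computes the replicate mean `m1`, the p-value `p`
#' against `m0`, the scaling factor `s = F^(-p)` and the scaled value `V`.
#'
#' @inheritParams one_sample_t_pvalue
#' @param penalty Penalty factor `F`; `"auto"` resolves to
#'   [default_penalty()] of the finite replicate count.
#' @return A one-row tibble with columns `n`, `m1`, `p`, `s`, `V`.
#' @examples
#' percept_from_replicates(c(1, 2, 3), m0 = 0, penalty = 30)
#' @export
percept_from_replicates <- function(values, m0 = 0, penalty = "auto",
                                    alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) abort("need at least 2 finite replicate values.")
  F <- if (identical(penalty, "auto")) default_penalty(n) else penalty
  p <- one_sample_t_pvalue(values, m0, alternative)
  s <- scaling_factor(p, F)
  tibble::tibble(
    n = n,
    m1 = mean(values),
    p = p,
    s = s,
    V = m0 + (mean(values) - m0) * s
  )
}
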