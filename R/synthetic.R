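# Seeded generators for everything the pipeline consumes: omics-like
# cohorts with known ground truth, and binary ground-truth images.
# Both are pure functions of their parameters plus the seed.

#' Generate a synthetic case/control cohort with known effects
#'
#' Emulates the statistical structure of a quantitative omics cohort:
#' each feature has a log-normal baseline intensity shared by all donors;
#' a designated fraction of features carries a true log2 fold-change in
#' the case cohort (sign randomised, half up / half down in expectation);
#' and every measurement receives independent Gaussian noise on the log2
#' scale. Intensities are
#' `baseline * 2^(effect * case_indicator + noise)`.
#'
#' Defaults mimic a proteomics-like dynamic range (baseline
#' `exp(N(14, 2))`, i.e. intensities mostly between ~1e4 and ~1e8) and a
#' cohort where a 30% minority of features is truly affected at
#' |log2 FC| = 0.5 against donor-level noise of 0.6 — noisy enough that
#' single small-n draws are unreliable. No claim is made of matching any
#' real dataset's moments.
#'
#' @param n_features Number of features.
#' @param n_control,n_case Donors per cohort (`n_control` may be 0 for a
#'   case-only table, and vice versa).
#' @param affected_fraction Fraction of features with a true effect.
#' @param effect_log2 True |log2 fold-change| of affected features.
#' @param noise_sd_log2 Per-measurement noise SD on the log2 scale.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean / SD of the
#'   per-feature baseline intensity.
#' @param seed Integer seed; same seed, same cohort.
#' @param truth Optional truth table from a previous call (`feature_id`,
#'   `affected`, `true_effect`): reuses those effects instead of drawing
#'   new ones, so several studies can share one ground truth while
#'   keeping independent noise.
#' @return List with `data` (long tibble: `feature_id`, `sample_id`,
#'   `group`, `value`) and `truth` (tibble: `feature_id`, `affected`,
#'   `true_effect` — the signed log2 effect, 0 for null features).
#' @examples
#' cohort <- generate_cohort(n_features = 20, n_control = 4, n_case = 4,
#'                           seed = 1)
#' head(cohort$truth)
#' @export
generate_cohort <- function(n_features = 500, n_control = 20, n_case = 20,
                            affected_fraction = 0.3, effect_log2 = 0.5,
                            noise_sd_log2 = 0.6, baseline_log_mean = 14,
                            baseline_log_sd = 2, seed, truth = NULL) {
  if (n_features < 1L) abort("`n_features` must be positive.")
  if (n_control < 0L || n_case < 0L || n_control + n_case < 1L) {
    abort("cohort sizes must be non-negative and not both zero.")
  }
  if (affected_fraction < 0 || affected_fraction > 1) {
    abort("`affected_fraction` must lie in [0, 1].")
  }
  if (noise_sd_log2 < 0) abort("`noise_sd_log2` must be non-negative.")

  feature_id <- sprintf("F%04d", seq_len(n_features))
  samples <- c(
    if (n_control > 0) sprintf("ctrl%03d", seq_len(n_control)),
    if (n_case > 0) sprintf("case%03d", seq_len(n_case))
  )
  group <- rep(c("control", "case"), c(n_control, n_case))

  if (!is.null(truth)) {
    require_columns(truth, c("feature_id", "affected", "true_effect"))
    if (nrow(truth) != n_features) {
      abort("`truth` must have one row per feature.")
    }
    feature_id <- truth$feature_id
  }
  withr::with_seed(seed, {
    if (is.null(truth)) {
      n_aff <- round(affected_fraction * n_features)
      affected <- seq_len(n_features) <= n_aff
      sign <- ifelse(runif(n_features) < 0.5, -1, 1)
      true_effect <- ifelse(affected, sign * effect_log2, 0)
    } else {
      affected <- truth$affected
      true_effect <- truth$true_effect
    }
    baseline <- exp(rnorm(n_features, baseline_log_mean, baseline_log_sd))

    shift <- outer(true_effect, as.numeric(group == "case"))  # features x samples
    noise <- matrix(rnorm(n_features * length(samples), sd = noise_sd_log2),
                    nrow = n_features)
    values <- baseline * 2^(shift + noise)
  })

  data <- tibble::tibble(
    feature_id = rep(feature_id, times = length(samples)),
    sample_id = rep(samples, each = n_features),
    group = rep(group, each = n_features),
    value = as.vector(values)
  )
  truth <- tibble::tibble(
    feature_id = feature_id,
    affected = affected,
    true_effect = true_effect
  )
  list(data = data, truth = truth)
}

#' Generate a binary ground-truth image
#'
#' Produces the 0/1 reference array for the imaging demonstration. Three
#' motifs are available: `"blocks"` (seeded random rectangles of 1s on a
#' 0 background), `"stripes"` (vertical stripes of the given period), and
#' `"checker"` (a checkerboard).
#'
#' @param height,width Positive image dimensions.
#' @param pattern `"blocks"`, `"stripes"`, or `"checker"`.
#' @param seed Integer seed (used by the `"blocks"` pattern).
#' @param period Stripe period in pixels (default 4: two columns of 0s,
#'   two of 1s, repeating).
#' @param n_blocks Number of random rectangles for `"blocks"`.
#' @return `height x width` matrix of 0s and 1s.
#' @examples
#' generate_ground_truth_image(2, 2, "checker")
#' @export
generate_ground_truth_image <- function(height, width,
                                        pattern = c("blocks", "stripes",
                                                    "checker"),
                                        seed = 1, period = 4, n_blocks = 6) {
  pattern <- match.arg(pattern)
  if (height < 1L || width < 1L) abort("dimensions must be positive.")
  img <- matrix(0, nrow = height, ncol = width)
  if (pattern == "checker") {
    img <- outer(seq_len(height), seq_len(width), function(r, c) (r + c) %% 2)
  } else if (pattern == "stripes") {
    if (period < 2L) abort("`period` must be at least 2.")
    half <- period / 2
    on <- ((seq_len(width) - 1) %/% half) %% 2 == 1
    img[, on] <- 1
  } else {
    img <- withr::with_seed(seed, {
      for (b in seq_len(n_blocks)) {
        bh <- sample(seq_len(max(1, height %/% 3)), 1)
        bw <- sample(seq_len(max(1, width %/% 3)), 1)
        r0 <- sample(seq_len(max(1, height - bh + 1)), 1)
        c0 <- sample(seq_len(max(1, width - bw + 1)), 1)
        img[r0:(r0 + bh - 1), c0:(c0 + bw - 1)] <- 1
      }
      img
    })
  }
  storage.mode(img) <- "double"
  img
}
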