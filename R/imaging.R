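# Replicate-image demonstration: noised copies of a binary ground truth,
# compared under mean smoothing versus per-pixel p-value scaling.
# Images are plain numeric matrices (row = y, column = x, 1-based as usual
# in R); a stack holds its replicates as an H x W x n array.

#' Build an image stack
#'
#' @param replicates `H x W x n` numeric array of replicate images.
#' @param ground_truth `H x W` reference matrix (the hypothetical mean at
#'   each pixel).
#' @return An `image_stack` object (list with `replicates`,
#'   `ground_truth`, `n`).
#' @export
image_stack <- function(replicates, ground_truth) {
  if (!is.array(replicates) || length(dim(replicates)) != 3L) {
    abort("`replicates` must be an H x W x n array.")
  }
  if (!is.matrix(ground_truth) ||
      !identical(dim(replicates)[1:2], dim(ground_truth))) {
    abort("`ground_truth` must be a matrix matching the replicate shape.")
  }
  n <- dim(replicates)[3]
  if (n < 2L) abort("an image stack needs at least 2 replicates.")
  structure(
    list(replicates = replicates, ground_truth = ground_truth, n = n),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$replicates)
  cat(sprintf("Image stack: %d replicates of %d x %d pixels\n",
              d[3], d[1], d[2]))
  invisible(x)
}

#' Simulate noised replicates of a ground-truth image
#'
#' Adds independent Gaussian noise (standard normal by default) to every
#' pixel of the ground truth, once per replicate — the image analogue of
#' per-feature biological variability across donors.
#'
#' @param ground_truth Numeric matrix (typically binary 0/1).
#' @param n Number of replicates, `>= 2`.
#' @param seed Integer seed; the same seed reproduces the same stack.
#' @param noise_sd Noise standard deviation; default 1 (standard normal).
#' @return An [image_stack()].
#' @examples
#' gt <- generate_ground_truth_image(8, 8, "checker")
#' stack <- simulate_stack(gt, n = 5, seed = 1)
#' @export
simulate_stack <- function(ground_truth, n, seed, noise_sd = 1) {
  if (!is.matrix(ground_truth) || !is.numeric(ground_truth)) {
    abort("`ground_truth` must be a numeric matrix.")
  }
  if (n < 2L) abort("`n` must be at least 2.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  h <- nrow(ground_truth); w <- ncol(ground_truth)
  reps <- withr::with_seed(seed, {
    noise <- if (noise_sd == 0) 0 else rnorm(h * w * n, sd = noise_sd)
    array(rep(ground_truth, n) + noise, dim = c(h, w, n))
  })
  image_stack(reps, ground_truth)
}

#' Draw a small-n subset from a larger stack
#'
#' Seeded sampling of `k` replicates without replacement, emulating a
#' low-replicate study drawn from a large population.
#'
#' @param stack An [image_stack()].
#' @param k Number of replicates to keep, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return An [image_stack()] with `k` replicates.
#' @export
subsample_stack <- function(stack, k, seed) {
  stopifnot(inherits(stack, "image_stack"))
  if (k < 2L || k > stack$n) abort("`k` must lie in [2, n].")
  idx <- withr::with_seed(seed, sample(stack$n, k))
  image_stack(stack$replicates[, , idx, drop = FALSE], stack$ground_truth)
}

#' Pixel-wise mean of a stack
#'
#' @param stack An [image_stack()].
#' @return `H x W` matrix of per-pixel replicate means.
#' @export
mean_image <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$replicates, c(1, 2), mean)
}

#' Pixel-wise scaling of a stack toward its ground truth
#'
#' At each pixel the replicate values are tested against the ground-truth
#' value with a one-sample t-test, and the replicate mean is scaled toward
#' the ground truth by `F^(-p)`. Pixels with zero replicate variance
#' follow the degenerate-variance convention of [one_sample_t_pvalue()]:
#' a consistent deviation is preserved (`p = 0`), perfect agreement maps
#' to the ground truth (`p = 1`).
#'
#' @param stack An [image_stack()].
#' @param penalty Penalty factor `F`; default 20.
#' @return `H x W` matrix of scaled values. Each pixel lies on the
#'   segment between the ground truth and the replicate mean.
#' @export
percept_image <- function(stack, penalty = 20) {
  stopifnot(inherits(stack, "image_stack"))
  check_penalty(penalty)
  n <- stack$n
  m <- apply(stack$replicates, c(1, 2), mean)
  s2 <- apply(stack$replicates, c(1, 2), stats::var)
  gt <- stack$ground_truth
  tstat <- (m - gt) / sqrt(s2 / n)
  p <- 2 * pt(-abs(tstat), df = n - 1)
  zero_var <- s2 == 0
  p[zero_var] <- ifelse(m[zero_var] == gt[zero_var], 1, 0)
  gt + (m - gt) * exp(-p * log(penalty))
}

#' Line scan across one image row
#'
#' Extracts, for every column of a chosen row, the ground-truth value,
#' the replicate mean, the scaled value, and the empirical 95% range of
#' the replicate values (2.5th to 97.5th percentile), for plotting the
#' classic profile comparison: where replicates vary wildly the scaled
#' trace hugs the ground truth; where they deviate consistently, mean and
#' scaled traces agree.
#'
#' @param stack An [image_stack()].
#' @param scaled `H x W` matrix of scaled values (from [percept_image()]).
#' @param row Row index, 1-based.
#' @return Tibble of class `percept_line_scan` with columns `column`,
#'   `ground_truth`, `mean`, `scaled`, `noise_ci_low`, `noise_ci_high`.
#' @export
line_scan <- function(stack, scaled, row) {
  stopifnot(inherits(stack, "image_stack"))
  h <- nrow(stack$ground_truth)
  if (row < 1L || row > h) abort(sprintf("`row` must lie in [1, %d].", h))
  vals <- stack$replicates[row, , , drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)  # W == 1
  ci <- apply(vals, 1, quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  out <- tibble::tibble(
    column = seq_len(ncol(stack$ground_truth)),
    ground_truth = stack$ground_truth[row, ],
    mean = rowMeans(vals),
    scaled = scaled[row, ],
    noise_ci_low = ci[1, ],
    noise_ci_high = ci[2, ]
  )
  class(out) <- c("percept_line_scan", class(out))
  out
}

#' Write / read an image as a delimited numeric grid
#'
#' Plain TSV grids, one row per image row — portable, diff-able, and
#' sufficient for the demonstration-scale images this module handles.
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @return `read_image_tsv()` returns a numeric matrix; `write_image_tsv()`
#'   returns `path` invisibly.
#' @export
write_image_tsv <- function(image, path) {
  stopifnot(is.matrix(image))
  utils::write.table(image, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}
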