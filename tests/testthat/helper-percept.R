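# Shared fixtures, built in code.

# closed-form Student-t CDF for tiny degrees of freedom, used as an
# independent oracle for the t-test p-value
t_cdf_df1 <- function(t) 0.5 + atan(t) / pi
t_cdf_df2 <- function(t) 0.5 + t / (2 * sqrt(2 + t^2))

# small intensity-space cohort table in long form
toy_cohort <- function() {
  tibble::tibble(
    feature_id = rep(c("P1", "P2"), each = 5),
    sample_id = rep(c("c1", "c2", "c3", "d1", "d2"), 2),
    group = rep(c("control", "control", "control", "case", "case"), 2),
    value = c(
      8, 12, 10, 15, 5,    # P1: control mean 10
      10, 10, 10, 20, 10   # P2: control mean 10
    )
  )
}

# long per-donor log2-ratio table from a matrix
ratios_long <- function(mat) {
  tibble::tibble(
    feature_id = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    log2_ratio = as.vector(mat)
  )
}
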