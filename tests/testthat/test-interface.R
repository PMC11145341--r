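# Tabular I/O, the end-to-end scale workflow, and the CLI dispatcher.

write_toy_wide <- function(path, delim = "\t") {
  wide <- tibble::tibble(
    protein = c("P1", "P2", "P3"),
    d1 = c(1.0, 0.2, -0.5),
    d2 = c(1.2, -0.1, -0.4),
    d3 = c(0.8, 0.05, -0.6)
  )
  if (delim == ",") readr::write_csv(wide, path) else readr::write_tsv(wide, path)
  wide
}

test_that("feature tables round-trip through delimited text", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_toy_wide(tsv, "\t")
  write_toy_wide(csv, ",")
  a <- read_feature_table(tsv)
  b <- read_feature_table(csv)
  expect_equal(a, b)  # dialects parse identically
  expect_equal(names(a), c("feature_id", "sample_id", "group", "value"))
  expect_equal(nrow(a), 9)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(a, out)
  expect_equal(read_feature_table(out), a)
})

test_that("non-numeric cells become NA with a warning, shape preserved", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "P1\t1.5\toops", "P2\t2\t3"), path)
  expect_warning(tbl <- read_feature_table(path), "1 non-numeric")
  expect_equal(nrow(tbl), 4)
  expect_equal(sum(is.na(tbl$value)), 1)
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1", "P1\t1", "P1\t2"), dup)
  expect_error(read_feature_table(dup), "duplicate")
})

test_that("group labels attach from a named vector or a sidecar file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_wide(path)
  tbl <- read_feature_table(path, groups = c(d1 = "control", d2 = "control",
                                             d3 = "case"))
  expect_equal(unique(tbl$group[tbl$sample_id == "d3"]), "case")
  sidecar <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "d1\tcontrol", "d2\tcontrol", "d3\tcase"),
             sidecar)
  tbl2 <- read_feature_table(path, groups = sidecar)
  expect_equal(tbl, tbl2)
})

test_that("the scale workflow runs end to end and is reproducible", {
  cohort <- generate_cohort(n_features = 300, n_control = 10, n_case = 6,
                            affected_fraction = 0, noise_sd_log2 = 0.4,
                            seed = 17)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- run_scale_workflow(cohort$data, out_dir = out1,
                            value_space = "intensity", penalty = 20,
                            seed = 5)
  run_scale_workflow(cohort$data, out_dir = out2,
                     value_space = "intensity", penalty = 20, seed = 5)
  # identical config and seed: byte-identical outputs
  expect_identical(readLines(file.path(out1, "scaled.tsv")),
                   readLines(file.path(out2, "scaled.tsv")))
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
  expect_true(all(c("feature_id", "n", "m1", "p", "s", "V", "category") %in%
                    names(res$result)))
  expect_equal(nrow(res$result), 300)
  # summary counts add up and thresholds came from the pseudo-controls
  expect_equal(sum(unlist(res$summary$category_counts)), 300)
  expect_lt(res$summary$thresholds$lower, 0)
  expect_gt(res$summary$thresholds$upper, 0)
})

test_that("auto penalty resolves to 10 x n and is recorded in the summary", {
  mat <- matrix(rnorm(30), nrow = 10,
                dimnames = list(sprintf("P%02d", 1:10), paste0("d", 1:3)))
  tbl <- ratios_long(mat) |>
    dplyr::rename(value = log2_ratio)
  res <- run_scale_workflow(tbl, out_dir = NULL, value_space = "log2_ratio",
                            penalty = "auto", seed = 1)
  expect_equal(res$summary$penalty, "auto")
  expect_equal(res$summary$resolved_penalty, 30)
  expect_equal(res$result$s, 30^(-res$result$p), tolerance = 1e-12)
})

test_that("a null table of log2 ratios is significant at the nominal rate", {
  # iid N(0, sd) per-donor effects: the one-sample t-test holds its level,
  # so about 5% of features clear alpha = 0.05 (binomial tolerance)
  withr::with_seed(29, {
    mat <- matrix(rnorm(400 * 6, sd = 0.4), nrow = 400,
                  dimnames = list(sprintf("P%03d", 1:400), paste0("d", 1:6)))
  })
  tbl <- ratios_long(mat) |> dplyr::rename(value = log2_ratio)
  res <- run_scale_workflow(tbl, value_space = "log2_ratio", penalty = 20)
  sig <- mean(res$result$p < 0.05, na.rm = TRUE)
  expect_lt(abs(sig - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("log2-ratio workflow falls back to percentile thresholds", {
  withr::with_seed(23, {
    mat <- matrix(rnorm(200 * 5, sd = 0.5), nrow = 200,
                  dimnames = list(sprintf("P%03d", 1:200), paste0("d", 1:5)))
  })
  tbl <- ratios_long(mat) |> dplyr::rename(value = log2_ratio)
  res <- run_scale_workflow(tbl, value_space = "log2_ratio", penalty = 20)
  th <- res$thresholds
  q <- quantile(res$result$m1, c(0.05, 0.95), names = FALSE)
  expect_equal(th$lower, q[1])
  expect_equal(th$upper, q[2])
})

test_that("the CLI chains synth, scale and evaluate through real files", {
  dir <- withr::local_tempdir()
  table_path <- file.path(dir, "cohort.tsv")
  percept_cli(c("synth-cohort", "--features", "60", "--control", "6",
                "--case", "5", "--seed", "3", "--out", table_path))
  expect_true(file.exists(table_path))
  expect_true(file.exists(file.path(dir, "cohort_truth.tsv")))

  out <- file.path(dir, "scaled")
  percept_cli(c("scale", "--table", table_path,
                "--groups", file.path(dir, "cohort_groups.tsv"),
                "--space", "intensity", "--penalty", "20",
                "--seed", "2", "--out", out))
  scaled <- readr::read_tsv(file.path(out, "scaled.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(scaled), 60)
  summary <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(summary$n_features, 60)

  img <- file.path(dir, "img")
  percept_cli(c("simulate-image", "--height", "12", "--width", "12",
                "--n", "5", "--seed", "1", "--out", img))
  expect_true(file.exists(file.path(img, "scaled.tsv")))
  scan <- readr::read_tsv(file.path(img, "line_scan.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(scan), 12)

  expect_output(percept_cli(character(0)), "usage: percept")
  expect_equal(percept_cli("no-such-command"), 2L)
})
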