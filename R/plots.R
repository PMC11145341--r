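# Convenience plots. These are deliberately plain ggplot2 objects the
# caller can restyle; no figure-replication ambitions.

#' Volcano plot of scaled features
#'
#' Effect size against -log10(p), coloured by volcano category, with the
#' effect thresholds and the significance level drawn as dashed lines.
#'
#' @param data Per-feature tibble with columns `m1`, `p` and (optionally)
#'   `category`, e.g. the `result` of [run_scale_workflow()] or
#'   [percept_table()] plus [categorize_features()].
#' @param thresholds An [effect_thresholds()] object.
#' @return A ggplot object.
#' @export
plot_volcano <- function(data, thresholds) {
  require_columns(data, c("m1", "p"))
  if (!"category" %in% names(data)) {
    data$category <- categorize_features(data$m1, data$p, thresholds)
  }
  ggplot2::ggplot(
    dplyr::filter(data, is.finite(.data$m1), is.finite(.data$p)),
    ggplot2::aes(x = .data$m1, y = -log10(pmax(.data$p, 1e-300)),
                 colour = .data$category)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(thresholds$lower, thresholds$upper),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      "S/A" = "black", "NS/A" = "grey30", "NS/NA" = "grey70",
      "S/NA" = "steelblue"
    ), drop = FALSE) +
    ggplot2::labs(x = "effect size (mean log2 ratio)",
                  y = expression(-log[10](italic(p))),
                  colour = NULL)
}

#' Line-scan profile plot
#'
#' Ground truth, replicate mean and scaled value along one image row,
#' with the empirical 95% replicate range as a grey ribbon.
#'
#' @param object A `percept_line_scan` tibble from [line_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot percept_line_scan
#' @export
autoplot.percept_line_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$noise_ci_low,
                                      ymax = .data$noise_ci_high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ground_truth,
                                    linetype = "ground truth")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean, colour = "mean")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$scaled, colour = "scaled")) +
    ggplot2::scale_linetype_manual(values = c("ground truth" = "dotted")) +
    ggplot2::scale_colour_manual(values = c(mean = "goldenrod",
                                            scaled = "magenta3")) +
    ggplot2::labs(x = "column", y = "value", colour = NULL, linetype = NULL)
}

#' Mean cumulative-distribution bands across trials
#'
#' Interpolates each trial's values onto the fixed CDF grid with
#' [interpolate_cdf()] and draws the across-trial mean with a +/- 1 SD
#' ribbon, one band per measure.
#'
#' @param trials A `percept_trials` tibble from [subsample_donors()].
#' @param increments CDF grid size; default 101.
#' @return A ggplot object comparing raw, scaled and population CDFs.
#' @export
plot_cdf_bands <- function(trials, increments = 101) {
  stopifnot(inherits(trials, "percept_trials"))
  population <- attr(trials, "population")
  band <- function(col, label) {
    purrr::imap(trials[[col]], function(v, i) {
      dplyr::mutate(interpolate_cdf(v, increments), trial = i)
    }) |>
      dplyr::bind_rows() |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       .by = "position") |>
      dplyr::mutate(measure = label)
  }
  bands <- dplyr::bind_rows(band("raw_means", "raw"),
                            band("scaled_values", "scaled"))
  pop <- dplyr::mutate(interpolate_cdf(population, increments),
                       measure = "population")
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$mean, y = .data$position,
                                      colour = .data$measure)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$mean - .data$sd,
                                      xmax = .data$mean + .data$sd,
                                      fill = .data$measure),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = pop,
                       ggplot2::aes(x = .data$value, y = .data$position)) +
    ggplot2::labs(x = "log2 ratio", y = "cumulative fraction",
                  colour = NULL, fill = NULL)
}
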