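# ggplot2 visualisations for the main result types.

#' @describeIn ld_profile Plot the two- and three-locus LD refinement
#'   scores against the distance bins (log-scaled x axis).
#' @param object,x An `ld_profile`.
#' @param ... Unused.
#' @export
autoplot.ld_profile <- function(object, ...) {
  df <- object$profile %>%
    mutate(mid = ifelse(is.finite(.data$hi), (.data$lo + .data$hi) / 2,
                        .data$lo * 2)) %>%
    tidyr::pivot_longer(c("score2", "score3"), names_to = "model",
                        values_to = "score") %>%
    mutate(model = dplyr::recode(.data$model, score2 = "two-locus",
                                 score3 = "three-locus")) %>%
    filter(!is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$score,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "physical distance (bp)",
                  y = "LD refinement score (1 - cosegregating fraction)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.ld_profile <- function(x, ...) print(autoplot(x, ...))

#' Histogram of LD refinement scores by somatic classification
#'
#' @param calls Output of [classify_somatic()].
#' @param threshold Classification threshold drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_ps_distribution <- function(calls, threshold = 0.25) {
  df <- as_tibble(calls) %>% filter(!is.na(.data$p_s))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_s, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 25, boundary = 0,
                            position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::xlim(-0.01, 0.51) +
    ggplot2::labs(x = expression(p[s]), y = "SNVs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn procrustes_project Scatter of reference PCA coordinates with
#'   the projected study sample(s) overlaid as crosses.
#' @param object,x An `ancestry_projection`.
#' @param ... Unused.
#' @export
autoplot.ancestry_projection <- function(object, ...) {
  ref <- as_tibble(object$Y_ref[, 1:2, drop = FALSE],
                   .name_repair = ~ c("PC1", "PC2"))
  prj <- as_tibble(object$y[, 1:2, drop = FALSE],
                   .name_repair = ~ c("PC1", "PC2"))
  ggplot2::ggplot(ref, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(colour = "grey55", size = 1.5) +
    ggplot2::geom_point(data = prj, shape = 4, size = 3, stroke = 1.5,
                        colour = "black") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' @export
plot.ancestry_projection <- function(x, ...) print(autoplot(x, ...))

#' @describeIn fit_error_model Per-category BAF thresholds of the
#'   sequencing-error model.
#' @param object,x A `snv_error_model`.
#' @param ... Unused.
#' @export
autoplot.snv_error_model <- function(object, ...) {
  df <- object$thresholds
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$threshold,
                                   fill = .data$from_fallback)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "grey70"),
                               labels = c(`FALSE` = "fitted",
                                          `TRUE` = "fallback"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "BAF threshold (median)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
plot.snv_error_model <- function(x, ...) print(autoplot(x, ...))
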