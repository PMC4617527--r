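#' Bar plot of one or more mutation spectra
#'
#' @param ... Named `mut_spectrum` objects (names become group labels).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(...) {
  spectra <- list(...)
  if (is.null(names(spectra)) || any(names(spectra) == "")) {
    names(spectra) <- paste0("group", seq_along(spectra))
  }
  df <- imap(spectra, ~ mutate(as_tibble(.x), group_label = .y)) |>
    list_rbind() |>
    mutate(class = factor(.data$class, levels = MUTATION_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$proportion,
                                   fill = .data$group_label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Proportion of independent mutations",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.mut_spectrum <- function(object, ...) plot_spectrum(spectrum = object)

#' Positional distribution of calls along the gene
#'
#' Mirrors the classic mutation-distribution plot: per-position independent
#' mutation counts, one group on the positive y-axis and (optionally) a second
#' on the negative axis.
#'
#' @param calls Annotated call tibble with `sample_id`, `position`, `kind`.
#' @param groups Optional named list mapping group label to sample ids; with
#'   two groups the second is drawn downward.
#' @param kinds Event kinds to include (default substitutions).
#' @return A ggplot object.
#' @export
plot_positions <- function(calls, groups = NULL, kinds = "sub") {
  calls <- filter(calls, .data$kind %in% kinds)
  if (is.null(groups)) groups <- list(all = unique(calls$sample_id))
  df <- imap(groups, function(ids, label) {
    calls |>
      filter(.data$sample_id %in% ids) |>
      distinct(.data$sample_id, .data$position, .data$kind, .data$detail) |>
      count(.data$position, name = "n_independent") |>
      mutate(group_label = label)
  }) |> list_rbind()
  if (length(groups) == 2) {
    second <- names(groups)[2]
    df <- mutate(df, n_independent = ifelse(.data$group_label == second,
                                            -.data$n_independent,
                                            .data$n_independent))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$n_independent,
                                   colour = .data$group_label)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Position (bp)", y = "Independent mutations",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Observed vs expected calibration plot with the fitted LOD/linear model
#'
#' @param points Calibration points (`expected`, `observed`).
#' @param model A `clonality_model`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(points, model) {
  ggplot2::ggplot(as_tibble(points),
                  ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                         linetype = 2) +
    ggplot2::geom_abline(slope = model$slope, intercept = model$intercept) +
    ggplot2::geom_hline(yintercept = model$lod, colour = "blue") +
    ggplot2::labs(x = "Expected count", y = "Observed count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
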