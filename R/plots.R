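#' Scatter panels of one simulation replicate
#'
#' Plots the three pairwise scatterplots of a single replicate run with
#' `keep_data = TRUE` — phenotype vs genotypic value, prediction vs
#' phenotype, prediction vs genotypic value — each panel annotated with the
#' Pearson r and Spearman rho of the draw.
#'
#' @param object A one-row replicate tibble from
#'   [run_replicate()] called with `keep_data = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.replicate_run <- function(object, ...) {
  data <- attr(object, "data")
  if (is.null(data)) stop("run the replicate with `keep_data = TRUE`", call. = FALSE)
  panels <- list(c("g", "p"), c("p", "y"), c("g", "y"))
  labels <- c("p vs g", "y vs p", "y vs g")
  long <- purrr::map2_dfr(panels, labels, function(v, lab) {
    if (anyNA(data[[v[2]]])) return(NULL)
    tibble::tibble(panel = lab, x = data[[v[1]]], yval = data[[v[2]]])
  })
  ann <- dplyr::summarise(
    dplyr::group_by(long, .data$panel),
    label = sprintf("r = %.2f, ρ = %.2f",
                    stats::cor(.data$x, .data$yval),
                    stats::cor(.data$x, .data$yval, method = "spearman")),
    x = min(.data$x), yval = max(.data$yval), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$yval)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$label),
                       hjust = 0, vjust = 1, size = 3) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' Correlation summary plot of a scenario
#'
#' Distribution of the per-replicate Pearson correlations of a
#' `scenario_result`, with the Monte-Carlo mean marked.
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_result <- function(object, ...) {
  long <- dplyr::filter(tidy(object), .data$method == "pearson",
                        !.data$flagged, !is.na(.data$correlation))
  means <- dplyr::summarise(dplyr::group_by(long, .data$pair),
                            m = mean(.data$correlation), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$pair, .data$correlation)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_point(data = means, ggplot2::aes(y = .data$m),
                        colour = "red", size = 2) +
    ggplot2::labs(x = NULL, y = "Pearson correlation") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_bw()
}

#' Compare mean correlations across a scenario table
#'
#' Dot plot of the mean correlations r(p, g), r(y, p), r(y, g) by scenario
#' row from a [run_table1()] report.
#'
#' @param table Report tibble from [run_table1()].
#' @return A ggplot.
#' @export
plot_table1 <- function(table) {
  long <- tidyr::pivot_longer(table,
                              cols = dplyr::any_of(c("mean_r_pg", "mean_r_yp", "mean_r_yg")),
                              names_to = "pair", values_to = "mean_r")
  long <- dplyr::mutate(long, pair = sub("mean_r_", "r(", .data$pair),
                        pair = paste0(sub("(.)(.)$", "\\1,\\2", .data$pair), ")"))
  ggplot2::ggplot(long, ggplot2::aes(.data$row, .data$mean_r,
                                     colour = .data$pair, shape = .data$pair)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "scenario row", y = "mean correlation", colour = NULL,
                  shape = NULL) +
    ggplot2::theme_bw()
}
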