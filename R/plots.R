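#' Silhouette plot of a generalized silhouette table
#'
#' The classic silhouette bar display: objects sorted by decreasing `s`
#' within each cluster, bar length `s(i)`, clusters in separate panels.
#' Objects with negative widths (the "misclassified" objects of the
#' misclassification rate) fall left of the zero line.
#'
#' @param object A `gen_silhouette` table.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gen_silhouette <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::arrange(cluster, dplyr::desc(s)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$s,
    fill = factor(.data$cluster)
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = NULL, y = "silhouette width s(i)", fill = "cluster",
      title = sprintf(
        "Generalized silhouette (p = %s): MSW = %.3f, MR = %.3f",
        format_p(attr(object, "p")), mean(object$s), mean(object$s < 0)
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid.major.y = ggplot2::element_blank()
    )
}

#' Point-pattern map of a sweep with misclassified objects circled
#'
#' Scatter of the 2-D pattern, one panel per exponent, points coloured by
#' cluster and objects with negative silhouette width circled.
#'
#' @param object A `gensil_sweep` from [archetype_sweep()] or [iris_sweep()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gensil_sweep <- function(object, ...) {
  coord_names <- setdiff(names(object$data), "cluster")[1:2]
  pts <- tibble::as_tibble(object$data)
  pts$object <- as.character(seq_len(nrow(pts)))
  long <- dplyr::left_join(object$objects, pts, by = "object", suffix = c("", ".pt"))
  long$p_label <- factor(format_p(long$p), levels = unique(format_p(long$p)))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data[[coord_names[1]]], y = .data[[coord_names[2]]],
    colour = factor(.data$cluster)
  )) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_point(
      data = function(d) d[d$s < 0, , drop = FALSE],
      shape = 1, size = 2.6, colour = "black", stroke = 0.4
    ) +
    ggplot2::facet_wrap(~p_label) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      colour = "cluster",
      title = sprintf("'%s': misclassified objects circled, by p", object$pattern)
    ) +
    ggplot2::theme_minimal()
}

#' MSW and MR profiles across the exponent grid
#'
#' Plots mean silhouette width and misclassification rate against `p` for a
#' profile tibble as returned by [silhouette_profile()] or found in the
#' `summary` element of a sweep. Infinite exponents are placed at the ends of
#' a categorical axis.
#'
#' @param profile A tibble with columns `p`, `msw`, `mr`.
#' @return A ggplot object.
#' @export
plot_msw_profile <- function(profile) {
  stopifnot(all(c("p", "msw", "mr") %in% names(profile)))
  df <- profile |>
    dplyr::mutate(p_label = factor(format_p(p), levels = format_p(sort(p)))) |>
    tidyr::pivot_longer(c("msw", "mr"), names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$p_label, y = .data$value,
    group = .data$index, colour = .data$index
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "power-mean exponent p", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Method-comparison curves: MSW against number of clusters
#'
#' One panel per exponent, one curve per linkage method, for a
#' `profile_grid` from [method_comparison()].
#'
#' @param grid A `profile_grid` tibble.
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(grid) {
  stopifnot(all(c("method", "k", "p", "msw") %in% names(grid)))
  df <- tibble::as_tibble(grid)
  df$p_label <- factor(format_p(df$p), levels = format_p(sort(unique(df$p))))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$k, y = .data$msw, colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~p_label, scales = "free_y") +
    ggplot2::labs(
      x = "number of clusters k", y = "mean silhouette width",
      colour = "linkage"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
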