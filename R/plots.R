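# ggplot2 visualisations: stick spectra, mirror comparisons, and
# molecular-network layouts.

#' Stick plot of a spectrum
#'
#' @param object An [ms_spectrum()].
#' @param label_top Label the n most intense peaks with their m/z.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_spectrum <- function(object, label_top = 5, ...) {
  pk <- object$peaks
  lab <- pk |> arrange(dplyr::desc(.data$intensity)) |> utils::head(label_top)
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::geom_text(
      data = lab, ggplot2::aes(label = sprintf("%.4f", .data$mz)),
      vjust = -0.4, size = 2.8
    ) +
    ggplot2::labs(
      x = "m/z", y = "intensity",
      title = object$id,
      subtitle = sprintf("precursor m/z %.4f (%d-)", object$precursor_mz,
                         object$charge)
    ) +
    ggplot2::theme_minimal()
}

#' Mirror plot of a query against a library spectrum
#'
#' Query peaks point up, library peaks down; useful for inspecting
#' [library_search()] hits.
#'
#' @param query,record [ms_spectrum()] objects.
#' @return A ggplot.
#' @export
plot_mirror <- function(query, record) {
  df <- dplyr::bind_rows(
    query$peaks |> mutate(which = "query",
                          y = .data$intensity / max(.data$intensity)),
    record$peaks |> mutate(which = "library",
                           y = -.data$intensity / max(.data$intensity))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$y, colour = .data$which)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "relative intensity",
                  title = sprintf("%s vs %s", query$id, record$id)) +
    ggplot2::theme_minimal()
}

#' Plot a molecular network
#'
#' Fruchterman-Reingold layout with nodes coloured by connected
#' component.
#'
#' @param object A `saponin_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saponin_network <- function(object, ...) {
  set.seed(1)  # layout only
  xy <- igraph::layout_with_fr(object$graph)
  nodes <- object$nodes |> mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    dplyr::left_join(nodes |> select("id", "x", "y"),
                     by = c(source = "id")) |>
    dplyr::left_join(nodes |> select("id", xend = "x", yend = "y"),
                     by = c(target = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$cosine),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = factor(.data$component)),
      size = 2, show.legend = FALSE
    ) +
    ggplot2::theme_void()
}

#' Annotated theoretical-spectrum plot
#'
#' Sticks at the theoretical fragment m/z, coloured by ion type.
#'
#' @param fragments Tibble from [theoretical_spectrum()].
#' @return A ggplot.
#' @export
plot_fragments <- function(fragments) {
  ggplot2::ggplot(fragments,
                  ggplot2::aes(x = .data$mz, y = 1, colour = .data$ion_type)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z", y = NULL, colour = "ion type") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::theme_minimal()
}
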