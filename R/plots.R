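#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_tile geom_vline labs theme_minimal scale_fill_viridis_c
#'   facet_wrap geom_errorbar position_dodge
#' @export
ggplot2::autoplot

#' Plot the ranked alignment-score curve
#'
#' Cumulative alignment scores in descending order; a useful visual check of
#' the knee used for gene selection.
#'
#' @param object A `tm_alignment_scores`.
#' @param selected Optional character vector of selected genes; a vertical
#'   line marks the selection boundary.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tm_alignment_scores <- function(object, selected = NULL, ...) {
  dat <- tibble::tibble(rank = seq_len(nrow(object)),
                        R = sort(object$R, decreasing = TRUE))
  p <- ggplot(dat, aes(x = .data$rank, y = .data$R)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "gene rank", y = "cumulative alignment score R") +
    theme_minimal()
  if (!is.null(selected)) {
    p <- p + geom_vline(xintercept = length(selected) + 0.5,
                        linetype = "dashed")
  }
  p
}

#' Heatmap of a transport plan
#'
#' @param object A `tm_transport_plan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tm_transport_plan <- function(object, ...) {
  g <- object$gamma
  dat <- tidyr::expand_grid(i = seq_len(nrow(g)), j = seq_len(ncol(g)))
  dat$mass <- as.vector(t(g))[(dat$i - 1) * ncol(g) + dat$j]
  ggplot(dat, aes(x = .data$j, y = .data$i, fill = .data$mass)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "target gene", y = "source gene", fill = "mass") +
    theme_minimal()
}

#' Bar chart of classifier metrics with run-to-run spread
#'
#' @param object A `tm_metrics`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tm_metrics <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$metric, y = .data$mean)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    labs(x = NULL, y = "score (mean over runs)") +
    theme_minimal()
}

#' Per-state dynamic-score trajectories of ranked components
#'
#' @param object A `tm_component_report` tibble (e.g. from
#'   [tm_select_dnb()]).
#' @param ... Unused.
#' @return A ggplot of D(t) per component across states.
#' @export
autoplot.tm_component_report <- function(object, ...) {
  dat <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    dplyr::mutate(object$per_state[[i]],
                  component = sprintf("rank %d (DNI %.3f)", object$rank[i],
                                      object$dni[i]))
  })
  ggplot(dat, aes(x = .data$state, y = .data$d, color = .data$component)) +
    geom_line() + geom_point() +
    labs(x = "disease state", y = "dynamic score D(t)", color = NULL) +
    theme_minimal()
}
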