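#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-gene results of a pipeline run
#'
#' One row per gene with its per-transition and cumulative alignment
#' scores, selection status, component membership and DNB flag.
#'
#' @param x A `tm_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tm_run <- function(x, ...) {
  comp <- dplyr::select(x$components, "gene", "component")
  out <- dplyr::left_join(tibble::as_tibble(x$scores), comp, by = "gene")
  dplyr::mutate(out,
                selected = .data$gene %in% x$selected,
                is_dnb = .data$gene %in% x$dnb_genes) |>
    dplyr::arrange(dplyr::desc(.data$R))
}

#' One-row summary of a pipeline run
#'
#' @param x A `tm_run`.
#' @param ... Unused.
#' @return A one-row tibble with network sizes, selection counts, the DNB
#'   module's DNI, and (when classification ran) mean test accuracy.
#' @export
glance.tm_run <- function(x, ...) {
  acc <- NA_real_
  if (!is.null(x$metrics)) {
    acc <- x$metrics$summary$mean[x$metrics$summary$metric == "accuracy"]
  }
  tibble::tibble(
    n_states = length(x$graphs),
    n_genes = length(x$graphs[[1]]$nodes),
    n_selected = length(x$selected),
    n_components = nrow(x$reports),
    n_dnb = length(x$dnb_genes),
    dni = x$reports$dni[1],
    accuracy = acc
  )
}

#' Tidy per-run classifier metrics
#'
#' @param x A `tm_metrics`.
#' @param ... Unused.
#' @return A long tibble with `run`, `metric`, `value`.
#' @export
tidy.tm_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$runs, -"run", names_to = "metric",
                      values_to = "value")
}

#' One-row metric summary
#'
#' @param x A `tm_metrics`.
#' @param ... Unused.
#' @return A one-row tibble with the mean of each metric over runs.
#' @export
glance.tm_metrics <- function(x, ...) {
  tidyr::pivot_wider(x$summary[c("metric", "mean")], names_from = "metric",
                     values_from = "mean")
}
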