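#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a connectivity map as slice heatmaps
#'
#' One tile panel per axial slice; out-of-mask voxels are blank.
#'
#' @param object A [connectivity_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.connectivity_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s connectivity (%s), subject %s",
                      object$seed_name, object$metric, object$subject_id),
      fill = object$metric
    ) +
    ggplot2::theme_minimal()
}

#' Plot a group comparison: t-map slices with surviving clusters outlined
#'
#' @param object An `fc_group_comparison` from [cluster_correct_fwe()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_group_comparison <- function(object, ...) {
  idx <- which(object$mask, arr.ind = TRUE)
  df <- tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                       t = object$t_map[object$mask])
  surv <- object$clusters[object$clusters$surviving, , drop = FALSE]
  sdf <- if (nrow(surv) > 0) {
    vox <- unlist(surv$voxels)
    co <- arrayInd(vox, dim(object$t_map))
    tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3])
  } else {
    tibble::tibble(x = integer(), y = integer(), z = integer())
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$t)) +
    ggplot2::geom_tile(data = sdf, fill = NA, colour = "black",
                       linewidth = 0.4) +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("group t-map (df = %d), |t| > %.2f, outlined = FWE p <= %.2f",
                      object$df, object$cluster_threshold_t, object$alpha),
      fill = "t"
    ) +
    ggplot2::theme_minimal()
}

#' Plot enrichment-decoding results
#'
#' Bar chart of `-log10(q)` per annotation set, faceted by selection mode,
#' with the FDR threshold marked.
#'
#' @param results Tibble from [decode_pair()].
#' @param alpha_fdr FDR reference line (default 0.05).
#' @return A ggplot.
#' @export
plot_enrichment <- function(results, alpha_fdr = 0.05) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = stats::reorder(.data$set_name, -.data$q_value),
                 y = -log10(.data$q_value))
  ) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = -log10(alpha_fdr), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = NULL, y = "-log10(FDR q)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
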