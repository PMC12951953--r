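#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a dynamic-feature-selection result
#'
#' @param x A `dfs_selection`.
#' @param ... Unused.
#' @return The accuracy trace as a tibble with `n`, `encoding`, `acc` and
#'   a logical `selected` column marking the optimal prefix.
#' @method tidy dfs_selection
#' @export
tidy.dfs_selection <- function(x, ...) {
  dplyr::mutate(x$trace, selected = .data$n <= x$n_star)
}

#' @rdname tidy.dfs_selection
#' @return For `glance`, a one-row summary tibble.
#' @method glance dfs_selection
#' @export
glance.dfs_selection <- function(x, ...) {
  tibble(species = x$species, model = x$model, n_star = x$n_star,
         acc_opt = x$acc_opt, n_candidates = nrow(x$trace))
}

#' Tidy a stacked ensemble: metalearner coefficients
#'
#' @param x A `stacked_4mc`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` for the elastic-net
#'   metalearner.
#' @method tidy stacked_4mc
#' @export
tidy.stacked_4mc <- function(x, ...) {
  co <- x$meta$coefficients
  tibble(term = rownames(co), estimate = as.vector(co))
}

#' @rdname tidy.stacked_4mc
#' @method glance stacked_4mc
#' @export
glance.stacked_4mc <- function(x, ...) {
  tibble(
    species = x$species,
    n_train = nrow(x$tier1_oof),
    base_models = paste(x$base_kinds, collapse = "+"),
    oof_stacking = x$oof,
    mean_base_cv_acc = if (length(x$fold_acc)) {
      mean(unlist(x$fold_acc))
    } else NA_real_
  )
}

#' Plot the incremental feature-selection trace
#'
#' @param object A `dfs_selection`.
#' @param ... Unused.
#' @return A ggplot: held-out accuracy versus number of fused encodings,
#'   with the selected prefix highlighted.
#' @method autoplot dfs_selection
#' @export
autoplot.dfs_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$acc)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 2) +
    ggplot2::geom_vline(xintercept = object$n_star, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$n, labels = df$encoding) +
    ggplot2::labs(
      x = "encodings fused (ranking order)", y = "mean held-out accuracy",
      title = sprintf("%s / %s: n* = %d", object$species, object$model,
                      object$n_star),
      color = "in F_opt") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a cross-species prediction grid
#'
#' @param grid Tibble from [cross_prediction_grid()].
#' @param metric Column to fill by ("AUC" or "ACC").
#' @return A ggplot tile map (source species as rows, targets as
#'   columns).
#' @export
plot_cross_prediction <- function(grid, metric = "AUC") {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$target, y = .data$source,
                                     fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[metric]])), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "target species", y = "source species") +
    ggplot2::theme_minimal()
}

#' Plot top enriched k-mers between two groups
#'
#' @param rows Tibble from [kmer_enrichment()].
#' @param top Number of k-mers per k, by absolute frequency difference.
#' @param alpha Significance threshold on the BH q-value.
#' @return A ggplot bar chart faceted by k.
#' @export
plot_enrichment <- function(rows, top = 10L, alpha = 0.05) {
  df <- rows |>
    dplyr::group_by(.data$k) |>
    dplyr::slice_max(abs(.data$freq_diff), n = top, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$kmer, .data$freq_diff),
    y = .data$freq_diff, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~k, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "frequency difference (group1 - group2)",
                  fill = sprintf("q < %.2g", alpha)) +
    ggplot2::theme_minimal()
}
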