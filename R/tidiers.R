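# broom-style tidiers and ggplot2 autoplot methods for the package's result
# types.

#' Tidy a Shapley feature ranking
#'
#' @param x A `cvf_ranking` from [shapley_rank()].
#' @param per_class Return the per-class top-10 contribution table instead of
#'   the global ranking.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.cvf_ranking <- function(x, per_class = FALSE, ...) {
  if (per_class) return(attr(x, "per_class"))
  tibble(feature = x$feature, importance = x$importance,
         rank = seq_len(nrow(x)))
}

#' Tidy per-class classification metrics
#'
#' @param x A `cvf_metrics` from [score_predictions()].
#' @param ... Unused.
#' @return Per-class tibble of precision/recall/F1/AUC/AUPR.
#' @exportS3Method generics::tidy
tidy.cvf_metrics <- function(x, ...) x$per_class

#' One-row summary of classification metrics
#'
#' @param x A `cvf_metrics`.
#' @param ... Unused.
#' @return One-row tibble of the macro aggregates.
#' @exportS3Method generics::glance
glance.cvf_metrics <- function(x, ...) {
  tibble(n = x$n, accuracy = x$accuracy, macro_f1 = x$macro_f1,
         precision = x$precision, recall = x$recall,
         macro_auc = x$macro_auc, macro_aupr = x$macro_aupr)
}

#' Tidy an average-treatment-effect result
#'
#' @param x A `cvf_ate` from [ate()].
#' @param level `"compound"` (default) or `"well"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.cvf_ate <- function(x, level = c("compound", "well"), ...) {
  level <- match.arg(level)
  if (level == "compound") x$compounds else x$wells
}

#' One-row summary of an ATE result
#'
#' @param x A `cvf_ate`.
#' @param ... Unused.
#' @return One-row tibble with compound counts per bucket and the ATE range.
#' @exportS3Method generics::glance
glance.cvf_ate <- function(x, ...) {
  tibble(n_compounds = nrow(x$compounds), n_wells = nrow(x$wells),
         n_strong = sum(x$compounds$bucket == "strong"),
         n_medium = sum(x$compounds$bucket == "medium"),
         n_weak = sum(x$compounds$bucket == "weak"),
         ate_min = min(x$compounds$ate), ate_max = max(x$compounds$ate))
}

#' Tidy a fitted fusion model's training log
#'
#' @param x A `cvf_fusion_model` or `cvf_mlp_model`.
#' @param ... Unused.
#' @return Per-epoch tibble of training loss and validation macro-F1.
#' @exportS3Method generics::tidy
tidy.cvf_fusion_model <- function(x, ...) x$log

#' @rdname tidy.cvf_fusion_model
#' @exportS3Method generics::tidy
tidy.cvf_mlp_model <- function(x, ...) x$log

#' Plot a Shapley feature ranking
#'
#' @param object A `cvf_ranking`.
#' @param top Number of features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cvf_ranking <- function(object, top = 20, ...) {
  df <- head(tidy(object), top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean |Shapley contribution|", y = NULL,
                  title = sprintf("Top %d features", nrow(df)))
}

#' Plot compound ATE values coloured by strength bucket
#'
#' @param object A `cvf_ate`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cvf_ate <- function(object, ...) {
  df <- object$compounds
  df$compound_id <- stats::reorder(df$compound_id, df$ate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ate, y = .data$compound_id,
                                   fill = .data$bucket)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Average treatment effect (mean z-score)", y = NULL,
                  fill = "Bucket")
}

#' Plot a five-channel image stack
#'
#' @param image A [image_stack()].
#' @param channels Channels to draw (default all five).
#' @return A ggplot with one facet per channel.
#' @export
plot_image_stack <- function(image, channels = CP_CHANNELS) {
  dfs <- purrr::map_dfr(channels, function(ch) {
    m <- image$pixels[ch, , ]
    tibble(channel = ch,
           x = rep(seq_len(nrow(m)), ncol(m)),
           y = rep(seq_len(ncol(m)), each = nrow(m)),
           value = as.vector(m))
  })
  dfs$channel <- factor(dfs$channel, levels = CP_CHANNELS)
  ggplot2::ggplot(dfs, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, nrow = 1) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a fusion training log
#'
#' @param object A `cvf_fusion_model` or `cvf_mlp_model`.
#' @param ... Unused.
#' @return A ggplot of loss and validation macro-F1 per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.cvf_fusion_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
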