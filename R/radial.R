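#' Unified metric value per selected feature
#'
#' The unified metric value of a feature is the arithmetic mean of the
#' scores of exactly those stage-1A metrics whose top-N list contained
#' it; it drives the size and color of the slices in the radial feature
#' charts. Expert-added features that were never selected by any metric
#' get value 0 and an expert flag so the chart can distinguish mandated
#' inclusion from measured relevance.
#'
#' @param stage1 A `stage1_result` (with `selecting_scores`).
#' @param final_features The final feature list, typically after
#'   [apply_expert_overlay()].
#' @param expert_added Features added by the expert overlay (defaults to
#'   the `"expert_added"` attribute of `final_features`).
#' @return A data.frame with columns `feature`, `value` and `expert`.
#' @export
unified_metric_values <- function(stage1, final_features,
                                  expert_added = attr(final_features,
                                                      "expert_added")) {
  expert_added <- expert_added %||% character()
  rows <- lapply(final_features, function(f) {
    sc <- stage1$selecting_scores[[f]]
    if (!is.null(sc))
      return(data.frame(feature = f, value = mean(sc), expert = f %in% expert_added,
                        stringsAsFactors = FALSE))
    if (f %in% expert_added)
      return(data.frame(feature = f, value = 0, expert = TRUE,
                        stringsAsFactors = FALSE))
    stop("feature '", f, "' was neither selected in stage 1 nor ",
         "flagged as expert-added")
  })
  do.call(rbind, rows)
}

#' Specification of one radial feature chart
#'
#' @param outcome Outcome label for the chart title.
#' @param values Data.frame from [unified_metric_values()].
#' @param path Output file path (extension ignored; `format` decides).
#' @param format `"svg"` (default) or `"png"`.
#' @return An object of class `chart_spec`.
#' @export
radial_chart_spec <- function(outcome, values, path = NULL,
                              format = c("svg", "png")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(values), nrow(values) >= 1,
            all(c("feature", "value", "expert") %in% names(values)),
            all(values$value >= 0))
  structure(list(outcome = outcome, values = values, path = path,
                 format = format), class = "chart_spec")
}

#' Render a radial feature chart
#'
#' One equal-angle slice per feature, in input order; radial extent and
#' red saturation are proportional to the unified metric value
#' normalized by the chart maximum. Expert-added features (value 0 by
#' construction) are drawn as hollow dashed slices so their mandated
#' inclusion is not misread as irrelevance. Output is deterministic for
#' a fixed spec.
#'
#' @param spec A [radial_chart_spec()].
#' @return The ggplot object, invisibly; if `spec$path` is set the chart
#'   is also written there.
#' @export
render_chart <- function(spec) {
  stopifnot(inherits(spec, "chart_spec"))
  df <- spec$values
  mx <- max(df$value)
  if (mx == 0) {
    warning("all unified metric values are zero; drawing uniform minimal slices")
    df$radius <- 0.1
    df$saturation <- 0
  } else {
    df$radius <- df$value / mx
    df$saturation <- df$value / mx
  }
  df$radius[df$expert] <- pmax(df$radius[df$expert], 0.1)
  df$feature <- factor(df$feature, levels = df$feature)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = feature, y = radius,
                                        fill = saturation)) +
    ggplot2::geom_col(width = 1, color = "grey30",
                      linetype = ifelse(df$expert, "dashed", "solid"),
                      alpha = ifelse(df$expert, 0.25, 1)) +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#cb181d",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = spec$outcome, x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (!is.null(spec$path)) {
    if (spec$format == "svg") {
      grDevices::svg(spec$path, width = 7, height = 7)
    } else {
      grDevices::png(spec$path, width = 700, height = 700)
    }
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}
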