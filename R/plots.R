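# ggplot2 displays for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar facet_wrap labs theme_minimal position_dodge
#'   scale_y_log10
#' @export
ggplot2::autoplot

#' Compactness curve of one or more shape models
#'
#' @param ... Named `limb_ssm` objects (e.g. `articulated = m1,
#'   recoupled = m2`).
#' @param max_modes Truncate the x axis.
#' @return A ggplot.
#' @export
plot_compactness <- function(..., max_modes = 20L) {
  models <- list(...)
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model", seq_along(models))
  }
  df <- bind_rows(lapply(names(models), function(nm) {
    mutate(compactness_curve(models[[nm]]), model = nm)
  }))
  df <- df[df$n_modes <= max_modes, ]
  ggplot(df, aes(x = .data$n_modes, y = .data$cumulative_variance,
                 colour = .data$model)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "Number of principal components",
         y = "Cumulative explained variance", colour = NULL) +
    theme_minimal()
}

#' Error-evolution plot (left/right dissimilarity vs. PLS components)
#'
#' @param curve Output of [error_evolution()].
#' @return A ggplot.
#' @export
plot_error_evolution <- function(curve) {
  ggplot(curve, aes(x = .data$k, y = .data$lr_dissimilarity,
                    colour = .data$joint, linetype = .data$mapping)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "PLS components", y = "Mean left/right dissimilarity (mm)",
         colour = NULL, linetype = NULL) +
    theme_minimal()
}

#' @export
autoplot.limb_validation <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("before_mean", "after_mean"),
                            names_to = "stage", values_to = "mean")
  df$stage <- sub("_mean", "", df$stage)
  df$sd <- ifelse(df$stage == "before", df$before_sd, df$after_sd)
  ggplot(df, aes(x = .data$metric, y = .data$mean, fill = .data$stage)) +
    geom_col(position = position_dodge(width = 0.9)) +
    geom_errorbar(aes(ymin = pmax(0, .data$mean - .data$sd),
                      ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.9), width = 0.3) +
    facet_wrap(~joint) +
    scale_y_log10() +
    labs(x = NULL, y = "Deviation (degrees / mm, log scale)", fill = NULL,
         title = sprintf("%s validation", attr(object, "experiment"))) +
    theme_minimal()
}

#' @export
autoplot.limb_ssm <- function(object, ...) {
  plot_compactness(model = object, ...)
}

#' @export
autoplot.limb_sex_effect <- function(object, ...) {
  ggplot(object$displacement,
         aes(x = .data$part, y = .data$displacement_mm)) +
    ggplot2::geom_boxplot() +
    labs(x = NULL, y = "Male-female displacement (mm)") +
    theme_minimal()
}
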