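# broom-style tidiers for the fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a shape model: one row per mode
#'
#' @param x A `limb_ssm`.
#' @param ... Unused.
#' @return Tibble with `mode`, `eigenvalue`, `prop_variance`,
#'   `cumulative_variance`, `retained`.
#' @export
tidy.limb_ssm <- function(x, ...) {
  mutate(compactness_curve(x), mode = .data$n_modes,
         retained = .data$n_modes <= x$t)[, c("mode", "eigenvalue",
                                        "prop_variance",
                                        "cumulative_variance", "retained")]
}

#' @rdname tidy.limb_ssm
#' @export
glance.limb_ssm <- function(x, ...) {
  tibble(n_landmarks = length(x$point_id), n_train = x$n_train,
         n_modes = x$t,
         total_variance = sum(x$eigenvalues_full),
         variance_retained = sum(x$eigenvalues) / sum(x$eigenvalues_full),
         first_mode_variance = x$eigenvalues_full[1L] / sum(x$eigenvalues_full))
}

#' Tidy a PLS fit: one row per component
#'
#' @param x A `limb_pls`.
#' @param ... Unused.
#' @return Tibble with `component` and the response variance captured by
#'   the fit truncated at that component.
#' @export
tidy.limb_pls <- function(x, ...) {
  tibble(component = seq_len(x$k),
         x_weight_norm = sqrt(colSums(x$weights^2)),
         y_loading_norm = sqrt(colSums(x$y_loadings^2)))
}

#' @rdname tidy.limb_pls
#' @export
glance.limb_pls <- function(x, ...) {
  tibble(k = x$k, n = x$n, n_predictors = nrow(x$B), n_responses = ncol(x$B))
}

#' Tidy a validation report (the per-joint, per-metric table)
#'
#' @param x A `limb_validation`.
#' @param ... Unused.
#' @export
tidy.limb_validation <- function(x, ...) as_tibble(x)

#' @rdname tidy.limb_validation
#' @export
glance.limb_validation <- function(x, ...) {
  tibble(experiment = attr(x, "experiment"), n = max(x$n),
         max_after_angle = max(x$after_mean[x$metric != "rmse"]),
         max_p_value = max(x$p_value))
}

#' Tidy a dimorphism analysis: per-PC canonical directions
#'
#' @param x A `limb_dimorphism`.
#' @param ... Unused.
#' @export
tidy.limb_dimorphism <- function(x, ...) {
  tibble(pc = seq_len(x$n_pcs), weight = x$weights, loading = x$loadings)
}

#' @rdname tidy.limb_dimorphism
#' @export
glance.limb_dimorphism <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value,
         percent_variance = x$percent_variance, n_pcs = x$n_pcs, n = x$n)
}

#' Tidy sex effect shapes: the per-landmark displacement map
#'
#' @param x A `limb_sex_effect`.
#' @param ... Unused.
#' @export
tidy.limb_sex_effect <- function(x, ...) x$displacement
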