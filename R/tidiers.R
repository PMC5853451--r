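# broom-style tidiers for fitted/derived result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a confusion result
#'
#' @param x A `confusion_result`.
#' @param ... Unused.
#' @return Long tibble of metric/value pairs.
#' @method tidy confusion_result
#' @export
tidy.confusion_result <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "sensitivity", "specificity",
                  "precision", "accuracy"),
    dplyr::everything(), names_to = "metric", values_to = "value")
}

#' @rdname tidy.confusion_result
#' @method glance confusion_result
#' @export
glance.confusion_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a delta-power comparison
#'
#' @param x A `delta_power_comparison`.
#' @param ... Unused.
#' @return Per-subject tibble of condition means.
#' @method tidy delta_power_comparison
#' @export
tidy.delta_power_comparison <- function(x, ...) x$per_subject

#' @rdname tidy.delta_power_comparison
#' @method glance delta_power_comparison
#' @export
glance.delta_power_comparison <- function(x, ...) {
  tibble::tibble(percent_increase = x$percent_increase,
                 t_statistic = x$t_statistic, p_value = x$p_value,
                 n_subjects = x$n_subjects)
}

#' Tidy a circular summary
#'
#' @param x A `circular_summary`.
#' @param ... Unused.
#' @return The 72-bin histogram tibble.
#' @method tidy circular_summary
#' @export
tidy.circular_summary <- function(x, ...) x$histogram

#' @rdname tidy.circular_summary
#' @method glance circular_summary
#' @export
glance.circular_summary <- function(x, ...) {
  tibble::tibble(n = x$n, mean_deg = x$mean_deg, sd_deg = x$sd_deg,
                 resultant_length = x$resultant_length)
}
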