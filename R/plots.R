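#' Stacked-bar plot of sample ancestry profiles
#'
#' The conventional admixture display: one bar per sample, stacked by
#' ancestry proportion. Zero (sparsified-out) components draw nothing.
#'
#' @param profiles A `sample_profiles` tibble from [aggregate_samples()],
#'   or any tibble with `sample_id`, `ancestry` and `proportion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sample_profiles <- function(profiles, ...) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                               fill = .data$ancestry)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "ancestry proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname plot_sample_profiles
#' @param object A `sample_profiles` tibble.
#' @export
autoplot.sample_profiles <- function(object, ...) plot_sample_profiles(object, ...)
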