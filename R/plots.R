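# ggplot2 methods for the package's result objects.

#' @describeIn accuracy_summary Density histogram of the accuracy
#'   distribution with mean (dashed) and mode (dotted) marked.
#' @param object The result object.
#' @export
autoplot.nmq_accuracy_summary <- function(object, ...) {
  h <- object$histogram[object$histogram$count > 0, ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_center, y = .data$density)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$mode, linetype = "dotted") +
    ggplot2::labs(x = "read accuracy", y = "density") +
    ggplot2::theme_minimal()
}

#' @describeIn recovery_curve Replicate points and the per-proportion mean
#'   line.
#' @param object The result object.
#' @param ... Unused.
#' @export
autoplot.nmq_subsample_curve <- function(object, ...) {
  m <- glance(object)
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = .data$proportion, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = m, ggplot2::aes(y = .data$mean), colour = "red") +
    ggplot2::labs(x = "subsampled proportion", y = object$statistic) +
    ggplot2::theme_minimal()
}

#' @describeIn region_correlation Scatter of paired regional proportions
#'   with the diagonal in red.
#' @param object The result object.
#' @export
autoplot.nmq_correlation <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(
      x = "dataset A regional methylation (%)",
      y = "dataset B regional methylation (%)",
      subtitle = sprintf("Pearson r = %.3f (n = %d)", object$r, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn gc_bias_profile Normalised coverage against GC percent; the
#'   horizontal line at 1 marks bias-free coverage.
#' @param object The result object.
#' @export
autoplot.nmq_gc_profile <- function(object, ...) {
  nz <- object$levels[!is.na(object$levels$normalized), ]
  ggplot2::ggplot(nz, ggplot2::aes(x = .data$gc_pct, y = .data$normalized)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "GC content (%)", y = "normalized coverage") +
    ggplot2::theme_minimal()
}
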