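# broom-style tidiers for the package's result objects.

#' @describeIn accuracy_summary Tidy the histogram (one row per bin).
#' @param x An `nmq_accuracy_summary`.
#' @param ... Unused.
#' @export
tidy.nmq_accuracy_summary <- function(x, ...) {
  x$histogram
}

#' @describeIn accuracy_summary One-row summary (`mean`, `mode`, `n`).
#' @export
glance.nmq_accuracy_summary <- function(x, ...) {
  tibble(mean = x$mean, mode = x$mode, n = x$n, bin_width = x$bin_width)
}

#' @describeIn recovery_curve Tidy the per-replicate values.
#' @param x An `nmq_subsample_curve`.
#' @param ... Unused.
#' @export
tidy.nmq_subsample_curve <- function(x, ...) {
  x$values
}

#' @describeIn recovery_curve Per-proportion summary (mean, sd, replicate
#'   count).
#' @export
glance.nmq_subsample_curve <- function(x, ...) {
  x$values |>
    group_by(proportion = .data$proportion) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' @describeIn region_correlation Tidy the paired regional values.
#' @param x An `nmq_correlation`.
#' @param ... Unused.
#' @export
tidy.nmq_correlation <- function(x, ...) {
  x$pairs
}

#' @describeIn region_correlation One-row summary (`r`, `n`, `p_value`).
#' @export
glance.nmq_correlation <- function(x, ...) {
  tibble(r = x$r, n = x$n, p_value = x$p_value,
         shared_only = isTRUE(x$shared_only))
}

#' @describeIn gc_bias_profile Tidy the per-GC-level table.
#' @param x An `nmq_gc_profile`.
#' @param ... Unused.
#' @export
tidy.nmq_gc_profile <- function(x, ...) {
  x$levels
}

#' @describeIn gc_bias_profile One-row summary of the normalised profile.
#' @export
glance.nmq_gc_profile <- function(x, ...) {
  nz <- x$levels[!is.na(x$levels$normalized), ]
  tibble(
    n_levels = nrow(nz),
    grand_mean = x$grand_mean,
    min_normalized = min(nz$normalized),
    max_normalized = max(nz$normalized)
  )
}
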