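# ggplot2 views of screen and context results.

#' Identity distribution of a screened cohort
#'
#' Histogram of best-parent identity with the gate threshold marked, the
#' usual first look at a candidate cohort: true family members sit well
#' above the gate, unrelated propeller proteins pile up below it.
#'
#' @param calls A `halide_screen` from [run_screen()].
#' @param bins Number of histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_identity_distribution <- function(calls, bins = 30) {
  cfg <- attr(calls, "config")
  ggplot2::ggplot(flatten_calls(calls),
                  ggplot2::aes(x = .data$identity,
                               fill = .data$passes_domain)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::geom_vline(xintercept = cfg$identity_threshold,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70"),
                               name = "both domains") +
    ggplot2::labs(x = "best-parent identity (full alignment length)",
                  y = "candidates",
                  title = "Identity gate across the candidate cohort")
}

#' Partner-gene distance plot
#'
#' Ordinal gene distances of partner genes to the nearest candidate gene,
#' with the clustering window marked; the machine-readable analog of a
#' cluster-diagram glance.
#'
#' @param context A `cohort_context` from [summarize_cohort()].
#' @return A ggplot object.
#' @export
plot_partner_distances <- function(context) {
  cfg <- attr(context, "config")
  df <- bind_rows(
    mutate(context$halogenase_calls[[1]], family = "halogenase (CylC-like)",
           window = cfg$halogenase_window),
    mutate(context$mar_calls[[1]], family = "MAR synthase (CylI-like)",
           window = cfg$mar_window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_distance,
                                   fill = .data$clustered)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0.5) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$window - 0.5),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~family, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#31a354",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "genes away from nearest candidate",
                  y = "partner genes",
                  title = "Partner-gene co-localization")
}

#' Autoplot method for screen results
#'
#' @param object A `halide_screen`.
#' @param ... Passed to [plot_identity_distribution()].
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.halide_screen <- function(object, ...) {
  plot_identity_distribution(object, ...)
}
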