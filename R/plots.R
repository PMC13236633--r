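#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_step geom_col
#'   geom_hline geom_vline labs theme_minimal scale_colour_manual
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of differential matrisome abundance
#'
#' Log2 abundance ratio (hi over lo) against -log10 p, coloured by call;
#' dashed guides mark the significance and fold thresholds used.
#'
#' @param object A [differential_abundance()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot differential_result
#' @export
autoplot.differential_result <- function(object, ...) {
  params <- attr(object, "params")
  df <- dplyr::filter(as_tibble(object), .data$testable)
  ggplot(df, aes(x = .data$log2_ratio, y = -log10(.data$p),
                 colour = .data$call)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = -log10(params$alpha), linetype = "dashed") +
    geom_vline(xintercept = log2(c(params$down, params$up)),
               linetype = "dashed") +
    scale_colour_manual(values = c(up_in_hi = "#c0392b", up_in_lo = "#2980b9",
                                   unchanged = "grey60")) +
    labs(x = sprintf("log2(%s / %s)", params$type_hi, params$type_lo),
         y = "-log10 p", colour = NULL) +
    theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param object A [km_estimate()] curve, or a named list of curves (one
#'   step per group).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  plot_km(list(all = object))
}

#' @rdname autoplot.km_curve
#' @param curves Named list of `km_curve`s.
#' @export
plot_km <- function(curves) {
  df <- purrr::imap_dfr(curves, function(km, g) {
    dplyr::bind_rows(tibble(time = 0, surv = 1, group = g),
                     tibble(time = km$time, surv = km$surv, group = g))
  })
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "time", y = "survival probability", colour = NULL) +
    theme_minimal()
}

#' Matrisome category distribution bar plot
#'
#' @param object A [category_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot category_distribution
#' @export
autoplot.category_distribution <- function(object, ...) {
  df <- tidy(object)
  df$category <- factor(df$category, levels = df$category)
  ggplot(df, aes(x = .data$category, y = .data$n, fill = .data$division)) +
    geom_col() +
    labs(x = NULL, y = "proteins", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
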