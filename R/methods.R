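#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PSA result
#'
#' @param x A `coi_psa` object from [run_psa()].
#' @param ... Unused.
#' @return The per-category summary tibble (`category`, `mean`, `sd`,
#'   `cr_low`, `cr_high`, `min`, `max`).
#' @export
tidy.coi_psa <- function(x, ...) {
  x$summary
}

#' @rdname tidy.coi_psa
#' @return `glance()`: a one-row tibble with run settings and the societal
#'   headline (mean and credibility range).
#' @export
glance.coi_psa <- function(x, ...) {
  soc <- x$summary[x$summary$category == "societal", ]
  tibble::tibble(
    iterations = x$iterations,
    seed = x$seed,
    societal_mean = soc$mean,
    societal_cr_low = soc$cr_low,
    societal_cr_high = soc$cr_high
  )
}

#' Tidy a tornado result
#'
#' @param x A `coi_tornado` object from [run_tornado()].
#' @param ... Unused.
#' @return A plain tibble of tornado entries.
#' @export
tidy.coi_tornado <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Plot the PSA output distributions
#'
#' Histograms of the per-iteration expected cost, faceted by category.
#'
#' @param object A `coi_psa` object.
#' @param categories Categories to show (default: the three economic
#'   categories and the societal total).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coi_psa <- function(object,
                             categories = c("direct_medical", "direct_non_medical",
                                            "indirect", "societal"),
                             bins = 60, ...) {
  df <- tibble::as_tibble(object$category_draws)[, categories, drop = FALSE]
  long <- tidyr::pivot_longer(df, dplyr::everything(),
                              names_to = "category", values_to = "cost")
  long$category <- factor(long$category, levels = categories)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cost)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~category, scales = "free") +
    ggplot2::labs(
      x = "Expected cost per case (2010 US$)", y = "Iterations",
      title = paste0("PSA output distributions (", object$iterations, " iterations)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars from the societal cost at each parameter's low bound to
#' the cost at its high bound, ordered by spread, with the base case marked.
#'
#' @param object A `coi_tornado` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coi_tornado <- function(object, ...) {
  df <- tidy.coi_tornado(object)
  df$label <- factor(df$label, levels = rev(df$label))
  base <- attr(object, "basecase")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$cost_low, xend = .data$cost_high,
                   y = .data$label, yend = .data$label),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(
      x = "Expected societal cost per case (2010 US$)", y = NULL,
      title = "One-way sensitivity of the societal cost"
    ) +
    ggplot2::theme_minimal()
}
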