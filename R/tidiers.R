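#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mining result
#'
#' @param x A `gar_rules` object.
#' @param ... Unused.
#' @return The rules tibble, one row per rule.
#' @exportS3Method generics::tidy
tidy.gar_rules <- function(x, ...) x$rules

#' One-row summary of a mining run
#'
#' @param x A `gar_rules` object.
#' @param ... Unused.
#' @return A one-row tibble: table dimensions, job and pruning counts, rule
#'   count, and the top rule's lift.
#' @exportS3Method generics::glance
glance.gar_rules <- function(x, ...) {
  tibble::tibble(
    n_rows = x$n_rows,
    n_columns = x$n_columns,
    n_jobs = x$n_jobs,
    n_pruned_branches = x$n_pruned,
    n_rules = nrow(x$rules),
    best_lift = if (nrow(x$rules) > 0L) x$rules$lift[1] else NA_real_,
    n_simplified = sum(!is.na(x$rules$simplified_from))
  )
}

#' Support-lift plot of mined rules
#'
#' Each point is one rule; position shows support and lift, colour shows
#' confidence. The horizontal line marks lift 1 (independence of LHS and
#' RHS).
#'
#' @param object A `gar_rules` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gar_rules <- function(object, ...) {
  tb <- object$rules
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$support, y = .data$lift,
                                   colour = .data$confidence)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "support (rows)", y = "lift",
                  colour = "confidence",
                  title = paste0("rules matching ", object$pattern)) +
    ggplot2::theme_minimal()
}

#' Plot method for mining results
#'
#' @param x A `gar_rules` object.
#' @param ... Passed to [autoplot.gar_rules()].
#' @export
plot.gar_rules <- function(x, ...) print(autoplot(x, ...))

#' @importFrom rlang .data
NULL
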