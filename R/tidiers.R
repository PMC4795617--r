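## Broom-style summaries and plots for resolver results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-iteration change counts of a resolver run
#'
#' @param x A `covres_result` from [resolve_groups()].
#' @param ... Unused.
#' @return A tibble with columns `iteration` and `changes`.
#' @export
tidy.covres_result <- function(x, ...) x$iterations

#' One-row summary of a resolver run
#'
#' @param x A `covres_result`.
#' @param ... Unused.
#' @return A one-row tibble: read and record counts, number of ambiguous
#'   groups, iterations run, convergence flag.
#' @export
glance.covres_result <- function(x, ...) {
  s <- x$stats
  tibble(
    reads = s$reads,
    multi_groups = s$multi_groups,
    records_in = s$records_in,
    records_out = s$records_out,
    unmapped = s$unmapped,
    supplementary_dropped = s$supplementary_dropped,
    pair_fallbacks = s$pair_fallbacks,
    iterations = nrow(x$iterations),
    total_changes = sum(x$iterations$changes),
    converged = s$converged
  )
}

#' @export
print.covres_result <- function(x, ...) {
  s <- x$stats
  cat("<covres_result>\n")
  cat(sprintf("  reads: %d (%d ambiguous groups)\n", s$reads, s$multi_groups))
  cat(sprintf("  records: %d in -> %d out\n", s$records_in, s$records_out))
  if (s$supplementary_dropped > 0L)
    cat(sprintf("  supplementary records dropped: %d\n", s$supplementary_dropped))
  if (s$pair_fallbacks > 0L)
    cat(sprintf("  pairs without a feasible proper pair: %d\n", s$pair_fallbacks))
  cat("  changes per iteration: ",
      paste(x$iterations$changes, collapse = ", "),
      if (s$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Plot per-iteration change counts
#'
#' @param object A `covres_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.covres_result <- function(object, ...) {
  df <- object$iterations
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$changes)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "sweep", y = "selection changes",
                  title = "Resolver convergence") +
    ggplot2::theme_minimal()
}

#' Plot a coverage report
#'
#' Coverage along each reference with the modal value marked.
#'
#' @param object A `coverage_report` from [coverage_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$coverage), function(r) {
    v <- object$coverage[[r]]
    tibble(ref = r, pos = seq_along(v) - 1L, depth = as.integer(v))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$modal, colour = "red",
                        linetype = "dashed") +
    ggplot2::facet_wrap(~ref, ncol = 1L, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "coverage",
                  title = "Per-base coverage after resolution") +
    ggplot2::theme_minimal()
}
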