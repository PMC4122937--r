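#' Plot the finishing-run trajectory
#'
#' Objective (2-telomere contigs / total contigs) and contig-class counts
#' across accepted rounds.
#'
#' @param object A `terminator_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot terminator_run
#' @export
autoplot.terminator_run <- function(object, ...) {
  d <- object$rounds %>%
    select("round", "n_2tel", "n_1tel", "n_0tel") %>%
    tidyr::pivot_longer(-"round", names_to = "class", values_to = "n") %>%
    mutate(class = factor(.data$class, c("n_2tel", "n_1tel", "n_0tel"),
                          c("2 telomeres", "1 telomere", "0 telomeres")))
  ggplot2::ggplot(d, ggplot2::aes(.data$round, .data$n, colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "finishing round", y = "contigs", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Copy-number concordance scatter plot
#'
#' @param pairs Paired tibble from [correlate_orthologs()] (columns
#'   `rpb_a`, `rpb_b`), or any tibble with an `x`/`y`-like pair given via
#'   `xcol`/`ycol`.
#' @param xcol,ycol Column names to plot.
#' @param log10 Use log10 scales.
#' @return A ggplot object.
#' @export
plot_copy_number <- function(pairs, xcol = "rpb_a", ycol = "rpb_b",
                             log10 = TRUE) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "reads/bp (A)", y = "reads/bp (B)") +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Fragmentation-site support along a contig
#'
#' @param sites Site tibble from [call_fragmentation_sites()].
#' @param contig_id Contig to display.
#' @return A ggplot object.
#' @export
plot_fragmentation <- function(sites, contig_id) {
  d <- filter(sites, .data$contig_id == !!contig_id)
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$support,
                                  colour = .data$is_terminal)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position (bp)", y = "supporting telomeric reads",
                  colour = "terminal", title = contig_id) +
    ggplot2::theme_minimal()
}
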