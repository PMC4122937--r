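#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a finishing run
#'
#' One row per accepted round with contig-class counts, bases added and the
#' objective.
#'
#' @param x A `terminator_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy terminator_run
#' @export
tidy.terminator_run <- function(x, ...) {
  x$rounds
}

#' One-row summary of a finishing run
#'
#' @param x A `terminator_run`.
#' @param ... Unused.
#' @return A one-row tibble with the final assembly's headline numbers.
#' @method glance terminator_run
#' @export
glance.terminator_run <- function(x, ...) {
  m <- round_metrics(x$contigs)
  tibble(
    n_rounds = nrow(x$rounds), n_contigs = m$n_contigs,
    n_telomeres = m$n_telomeres, n_2tel = m$n_2tel, n_1tel = m$n_1tel,
    n_0tel = m$n_0tel, assembly_size = sum(nchar(x$contigs$seq)),
    objective = m$objective
  )
}
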