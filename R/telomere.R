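#' Telomere repeat specification
#'
#' Describes the C4A4-type telomeric repeat of stichotrich nanochromosomes
#' and the thresholds used to detect it. Read selection uses the literal
#' 2.5-unit selector (exact match, for precision); contig-end classification
#' tolerates `max_mismatch_per_20bp` substitutions per 20 bp of run, because
#' an assembled consensus may carry allelic or erroneous bases (recall).
#'
#' @param unit Repeat unit as seen at the 5' (C-rich) chromosome end.
#' @param read_selector Literal prefix a read must carry to count as
#'   telomeric; must be a prefix of the repeated unit.
#' @param min_contig_run Minimum run length (bp) for a contig end to be
#'   called telomere-capped.
#' @param end_window A capping run must begin within this many bp of the
#'   contig terminus.
#' @param max_mismatch_per_20bp Mismatch tolerance of the contig-end scan,
#'   per complete 20 bp of run.
#' @return A `telomere_spec` list.
#' @examples
#' telomere_spec()
#' @export
telomere_spec <- function(unit = "CCCCAAAA",
                          read_selector = "CCCCAAAACCCCAAAACCCC",
                          min_contig_run = 16L, end_window = 30L,
                          max_mismatch_per_20bp = 1L) {
  unit <- toupper(unit); read_selector <- toupper(read_selector)
  rep_ref <- strrep(unit, ceiling(nchar(read_selector) / nchar(unit)))
  if (substr(rep_ref, 1, nchar(read_selector)) != read_selector) {
    abort("read_selector must be a prefix-repetition of unit")
  }
  if (min_contig_run < nchar(unit)) {
    abort("min_contig_run must be at least one repeat unit")
  }
  structure(list(unit = unit, read_selector = read_selector,
                 min_contig_run = as.integer(min_contig_run),
                 end_window = as.integer(end_window),
                 max_mismatch_per_20bp = as.integer(max_mismatch_per_20bp)),
            class = "telomere_spec")
}

#' Classify contig ends by telomere state
#'
#' Scans both ends of every contig for a run of the telomeric repeat (either
#' strand's phase, so reverse-complemented contigs classify symmetrically).
#' A run counts as a cap when it is at least `min_contig_run` bp long and
#' begins within `end_window` bp of the terminus. Adds or replaces the
#' columns `left_telomere`, `right_telomere`, `left_telomere_len`,
#' `right_telomere_len` and `n_telomeres`.
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param spec A [telomere_spec()].
#' @return The contig tibble with telomere columns set.
#' @examples
#' ctg <- tibble::tibble(
#'   id = "c1",
#'   seq = paste0("CCCCAAAACCCCAAAACCCC", strrep("GATC", 25),
#'                "GGGGTTTTGGGGTTTTGGGG")
#' )
#' classify_contigs(ctg)
#' @export
classify_contigs <- function(contigs, spec = telomere_spec()) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  runs <- vapply(contigs$seq, function(s) {
    if (nchar(s) < spec$min_contig_run) return(c(0L, 0L))
    cpp_telo_runs(s, spec$unit, spec$end_window,
                  spec$max_mismatch_per_20bp, spec$min_contig_run)
  }, integer(2), USE.NAMES = FALSE)
  contigs$length <- nchar(contigs$seq)
  contigs$left_telomere_len <- runs[1, ]
  contigs$right_telomere_len <- runs[2, ]
  contigs$left_telomere <- contigs$left_telomere_len > 0L
  contigs$right_telomere <- contigs$right_telomere_len > 0L
  contigs$n_telomeres <- as.integer(contigs$left_telomere) +
    as.integer(contigs$right_telomere)
  contigs
}

is_classified <- function(contigs) {
  all(c("left_telomere", "right_telomere") %in% names(contigs))
}

#' Count telomeres in a classified assembly
#'
#' The assembly telomere tally: 2 x (2-telomere contigs) + (1-telomere
#' contigs).
#'
#' @param contigs Classified contig tibble (see [classify_contigs()]).
#' @return Integer count.
#' @export
count_telomeres <- function(contigs) {
  if (!is_classified(contigs)) {
    abort("contigs are not classified; run classify_contigs() first")
  }
  sum(contigs$left_telomere) + sum(contigs$right_telomere)
}

#' Select and strip telomeric read pairs
#'
#' A pair is selected when either mate begins exactly with the telomeric
#' read selector (in an inward-oriented library every telomere-junction read
#' presents the C-rich repeat at its stored 5' start, so the single C-rich
#' selector covers both chromosome ends; the junction's side is recovered
#' later from the mapped strand). The maximal leading telomeric run --
#' whole and partial units -- is stripped from the selected mate and its
#' length recorded. Stripping is idempotent: a stripped read strips to
#' itself.
#'
#' Pairs whose selected mate retains fewer than `min_residual` bases after
#' stripping are dropped; the count of such pairs is attached as the
#' `n_too_short` attribute.
#'
#' @param pairs Read-pair tibble.
#' @param spec A [telomere_spec()].
#' @param min_residual Minimum non-telomeric residual length (bp).
#' @return Tibble with columns `id`, `mate` (1 or 2, the telomeric mate),
#'   `stripped_seq`, `strip_len`, `other_seq`.
#' @export
telomeric_reads <- function(pairs, spec = telomere_spec(), min_residual = 20L) {
  sel_len <- nchar(spec$read_selector)
  is1 <- substr(pairs$seq1, 1L, sel_len) == spec$read_selector
  is2 <- substr(pairs$seq2, 1L, sel_len) == spec$read_selector
  sel <- is1 | is2
  if (!any(sel)) {
    out <- tibble(id = character(), mate = integer(),
                  stripped_seq = character(), strip_len = integer(),
                  other_seq = character())
    attr(out, "n_too_short") <- 0L
    return(out)
  }
  p <- pairs[sel, ]
  mate <- if_else(is1[sel], 1L, 2L)  # mate 1 wins if both are telomeric
  raw <- if_else(mate == 1L, p$seq1, p$seq2)
  other <- if_else(mate == 1L, p$seq2, p$seq1)
  strip_len <- cpp_telo_prefix(raw, spec$unit)
  out <- tibble(id = p$id, mate = mate,
                stripped_seq = substr(raw, strip_len + 1L, nchar(raw)),
                strip_len = strip_len, other_seq = other)
  keep <- nchar(out$stripped_seq) >= min_residual
  n_short <- sum(!keep)
  if (n_short > 0) {
    inform(sprintf("telomeric_reads: %d pair(s) dropped (residual < %d nt)",
                   n_short, min_residual))
  }
  out <- out[keep, ]
  attr(out, "n_too_short") <- n_short
  out
}
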