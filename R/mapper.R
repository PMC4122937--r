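#' Mapper parameters
#'
#' Controls the package's deterministic, self-contained gapless read mapper.
#' Two modes are provided: `strict` (full-length alignment, at most
#' `strict_max_mismatch` substitutions) is used for extension anchoring and
#' telomere-addition-site mapping; `lenient` (>= 90% identity over >= 70% of
#' the read, end overhangs allowed) is used for coverage and depth metrics.
#'
#' Placements are found via exact shared k-mers and scored gaplessly; the
#' best placement maximizes matching bases, with ties broken by fewest
#' mismatches, then lowest contig id, lowest coordinate, forward strand.
#' A read with at most `floor(read_len / k) - 1` substitutions is guaranteed
#' to retain a clean seed, so the seeded search then equals an exhaustive
#' scan. `N` always counts as a mismatch.
#'
#' @param k Seed length.
#' @param mode `"strict"` or `"lenient"`.
#' @param strict_max_mismatch Mismatch budget in strict mode.
#' @param lenient_min_identity Minimum identity over the aligned part in
#'   lenient mode.
#' @param lenient_min_aligned_fraction Minimum fraction of the read aligned
#'   in lenient mode.
#' @param proper_pair_min,proper_pair_max Outer-distance bounds for a proper
#'   pair (defaults: library mean +/- 4 SD of the default simulated
#'   library).
#' @return A `mapper_params` list.
#' @export
mapper_params <- function(k = 21L, mode = c("strict", "lenient"),
                          strict_max_mismatch = 1L,
                          lenient_min_identity = 0.90,
                          lenient_min_aligned_fraction = 0.70,
                          proper_pair_min = 83L, proper_pair_max = 243L) {
  mode <- match.arg(mode)
  stopifnot(lenient_min_identity > 0, lenient_min_identity <= 1,
            lenient_min_aligned_fraction > 0, lenient_min_aligned_fraction <= 1)
  structure(list(k = as.integer(k), mode = mode,
                 strict_max_mismatch = as.integer(strict_max_mismatch),
                 lenient_min_identity = lenient_min_identity,
                 lenient_min_aligned_fraction = lenient_min_aligned_fraction,
                 proper_pair_min = as.integer(proper_pair_min),
                 proper_pair_max = as.integer(proper_pair_max)),
            class = "mapper_params")
}

#' Map reads to contigs
#'
#' Gapless best-only mapping of single reads. Contigs shorter than `k` are
#' unmappable and reported via a message.
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param reads Character vector of read sequences, or a tibble with `id`
#'   and `seq` columns.
#' @param params A [mapper_params()].
#' @return Alignment tibble: `read_id`, `contig_id`, `start`, `end` (0-based
#'   half-open, clipped to the contig), `strand`, `n_mismatch`, `overlap`,
#'   `aligned_fraction`. Unmapped reads are absent.
#' @export
map_reads <- function(contigs, reads, params = mapper_params()) {
  if (nrow(contigs) == 0L) abort("contig list is empty")
  contigs <- arrange(contigs, .data$id)
  short <- sum(nchar(contigs$seq) < params$k)
  if (short > 0) {
    inform(sprintf("map_reads: %d contig(s) shorter than k=%d are unmappable",
                   short, params$k))
  }
  if (is.data.frame(reads)) {
    read_ids <- reads$id
    seqs <- reads$seq
  } else {
    read_ids <- if (!is.null(names(reads))) names(reads) else
      as.character(seq_along(reads))
    seqs <- unname(reads)
  }
  if (length(seqs) == 0L) {
    return(tibble(read_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_mismatch = integer(), overlap = integer(),
                  aligned_fraction = double()))
  }
  strict <- params$mode == "strict"
  hits <- cpp_map_reads(
    contigs$seq, seqs, params$k,
    min_identity = if (strict) 0 else params$lenient_min_identity,
    min_aligned_frac = if (strict) 1 else params$lenient_min_aligned_fraction,
    max_mismatch = if (strict) params$strict_max_mismatch else .Machine$integer.max,
    require_full = strict, seed_stride = 1L
  )
  tibble(
    read_id = read_ids[hits$read],
    contig_id = contigs$id[hits$contig],
    start = hits$start, end = hits$end, strand = hits$strand,
    n_mismatch = hits$n_mismatch, overlap = hits$overlap,
    aligned_fraction = hits$overlap / nchar(seqs[hits$read])
  )
}

#' Map read pairs and flag proper pairs
#'
#' Both mates are mapped independently (best-only) and a pair is properly
#' paired when both mates hit the same contig on opposite strands, inward
#' oriented, with an outer distance within
#' `[proper_pair_min, proper_pair_max]`.
#'
#' @param contigs Contig tibble.
#' @param pairs Read-pair tibble (`id`, `seq1`, `seq2`).
#' @param params A [mapper_params()].
#' @return Alignment tibble as in [map_reads()] plus `mate` (1/2) and
#'   `properly_paired`; the proper-pair fraction (over pairs with both mates
#'   mapped) is attached as attribute `proper_pair_fraction`.
#' @export
map_pairs <- function(contigs, pairs, params = mapper_params()) {
  a1 <- map_reads(contigs, setNames(pairs$seq1, pairs$id), params)
  a2 <- map_reads(contigs, setNames(pairs$seq2, pairs$id), params)
  a1$mate <- 1L; a2$mate <- 2L
  aln <- bind_rows(a1, a2)

  both <- inner_join(a1, a2, by = "read_id", suffix = c("_1", "_2"))
  both <- both %>% mutate(
    same = .data$contig_id_1 == .data$contig_id_2,
    opposite = .data$strand_1 != .data$strand_2,
    fwd_start = if_else(.data$strand_1 == "+", .data$start_1, .data$start_2),
    rev_end = if_else(.data$strand_1 == "+", .data$end_2, .data$end_1),
    inward = .data$fwd_start <= .data$rev_end,
    outer = .data$rev_end - .data$fwd_start,
    proper = .data$same & .data$opposite & .data$inward &
      .data$outer >= params$proper_pair_min &
      .data$outer <= params$proper_pair_max
  )
  proper_ids <- both$read_id[both$proper]
  aln$properly_paired <- aln$read_id %in% proper_ids
  aln <- arrange(aln, .data$read_id, .data$mate)
  attr(aln, "proper_pair_fraction") <-
    if (nrow(both)) mean(both$proper) else NA_real_
  aln
}
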