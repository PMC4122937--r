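#' Estimate nanochromosome copy number from read depth
#'
#' Every read mapped in lenient mode increments exactly one contig (its
#' best, tie-broken placement); the per-contig count is normalized by
#' contig length to reads per base, the package's relative copy-number
#' statistic.
#'
#' @param contigs Contig tibble.
#' @param pairs Read-pair tibble.
#' @param mp A [mapper_params()] (lenient mode is enforced).
#' @return Tibble sorted by contig id: `contig_id`, `length`,
#'   `mapped_reads`, `reads_per_base`, `normalized_rpb` (equal to
#'   `reads_per_base` until [normalize_libraries()] rescales it). The total
#'   mapped-read count is attached as attribute `total_mapped`.
#' @export
estimate_copy_number <- function(contigs, pairs, mp = mapper_params()) {
  if (nrow(contigs) == 0L) abort("contig list is empty")
  mp$mode <- "lenient"
  a1 <- map_reads(contigs, setNames(pairs$seq1, pairs$id), mp)
  a2 <- map_reads(contigs, setNames(pairs$seq2, pairs$id), mp)
  counts <- bind_rows(a1, a2) %>% count(.data$contig_id)
  est <- tibble(contig_id = contigs$id, length = nchar(contigs$seq)) %>%
    left_join(counts, by = "contig_id") %>%
    mutate(mapped_reads = if_else(is.na(.data$n), 0L, .data$n),
           reads_per_base = .data$mapped_reads / .data$length,
           normalized_rpb = .data$reads_per_base) %>%
    select(-dplyr::any_of("n")) %>%
    arrange(.data$contig_id)
  attr(est, "total_mapped") <- sum(est$mapped_reads)
  est
}

#' Normalize copy-number estimates across libraries
#'
#' The smaller library's reads-per-base values are multiplied by the ratio
#' of total mapped reads (larger/smaller), so the two libraries become
#' directly comparable; the applied factor is reported. Rank order within
#' each library is unchanged.
#'
#' @param est_a,est_b Estimate tibbles from [estimate_copy_number()] (or
#'   carrying a `total_mapped` attribute).
#' @return List with rescaled `a` and `b` and the scale `factor`.
#' @export
normalize_libraries <- function(est_a, est_b) {
  ta <- attr(est_a, "total_mapped") %||% sum(est_a$mapped_reads)
  tb <- attr(est_b, "total_mapped") %||% sum(est_b$mapped_reads)
  if (ta == 0 || tb == 0) abort("a library has zero mapped reads")
  factor <- max(ta, tb) / min(ta, tb)
  if (ta < tb) {
    est_a$normalized_rpb <- est_a$reads_per_base * factor
    est_b$normalized_rpb <- est_b$reads_per_base
  } else if (tb < ta) {
    est_b$normalized_rpb <- est_b$reads_per_base * factor
    est_a$normalized_rpb <- est_a$reads_per_base
  }
  inform(sprintf("normalize_libraries: factor %.3f applied to the smaller library",
                 factor))
  list(a = est_a, b = est_b, factor = factor)
}

#' Correlate copy numbers of orthologous nanochromosomes
#'
#' Pearson correlation of normalized reads-per-base over reciprocal-best
#' ortholog pairs, optionally restricted to single-gene contigs (contigs
#' with exactly one gene in the homology table) and optionally on log10
#' values.
#'
#' @param est_a,est_b Estimate tibbles.
#' @param homology Homology tibble: `contig_a`, `gene_a`, `contig_b`,
#'   `gene_b`, `evalue`, `reciprocal_best`.
#' @param single_gene_only Restrict to single-gene contigs on both sides.
#' @param log10 Correlate log10-transformed values.
#' @return List with `r`, `n` and the paired tibble `pairs`.
#' @export
correlate_orthologs <- function(est_a, est_b, homology,
                                single_gene_only = TRUE, log10 = FALSE) {
  rb <- filter(homology, .data$reciprocal_best)
  if (single_gene_only) {
    one_a <- homology %>% count(.data$contig_a) %>% filter(.data$n == 1L)
    one_b <- homology %>% count(.data$contig_b) %>% filter(.data$n == 1L)
    rb <- rb %>% filter(.data$contig_a %in% one_a$contig_a,
                        .data$contig_b %in% one_b$contig_b)
  }
  paired <- rb %>%
    inner_join(select(est_a, "contig_id", rpb_a = "normalized_rpb"),
               by = c(contig_a = "contig_id")) %>%
    inner_join(select(est_b, "contig_id", rpb_b = "normalized_rpb"),
               by = c(contig_b = "contig_id"))
  if (nrow(paired) < 3L) abort("fewer than 3 ortholog pairs with estimates")
  x <- paired$rpb_a; y <- paired$rpb_b
  if (log10) { x <- log10(x); y <- log10(y) }
  list(r = cor(x, y), n = nrow(paired),
       pairs = select(paired, "contig_a", "contig_b", "rpb_a", "rpb_b"))
}

#' Compute assembly metrics
#'
#' The standard nanochromosomal assembly report: size, contig and telomere
#' tallies, 2/1/0-telomere decomposition, the fraction of reads mapping in
#' lenient mode (total and restricted to telomere-selector reads, the
#' latter mapped after stripping), and the proper-pair fraction.
#'
#' @param contigs Contig tibble.
#' @param pairs Read-pair tibble (may have zero rows).
#' @param spec A [telomere_spec()].
#' @param mp A [mapper_params()].
#' @return One-row metrics tibble.
#' @export
compute_metrics <- function(contigs, pairs, spec = telomere_spec(),
                            mp = mapper_params()) {
  if (!is_classified(contigs)) contigs <- classify_contigs(contigs, spec)
  m <- round_metrics(contigs)
  lens <- nchar(contigs$seq)
  base <- tibble(
    assembly_size = sum(lens), n_contigs = nrow(contigs),
    n_telomeres = m$n_telomeres,
    mean_contig_len = if (nrow(contigs)) mean(lens) else NA_real_,
    max_contig_len = if (nrow(contigs)) max(lens) else NA_integer_,
    n_2tel = m$n_2tel, n_1tel = m$n_1tel, n_0tel = m$n_0tel
  )
  if (nrow(pairs) == 0L) {
    return(bind_cols(base, tibble(total_read_coverage_pct = 0,
                                  telomeric_read_coverage_pct = 0,
                                  proper_pair_pct = NA_real_)))
  }
  mp$mode <- "lenient"
  aln <- map_pairs(contigs, pairs, mp)
  total_pct <- 100 * nrow(aln) / (2 * nrow(pairs))

  tel <- telomeric_reads(pairs, spec, min_residual = mp$k)
  n_telomeric <- nrow(tel) + attr(tel, "n_too_short")
  tel_pct <- if (n_telomeric > 0) {
    ta <- map_reads(contigs, setNames(tel$stripped_seq, tel$id), mp)
    100 * nrow(ta) / n_telomeric
  } else NA_real_

  bind_cols(base, tibble(
    total_read_coverage_pct = total_pct,
    telomeric_read_coverage_pct = tel_pct,
    proper_pair_pct = 100 * attr(aln, "proper_pair_fraction")
  ))
}

#' Two-gene contig synteny between assemblies
#'
#' A two-gene contig of assembly A is syntenic when both of its genes match
#' (e-value below `max_evalue`) genes residing on one contig of assembly B.
#' Gene-order agreement among syntenic pairs is reported separately.
#'
#' @param homology Homology tibble (`contig_a`, `gene_a`, `contig_b`,
#'   `gene_b`, `evalue`).
#' @param gene_map_a,gene_map_b Tibbles `contig`, `gene` giving each
#'   assembly's genes in contig order.
#' @param max_evalue Match threshold.
#' @param contigs_a Optional contig tibble for validating the gene map.
#' @return List with `summary` (one-row tibble: `n_two_gene`, `n_syntenic`,
#'   `fraction_syntenic`, `fraction_order_agree`) and the per-contig tibble
#'   `pairs`.
#' @export
two_gene_synteny <- function(homology, gene_map_a, gene_map_b,
                             max_evalue = 1e-10, contigs_a = NULL) {
  if (!is.null(contigs_a) && !all(gene_map_a$contig %in% contigs_a$id)) {
    abort(sprintf("gene map contig '%s' absent from assembly",
                  setdiff(gene_map_a$contig, contigs_a$id)[1]))
  }
  two_gene <- gene_map_a %>% group_by(.data$contig) %>%
    filter(n() == 2L) %>%
    mutate(gene_order = row_number()) %>% ungroup()
  if (nrow(two_gene) == 0L) {
    return(list(summary = tibble(n_two_gene = 0L, n_syntenic = 0L,
                                 fraction_syntenic = NA_real_,
                                 fraction_order_agree = NA_real_),
                pairs = tibble()))
  }
  hits <- homology %>% filter(.data$evalue < max_evalue) %>%
    inner_join(two_gene, by = c(gene_a = "gene"),
               relationship = "many-to-many") %>%
    inner_join(gene_map_b %>% group_by(.data$contig) %>%
                 mutate(order_b = row_number()) %>% ungroup() %>%
                 rename(contig_b_map = "contig"),
               by = c(gene_b = "gene"), relationship = "many-to-many") %>%
    filter(.data$contig_b == .data$contig_b_map)

  per_contig <- hits %>%
    distinct(.data$contig, .data$gene_a, .data$contig_b,
             .data$gene_order, .data$order_b) %>%
    group_by(.data$contig, .data$contig_b) %>%
    summarise(n_genes_matched = dplyr::n_distinct(.data$gene_a),
              order_agree = all(sign(diff(.data$gene_order[order(.data$gene_order)])) ==
                                  sign(diff(.data$order_b[order(.data$gene_order)]))),
              .groups = "drop") %>%
    filter(.data$n_genes_matched == 2L)

  syntenic_contigs <- unique(per_contig$contig)
  n2 <- dplyr::n_distinct(two_gene$contig)
  list(
    summary = tibble(
      n_two_gene = n2, n_syntenic = length(syntenic_contigs),
      fraction_syntenic = length(syntenic_contigs) / n2,
      fraction_order_agree = if (nrow(per_contig)) mean(per_contig$order_agree)
      else NA_real_
    ),
    pairs = per_contig
  )
}

#' Global alignment identity between two sequences
#'
#' Utility for truth-recovery checks: Needleman-Wunsch global alignment of
#' `a` against `b` on both strands, with identity defined as matching bases
#' over the longer of the two sequences, so missing bases, surplus bases
#' and small junction shifts (indels) each cost exactly their length.
#'
#' @param a,b DNA strings.
#' @param min_overlap Unused; retained for call compatibility.
#' @return One-row tibble: `identity`, `matches`, `strand`.
#' @export
pairwise_identity <- function(a, b, min_overlap = 20L) {
  score <- function(x) {
    aln <- Biostrings::pairwiseAlignment(x, b, type = "global",
                                         gapOpening = 2, gapExtension = 1)
    Biostrings::nmatch(aln)
  }
  mf <- score(a); mr <- score(cpp_revcomp(a))
  tibble(identity = max(mf, mr) / max(nchar(a), nchar(b)),
         matches = max(mf, mr), strand = if (mf >= mr) "+" else "-")
}
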