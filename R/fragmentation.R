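#' Fragmentation-site calling parameters
#'
#' @param cluster_window Raw telomere-addition positions of the same sense
#'   are clustered when consecutive sites are within this many bp
#'   (single-linkage).
#' @param terminal_margin Sites within this many bp of a contig end are
#'   terminal (ordinary chromosome ends); the rest are internal and signal
#'   alternative fragmentation.
#' @param min_support Minimum supporting telomeric reads per reported
#'   cluster.
#' @return A `fragsite_params` list.
#' @export
fragsite_params <- function(cluster_window = 100L, terminal_margin = 50L,
                            min_support = 1L) {
  stopifnot(cluster_window > 0)
  structure(list(cluster_window = as.integer(cluster_window),
                 terminal_margin = as.integer(terminal_margin),
                 min_support = as.integer(min_support)),
            class = "fragsite_params")
}

#' Call telomere-addition sites from telomere-stripped reads
#'
#' Selects read pairs carrying the telomeric selector, strips the maximal
#' leading repeat, and maps the stripped residual in strict mode. The
#' stripped end's mapped boundary is a raw site: alignment start for a
#' forward hit (a left, C-rich junction), alignment end for a reverse hit
#' (a right, G-rich junction). Raw sites of the same contig and sense are
#' clustered within `cluster_window`; a cluster's position is the
#' support-weighted mode of its raw coordinates (ties to the smaller
#' coordinate), so every reported position is witnessed by at least one
#' read.
#'
#' @param contigs Contig tibble.
#' @param pairs Read-pair tibble.
#' @param spec A [telomere_spec()].
#' @param fp A [fragsite_params()].
#' @param mp A [mapper_params()] (strict mode is enforced).
#' @return Site tibble: `contig_id`, `position` (0-based), `end_sense`
#'   (`left`/`right`), `support`, `is_terminal`. The contig universe is
#'   attached as attribute `contig_ids`, and the number of mapped stripped
#'   reads as `n_mapped`.
#' @export
call_fragmentation_sites <- function(contigs, pairs, spec = telomere_spec(),
                                     fp = fragsite_params(),
                                     mp = mapper_params()) {
  tel <- telomeric_reads(pairs, spec)
  empty <- tibble(contig_id = character(), position = integer(),
                  end_sense = character(), support = integer(),
                  is_terminal = logical())
  if (nrow(tel) == 0L) {
    attr(empty, "contig_ids") <- contigs$id
    attr(empty, "n_mapped") <- 0L
    return(empty)
  }
  mappable <- nchar(tel$stripped_seq) >= mp$k
  n_short <- sum(!mappable)
  if (n_short > 0) {
    inform(sprintf(
      "call_fragmentation_sites: %d stripped read(s) shorter than k=%d discarded",
      n_short, mp$k))
  }
  tel <- tel[mappable, ]
  mp$mode <- "strict"
  aln <- map_reads(contigs, setNames(tel$stripped_seq, tel$id), mp)
  lens <- setNames(nchar(contigs$seq), contigs$id)
  if (nrow(aln) == 0L) {
    attr(empty, "contig_ids") <- contigs$id
    attr(empty, "n_mapped") <- 0L
    return(empty)
  }
  raw <- aln %>% mutate(
    position = if_else(.data$strand == "+", .data$start, .data$end),
    end_sense = if_else(.data$strand == "+", "left", "right")
  )

  clustered <- raw %>%
    group_by(.data$contig_id, .data$end_sense) %>%
    arrange(.data$position, .by_group = TRUE) %>%
    mutate(cluster = cumsum(c(1L, diff(.data$position) > fp$cluster_window))) %>%
    group_by(.data$contig_id, .data$end_sense, .data$cluster) %>%
    summarise(position = weighted_mode(.data$position),
              support = n(), .groups = "drop") %>%
    select(-dplyr::any_of("cluster"))

  sites <- clustered %>%
    mutate(len = lens[.data$contig_id],
           is_terminal = .data$position <= fp$terminal_margin |
             .data$position >= .data$len - fp$terminal_margin) %>%
    filter(.data$support >= fp$min_support) %>%
    select("contig_id", "position", "end_sense", "support", "is_terminal") %>%
    arrange(.data$contig_id, .data$position)

  attr(sites, "contig_ids") <- contigs$id
  attr(sites, "n_mapped") <- nrow(raw)
  sites
}

# most frequent value; ties to the smallest
weighted_mode <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Flag contigs with alternative fragmentation
#'
#' A contig is alternatively fragmented when it carries at least one
#' internal (non-terminal) telomere-addition cluster passing `min_support`.
#'
#' @param sites Site tibble from [call_fragmentation_sites()].
#' @param contigs Contig tibble (defines the universe; contigs with no
#'   sites are reported unflagged).
#' @param fp A [fragsite_params()].
#' @return Tibble `contig_id`, `alt_frag`.
#' @export
flag_alt_fragmentation <- function(sites, contigs, fp = fragsite_params()) {
  internal <- sites %>%
    filter(!.data$is_terminal, .data$support >= fp$min_support) %>%
    distinct(.data$contig_id) %>%
    mutate(alt_frag = TRUE)
  tibble(contig_id = contigs$id) %>%
    left_join(internal, by = "contig_id") %>%
    mutate(alt_frag = !is.na(.data$alt_frag))
}

#' Compare fragmentation between two assemblies
#'
#' Given site calls for two assemblies and a pairing of their contigs
#' (e.g. orthologous nanochromosomes), counts pairs where both, either, or
#' neither member is alternatively fragmented, and the both/either
#' conservation fraction. When the paired contigs share a coordinate
#' system, internal sites are additionally matched within `tolerance` bp.
#'
#' @param sites_a,sites_b Site tibbles from [call_fragmentation_sites()].
#' @param pairing Tibble with columns `contig_a`, `contig_b`.
#' @param tolerance Coordinate tolerance (bp) for per-site matching; `NULL`
#'   disables site matching.
#' @param fp A [fragsite_params()].
#' @return A list with `counts` (one-row tibble: `n_pairs`, `both`,
#'   `either`, `neither`, `fraction_both_of_either`) and, when matched,
#'   `site_matches`.
#' @export
compare_site_sets <- function(sites_a, sites_b, pairing, tolerance = NULL,
                              fp = fragsite_params()) {
  for (side in c("a", "b")) {
    ids <- attr(if (side == "a") sites_a else sites_b, "contig_ids")
    col <- pairing[[paste0("contig_", side)]]
    if (!is.null(ids) && !all(col %in% ids)) {
      abort(sprintf("pairing references unknown contig '%s' in assembly %s",
                    setdiff(col, ids)[1], side))
    }
  }
  flag <- function(sites) {
    sites %>% filter(!.data$is_terminal, .data$support >= fp$min_support) %>%
      pull(.data$contig_id) %>% unique()
  }
  fa <- pairing$contig_a %in% flag(sites_a)
  fb <- pairing$contig_b %in% flag(sites_b)
  both <- sum(fa & fb); either <- sum(fa | fb)
  counts <- tibble(
    n_pairs = nrow(pairing), both = both, either = either,
    neither = nrow(pairing) - either,
    fraction_both_of_either = if (either > 0) both / either else NA_real_
  )
  out <- list(counts = counts)
  if (!is.null(tolerance)) {
    ia <- sites_a %>% filter(!.data$is_terminal) %>%
      inner_join(pairing, by = c(contig_id = "contig_a"),
                 relationship = "many-to-many")
    ib <- sites_b %>% filter(!.data$is_terminal)
    matches <- ia %>%
      inner_join(ib, by = c(contig_b = "contig_id", "end_sense"),
                 suffix = c("_a", "_b"), relationship = "many-to-many") %>%
      filter(abs(.data$position_a - .data$position_b) <= tolerance)
    out$site_matches <- matches %>%
      select("contig_id", "contig_b", "end_sense",
             "position_a", "position_b", "support_a", "support_b")
  }
  out
}
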