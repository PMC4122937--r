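#' Extension parameters for the finishing loop
#'
#' @param max_overhang_mismatch Substitutions tolerated in a candidate
#'   mate's overlap with the contig end (0 or 1).
#' @param min_support Minimum reads voting for an extended column.
#' @param max_round_extension Maximum bases appended per end per round;
#'   defaults to the read length of the default simulated library.
#' @param stop_at_telomere Halt an end permanently once its extension
#'   completes a telomere run (and trim any bases voted beyond it).
#' @param min_mate_overlap Minimum bases a candidate mate must overlap the
#'   contig end region to be placed at all.
#' @return An `extension_params` list.
#' @export
extension_params <- function(max_overhang_mismatch = 1L, min_support = 3L,
                             max_round_extension = 90L,
                             stop_at_telomere = TRUE,
                             min_mate_overlap = 10L) {
  stopifnot(min_support >= 1, max_overhang_mismatch %in% c(0L, 1L))
  structure(list(max_overhang_mismatch = as.integer(max_overhang_mismatch),
                 min_support = as.integer(min_support),
                 max_round_extension = as.integer(max_round_extension),
                 stop_at_telomere = isTRUE(stop_at_telomere),
                 min_mate_overlap = as.integer(min_mate_overlap)),
            class = "extension_params")
}

#' Merge and chaff-removal parameters
#'
#' Defaults follow the meta-assembly rules used for nanochromosomal
#' finishing: overlaps of at least 40 bp at 97% identity or better are
#' merged; contigs under 500 bp contained in a longer contig at over 80%
#' coverage and over 90% identity are chaff.
#'
#' @param min_overlap Minimum end-overlap length (bp).
#' @param min_identity Minimum overlap identity for merging.
#' @param chaff_max_len Contigs shorter than this are chaff candidates (bp).
#' @param chaff_min_coverage Fraction of a chaff candidate that must align.
#' @param chaff_min_identity Identity of the chaff alignment.
#' @return A `merge_params` list.
#' @export
merge_params <- function(min_overlap = 40L, min_identity = 0.97,
                         chaff_max_len = 500L, chaff_min_coverage = 0.80,
                         chaff_min_identity = 0.90) {
  stopifnot(min_identity > 0, min_identity <= 1, min_overlap >= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity,
                 chaff_max_len = as.integer(chaff_max_len),
                 chaff_min_coverage = chaff_min_coverage,
                 chaff_min_identity = chaff_min_identity),
            class = "merge_params")
}

# Detect entry into the telomeric cap at a framed (right) end and install
# the canonical 2.5-unit cap at the junction. Telomere-addition jitter
# shifts the repeat phase between junction-spanning reads, so column votes
# inside the repeat deadlock or produce out-of-phase repeat bases; the
# repeat itself is invariant, so once its start (the junction) is located,
# everything after it is replaced by the canonical cap. The junction is the
# first G-block in the terminal zone whose suffix is >= 80% G/T.
# Returns the capped sequence, or NULL when the end shows no cap entry.
install_telomere_cap <- function(framed, spec) {
  cap <- cpp_revcomp(spec$read_selector)
  tlen <- nchar(cap)
  L <- nchar(framed)
  if (L < tlen + 4L) return(NULL)
  zone_start <- max(1L, L - (tlen + 16L) + 1L)
  zone <- substr(framed, zone_start, L)
  hits <- gregexpr("GGGG", zone)[[1]]
  if (hits[1] == -1L) return(NULL)
  for (h in hits) {
    pos <- zone_start + h - 1L  # junction candidate (1-based)
    suffix <- substr(framed, pos, L)
    gt <- stringr::str_count(suffix, "[GT]") / nchar(suffix)
    if (gt >= 0.8) {
      return(paste0(substr(framed, 1L, pos - 1L), cap))
    }
  }
  NULL
}

#' Extend uncapped contig ends with pair-anchored reads
#'
#' For every contig end that is not telomere-capped, read pairs with one
#' mate mapped full-length in strict mode (at most one substitution),
#' oriented so the free mate points off the end, are collected. Each free
#' mate is placed on the terminal region at its best offset (at most
#' `max_overhang_mismatch` substitutions over the overlap); overhanging
#' bases vote per column, and columns are appended while at least
#' `min_support` reads vote and a strict-majority base exists. An end halts
#' permanently once the appended sequence completes a telomere run; bases
#' voted beyond the completed telomere are trimmed. Interior contig bases
#' are never modified.
#'
#' @param contigs Classified contig tibble.
#' @param pairs Read-pair tibble, or a cached strict-mode alignment tibble
#'   from a previous [map_pairs()] call on the same contigs.
#' @param ext An [extension_params()].
#' @param mp A [mapper_params()] (strict mode is enforced).
#' @param spec A [telomere_spec()].
#' @return A list with elements `contigs` (extended, re-classified) and
#'   `report` (one-row tibble: ends considered/extended/capped, bases
#'   added).
#' @export
extend_ends <- function(contigs, pairs, ext = extension_params(),
                        mp = mapper_params(), spec = telomere_spec()) {
  if (!is_classified(contigs)) contigs <- classify_contigs(contigs, spec)
  mp$mode <- "strict"
  a1 <- map_reads(contigs, setNames(pairs$seq1, pairs$id), mp)
  a2 <- map_reads(contigs, setNames(pairs$seq2, pairs$id), mp)
  a1$mate <- 1L; a2$mate <- 2L
  aln <- bind_rows(a1, a2)
  other_seq <- c(setNames(pairs$seq2, sprintf("%s.1", pairs$id)),
                 setNames(pairs$seq1, sprintf("%s.2", pairs$id)))

  reach <- mp$proper_pair_max
  W <- max(2L * ext$max_round_extension, reach)
  lens <- setNames(nchar(contigs$seq), contigs$id)
  aln$ctg_len <- lens[aln$contig_id]

  bases_added <- 0L; ends_ext <- 0L; ends_capped <- 0L; ends_open <- 0L
  seqs <- setNames(contigs$seq, contigs$id)

  for (side in c("right", "left")) {
    if (side == "right") {
      open <- contigs$id[!contigs$right_telomere]
      anch <- filter(aln, .data$strand == "+",
                     .data$ctg_len - .data$end <= reach,
                     .data$contig_id %in% open)
    } else {
      open <- contigs$id[!contigs$left_telomere]
      anch <- filter(aln, .data$strand == "-", .data$start <= reach,
                     .data$contig_id %in% open)
    }
    ends_open <- ends_open + length(open)
    cand <- if (nrow(anch) == 0L) list() else
      split(paste0(anch$read_id, ".", anch$mate), anch$contig_id)
    for (cid in open) {
      s <- seqs[[cid]]
      framed <- if (side == "right") s else cpp_revcomp(s)
      tail_seq <- substr(framed, max(1L, nchar(framed) - W + 1L), nchar(framed))
      extn <- ""
      if (!is.null(cand[[cid]])) {
        # free mate in the frame where this end is a right end
        reads <- cpp_revcomp(unname(other_seq[cand[[cid]]]))
        res <- cpp_extend_end(tail_seq, reads, ext$max_overhang_mismatch,
                              ext$min_mate_overlap, ext$min_support,
                              ext$max_round_extension)
        extn <- res$ext
      }
      grew <- nchar(extn) > 0L
      framed_new <- paste0(framed, extn)
      capped <- FALSE
      if (ext$stop_at_telomere) {
        done <- install_telomere_cap(framed_new, spec)
        if (!is.null(done)) {
          framed_new <- done
          capped <- TRUE
        }
      }
      if (!grew && !capped) next
      added <- nchar(framed_new) - nchar(framed)
      seqs[[cid]] <- if (side == "right") framed_new else cpp_revcomp(framed_new)
      bases_added <- bases_added + max(0L, added)
      ends_ext <- ends_ext + 1L
      if (capped) ends_capped <- ends_capped + 1L
    }
  }

  contigs$seq <- unname(seqs[contigs$id])
  contigs <- classify_contigs(contigs, spec)
  list(contigs = contigs,
       report = tibble(ends_open = ends_open, ends_extended = ends_ext,
                       ends_capped = ends_capped, bases_added = bases_added))
}

# candidate end-overlap discovery by shared k-mers in terminal regions;
# low-complexity k-mers (< 3 distinct bases) are masked -- they cover the
# telomeric repeat, which every capped contig shares and which can never be
# an overlap junction
overlap_candidates <- function(seqs, lens, k = 16L, region = 300L) {
  rows <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]; L <- lens[i]
    for (orient in c("+", "-")) {
      so <- if (orient == "+") s else cpp_revcomp(s)
      keep <- unique(c(seq_len(min(region, L - k + 1L)),
                       max(1L, L - region - k + 2L):(L - k + 1L)))
      keep <- keep[keep >= 1L]
      kmer <- substring(so, keep, keep + k - 1L)
      ca <- stringr::str_count(kmer, "[CA]")
      cplx <- ca <= k - 3L & (k - ca) <= k - 3L  # < k-2 C/A and < k-2 G/T
      rows[[length(rows) + 1L]] <- tibble(
        kmer = kmer[cplx], ci = i, orient = orient, pos = keep[cplx] - 1L
      )
    }
  }
  bind_rows(rows)
}

#' Merge overlapping contigs
#'
#' Candidate end-overlaps are discovered through shared k-mers in terminal
#' regions (both orientations) and verified by gapless end-alignment. Pairs
#' meeting the overlap-length and identity thresholds are merged greedily in
#' descending overlap-length x identity order, with deterministic id-based
#' tie-breaking; overlap consensus takes the longer contig's base wherever
#' the two disagree. Contigs aligning wholly inside another at or above
#' `min_identity` are absorbed. A telomere-capped end is never an overlap
#' junction. Passes repeat until no merge applies.
#'
#' @param contigs Contig tibble (classified; unclassified input is
#'   classified with `spec` first).
#' @param mg A [merge_params()].
#' @param spec A [telomere_spec()].
#' @return The merged contig tibble, re-classified.
#' @export
merge_overlaps <- function(contigs, mg = merge_params(),
                           spec = telomere_spec()) {
  if (!is_classified(contigs)) contigs <- classify_contigs(contigs, spec)
  repeat {
    n0 <- nrow(contigs)
    contigs <- merge_pass(contigs, mg, spec)
    if (nrow(contigs) == n0) break
  }
  contigs
}

merge_pass <- function(contigs, mg, spec) {
  contigs <- arrange(contigs, .data$id)
  n <- nrow(contigs)
  if (n < 2L) return(contigs)
  seqs <- contigs$seq; lens <- nchar(seqs)
  km <- overlap_candidates(seqs, lens)
  hits <- inner_join(km, km, by = "kmer", suffix = c("_a", "_b"),
                     relationship = "many-to-many") %>%
    filter(.data$ci_a != .data$ci_b)
  if (nrow(hits) == 0L) return(contigs)

  # left side of a junction in forward or reverse orientation; offsets from
  # shared k-mers; mirrored duplicates are kept and resolved by the greedy
  # consumed-set
  cand <- hits %>%
    mutate(offset = .data$pos_a - .data$pos_b) %>%
    distinct(.data$ci_a, .data$orient_a, .data$ci_b, .data$orient_b,
             .data$offset) %>%
    mutate(len_a = lens[.data$ci_a], len_b = lens[.data$ci_b]) %>%
    filter(.data$offset > 0L, .data$offset < .data$len_a)

  if (nrow(cand) == 0L) return(contigs)

  oriented <- function(i, o) if (o == "+") seqs[[i]] else cpp_revcomp(seqs[[i]])
  capped <- cbind(contigs$left_telomere, contigs$right_telomere)
  end_capped <- function(i, o, which_end) {
    # which_end in the oriented frame; map back to as-given strand
    if (o == "+") capped[i, if (which_end == "right") 2L else 1L]
    else capped[i, if (which_end == "right") 1L else 2L]
  }

  scored <- purrr::pmap_dfr(cand, function(ci_a, orient_a, ci_b, orient_b,
                                           offset, len_a, len_b) {
    sa <- oriented(ci_a, orient_a); sb <- oriented(ci_b, orient_b)
    contained <- offset + len_b <= len_a
    ov <- if (contained) len_b else len_a - offset
    A <- substr(sa, offset + 1L, offset + ov)
    B <- substr(sb, 1L, ov)
    mm <- cpp_hamming(A, B)[1]
    ident <- 1 - mm / ov
    tibble(ci_a = ci_a, orient_a = orient_a, ci_b = ci_b,
           orient_b = orient_b, offset = offset, overlap = ov,
           identity = ident, contained = contained)
  })

  merges <- scored %>%
    filter((.data$contained & .data$identity >= mg$min_identity) |
             (!.data$contained & .data$overlap >= mg$min_overlap &
                .data$identity >= mg$min_identity)) %>%
    filter(.data$contained |
             (!purrr::map2_lgl(.data$ci_a, .data$orient_a, end_capped,
                               which_end = "right") &
                !purrr::map2_lgl(.data$ci_b, .data$orient_b, end_capped,
                                 which_end = "left"))) %>%
    mutate(score = .data$overlap * .data$identity,
           id_a = contigs$id[.data$ci_a], id_b = contigs$id[.data$ci_b]) %>%
    arrange(desc(.data$score), .data$id_a, .data$id_b)

  if (nrow(merges) == 0L) return(contigs)

  consumed <- rep(FALSE, n)
  out <- as.list(contigs$seq)
  names(out) <- contigs$id
  for (r in seq_len(nrow(merges))) {
    m <- merges[r, ]
    if (consumed[m$ci_a] || consumed[m$ci_b]) next
    if (m$contained) {
      consumed[m$ci_b] <- TRUE
      out[[contigs$id[m$ci_b]]] <- NULL
      next
    }
    sa <- oriented(m$ci_a, m$orient_a); sb <- oriented(m$ci_b, m$orient_b)
    la <- nchar(sa); lb <- nchar(sb)
    ovA <- substr(sa, m$offset + 1L, la)
    ovB <- substr(sb, 1L, m$overlap)
    # two-sequence column vote with ties to the longer contig reduces to
    # taking the longer contig's overlap bases wholesale
    cons <- if (la >= lb) ovA else ovB
    merged <- paste0(substr(sa, 1L, m$offset), cons,
                     substr(sb, m$overlap + 1L, lb))
    keep_id <- contigs$id[min(m$ci_a, m$ci_b)]
    drop_id <- contigs$id[max(m$ci_a, m$ci_b)]
    consumed[c(m$ci_a, m$ci_b)] <- TRUE
    out[[drop_id]] <- NULL
    out[[keep_id]] <- merged
  }
  res <- tibble(id = names(out), seq = unname(unlist(out)))
  classify_contigs(res, spec)
}

#' Remove chaff contigs
#'
#' A contig shorter than `chaff_max_len` is dropped when it aligns (either
#' strand, gapless) to a contig of at least `chaff_max_len` with coverage
#' above `chaff_min_coverage` of its length and identity above
#' `chaff_min_identity`. Dropped contigs and their absorbers are reported
#' via the `dropped` attribute.
#'
#' @param contigs Contig tibble.
#' @param mg A [merge_params()].
#' @return The filtered contig tibble.
#' @export
remove_chaff <- function(contigs, mg = merge_params()) {
  small <- which(nchar(contigs$seq) < mg$chaff_max_len)
  big <- which(nchar(contigs$seq) >= mg$chaff_max_len)
  if (length(small) == 0L || length(big) == 0L) {
    attr(contigs, "dropped") <- tibble(id = character(), absorbed_by = character())
    return(contigs)
  }
  dropped <- character(0); absorber <- character(0)
  for (i in small) {
    q <- contigs$seq[i]; ql <- nchar(q); qr <- cpp_revcomp(q)
    for (j in big) {
      hit <- FALSE
      for (qs in c(q, qr)) {
        g <- cpp_glocal(qs, contigs$seq[j], min(ql, 20L))
        if (g$overlap / ql > mg$chaff_min_coverage &&
            g$matches / g$overlap > mg$chaff_min_identity) { hit <- TRUE; break }
      }
      if (hit) {
        dropped <- c(dropped, contigs$id[i])
        absorber <- c(absorber, contigs$id[j])
        break
      }
    }
  }
  out <- contigs[!contigs$id %in% dropped, ]
  if (length(dropped)) {
    inform(sprintf("remove_chaff: dropped %d contig(s)", length(dropped)))
  }
  attr(out, "dropped") <- tibble(id = dropped, absorbed_by = absorber)
  out
}

round_metrics <- function(contigs) {
  n2 <- sum(contigs$left_telomere & contigs$right_telomere)
  n1 <- sum(xor(contigs$left_telomere, contigs$right_telomere))
  n0 <- nrow(contigs) - n2 - n1
  tibble(n_contigs = nrow(contigs), n_telomeres = 2L * n2 + n1,
         n_2tel = n2, n_1tel = n1, n_0tel = n0,
         objective = if (nrow(contigs)) n2 / nrow(contigs) else 0)
}

#' Run the telomere-finishing loop
#'
#' Iterates classify, extend, merge, chaff-removal until the objective --
#' the fraction of contigs that are complete nanochromosomes (2-telomere
#' contigs / total contigs) -- gains less than `min_gain`, or `max_rounds`
#' is reached. A round that would decrease the objective is rejected and
#' the loop stops, so the objective is monotone non-decreasing across
#' accepted rounds.
#'
#' @param contigs Draft contig tibble.
#' @param pairs Read-pair tibble.
#' @param spec A [telomere_spec()].
#' @param ext An [extension_params()].
#' @param mg A [merge_params()].
#' @param mp A [mapper_params()].
#' @param max_rounds,min_gain Stopping rule.
#' @return A `terminator_run` object: list with `contigs` (final, classified),
#'   `rounds` (per-round report tibble) and the parameter objects.
#' @export
run_terminator <- function(contigs, pairs, spec = telomere_spec(),
                           ext = extension_params(), mg = merge_params(),
                           mp = mapper_params(), max_rounds = 20L,
                           min_gain = 0.001) {
  contigs <- classify_contigs(contigs, spec)
  reports <- list()
  m0 <- round_metrics(contigs)
  obj <- m0$objective
  for (round in seq_len(max_rounds)) {
    prev <- contigs
    er <- extend_ends(contigs, pairs, ext, mp, spec)
    stage <- merge_overlaps(er$contigs, mg, spec)
    stage <- remove_chaff(stage, mg)
    stage <- classify_contigs(stage, spec)
    m <- round_metrics(stage)
    if (m$objective < obj) {
      inform(sprintf("round %d rejected (objective %.4f < %.4f)",
                     round, m$objective, obj))
      contigs <- prev
      break
    }
    gain <- m$objective - obj
    contigs <- stage
    obj <- m$objective
    reports[[round]] <- bind_cols(
      tibble(round = round, contigs_in = nrow(prev)),
      rename(m, contigs_out = "n_contigs"), er$report
    )
    if (gain < min_gain) break
  }
  rounds <- if (length(reports)) bind_rows(reports) else
    bind_cols(tibble(round = 0L, contigs_in = nrow(contigs)),
              rename(m0, contigs_out = "n_contigs"),
              tibble(ends_open = NA_integer_, ends_extended = NA_integer_,
                     ends_capped = NA_integer_, bases_added = 0L))
  structure(list(contigs = classify_contigs(contigs, spec), rounds = rounds,
                 spec = spec, ext = ext, mg = mg, mp = mp),
            class = "terminator_run")
}

#' @export
print.terminator_run <- function(x, ...) {
  last <- tail(x$rounds, 1)
  cat(sprintf(
    "<terminator_run> %d rounds; %d contigs (%d with 2 telomeres); objective %.3f\n",
    nrow(x$rounds), nrow(x$contigs),
    sum(x$contigs$left_telomere & x$contigs$right_telomere),
    last$objective
  ))
  invisible(x)
}
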