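#' Simulation parameters for a synthetic nanochromosomal genome
#'
#' Defaults emulate a stichotrich macronuclear genome sequenced with a
#' short-fragment paired-end Illumina library: gene-sized telomere-capped
#' chromosomes with lognormal length (median 2.5 kb) and lognormal copy
#' number, about 10% of chromosomes carrying an internal telomere-addition
#' site (alternative fragmentation), small Gaussian jitter of the precise
#' telomere-addition site, two haplotypes, 90-bp reads with a mean outer
#' distance of 163 bp, and 60-fold mean coverage.
#'
#' @param n_chromosomes Number of nanochromosomes.
#' @param length_meanlog,length_sdlog Lognormal chromosome-length
#'   parameters (bp); the default meanlog gives a 2,500 bp median.
#' @param length_min,length_max Hard chromosome-length bounds (bp);
#'   out-of-bound draws are resampled.
#' @param gc_content Genomic GC fraction.
#' @param telomere_len Telomere length per end (bp).
#' @param copy_sdlog Lognormal sigma of copy number; draws are rescaled to
#'   mean 1.
#' @param alt_frag_fraction Fraction of chromosomes with an internal
#'   telomere-addition site.
#' @param alt_frag_isoform_weight Abundance of each fragmentation isoform
#'   relative to its parent chromosome.
#' @param tas_jitter_sd SD (bp) of per-molecule jitter of the telomere
#'   junction coordinate.
#' @param heterozygosity Substitutions per bp between the two haplotypes.
#' @param read_len Read length (bp).
#' @param frag_mean,frag_sd Outer-distance (fragment size) mean and SD (bp).
#' @param error_rate Per-base substitution sequencing-error rate.
#' @param coverage Mean fold coverage over the parent chromosomes.
#' @param draft_trim_max Draft contigs lose Uniform(0..this) bp per end.
#' @param draft_split_fraction Fraction of chromosomes emitted as two
#'   overlapping draft contigs.
#' @param draft_split_overlap Overlap (bp) between split draft contigs.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_chromosomes = 200L, length_meanlog = log(2500),
                       length_sdlog = 0.55, length_min = 500L,
                       length_max = 20000L, gc_content = 0.35,
                       telomere_len = 20L, copy_sdlog = 0.6,
                       alt_frag_fraction = 0.10,
                       alt_frag_isoform_weight = 0.3, tas_jitter_sd = 3,
                       heterozygosity = 0.002, read_len = 90L,
                       frag_mean = 163, frag_sd = 20, error_rate = 0.001,
                       coverage = 60, draft_trim_max = 80L,
                       draft_split_fraction = 0,
                       draft_split_overlap = 60L, seed = 1L) {
  p <- as.list(environment())
  fracs <- c(p$gc_content, p$alt_frag_fraction, p$heterozygosity,
             p$error_rate, p$draft_split_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (p$frag_mean < p$read_len) abort("frag_mean must be >= read_len")
  if (p$coverage <= 0) abort("coverage must be positive")
  if (p$length_min < 2 * p$telomere_len + 100) {
    abort("length_min must be at least 2*telomere_len + 100")
  }
  structure(p, class = "sim_params")
}

# phase-0 C-rich telomere of length L, and its right-end complement
telo_left_seq <- function(L, unit = "CCCCAAAA") {
  substr(strrep(unit, ceiling(L / nchar(unit))), 1L, L)
}
telo_right_seq <- function(L, unit = "CCCCAAAA") {
  cpp_revcomp(telo_left_seq(L, unit))
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a nanochromosomal genome with planted truth
#'
#' Every chromosome begins with `telomere_len` bases of phase-0 C-rich
#' telomeric repeat and ends with its reverse complement. Alternatively
#' fragmented chromosomes carry one internal telomere-addition site at
#' least 100 bp from either telomere, producing a complementary pair of
#' isoforms: the left isoform keeps the left telomere and gains a new right
#' telomere at the breakpoint, and vice versa. A second haplotype differs by
#' i.i.d. substitutions in the genomic interior. Deterministic under a fixed
#' seed.
#'
#' @param params A [sim_params()].
#' @return A `truth_set` list with tibbles `chromosomes` (id, seq, length,
#'   copy_number, alt_frag, breakpoint), `isoforms` (id, parent, breakpoint,
#'   side, weight) and `variants` (chrom, pos, ref, alt; 0-based), plus the
#'   originating `params`.
#' @export
simulate_genome <- function(params = sim_params()) {
  withr::with_seed(params$seed, {
    n <- params$n_chromosomes
    t <- params$telomere_len

    lens <- integer(0)
    while (length(lens) < n) {
      draw <- round(rlnorm(n, params$length_meanlog, params$length_sdlog))
      draw <- draw[draw >= params$length_min & draw <= params$length_max]
      lens <- c(lens, draw)
    }
    lens <- lens[seq_len(n)]

    tl <- telo_left_seq(t); tr <- telo_right_seq(t)
    interiors <- vapply(lens - 2L * t, random_dna, character(1),
                        gc = params$gc_content)
    seqs <- paste0(tl, interiors, tr)

    cn <- rlnorm(n, 0, params$copy_sdlog)
    cn <- cn / mean(cn)

    alt <- runif(n) < params$alt_frag_fraction
    bp <- rep(NA_integer_, n)
    can <- alt & (lens - 2L * (t + 100L) > 1L)
    bp[can] <- vapply(which(can), function(i) {
      as.integer(sample((t + 100L):(lens[i] - t - 100L), 1L))
    }, integer(1))
    alt <- !is.na(bp)

    chroms <- tibble(
      id = sprintf("chr%04d", seq_len(n)), seq = seqs, length = lens,
      copy_number = cn, alt_frag = alt, breakpoint = bp
    )

    isoforms <- tibble(
      id = character(), parent = character(), breakpoint = integer(),
      side = character(), weight = double()
    )
    if (any(alt)) {
      w <- params$alt_frag_isoform_weight
      ai <- which(alt)
      isoforms <- tibble(
        id = c(sprintf("%s_L", chroms$id[ai]), sprintf("%s_R", chroms$id[ai])),
        parent = rep(chroms$id[ai], 2),
        breakpoint = rep(bp[ai], 2),
        side = rep(c("left", "right"), each = length(ai)),
        weight = rep(w * cn[ai], 2)
      )
    }

    variants <- tibble(chrom = character(), pos = integer(),
                       ref = character(), alt = character())
    if (params$heterozygosity > 0) {
      vl <- lapply(seq_len(n), function(i) {
        interior <- t:(lens[i] - t - 1L)  # 0-based, telomeres excluded
        nv <- rbinom(1L, length(interior), params$heterozygosity)
        if (nv == 0L) return(NULL)
        pos <- sort(sample(interior, nv))
        ref <- substring(seqs[i], pos + 1L, pos + 1L)
        altb <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                       character(1), USE.NAMES = FALSE)
        tibble(chrom = chroms$id[i], pos = pos, ref = ref, alt = altb)
      })
      variants <- bind_rows(variants, purrr::compact(vl))
    }

    structure(list(chromosomes = chroms, isoforms = isoforms,
                   variants = variants, params = params),
              class = "truth_set")
  })
}

# molecule table: one row per sequenced species (parents + isoforms).
# [gc_left, gc_right) is the inter-junction interval in chromosome
# coordinates; the molecule is telo_left + S[gc_left:gc_right) + telo_right.
molecule_table <- function(truth) {
  t <- truth$params$telomere_len
  ch <- truth$chromosomes
  mols <- tibble(
    mol_id = ch$id, chrom = ch$id,
    gc_left = t, gc_right = ch$length - t,
    weight = ch$copy_number
  )
  if (nrow(truth$isoforms)) {
    iso <- truth$isoforms
    pl <- ch$length[match(iso$parent, ch$id)]
    mols <- bind_rows(mols, tibble(
      mol_id = iso$id, chrom = iso$parent,
      gc_left = if_else(iso$side == "left", t, iso$breakpoint),
      gc_right = if_else(iso$side == "left", iso$breakpoint, pl - t),
      weight = iso$weight
    ))
  }
  mols
}

# apply haplotype-2 variants to chromosome sequences
hap2_seqs <- function(truth) {
  seqs <- setNames(truth$chromosomes$seq, truth$chromosomes$id)
  if (nrow(truth$variants)) {
    for (cid in unique(truth$variants$chrom)) {
      v <- truth$variants[truth$variants$chrom == cid, ]
      s <- seqs[[cid]]
      for (j in seq_len(nrow(v))) substr(s, v$pos[j] + 1L, v$pos[j] + 1L) <- v$alt[j]
      seqs[[cid]] <- s
    }
  }
  seqs
}

# extract [a, b) (0-based, molecule coordinates) from molecules described by
# chromosome sequence S, jittered junctions cl/cr, telomere length t.
# All arguments vectorized.
extract_molecule <- function(S, cl, cr, t, a, b, unit = "CCCCAAAA") {
  tl <- telo_left_seq(t, unit); tr <- telo_right_seq(t, unit)
  n <- length(a)
  w <- cr - cl  # genomic interior width
  p1 <- substr(rep(tl, n), pmax(a, 0L) + 1L, pmin(b, t))
  p1[pmax(a, 0L) >= pmin(b, t)] <- ""
  s2 <- pmax(a - t, 0L); e2 <- pmin(b - t, w)
  p2 <- stringr::str_sub(S, cl + s2 + 1L, cl + e2)
  p2[s2 >= e2] <- ""
  s3 <- pmax(a - t - w, 0L); e3 <- pmin(b - t - w, t)
  p3 <- substr(rep(tr, n), s3 + 1L, e3)
  p3[s3 >= e3] <- ""
  paste0(p1, p2, p3)
}

#' Simulate paired-end reads from a truth set
#'
#' Fragments are drawn with probability proportional to molecule weight
#' (copy number) times molecule length; outer distances are
#' Normal(`frag_mean`, `frag_sd`) truncated to the feasible range; each
#' molecule's telomere junctions are jittered by Normal(0, `tas_jitter_sd`);
#' mates are inward-oriented with the sequenced strand randomized;
#' substitution errors are i.i.d. at `error_rate`. Per-read provenance
#' (molecule, coordinates, haplotype, jitter, error positions) is recorded,
#' and reproduces every read exactly (see `vignette("nanoterm-methods")`).
#'
#' @param truth A `truth_set` from [simulate_genome()].
#' @param params A [sim_params()]; defaults to the truth set's own.
#' @param n_pairs Number of pairs; default derived from `coverage`.
#' @return A list with tibbles `pairs` (id, seq1, qual1, seq2, qual2) and
#'   `provenance`.
#' @export
simulate_reads <- function(truth, params = truth$params, n_pairs = NULL) {
  withr::with_seed(params$seed + 1L, {
    t <- params$telomere_len
    rl <- params$read_len
    mols <- molecule_table(truth)
    ch <- truth$chromosomes
    if (is.null(n_pairs)) {
      n_pairs <- round(params$coverage * sum(ch$length) / (2 * rl))
    }
    mol_len <- 2L * t + (mols$gc_right - mols$gc_left)
    exp_pairs <- n_pairs * (mols$weight * mol_len) / sum(mols$weight * mol_len)
    if (any(exp_pairs < 1)) {
      warn(sprintf("%d molecule(s) expect < 1 read pair at this coverage",
                   sum(exp_pairs < 1)))
    }

    mi <- sample.int(nrow(mols), n_pairs, replace = TRUE,
                     prob = mols$weight * mol_len)

    jl <- as.integer(round(rnorm(n_pairs, 0, params$tas_jitter_sd)))
    jr <- as.integer(round(rnorm(n_pairs, 0, params$tas_jitter_sd)))
    # jittered junctions, kept inside the genomic interval of the parent
    cl <- pmin(pmax(mols$gc_left[mi] + jl, 0L), mols$gc_right[mi] - 1L)
    cr <- pmax(pmin(mols$gc_right[mi] + jr, ch$length[match(mols$chrom[mi], ch$id)]),
               cl + 1L)
    mlen <- 2L * t + (cr - cl)

    d <- as.integer(round(rnorm(n_pairs, params$frag_mean, params$frag_sd)))
    d <- pmin(pmax(d, rl), mlen)
    # random fragmentation yields two terminal fragments per molecule, so a
    # size-selected fragment is molecule-terminal with probability ~d/mlen
    # per end; interior fragments start uniformly
    u <- runif(n_pairs)
    p_term <- d / mlen
    f <- as.integer(floor(runif(n_pairs) * (mlen - d + 1L)))
    f[u < p_term] <- 0L
    term_r <- u >= p_term & u < 2 * p_term
    f[term_r] <- (mlen - d)[term_r]

    hap <- sample(1:2, n_pairs, replace = TRUE)
    S1 <- setNames(ch$seq, ch$id)
    S2 <- hap2_seqs(truth)
    src <- if_else(hap == 1L, S1[mols$chrom[mi]], S2[mols$chrom[mi]])

    frag <- extract_molecule(src, cl, cr, t, f, f + d, params$unit %||% "CCCCAAAA")
    r1 <- substr(frag, 1L, rl)
    r2 <- cpp_revcomp(substr(frag, d - rl + 1L, d))

    swap <- runif(n_pairs) < 0.5  # sequence the fragment from its other strand
    seq1 <- if_else(swap, r2, r1)
    seq2 <- if_else(swap, r1, r2)

    err1 <- inject_errors(seq1, params$error_rate)
    err2 <- inject_errors(seq2, params$error_rate)

    qual <- strrep("I", rl)
    ids <- sprintf("read%07d", seq_len(n_pairs))
    pairs <- tibble(id = ids, seq1 = err1$seq, qual1 = qual,
                    seq2 = err2$seq, qual2 = qual)
    provenance <- tibble(
      id = ids, molecule = mols$mol_id[mi], chrom = mols$chrom[mi],
      hap = hap, junction_left = cl, junction_right = cr,
      frag_start = f, frag_len = d, swapped = swap,
      errors1 = err1$log, errors2 = err2$log
    )
    list(pairs = pairs, provenance = provenance)
  })
}

# substitution errors at i.i.d. rate; returns mutated seqs plus a log of
# "pos:base" entries (1-based within the stored read)
inject_errors <- function(seqs, rate) {
  n <- length(seqs)
  log <- character(n)
  if (rate > 0 && n > 0) {
    L <- nchar(seqs[1])
    ne <- rbinom(n, L, rate)
    hit <- which(ne > 0)
    for (i in hit) {
      pos <- sample.int(L, ne[i])
      entries <- character(ne[i])
      for (k in seq_along(pos)) {
        old <- substr(seqs[i], pos[k], pos[k])
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        substr(seqs[i], pos[k], pos[k]) <- new
        entries[k] <- paste0(pos[k], ":", new)
      }
      log[i] <- paste(entries[order(pos)], collapse = ";")
    }
  }
  list(seq = seqs, log = log)
}

# reconstruct a stored read pair from provenance (used by tests to verify
# the conservation invariant)
reconstruct_pair <- function(truth, prov) {
  p <- truth$params
  t <- p$telomere_len; rl <- p$read_len
  src <- if (prov$hap == 1L) {
    truth$chromosomes$seq[truth$chromosomes$id == prov$chrom]
  } else {
    hap2_seqs(truth)[[prov$chrom]]
  }
  frag <- extract_molecule(src, prov$junction_left, prov$junction_right, t,
                           prov$frag_start, prov$frag_start + prov$frag_len)
  r1 <- substr(frag, 1L, rl)
  r2 <- cpp_revcomp(substr(frag, prov$frag_len - rl + 1L, prov$frag_len))
  if (prov$swapped) { tmp <- r1; r1 <- r2; r2 <- tmp }
  apply_err <- function(s, log) {
    if (is.na(log) || log == "") return(s)
    for (e in strsplit(log, ";")[[1]]) {
      kv <- strsplit(e, ":")[[1]]
      substr(s, as.integer(kv[1]), as.integer(kv[1])) <- kv[2]
    }
    s
  }
  list(seq1 = apply_err(r1, prov$errors1), seq2 = apply_err(r2, prov$errors2))
}

#' Degrade a truth set into a draft assembly
#'
#' Emits one contig per parent chromosome with Uniform(0..`draft_trim_max`)
#' bases removed from each end, emulating assembler telomere loss. A
#' `draft_split_fraction` of chromosomes is instead emitted as two
#' overlapping contigs (overlap `draft_split_overlap` bp) to exercise
#' overlap merging. The truth alignment of every contig is recorded in the
#' `source_chrom`/`source_start` columns.
#'
#' @param truth A `truth_set`.
#' @param params A [sim_params()]; defaults to the truth set's own.
#' @return Contig tibble with columns `id`, `seq`, `length`,
#'   `source_chrom`, `source_start`.
#' @export
make_draft <- function(truth, params = truth$params) {
  withr::with_seed(params$seed + 2L, {
    ch <- truth$chromosomes
    n <- nrow(ch)
    trim_l <- sample.int(params$draft_trim_max + 1L, n, replace = TRUE) - 1L
    trim_r <- sample.int(params$draft_trim_max + 1L, n, replace = TRUE) - 1L
    if (any(trim_l + trim_r >= ch$length)) abort("trim exceeds chromosome length")
    split <- runif(n) < params$draft_split_fraction

    rows <- lapply(seq_len(n), function(i) {
      s <- substr(ch$seq[i], trim_l[i] + 1L, ch$length[i] - trim_r[i])
      L <- nchar(s)
      if (split[i] && L >= 2L * params$draft_split_overlap + 80L) {
        mid <- L %/% 2L
        ov <- params$draft_split_overlap
        a <- substr(s, 1L, mid + ov %/% 2L)
        b <- substr(s, mid - (ov - ov %/% 2L) + 1L, L)
        tibble(id = paste0("ctg_", ch$id[i], c("a", "b")),
               seq = c(a, b), length = nchar(c(a, b)),
               source_chrom = ch$id[i],
               source_start = c(trim_l[i], trim_l[i] + mid - (ov - ov %/% 2L)))
      } else {
        tibble(id = paste0("ctg_", ch$id[i]), seq = s, length = L,
               source_chrom = ch$id[i], source_start = trim_l[i])
      }
    })
    bind_rows(rows)
  })
}

#' Write a complete simulation to disk
#'
#' Emits `truth.fasta`, `truth_tables.tsv`, `draft.fasta`,
#' `reads_1.fastq.gz`, `reads_2.fastq.gz`, `provenance.tsv` and a run
#' manifest into `dir`.
#'
#' @param truth A `truth_set`.
#' @param reads Result of [simulate_reads()].
#' @param draft Result of [make_draft()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, reads, draft, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(truth$chromosomes, file.path(dir, "truth.fasta"))
  readr::write_tsv(select(truth$chromosomes, -"seq"),
                   file.path(dir, "truth_tables.tsv"))
  if (nrow(truth$isoforms)) {
    readr::write_tsv(truth$isoforms, file.path(dir, "truth_isoforms.tsv"))
  }
  write_fasta(draft, file.path(dir, "draft.fasta"))
  write_fastq_pairs(reads$pairs, file.path(dir, "reads_1.fastq.gz"),
                    file.path(dir, "reads_2.fastq.gz"))
  readr::write_tsv(reads$provenance, file.path(dir, "provenance.tsv"))
  write_manifest(dir, run_config(sim = truth$params, seed = truth$params$seed),
                 extra = list(n_chromosomes = nrow(truth$chromosomes),
                              n_pairs = nrow(reads$pairs),
                              n_draft_contigs = nrow(draft)))
  invisible(dir)
}
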