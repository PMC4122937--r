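# Fixtures and independent brute-force oracles used across the suite.

rnd_dna <- function(n, gc = 0.35) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

TELO_L <- "CCCCAAAACCCCAAAACCCC"
TELO_R <- "GGGGTTTTGGGGTTTTGGGG"

# telomere-capped test chromosome; junction-adjacent interior bases are
# forced off the repeat phase so the cap length is exactly 20 by construction
capped_contig <- function(interior) {
  if (substr(interior, 1, 1) == "A") substr(interior, 1, 1) <- "G"
  if (substr(interior, nchar(interior), nchar(interior)) == "T") {
    substr(interior, nchar(interior), nchar(interior)) <- "C"
  }
  paste0(TELO_L, interior, TELO_R)
}

# brute-force maximal telomeric prefix: walk the infinite repetition of the
# unit character by character
strip_oracle <- function(seq, unit = "CCCCAAAA") {
  u <- strsplit(unit, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  L <- 0L
  while (L < length(s) && s[L + 1L] == u[(L %% length(u)) + 1L]) L <- L + 1L
  L
}

# brute-force sliding-window repeat scorer for contig-end classification:
# every start offset within the end window, every repeat phase, both the
# C-rich and G-rich pattern; run budget is max_mm per complete 20 bp and a
# run must end on >= 4 consecutive matching bases
telo_run_oracle <- function(seq, spec = telomere_spec()) {
  score_left <- function(s, unit) {
    u <- strsplit(unit, "")[[1]]
    ch <- strsplit(s, "")[[1]]
    best <- 0L
    for (st in 0:min(spec$end_window, length(ch) - 1L)) {
      for (p in 0:(length(u) - 1L)) {
        mm <- 0L; consec <- 0L
        for (i in seq_len(length(ch) - st)) {
          ok <- ch[st + i] == u[((p + i - 1L) %% length(u)) + 1L]
          if (ok) consec <- consec + 1L else { mm <- mm + 1L; consec <- 0L }
          allowed <- spec$max_mismatch_per_20bp * (i %/% 20L)
          if (ok && mm <= allowed && (consec >= 4L || consec == i) && i > best)
            best <- i
        }
      }
    }
    best
  }
  both <- function(s) max(score_left(s, spec$unit),
                          score_left(s, revcomp(spec$unit)))
  left <- both(seq)
  right <- both(revcomp(seq))
  c(left = if (left >= spec$min_contig_run) left else 0L,
    right = if (right >= spec$min_contig_run) right else 0L)
}

# exhaustive full-length Hamming minimizer over all placements and both
# strands (Biostrings C path, independent of the package's seeded mapper);
# returns NULL when no full placement has <= max_mm mismatches
oracle_map_one <- function(read, contigs, max_mm = 9L) {
  best <- NULL
  for (strand in c("+", "-")) {
    q <- Biostrings::DNAString(if (strand == "+") read else revcomp(read))
    for (ci in seq_len(nrow(contigs))) {
      subj <- Biostrings::DNAString(contigs$seq[ci])
      np <- length(subj) - length(q) + 1L
      if (np < 1L) next
      d <- Biostrings::neditStartingAt(q, subj, starting.at = seq_len(np),
                                       with.indels = FALSE)
      j <- which.min(d)
      cand <- list(mm = d[j], ci = ci, start = j - 1L, strand = strand)
      if (cand$mm <= max_mm && (is.null(best) ||
          cand$mm < best$mm ||
          (cand$mm == best$mm && (cand$ci < best$ci ||
            (cand$ci == best$ci && (cand$start < best$start ||
              (cand$start == best$start && strand == "+"))))))) {
        best <- cand
      }
    }
  }
  best
}

# a read sampled from a contig with a chosen number of substitutions
mutated_read <- function(contigs, len = 90L, n_sub = 0L) {
  i <- sample(nrow(contigs), 1L)
  s <- sample(nchar(contigs$seq[i]) - len + 1L, 1L)
  r <- substr(contigs$seq[i], s, s + len - 1L)
  if (n_sub > 0L) {
    for (p in sample(len, n_sub)) {
      substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(r, p, p)), 1L)
    }
  }
  if (runif(1) < 0.5) r <- revcomp(r) else r
}

small_sim <- function(n = 15L, seed = 1L, ...) {
  p <- sim_params(n_chromosomes = n, seed = seed, ...)
  truth <- simulate_genome(p)
  list(params = p, truth = truth, reads = simulate_reads(truth),
       draft = make_draft(truth))
}
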