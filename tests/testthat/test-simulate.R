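test_that("genome simulation honours counts, caps and bounds", {
  p <- sim_params(n_chromosomes = 10, alt_frag_fraction = 0, seed = 21)
  truth <- simulate_genome(p)
  expect_equal(nrow(truth$chromosomes), 10L)
  expect_equal(nrow(truth$isoforms), 0L)
  expect_true(all(startsWith(truth$chromosomes$seq, TELO_L)))
  expect_true(all(endsWith(truth$chromosomes$seq, TELO_R)))
  expect_true(all(truth$chromosomes$length >= p$length_min))
  expect_true(all(truth$chromosomes$length <= p$length_max))
  expect_equal(mean(truth$chromosomes$copy_number), 1, tolerance = 1e-12)
})

test_that("about the configured fraction of chromosomes is alternatively fragmented", {
  p <- sim_params(n_chromosomes = 100, alt_frag_fraction = 0.10, seed = 22)
  truth <- simulate_genome(p)
  n_alt <- sum(truth$chromosomes$alt_frag)
  # 10 +/- 3 binomial SD
  expect_gt(n_alt, 10 - 3 * sqrt(100 * 0.1 * 0.9))
  expect_lt(n_alt, 10 + 3 * sqrt(100 * 0.1 * 0.9))
  expect_equal(nrow(truth$isoforms), 2L * n_alt)
  # breakpoints strictly internal, >= 100 bp from either telomere
  bp <- truth$chromosomes$breakpoint[truth$chromosomes$alt_frag]
  len <- truth$chromosomes$length[truth$chromosomes$alt_frag]
  expect_true(all(bp >= 120 & bp <= len - 120))
})

test_that("isoforms are a parent prefix or suffix plus a fresh cap", {
  p <- sim_params(n_chromosomes = 40, alt_frag_fraction = 0.3, seed = 23)
  truth <- simulate_genome(p)
  t <- p$telomere_len
  mols <- nanoterm:::molecule_table(truth)
  iso <- mols[!mols$mol_id %in% truth$chromosomes$id, ]
  for (i in seq_len(nrow(iso))) {
    parent <- truth$chromosomes$seq[truth$chromosomes$id == iso$chrom[i]]
    core <- substr(parent, iso$gc_left[i] + 1L, iso$gc_right[i])
    full <- paste0(TELO_L, core, TELO_R)
    if (endsWith(iso$mol_id[i], "_L")) {
      expect_equal(substr(full, 1, nchar(full) - t),
                   substr(parent, 1, iso$gc_right[i]))
    } else {
      expect_equal(substr(full, t + 1, nchar(full)),
                   substr(parent, iso$gc_left[i] + 1L, nchar(parent)))
    }
  }
})

test_that("simulation is byte-deterministic under a fixed seed", {
  p <- sim_params(n_chromosomes = 8, seed = 24, coverage = 15)
  a <- simulate_genome(p); b <- simulate_genome(p)
  expect_identical(a$chromosomes, b$chromosomes)
  expect_identical(a$variants, b$variants)
  ra <- simulate_reads(a); rb <- simulate_reads(b)
  expect_identical(ra$pairs, rb$pairs)
  expect_identical(ra$provenance, rb$provenance)
  da <- make_draft(a); db <- make_draft(b)
  expect_identical(da, db)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, ra, da, d1); write_simulation(b, rb, db, d2)
  for (f in c("truth.fasta", "draft.fasta", "provenance.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("provenance reproduces every read from truth exactly", {
  sim <- small_sim(n = 10, seed = 25, coverage = 20)
  idx <- sample(nrow(sim$reads$pairs), 200)
  for (i in idx) {
    rec <- nanoterm:::reconstruct_pair(sim$truth, sim$reads$provenance[i, ])
    expect_identical(rec$seq1, sim$reads$pairs$seq1[i])
    expect_identical(rec$seq2, sim$reads$pairs$seq2[i])
  }
})

test_that("error-free reads are exact substrings of truth or its reverse complement", {
  p <- sim_params(n_chromosomes = 1, alt_frag_fraction = 0, error_rate = 0,
                  heterozygosity = 0, tas_jitter_sd = 0, coverage = 50,
                  length_meanlog = log(1000), seed = 26)
  truth <- simulate_genome(p)
  reads <- simulate_reads(truth)
  s <- truth$chromosomes$seq[1]
  both <- paste0(s, "NNN", revcomp(s))
  hits1 <- vapply(reads$pairs$seq1, function(r) grepl(r, both, fixed = TRUE),
                  logical(1))
  hits2 <- vapply(reads$pairs$seq2, function(r) grepl(r, both, fixed = TRUE),
                  logical(1))
  expect_true(all(hits1) && all(hits2))
})

test_that("read depth scales with copy number (4:1 within 3 binomial SD)", {
  p <- sim_params(n_chromosomes = 2, alt_frag_fraction = 0, error_rate = 0,
                  heterozygosity = 0, seed = 27, coverage = 40)
  truth <- simulate_genome(p)
  L <- 2000L
  core <- vapply(vapply(rep(L - 40L, 2), rnd_dna, character(1)),
                 capped_contig, character(1), USE.NAMES = FALSE)
  truth$chromosomes <- tibble::tibble(
    id = c("hi", "lo"), seq = core, length = L,
    copy_number = c(4, 1), alt_frag = FALSE, breakpoint = NA_integer_
  )
  truth$variants <- truth$variants[0, ]
  reads <- simulate_reads(truth)
  n_hi <- sum(reads$provenance$chrom == "hi")
  n_lo <- sum(reads$provenance$chrom == "lo")
  n <- n_hi + n_lo
  expect_gt(n_hi, n * 0.8 - 3 * sqrt(n * 0.8 * 0.2))
  expect_lt(n_hi, n * 0.8 + 3 * sqrt(n * 0.8 * 0.2))
})

test_that("depth regressed on planted copy number is tightly linear", {
  p <- sim_params(n_chromosomes = 30, alt_frag_fraction = 0, error_rate = 0,
                  heterozygosity = 0, seed = 28, coverage = 60)
  truth <- simulate_genome(p)
  reads <- simulate_reads(truth)
  depth <- table(factor(reads$provenance$chrom, truth$chromosomes$id)) * 2 /
    truth$chromosomes$length
  r <- cor(as.numeric(depth), truth$chromosomes$copy_number)
  expect_gte(r, 0.98)
  expect_gt(coef(lm(as.numeric(depth) ~ truth$chromosomes$copy_number))[2], 0)
})

test_that("draft degradation trims, splits and records truth alignment", {
  p0 <- sim_params(n_chromosomes = 10, seed = 29, draft_trim_max = 0)
  truth <- simulate_genome(p0)
  expect_identical(make_draft(truth)$seq, truth$chromosomes$seq)

  p1 <- sim_params(n_chromosomes = 100, seed = 30, draft_trim_max = 50,
                   draft_split_fraction = 0.2, draft_split_overlap = 60)
  truth1 <- simulate_genome(p1)
  draft <- make_draft(truth1)
  n_split <- sum(table(draft$source_chrom) == 2L)
  expect_gt(n_split, 20 - 3 * sqrt(100 * 0.2 * 0.8))
  expect_lt(n_split, 20 + 3 * sqrt(100 * 0.2 * 0.8))
  # every draft contig is the recorded substring of its source chromosome
  src <- setNames(truth1$chromosomes$seq, truth1$chromosomes$id)
  for (i in seq_len(nrow(draft))) {
    expect_identical(draft$seq[i],
                     substr(src[[draft$source_chrom[i]]],
                            draft$source_start[i] + 1L,
                            draft$source_start[i] + nchar(draft$seq[i])))
  }
  # split halves overlap by the configured amount
  two <- names(which(table(draft$source_chrom) == 2L))[1]
  halves <- draft[draft$source_chrom == two, ]
  ov <- halves$source_start[1] + nchar(halves$seq[1]) - halves$source_start[2]
  expect_equal(ov, 60L)
})

test_that("infeasible parameters are rejected", {
  expect_error(sim_params(length_min = 100), "telomere_len")
  expect_error(sim_params(frag_mean = 50), "read_len")
  expect_error(sim_params(coverage = 0), "coverage")
  expect_error(sim_params(alt_frag_fraction = 1.2), "fraction")
})
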