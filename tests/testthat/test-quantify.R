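test_that("reads-per-base arithmetic and zero-read contigs", {
  withr::local_seed(101)
  ctg <- tibble::tibble(id = c("cov", "empty"),
                        seq = c(rnd_dna(1000), rnd_dna(800)))
  n_pairs <- 250L
  starts <- sample(911L, n_pairs, replace = TRUE)
  pairs <- tibble::tibble(
    id = sprintf("r%03d", seq_len(n_pairs)),
    seq1 = substring(ctg$seq[1], starts, starts + 89L), qual1 = "I",
    seq2 = revcomp(substring(ctg$seq[1], starts, starts + 89L)), qual2 = "I"
  )
  est <- estimate_copy_number(ctg, pairs)
  expect_equal(est$contig_id, c("cov", "empty"))  # sorted, zero-read retained
  expect_equal(est$mapped_reads, c(500L, 0L))     # each mate counted once
  expect_equal(est$reads_per_base, c(0.5, 0))
  expect_equal(attr(est, "total_mapped"), 500L)
})

test_that("library normalization reproduces the ratio-of-totals factor", {
  est <- function(total, rpb) {
    e <- tibble::tibble(contig_id = sprintf("c%d", seq_along(rpb)),
                        length = 1000L, mapped_reads = 0L,
                        reads_per_base = rpb, normalized_rpb = rpb)
    attr(e, "total_mapped") <- total
    e
  }
  a <- est(1242000L, c(0.5, 1.0, 2.0))
  b <- est(1000000L, c(0.4, 0.9, 1.8))
  norm <- suppressMessages(normalize_libraries(a, b))
  expect_equal(norm$factor, 1.242)
  expect_equal(norm$b$normalized_rpb, c(0.4, 0.9, 1.8) * 1.242)
  expect_equal(norm$a$normalized_rpb, a$reads_per_base)     # larger unchanged
  expect_equal(order(norm$b$normalized_rpb), order(b$reads_per_base))

  eq <- suppressMessages(normalize_libraries(a, a))
  expect_equal(eq$factor, 1)
  expect_equal(eq$b$normalized_rpb, a$reads_per_base)
  expect_error(normalize_libraries(a, est(0L, 1)), "zero")
})

test_that("ortholog correlation: perfect linearity, identity, permutation null", {
  withr::local_seed(102)
  n <- 40L
  rpb <- rlnorm(n, 0, 0.5)
  mk <- function(vals, side) {
    e <- tibble::tibble(contig_id = sprintf("%s%02d", side, seq_len(n)),
                        length = 1000L, mapped_reads = 100L,
                        reads_per_base = vals, normalized_rpb = vals)
    attr(e, "total_mapped") <- 1000L
    e
  }
  hom <- tibble::tibble(
    contig_a = sprintf("a%02d", 1:n), gene_a = sprintf("ga%02d", 1:n),
    contig_b = sprintf("b%02d", 1:n), gene_b = sprintf("gb%02d", 1:n),
    evalue = 1e-50, reciprocal_best = TRUE
  )
  res <- correlate_orthologs(mk(rpb, "a"), mk(2 * rpb, "b"), hom)
  expect_equal(res$r, 1)
  expect_equal(res$n, n)
  expect_equal(correlate_orthologs(mk(rpb, "a"), mk(rpb, "b"), hom)$r, 1)

  # shuffled pairing: |r| within the null band from 1,000 permutations
  shuffled <- hom
  shuffled$contig_b <- sample(shuffled$contig_b)
  r_shuf <- correlate_orthologs(mk(rpb, "a"), mk(2 * rpb, "b"), shuffled)$r
  null_r <- replicate(1000, cor(rpb, sample(2 * rpb)))
  expect_lt(abs(r_shuf), quantile(abs(null_r), 0.999))

  expect_error(correlate_orthologs(mk(rpb, "a")[1:2, ], mk(rpb, "b"), hom),
               "fewer than 3")
})

test_that("single-gene restriction excludes multi-gene contigs", {
  est <- function(ids) {
    e <- tibble::tibble(contig_id = ids, length = 1000L, mapped_reads = 10L,
                        reads_per_base = seq_along(ids),
                        normalized_rpb = seq_along(ids))
    attr(e, "total_mapped") <- 100L
    e
  }
  hom <- tibble::tibble(
    contig_a = c("a1", "a2", "a3", "a4", "a4"),
    gene_a = c("g1", "g2", "g3", "g4", "g5"),
    contig_b = c("b1", "b2", "b3", "b4", "b4"),
    gene_b = c("h1", "h2", "h3", "h4", "h5"),
    evalue = 1e-20, reciprocal_best = TRUE
  )
  res <- correlate_orthologs(est(paste0("a", 1:4)), est(paste0("b", 1:4)), hom,
                             single_gene_only = TRUE)
  expect_equal(res$n, 3L)  # a4/b4 carry two genes and are excluded
})

test_that("assembly metrics decompose correctly on hand-built contigs", {
  withr::local_seed(103)
  ctg <- tibble::tibble(
    id = c("two", "one", "zero"),
    seq = c(capped_contig(rnd_dna(60)),                    # 100 bp, 2 tel
            paste0(TELO_L, rnd_dna(180)),                  # 200 bp, 1 tel
            rnd_dna(300))                                  # 300 bp, 0 tel
  )
  no_reads <- tibble::tibble(id = character(), seq1 = character(),
                             seq2 = character())
  m <- compute_metrics(ctg, no_reads)
  expect_equal(m$assembly_size, 600L)
  expect_equal(m$n_contigs, 3L)
  expect_equal(m$n_telomeres, 3L)
  expect_equal(m$mean_contig_len, 200)
  expect_equal(m$max_contig_len, 300L)
  expect_equal(c(m$n_2tel, m$n_1tel, m$n_0tel), c(1L, 1L, 1L))
  expect_equal(m$total_read_coverage_pct, 0)
  # identities hold on simulator output too
  sim <- small_sim(n = 10, seed = 104)
  ms <- suppressMessages(compute_metrics(sim$truth$chromosomes,
                                         sim$reads$pairs[1:2000, ]))
  expect_equal(ms$n_contigs, ms$n_2tel + ms$n_1tel + ms$n_0tel)
  expect_equal(ms$n_telomeres, 2L * ms$n_2tel + ms$n_1tel)
})

test_that("with clean ends and error-free reads, coverage is essentially total", {
  p <- sim_params(n_chromosomes = 12, seed = 105, error_rate = 0,
                  heterozygosity = 0, tas_jitter_sd = 0,
                  alt_frag_fraction = 0, coverage = 20)
  truth <- simulate_genome(p)
  reads <- simulate_reads(truth)
  m <- suppressMessages(compute_metrics(classify_contigs(truth$chromosomes),
                                        reads$pairs))
  expect_gte(m$total_read_coverage_pct, 99.9)
  expect_gte(m$telomeric_read_coverage_pct, 99.9)
  expect_gte(m$proper_pair_pct, 99)
})

test_that("copy-number estimates are invariant under contig reverse complement", {
  sim <- small_sim(n = 8, seed = 106, coverage = 20)
  ctg <- sim$truth$chromosomes
  fwd <- estimate_copy_number(ctg, sim$reads$pairs[1:1500, ])
  rc <- ctg
  rc$seq <- revcomp(rc$seq)
  bwd <- estimate_copy_number(rc, sim$reads$pairs[1:1500, ])
  expect_equal(fwd$mapped_reads, bwd$mapped_reads)
})

test_that("two-gene synteny flags contigs whose genes land on one partner contig", {
  gm_a <- tibble::tibble(contig = rep(c("A1", "A2", "A3"), each = 2),
                         gene = paste0("g", 1:6))
  gm_b <- tibble::tibble(contig = c("B1", "B1", "B2", "B3", "B4", "B4"),
                         gene = paste0("h", 1:6))
  hom <- tibble::tibble(
    contig_a = rep(c("A1", "A2", "A3"), each = 2),
    gene_a = paste0("g", 1:6),
    contig_b = c("B1", "B1",   # A1: both genes on B1 -> syntenic
                 "B2", "B3",   # A2: split across B2/B3 -> not
                 "B4", "B4"),  # A3: on B4 but one weak match
    gene_b = c("h1", "h2", "h3", "h4", "h5", "h6"),
    evalue = c(1e-30, 1e-30, 1e-30, 1e-30, 1e-30, 1e-5),
    reciprocal_best = TRUE
  )
  res <- two_gene_synteny(hom, gm_a, gm_b)
  expect_equal(res$summary$n_two_gene, 3L)
  expect_equal(res$summary$n_syntenic, 1L)
  expect_equal(res$summary$fraction_syntenic, 1 / 3)

  expect_error(two_gene_synteny(hom, gm_a, gm_b,
                                contigs_a = tibble::tibble(id = "A1")),
               "absent")
})

test_that("a constructed 43-of-100 table yields fraction 0.43", {
  n <- 100L
  gm_a <- tibble::tibble(contig = rep(sprintf("A%03d", 1:n), each = 2),
                         gene = sprintf("g%03d", 1:(2 * n)))
  gm_b <- tibble::tibble(contig = rep(sprintf("B%03d", 1:n), each = 2),
                         gene = sprintf("h%03d", 1:(2 * n)))
  syntenic <- seq_len(43L)
  hom <- tibble::tibble(
    contig_a = gm_a$contig, gene_a = gm_a$gene,
    contig_b = rep(sprintf("B%03d", c(syntenic, 201:257)), each = 2),
    gene_b = gm_b$gene, evalue = 1e-20, reciprocal_best = TRUE
  )
  res <- two_gene_synteny(hom, gm_a, gm_b)
  expect_equal(res$summary$fraction_syntenic, 0.43)
})
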