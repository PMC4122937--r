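test_that("merge thresholds are exact at the 40 bp / 97% boundary", {
  withr::local_seed(61)
  left <- rnd_dna(260)
  ov40 <- rnd_dna(40)
  right <- rnd_dna(220)
  a <- paste0(left, ov40)                 # 300 bp
  b <- paste0(ov40, right)                # 260 bp, exact 40 bp end overlap
  merged <- merge_overlaps(tibble::tibble(id = c("a", "b"), seq = c(a, b)))
  expect_equal(nrow(merged), 1L)
  expect_equal(nchar(merged$seq), 520L)   # 300 + 260 - 40
  expect_identical(merged$seq, paste0(left, ov40, right))

  # 39 bp overlap at 100% identity: below the length floor
  a39 <- paste0(left, substr(ov40, 1, 39))
  b39 <- paste0(substr(ov40, 1, 39), right)
  expect_equal(nrow(merge_overlaps(tibble::tibble(id = c("a", "b"),
                                                  seq = c(a39, b39)))), 2L)

  # 40 bp overlap with 2 mismatches (95%): below the identity floor
  ov_mm <- ov40
  for (p in c(5L, 25L)) {
    substr(ov_mm, p, p) <- setdiff(c("A", "C", "G", "T"), substr(ov_mm, p, p))[1]
  }
  expect_equal(nrow(merge_overlaps(tibble::tibble(
    id = c("a", "b"), seq = c(a, paste0(ov_mm, right))))), 2L)
})

test_that("a 100 bp overlap at 97% merges and consensus follows the longer contig", {
  withr::local_seed(62)
  truth <- rnd_dna(700)
  a <- substr(truth, 1, 450)              # error-free, longer
  b <- substr(truth, 351, 700)            # 100 bp overlap
  for (p in c(360L, 390L, 420L)) {        # 3 substitutions in b's overlap
    q <- p - 350L
    substr(b, q, q) <- setdiff(c("A", "C", "G", "T"), substr(b, q, q))[1]
  }
  merged <- merge_overlaps(tibble::tibble(id = c("a", "b"), seq = c(a, b)))
  expect_equal(nrow(merged), 1L)
  # overlap consensus = longer contig's bases = truth
  expect_identical(substr(merged$seq, 1, 450), substr(truth, 1, 450))
})

test_that("merging joins reverse-complement overlaps and respects capped ends", {
  withr::local_seed(63)
  truth <- rnd_dna(500)
  a <- substr(truth, 1, 300)
  b <- revcomp(substr(truth, 241, 500))   # reverse-strand partner, 60 bp ovl
  merged <- merge_overlaps(tibble::tibble(id = c("a", "b"), seq = c(a, b)))
  expect_equal(nrow(merged), 1L)
  expect_true(merged$seq == truth || merged$seq == revcomp(truth))

  # a telomere-capped end is never an overlap junction
  capped <- paste0(substr(truth, 1, 260), TELO_R)  # cap at the junction side
  partner <- substr(truth, 221, 500)
  res <- merge_overlaps(tibble::tibble(id = c("a", "b"),
                                       seq = c(capped, partner)))
  expect_equal(nrow(res), 2L)
})

test_that("chaff removal applies the 80% coverage / 90% identity rule", {
  withr::local_seed(64)
  big <- rnd_dna(5000)
  inside <- substr(big, 2001, 2400)               # 400 bp interior slice
  nomatch <- rnd_dna(400)
  partial <- paste0(substr(big, 101, 400), rnd_dna(100))  # 75% covered
  ctg <- tibble::tibble(id = c("big", "inside", "nomatch", "partial"),
                        seq = c(big, inside, nomatch, partial))
  kept <- suppressMessages(remove_chaff(ctg))
  expect_setequal(kept$id, c("big", "nomatch", "partial"))
  expect_equal(attr(kept, "dropped")$id, "inside")
  expect_equal(attr(kept, "dropped")$absorbed_by, "big")
})

test_that("pair-constrained extension rebuilds a trimmed end to the telomere", {
  p <- sim_params(n_chromosomes = 1, error_rate = 0, heterozygosity = 0,
                  tas_jitter_sd = 0, alt_frag_fraction = 0, coverage = 60,
                  length_meanlog = log(1200), seed = 65)
  truth <- simulate_genome(p)
  reads <- simulate_reads(truth)
  s <- truth$chromosomes$seq[1]
  draft <- tibble::tibble(id = "c", seq = substr(s, 1, nchar(s) - 30))
  er <- extend_ends(classify_contigs(draft), reads$pairs)
  expect_true(er$contigs$right_telomere)
  expect_identical(er$contigs$seq, s)     # exact truth terminus recovered
})

test_that("candidate mates beyond the overhang mismatch budget do not vote", {
  withr::local_seed(66)
  end_seq <- rnd_dna(60)
  clean <- paste0(substr(end_seq, 31, 60), "ACGTACGTAC")
  dirty <- clean
  for (p in c(5L, 15L)) {                 # 2 substitutions in the overlap
    substr(dirty, p, p) <- setdiff(c("A", "C", "G", "T"), substr(dirty, p, p))[1]
  }
  res <- cpp_extend_end(end_seq, c(clean, clean, dirty), 1L, 10L, 3L, 50L)
  expect_equal(res$n_used, 2L)            # the 2-mismatch read is excluded
  expect_equal(res$ext, "")               # support 2 < min_support 3
  res2 <- cpp_extend_end(end_seq, c(clean, clean, clean), 1L, 10L, 3L, 50L)
  expect_equal(res2$ext, "ACGTACGTAC")
})

test_that("a complete draft is a fixpoint of the finishing loop", {
  sim <- small_sim(n = 8, seed = 67, draft_trim_max = 0)
  run <- suppressMessages(run_terminator(sim$draft, sim$reads$pairs))
  expect_lte(nrow(run$rounds), 1L)
  expect_setequal(run$contigs$seq, sim$truth$chromosomes$seq)
  # with no mapped pairs at all, contigs are returned unchanged
  empty_pairs <- tibble::tibble(id = character(), seq1 = character(),
                                qual1 = character(), seq2 = character(),
                                qual2 = character())
  er <- extend_ends(classify_contigs(sim$draft), empty_pairs)
  expect_identical(er$contigs$seq, sim$draft$seq)
  expect_equal(er$report$bases_added, 0L)
})

test_that("split drafts are merged back and the loop recovers truth", {
  sim <- small_sim(n = 12, seed = 68, draft_split_fraction = 0.4,
                   draft_split_overlap = 60, coverage = 50)
  expect_gt(nrow(sim$draft), 12L)
  run <- suppressMessages(run_terminator(sim$draft, sim$reads$pairs))
  expect_equal(nrow(run$contigs), 12L)    # split pairs merged
  m <- nanoterm:::round_metrics(run$contigs)
  expect_gte(m$objective, 0.9)
})

test_that("the objective is monotone non-decreasing and the core is immutable", {
  sim <- small_sim(n = 10, seed = 69)
  run <- suppressMessages(run_terminator(sim$draft, sim$reads$pairs))
  expect_true(all(diff(run$rounds$objective) >= 0))
  # interior immutability: each draft core survives as an exact substring
  final <- setNames(run$contigs$seq, run$contigs$id)
  for (i in seq_len(nrow(sim$draft))) {
    out <- final[[sim$draft$id[i]]]
    if (is.null(out)) next                # merged away under another id
    expect_true(grepl(sim$draft$seq[i], out, fixed = TRUE))
  }
})

test_that("finishing reports tidy round summaries and a one-row glance", {
  sim <- small_sim(n = 6, seed = 70)
  run <- suppressMessages(run_terminator(sim$draft, sim$reads$pairs))
  td <- tidy(run)
  expect_true(all(c("round", "objective", "n_2tel", "bases_added") %in%
                    names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_contigs, nrow(run$contigs))
  expect_s3_class(autoplot(run), "ggplot")
})
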