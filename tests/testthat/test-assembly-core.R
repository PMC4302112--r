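test_that("coverage separates strands and spliced segments", {
  reads <- dplyr::bind_rows(
    stack_reads(2, 100, 149, strand = "+"),
    r_spliced("sp", list(c(100, 129), c(330, 349)), strand = "+"))
  cov <- build_coverage(reads, c(chrT = 500L))
  d <- cov_vec(cov, "chrT", "+")
  expect_equal(unique(d[100:149]), 2L)
  expect_equal(sum(d), 100L)
  s <- cov_vec(cov, "chrT", "+", "spliced_depth")
  expect_equal(unique(s[100:129]), 1L)
  expect_equal(unique(s[130:329]), 0L)
  expect_equal(unique(s[330:349]), 1L)
  # empty read set: all-zero tracks
  cov0 <- build_coverage(reads[0, ], c(chrT = 10L))
  expect_true(all(vapply(cov0$depth, sum, 0) == 0))
  # out-of-bounds segment is a consistency error
  expect_error(build_coverage(r1("x", 490, 539), c(chrT = 500L)), "beyond")
})

test_that("overlapping reads join into blocks; short gaps are force-joined", {
  p <- assembly_params(min_reads = 1, min_gap_forced_join = 20)
  b <- build_blocks(dplyr::bind_rows(r1("a", 1, 50), r1("b", 30, 80)), p)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end, b$read_count), c(1, 80, 2))

  # gap of 9 < 20 joins; mean coverage counts internal zero-depth positions
  b <- build_blocks(dplyr::bind_rows(r1("a", 1, 50), r1("b", 60, 110)), p)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(1, 110))
  expect_equal(b$mean_coverage, 101 / 110)  # 50 + 51 aligned bases over span 110

  # gap of exactly min_gap splits
  b <- build_blocks(dplyr::bind_rows(r1("a", 1, 50), r1("b", 71, 120)), p)
  expect_equal(nrow(b), 2L)

  # strand separation
  b <- build_blocks(dplyr::bind_rows(r1("a", 1, 50, "+"), r1("b", 10, 60, "-")),
                    p)
  expect_equal(nrow(b), 2L)
  expect_setequal(b$strand, c("+", "-"))

  # the read-count filter removes small components
  reads3 <- dplyr::bind_rows(r1("a", 1, 50), r1("b", 20, 70), r1("c", 40, 90))
  expect_equal(nrow(build_blocks(reads3, assembly_params(min_reads = 5))), 0L)
  expect_equal(nrow(build_blocks(reads3, assembly_params(min_reads = 3))), 1L)
})

test_that("build_blocks matches the brute-force interval-union oracle", {
  for (seed in 1:20) {
    reads <- random_reads(n = 40 + seed * 7, genome_len = 3000, seed = seed)
    p <- assembly_params(min_reads = 1 + seed %% 4,
                         min_gap_forced_join = 5 + (seed * 13) %% 60)
    got <- build_blocks(reads, p)[, c("chrom", "strand", "start", "end",
                                      "read_count")]
    want <- oracle_blocks(reads, p$min_gap_forced_join, p$min_reads)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("raising min_reads never increases block count", {
  reads <- random_reads(300, genome_len = 8000, seed = 42)
  counts <- vapply(1:8, function(mr) {
    nrow(build_blocks(reads, assembly_params(min_reads = mr)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("blocks are assigned to same-strand overlapping genes in order", {
  ann <- dplyr::bind_rows(mk_gene("G1", 1000, 2000),
                          mk_gene("G2", 2500, 3500),
                          mk_gene("G3", 5000, 6000, strand = "-"))
  b <- classify_blocks(mk_block(1050, 1400, 10), ann)
  expect_equal(b$genes[[1]], "G1")
  # antisense overlap does not assign
  b <- classify_blocks(mk_block(1050, 1400, 10, strand = "-"), ann)
  expect_equal(b$genes[[1]], character())
  # spanning two genes lists both in genomic order
  b <- classify_blocks(mk_block(1500, 2600, 10), ann)
  expect_equal(b$genes[[1]], c("G1", "G2"))
})

test_that("gap statistics are the mean and sample SD over within-gene pairs", {
  blocks <- dplyr::bind_rows(
    mk_block(1, 100, 10, "A"),    mk_block(111, 200, 20, "A"),    # gap 10
    mk_block(301, 400, 30, "B"),  mk_block(421, 500, 30, "B"),    # gap 20
    mk_block(601, 700, 8, "C"),   mk_block(731, 800, 16, "C"))    # gap 30
  s <- compute_gap_stats(blocks)
  expect_equal(s$n_pairs, 3L)
  expect_equal(s$grbb_mean, 20)
  expect_equal(s$grbb_sd, 10)
  expect_equal(s$crrbb_mean, mean(c(0.5, 1, 0.5)))

  # coverage ratio is min/max: pairs (10,20) and (30,30)
  two <- dplyr::bind_rows(
    mk_block(1, 100, 10, "A"), mk_block(111, 200, 20, "A"),
    mk_block(301, 400, 30, "B"), mk_block(421, 500, 30, "B"))
  s2 <- compute_gap_stats(two)
  expect_equal(s2$crrbb_mean, 0.75)

  # consecutive blocks of different genes contribute nothing
  s0 <- compute_gap_stats(dplyr::bind_rows(mk_block(1, 100, 10, "A"),
                                           mk_block(111, 200, 20, "B")))
  expect_equal(s0$n_pairs, 0L)
  expect_equal(s0$grbb_sd, 0)

  expect_equal(glance(s)$n_pairs, 3L)
  expect_equal(tidy(s)$mean, c(20, mean(c(0.5, 1, 0.5))))
})

test_that("the 2-SD rule merges qualifying intergenic blocks and no others", {
  stats <- txblocks:::new_gap_stats(20, 10, 0.8, 0.1, 5L)
  p <- assembly_params(min_reads = 1)
  ref <- mk_block(100, 200, 10, "G")

  # gap 15 <= 40 and ratio 0.9 >= 0.6: merged, span and coverage recomputed
  merged <- join_intergenic_blocks(
    dplyr::bind_rows(ref, mk_block(216, 300, 9)), p, stats = stats)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100, 300))
  expect_equal(merged$genes[[1]], "G")
  expect_equal(merged$mean_coverage, (10 * 101 + 9 * 85) / 201)

  # gap 100 > 40: kept as an independent candidate transcript
  kept <- join_intergenic_blocks(
    dplyr::bind_rows(ref, mk_block(301, 400, 9)), p, stats = stats)
  expect_equal(nrow(kept), 2L)

  # coverage ratio below the band blocks the merge
  kept2 <- join_intergenic_blocks(
    dplyr::bind_rows(ref, mk_block(216, 300, 3)), p, stats = stats)
  expect_equal(nrow(kept2), 2L)

  # opposite strand never merges
  kept3 <- join_intergenic_blocks(
    dplyr::bind_rows(ref, mk_block(216, 300, 9, strand = "-")), p,
    stats = stats)
  expect_equal(nrow(kept3), 2L)
})

test_that("two-sided candidates merge toward the smaller gap", {
  stats <- txblocks:::new_gap_stats(50, 25, 0.8, 0.2, 5L)
  p <- assembly_params(min_reads = 1)
  blocks <- dplyr::bind_rows(
    mk_block(100, 200, 10, "L"),
    mk_block(231, 280, 10),          # gap 30 to L, gap 20 to R
    mk_block(301, 400, 10, "R"))
  out <- join_intergenic_blocks(blocks, p, stats = stats)
  right <- out[lengths(out$genes) > 0 & vapply(out$genes, function(g)
    "R" %in% g, TRUE), ]
  expect_equal(right$start, 231)
  expect_equal(out$end[out$start == 100], 200)
})

test_that("joining reaches a fixed point with disjoint blocks", {
  for (seed in c(3, 17, 29)) {
    reads <- random_reads(400, genome_len = 6000, seed = seed)
    ann <- dplyr::bind_rows(mk_gene("G1", 500, 1500),
                            mk_gene("G2", 3000, 4200),
                            mk_gene("G3", 900, 2100, strand = "-"))
    p <- assembly_params(min_reads = 2)
    blocks <- classify_blocks(build_blocks(reads, p), ann)
    out <- join_intergenic_blocks(blocks, p)
    expect_lte(nrow(out), nrow(blocks))
    by_grp <- split(out, paste(out$chrom, out$strand))
    for (g in by_grp) {
      g <- g[order(g$start), ]
      if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    }
    # idempotence at the fixed point
    again <- join_intergenic_blocks(out, p)
    expect_equal(nrow(again), nrow(out))
  }
})
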