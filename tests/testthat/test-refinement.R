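test_that("intron acceptance follows the spliced/unspliced boundary ratio", {
  len <- c(chrT = 2000L)
  # support 5 against boundary depth 40: ratio 0.125 >= 0.1 accepted
  reads <- make_junction_reads(501, 800, support = 5, boundary_depth = 40)
  cov <- build_coverage(reads, len)
  ic <- detect_introns(reads, cov, assembly_params())
  expect_equal(nrow(ic), 1L)
  expect_equal(c(ic$donor, ic$acceptor), c(501, 800))
  expect_equal(ic$spliced_support, 5L)
  expect_equal(ic$boundary_unspliced, 40)
  expect_equal(ic$ratio, 0.125)
  expect_true(ic$accepted)

  # support 3: ratio 0.075 rejected
  reads <- make_junction_reads(501, 800, support = 3, boundary_depth = 40)
  ic <- detect_introns(reads, build_coverage(reads, len), assembly_params())
  expect_false(ic$accepted)

  # stricter mode for junction-noisy genomes: 0.5 < 0.65 rejected
  reads <- make_junction_reads(501, 800, support = 5, boundary_depth = 10)
  ic <- detect_introns(reads, build_coverage(reads, len),
                       assembly_params(intron_ratio = 0.65))
  expect_equal(ic$ratio, 0.5)
  expect_false(ic$accepted)

  # no unspliced competition: infinite ratio, accepted
  reads <- r_spliced("only", list(c(476, 500), c(801, 825)))
  ic <- detect_introns(reads, build_coverage(reads, len), assembly_params())
  expect_equal(ic$ratio, Inf)
  expect_true(ic$accepted)
})

test_that("intron acceptance is monotone in support and anti-monotone in depth", {
  len <- c(chrT = 2000L)
  ratio_at <- function(support, depth) {
    reads <- make_junction_reads(501, 800, support, depth)
    detect_introns(reads, build_coverage(reads, len), assembly_params())$ratio
  }
  r <- vapply(c(2, 4, 8), ratio_at, numeric(1), depth = 40)
  expect_true(all(diff(r) > 0))
  r2 <- vapply(c(10, 20, 40), function(d) ratio_at(4, d), numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("within-gene blocks merge across gaps, bridging accepted introns", {
  ann <- mk_gene("G1", 1000, 3000)
  cov <- manual_coverage("chrT", {
    d <- integer(4000); d[1000:1959] <- 30L; d[2000:3000] <- 30L; d
  })
  blocks <- dplyr::bind_rows(mk_block(1000, 1959, 30, "G1"),
                             mk_block(2000, 3000, 30, "G1"))
  no_intron <- tibble::tibble(chrom = character(), strand = character(),
                              donor = integer(), acceptor = integer(),
                              spliced_support = integer(),
                              boundary_unspliced = numeric(),
                              ratio = numeric(), accepted = logical())
  drafts <- merge_within_gene(blocks, no_intron, ann, cov)
  expect_equal(nrow(drafts), 1L)
  expect_equal(c(drafts$start, drafts$end), c(1000, 3000))
  expect_equal(nrow(drafts$introns[[1]]), 0L)

  # an accepted intron in the gap is recorded and excluded from coverage
  intr <- tibble::tibble(chrom = "chrT", strand = "+", donor = 1960L,
                         acceptor = 1999L, spliced_support = 10L,
                         boundary_unspliced = 30, ratio = 1 / 3,
                         accepted = TRUE)
  drafts <- merge_within_gene(blocks, intr, ann, cov)
  expect_equal(nrow(drafts), 1L)
  expect_equal(drafts$introns[[1]]$donor, 1960L)
  expect_equal(drafts$mean_coverage, 30)  # exonic positions only

  # blocks of different genes stay separate drafts
  ann2 <- dplyr::bind_rows(mk_gene("G1", 1000, 1900), mk_gene("G2", 2100, 3000))
  blocks2 <- dplyr::bind_rows(mk_block(1000, 1900, 30, "G1"),
                              mk_block(2100, 3000, 30, "G2"))
  expect_equal(nrow(merge_within_gene(blocks2, no_intron, ann2, cov)), 2L)
})

test_that("tail trimming fires only above the coverage threshold and is idempotent", {
  d <- integer(2000)
  d[1001:1003] <- c(1L, 2L, 3L)
  d[1004:1500] <- 25L
  cov <- manual_coverage("chrT", d)
  draft <- mk_draft(1001, 1500, "G1", cov = 25)
  p <- assembly_params()

  trimmed <- trim_ends(draft, cov, p)
  expect_equal(trimmed$start, 1004L)
  expect_equal(trimmed$end, 1500L)
  expect_identical(trim_ends(trimmed, cov, p), trimmed)

  # below the threshold nothing moves
  low <- mk_draft(1001, 1500, "G1", cov = 15)
  expect_identical(trim_ends(low, cov, p), low)

  # uniform deep coverage is untouched
  cov30 <- manual_coverage("chrT", {x <- integer(2000); x[1001:1500] <- 30L; x})
  deep <- mk_draft(1001, 1500, "G1", cov = 30)
  expect_identical(trim_ends(deep, cov30, p), deep)

  # a transcript consumed entirely is dropped with a warning
  shallow_cov <- manual_coverage("chrT", {x <- integer(2000); x[1001:1500] <- 2L; x})
  ghost <- mk_draft(1001, 1500, "G1", cov = 25)
  expect_warning(out <- trim_ends(ghost, shallow_cov, p), "dropped")
  expect_equal(nrow(out), 0L)

  # trimming can be disabled outright
  expect_identical(trim_ends(draft, cov, assembly_params(trim_enabled = FALSE)),
                   draft)
})

test_that("trimming is idempotent on random coverage fixtures", {
  set.seed(99)
  p <- assembly_params()
  for (i in 1:25) {
    d <- as.integer(rpois(3000, sample(c(1, 5, 30), 1)))
    cov <- manual_coverage("chrT", d)
    s <- sample(100:1000, 1); e <- s + sample(200:1500, 1)
    draft <- mk_draft(s, e, "G1", cov = mean(d[s:e]))
    out <- suppressWarnings(trim_ends(draft, cov, p))
    expect_identical(suppressWarnings(trim_ends(out, cov, p)), out)
    if (nrow(out) == 1 && draft$mean_coverage > p$high_coverage_threshold) {
      expect_gt(d[out$start], p$trim_depth)
      expect_gt(d[out$end], p$trim_depth)
    }
    if (draft$mean_coverage <= p$high_coverage_threshold) {
      expect_identical(out, draft)
    }
  }
})

test_that("polycistronic validation requires continuous, balanced coverage", {
  ann <- dplyr::bind_rows(mk_gene("GA", 1001, 1500), mk_gene("GB", 1601, 2100))
  p <- assembly_params()
  depth_profile <- function(ga, gb, inter) {
    d <- integer(3000)
    d[1001:1500] <- ga; d[1501:1600] <- inter; d[1601:2100] <- gb
    d
  }

  # balanced genes, solid intergenic depth: validated
  d <- depth_profile(100L, 95L, 80L); d[1550] <- 12L
  draft <- mk_draft(1001, 2100, c("GA", "GB"), cov = mean(d[1001:2100]),
                    status = "candidate")
  out <- validate_polycistronic(draft, manual_coverage("chrT", d), ann, p)
  expect_equal(nrow(out), 1L)
  expect_equal(out$polycistronic_status, "validated")

  # one zero-depth intergenic base: split into two monocistronic pieces
  d0 <- depth_profile(100L, 95L, 80L); d0[1550] <- 0L
  out0 <- validate_polycistronic(draft, manual_coverage("chrT", d0), ann, p)
  expect_equal(nrow(out0), 2L)
  expect_setequal(out0$polycistronic_status, "monocistronic")
  expect_setequal(unlist(out0$covered_genes), c("GA", "GB"))  # genes conserved
  expect_true(all(out0$start != 1550 & out0$end != 1550))

  # strongly unbalanced gene depths: split despite continuous coverage
  du <- depth_profile(100L, 5L, 50L)
  draft_u <- mk_draft(1001, 2100, c("GA", "GB"), cov = mean(du[1001:2100]),
                      status = "candidate")
  outu <- validate_polycistronic(draft_u, manual_coverage("chrT", du), ann, p)
  expect_equal(nrow(outu), 2L)

  # weak intergenic coverage relative to the genes: split
  dw <- depth_profile(100L, 95L, 10L)
  outw <- validate_polycistronic(draft, manual_coverage("chrT", dw), ann, p)
  expect_equal(nrow(outw), 2L)
})

test_that("UTR lengths are signed and strand-aware", {
  ann <- mk_gene("G1", 1000, 2000)
  plus <- compute_utrs(mk_draft(950, 2100, "G1"), ann)
  expect_equal(plus$utr5_len, 50L)
  expect_equal(plus$utr3_len, 100L)

  minus <- compute_utrs(mk_draft(950, 2100, "G1", strand = "-"), ann)
  expect_equal(minus$utr5_len, 100L)
  expect_equal(minus$utr3_len, 50L)

  truncated <- compute_utrs(mk_draft(1040, 2100, "G1"), ann)
  expect_equal(truncated$utr5_len, -40L)

  none <- compute_utrs(mk_draft(100, 200), ann)
  expect_true(is.na(none$utr5_len))
})
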