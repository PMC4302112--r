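ann_cls <- dplyr::bind_rows(
  mk_gene("GC1", 1000, 2000),
  mk_gene("GT1", 4000, 4080, feature_class = "tRNA"),
  mk_gene("GN1", 5000, 5200, feature_class = "other_ncRNA"),
  mk_gene("GC2", 8000, 9000))

test_that("covered genes dominate the classification cascade", {
  p <- assembly_params()
  t <- classify_transcripts(
    dplyr::bind_rows(mk_draft(900, 2100, "GC1"),
                     mk_draft(4000, 4080, "GT1"),
                     mk_draft(5000, 5200, "GN1")),
    ann_cls, p)
  expect_equal(t$class_label, c("protein_coding", "tRNA", "other_ncRNA"))
  expect_true(all(is.na(t$anti_gene)))
})

test_that("antisense classification uses a strict majority of transcript length", {
  p <- assembly_params()
  # 80% of a 500-base transcript antisense to GC1: SAUT
  saut <- classify_transcripts(mk_draft(1601, 2100, strand = "-"), ann_cls, p)
  expect_equal(saut$class_label, "SAUT")
  expect_equal(saut$anti_gene, "GC1")
  # exactly 50%: not a SAUT, falls through to SUT
  half <- classify_transcripts(mk_draft(1751, 2250, strand = "-"), ann_cls, p)
  expect_equal(half$class_label, "SUT")
  # 40%: SUT
  minor <- classify_transcripts(mk_draft(1801, 2300, strand = "-"), ann_cls, p)
  expect_equal(minor$class_label, "SUT")
})

test_that("intergenic transcripts become SUTs named for the closest gene", {
  p <- assembly_params()
  t <- classify_transcripts(mk_draft(2301, 2500), ann_cls, p)
  expect_equal(t$class_label, "SUT")
  expect_equal(t$closest_gene, "GC1")  # 300 bases away, nearer than GT1
  # equidistant genes: the tie resolves downstream on the transcript's strand
  mid <- classify_transcripts(mk_draft(2901, 3099), ann_cls, p)
  expect_equal(mid$closest_gene, "GT1")
  mid_rev <- classify_transcripts(mk_draft(2901, 3099, strand = "-"), ann_cls, p)
  expect_equal(mid_rev$closest_gene, "GC1")
})

test_that("transcripts inside an accepted intron of a same-strand transcript
           are intronic ncRNAs", {
  p <- assembly_params()
  host <- mk_draft(900, 2100, "GC1",
                   introns = tibble::tibble(donor = 1200L, acceptor = 1700L))
  inside <- mk_draft(1300, 1500)
  t <- classify_transcripts(dplyr::bind_rows(host, inside), ann_cls, p)
  expect_equal(t$class_label, c("protein_coding", "intronic_ncRNA"))
  # antisense placement inside the intron is antisense first (cascade order):
  # it overlaps the coding gene on the opposite strand over its whole length
  anti_in <- mk_draft(1300, 1500, strand = "-")
  t2 <- classify_transcripts(dplyr::bind_rows(host, anti_in), ann_cls, p)
  expect_equal(t2$class_label[2], "SAUT")
})

test_that("classification is a total partition over the six classes", {
  p <- assembly_params()
  set.seed(7)
  drafts <- dplyr::bind_rows(lapply(1:40, function(i) {
    s <- sample(100:9500, 1)
    mk_draft(s, s + sample(100:800, 1), strand = sample(c("+", "-"), 1))
  }))
  drafts$covered_genes <- lapply(seq_len(nrow(drafts)), function(i) character())
  cls <- classify_blocks(
    dplyr::mutate(drafts, read_count = 10L), ann_cls)$genes
  drafts$covered_genes <- cls
  t <- classify_transcripts(drafts, ann_cls, p)
  expect_true(all(t$class_label %in%
                    c("protein_coding", "SAUT", "SUT", "tRNA", "other_ncRNA",
                      "intronic_ncRNA")))
  expect_false(any(t$class_label %in% c("SUT", "SAUT") &
                     lengths(t$covered_genes) > 0))
})

test_that("class_summary counts every class and orders coverage by design", {
  t <- dplyr::bind_rows(
    mk_draft(1, 100, "GC1", cov = 50), mk_draft(201, 300, "GC1", cov = 40),
    mk_draft(401, 500, "GC2", cov = 60), mk_draft(601, 700, cov = 5))
  t$class_label <- c("protein_coding", "protein_coding", "protein_coding",
                     "SUT")
  s <- class_summary(t)
  expect_equal(nrow(s), 6L)
  expect_equal(s$n[s$class_label == "protein_coding"], 3L)
  expect_equal(s$n[s$class_label == "SUT"], 1L)
  expect_equal(s$n[s$class_label == "tRNA"], 0L)
  expect_equal(s$cov_median[s$class_label == "protein_coding"], 50)

  s0 <- class_summary(t[0, ])
  expect_equal(sum(s0$n), 0L)
})

test_that("simulated antisense depths below coding depths show up in the summary", {
  sim <- sim_genome(n_genes = 8, seed = 21, n_antisense = 4)
  is_anti <- grepl("^tx_anti", sim$truth$tx_id)
  depths <- ifelse(is_anti, 8, 40)
  reads <- sim_reads(sim, depth = depths, seed = 21)
  tx <- assemble_transcriptome(reads, sim$annotation,
                               params = assembly_params(min_reads = 3))
  s <- class_summary(tx)
  expect_lt(s$cov_median[s$class_label == "SAUT"],
            s$cov_median[s$class_label == "protein_coding"])
})
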