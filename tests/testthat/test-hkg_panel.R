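ann_row <- function(sample, contig, gene, e, tpm = 1) {
  data.frame(sample_id = sample, contig_id = contig, gene_label = gene,
             e_value = e, tpm = tpm, stringsAsFactors = FALSE)
}

test_that("filter_hits applies a strict e-value cut", {
  x <- rbind(ann_row("s1", "c1", "g1", 1e-5),
             ann_row("s1", "c2", "g1", 1e-4),
             ann_row("s1", "c3", "g1", 2e-4))
  kept <- filter_hits(x)
  expect_identical(kept$contig_id, "c1")  # exactly 1e-4 is discarded
  expect_identical(nrow(filter_hits(x[0, ])), 0L)
  expect_error(filter_hits(x, e_threshold = 0), "positive")
})

test_that("build_panel intersects gene labels and picks representatives", {
  x <- rbind(
    ann_row("s1", "c1", "g1", 1e-9), ann_row("s1", "c2", "g2", 1e-8),
    ann_row("s2", "c3", "g1", 1e-7), ann_row("s2", "c4", "g2", 1e-6),
    ann_row("s3", "c5", "g1", 1e-5), ann_row("s3", "c6", "g2", 1e-9),
    ann_row("s3", "c7", "g3", 1e-20)
  )
  panel <- build_panel(x)
  expect_identical(panel$gene_labels, c("g1", "g2"))
  expect_identical(panel$n_samples, 3L)

  # representative: best e-value, then highest tpm, then contig id
  y <- rbind(ann_row("s1", "cA", "g1", 1e-9), ann_row("s1", "cB", "g1", 1e-6))
  expect_identical(build_panel(y)$representatives$contig_id, "cA")
  y <- rbind(ann_row("s1", "cA", "g1", 1e-9, tpm = 5),
             ann_row("s1", "cB", "g1", 1e-9, tpm = 50))
  expect_identical(build_panel(y)$representatives$contig_id, "cB")
  y <- rbind(ann_row("s1", "cB", "g1", 1e-9, tpm = 5),
             ann_row("s1", "cA", "g1", 1e-9, tpm = 5))
  expect_identical(build_panel(y)$representatives$contig_id, "cA")

  # order independence
  set.seed(1)
  shuffled <- x[sample(nrow(x)), ]
  expect_identical(build_panel(shuffled), build_panel(x))

  # monotonicity: adding a sample never enlarges the panel
  extra <- rbind(x, ann_row("s4", "c8", "g1", 1e-9))
  expect_true(all(build_panel(extra)$gene_labels %in% panel$gene_labels))

  lonely <- rbind(ann_row("s1", "c1", "g1", 1e-9),
                  ann_row("s2", "c2", "g2", 1e-9))
  expect_warning(p0 <- build_panel(lonely), "empty")
  expect_length(p0$gene_labels, 0L)

  dup <- rbind(ann_row("s1", "c1", "g1", 1e-9),
               ann_row("s1", "c1", "g2", 1e-9))
  expect_error(build_panel(dup), "duplicate")
})

test_that("planted shared-gene count is recovered on synthetic annotations", {
  for (seed in c(1, 42)) {
    ann <- simulate_annotation_table(n_samples = 5, n_shared = 66,
                                     n_private = 4, seed = seed)
    panel <- build_panel(filter_hits(ann))
    expect_length(panel$gene_labels, 66L)
    # brute-force oracle: intersect unique per-sample label sets on the
    # filtered table
    f <- ann[ann$e_value < 1e-4, ]
    oracle <- Reduce(intersect, lapply(split(f$gene_label, f$sample_id),
                                       unique))
    expect_setequal(panel$gene_labels, oracle)
    # decoys are shared by all samples but must be filtered out
    expect_false(any(grepl("^DECOY", panel$gene_labels)))
    unfiltered <- suppressWarnings(build_panel(ann))
    expect_true(any(grepl("^DECOY", unfiltered$gene_labels)))
  }
})

test_that("export_gene_sets writes one FASTA per gene with sample|contig ids", {
  x <- rbind(
    ann_row("s1", "c1", "g1", 1e-9), ann_row("s1", "c2", "g2", 1e-8),
    ann_row("s2", "c3", "g1", 1e-7), ann_row("s2", "c4", "g2", 1e-6),
    ann_row("s3", "c5", "g1", 1e-5), ann_row("s3", "c6", "g2", 1e-9)
  )
  panel <- build_panel(x)
  seqs <- stats::setNames(rep("ACGTACGT", 6), paste0("c", 1:6))
  dir <- withr::local_tempdir()
  paths <- export_gene_sets(panel, seqs, dir)
  expect_length(paths, 2L)
  expect_true(all(file.exists(paths)))
  g1 <- read_fasta(paths[["g1"]])
  expect_equal(nrow(g1), 3L)
  expect_setequal(g1$id, c("s1|c1", "s2|c3", "s3|c5"))

  expect_error(export_gene_sets(panel, seqs[-1], dir), "c1")
})
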