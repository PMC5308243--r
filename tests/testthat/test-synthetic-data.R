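test_that("a boundary-intron spec produces the signature and exact phase recovery", {
  spec <- synthetic_gene_spec("b1", signal_len = 22, precursor_len = 85,
                              introns = data.frame(codon = 22, phase = 1,
                                                   length = 90))
  g <- generate_gene(spec, seed = 2)
  rec <- map_to_precursor(compute_intron_phases(g$model), g$annotation)
  expect_equal(rec$phase, 1L)
  expect_equal(rec$offset_from_cleavage, 0L)
  expect_true(call_boundary_signature(rec, g$annotation)$has_boundary_phase1)
  expect_true(g$signature)
})

test_that("a protease-like spec with mixed phases is recovered exactly", {
  spec <- synthetic_gene_spec("chtp", signal_len = 18, precursor_len = 150,
                              introns = data.frame(codon = c(18, 50, 80, 110),
                                                   phase = c(1, 0, 1, 2),
                                                   length = c(88, 120, 95, 70)))
  g <- generate_gene(spec, seed = 8)
  rec <- compute_intron_phases(g$model)
  expect_equal(rec$phase, c(1L, 0L, 1L, 2L))
  expect_equal(rec$interrupted_codon_index, c(18L, 50L, 80L, 110L))
})

test_that("generation is byte-deterministic under a fixed seed", {
  spec <- venom_cohort_specs()[["ICK_KTx1"]]
  g1 <- generate_gene(spec, seed = 6)
  g2 <- generate_gene(spec, seed = 6)
  expect_identical(g1, g2)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(generate_cohort(4, seed = 33, utr5_prob = 0.5), d1)
  write_cohort(generate_cohort(4, seed = 33, utr5_prob = 0.5), d2)
  for (f in c("loci.fa", "genes.gff3", "precursors.tsv", "truth.json")) {
    l1 <- readLines(file.path(d1, f)); l2 <- readLines(file.path(d2, f))
    if (f == "genes.gff3") { l1 <- l1[-3]; l2 <- l2[-3] }  # date header
    expect_identical(l1, l2)
  }
})

test_that("all generated introns carry GT..AG termini on the coding strand", {
  set.seed(121)
  for (i in 1:12) {
    g <- generate_gene(random_gene_spec(paste0("gt", i)))
    m <- g$model
    iv <- intronsig:::intron_intervals(m)
    for (j in seq_len(nrow(iv))) {
      din <- intronsig:::intron_donor_acceptor_dinucs(
        m$sequence, min(iv$start[j], iv$end[j]),
        max(iv$start[j], iv$end[j]), m$strand)
      expect_identical(unname(din), c("GT", "AG"))
    }
  }
})

test_that("emitted files round-trip to the ground truth exactly", {
  for (seed in c(3, 14)) {
    co <- generate_cohort(10, signature_prob = 0.5, utr5_prob = 0.3,
                          introns_per_gene = 1:3, seed = seed)
    d <- tempfile()
    write_cohort(co, d)
    models <- load_gene_models(file.path(d, "genes.gff3"),
                               file.path(d, "loci.fa"))
    annots <- load_precursor_annotations(file.path(d, "precursors.tsv"))
    res <- annotate_gene_set(models, annots)
    got <- res$introns[, c("gene_id", "ordinal", "region", "phase",
                           "interrupted_codon_index", "precursor_region",
                           "offset_from_cleavage")]
    truth <- co$truth[order(co$truth$gene_id, co$truth$ordinal), ]
    got <- got[order(got$gene_id, got$ordinal), ]
    rownames(truth) <- rownames(got) <- NULL
    expect_equal(got, truth)
    sig <- vapply(co$genes, function(g) g$signature, TRUE)
    names(sig) <- vapply(co$genes, function(g) g$annotation$gene_id, "")
    expect_identical(res$calls$has_boundary_phase1,
                     unname(sig[res$calls$gene_id]))
  }
})

test_that("signature planting probabilities are honoured at the extremes", {
  co0 <- generate_cohort(60, signature_prob = 0, seed = 5, sequences = FALSE)
  expect_equal(sum(co0$signature), 0)
  co1 <- generate_cohort(12, signature_prob = 1, seed = 5, sequences = FALSE)
  expect_equal(mean(co1$signature), 1.0)
})

test_that("invalid intron placements are rejected at spec construction", {
  expect_error(synthetic_gene_spec("x", 22, 85,
                                   introns = data.frame(codon = 90, phase = 1,
                                                        length = 70)),
               "outside the CDS")
  expect_error(synthetic_gene_spec("x", 22, 85,
                                   introns = data.frame(codon = 0, phase = 0,
                                                        length = 70)),
               "outside the CDS")
  expect_error(synthetic_gene_spec("x", 22, 85,
                                   introns = data.frame(codon = c(30, 30),
                                                        phase = c(1, 1),
                                                        length = 70)),
               "strictly increasing")
  expect_error(synthetic_gene_spec("x", 22, 85, utr5_intron = c(80, 60)),
               "outside the UTR")
})

test_that("the packaged cohort files match in-memory regeneration", {
  d <- cohort12_path()
  co <- venom_cohort()
  models <- load_gene_models(file.path(d, "genes.gff3"),
                             file.path(d, "loci.fa"))
  regen <- lapply(co$genes, function(g) g$model)
  regen <- regen[order(vapply(regen, function(m) m$gene_id, ""))]
  for (i in seq_along(models)) {
    expect_identical(models[[i]]$sequence, regen[[i]]$sequence)
    expect_equal(models[[i]]$exons, regen[[i]]$exons, ignore_attr = TRUE)
  }
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_length(truth, 12)
  expect_true(all(vapply(truth, function(t) isTRUE(t$signature), TRUE)))
})
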