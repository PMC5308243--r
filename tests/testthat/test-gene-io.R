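write_mini_gff3 <- function(path, lines) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("GFF3 1-based inclusive coordinates become 0-based half-open", {
  f <- write_mini_gff3(tempfile(fileext = ".gff3"), c(
    "chr1\t.\tgene\t101\t160\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t101\t160\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\t.\texon\t101\t160\t.\t+\t.\tParent=t1",
    "chr1\t.\tCDS\t101\t160\t.\t+\t0\tParent=t1"
  ))
  models <- load_gene_models(f)
  expect_length(models, 1)
  expect_equal(models[[1]]$exons, data.frame(start = 100L, end = 160L))
  expect_equal(models[[1]]$gene_id, "g1")
})

test_that("minus-strand exons come back acceptor-first and splice like the oracle", {
  set.seed(11)
  spec <- random_gene_spec("gneg")
  spec$strand <- "-"
  g <- generate_gene(spec, seed = 5)
  d <- tempfile()
  write_cohort(list(genes = list(g)), d)
  m <- load_gene_models(file.path(d, "genes.gff3"), file.path(d, "loci.fa"))[[1]]
  # transcript orientation: first exon has the highest genomic start
  expect_true(all(diff(m$exons$start) < 0))
  expect_identical(spliced_cds(m), oracle_spliced_cds(m))
  expect_identical(spliced_cds(m), spliced_cds(g$model))
})

test_that("a signal/mature two-exon topology loads as one complete model", {
  # one intron at the end of the signal peptide, mature+propeptide second exon
  spec <- synthetic_gene_spec("kn1", signal_len = 23, precursor_len = 58,
                              mature_spans = data.frame(start = 23, end = 36),
                              propeptide_spans = data.frame(start = 36, end = 58),
                              introns = data.frame(codon = 23, phase = 1,
                                                   length = 80))
  g <- generate_gene(spec, seed = 9)
  d <- tempfile()
  write_cohort(list(genes = list(g)), d)
  models <- load_gene_models(file.path(d, "genes.gff3"), file.path(d, "loci.fa"))
  expect_length(models, 1)
  expect_equal(nrow(models[[1]]$exons), 2)
  expect_true(models[[1]]$complete)
})

test_that("spliced_cds honours strand and segment order", {
  m <- gene_model("g", "s", "+", exons = data.frame(start = 0, end = 6),
                  cds = data.frame(start = 0, end = 6), sequence = "ATGAAA")
  expect_identical(spliced_cds(m), "ATGAAA")
  mneg <- gene_model("g", "s", "-", exons = data.frame(start = 0, end = 6),
                     cds = data.frame(start = 0, end = 6), sequence = "ATGAAA")
  expect_identical(spliced_cds(mneg), "TTTCAT")
  set.seed(21)
  for (i in 1:10) {
    g <- generate_gene(random_gene_spec(paste0("r", i), max_introns = 3))
    expect_identical(spliced_cds(g$model), oracle_spliced_cds(g$model))
  }
})

test_that("translate_cds applies the standard code and flags internal stops", {
  expect_identical(translate_cds("ATGGAATAA"), "ME")
  expect_error(translate_cds("ATGTAAGAA"), "codon index 1")
  expect_error(translate_cds("ATGGA"), "multiple of 3")
  g <- generate_gene(random_gene_spec("tr1"), seed = 3)
  expect_identical(translate_cds(spliced_cds(g$model)), g$protein)
})

test_that("precursor annotations load from TSV and JSON with span inference", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsignal_len\tprecursor_len\tpropeptide_spans\tmature_spans",
               "G1\t22\t85\t\t",
               "G2\t22\t85\t22-28\t28-85",
               "G3\t23\t58\t36-58\t23-36"), tsv)
  anns <- load_precursor_annotations(tsv)
  expect_equal(anns$G1$mature_spans, data.frame(start = 22L, end = 85L))
  expect_equal(anns$G2$propeptide_spans, data.frame(start = 22L, end = 28L))
  # region order is unconstrained: mature before propeptide is fine
  expect_equal(anns$G3$mature_spans$start, 23L)
  expect_true(anns$G3$complete)

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(gene_id = "G1", signal_len = 22,
                                 precursor_len = 85)),
                       js, auto_unbox = TRUE)
  expect_equal(load_precursor_annotations(js)$G1$mature_spans$end, 85L)
})

test_that("invalid precursor annotations are rejected", {
  expect_error(precursor_annotation("g", signal_len = 0, precursor_len = 50),
               "signal_len")
  expect_error(
    precursor_annotation("g", signal_len = 22, precursor_len = 85,
                         propeptide_spans = data.frame(start = 20, end = 30)),
    "overlap")
})

test_that("GFF3 writer round-trips a model set exactly", {
  co <- generate_cohort(5, seed = 77, utr5_prob = 0.4, introns_per_gene = 1:3)
  d <- tempfile()
  write_cohort(co, d)
  models <- load_gene_models(file.path(d, "genes.gff3"), file.path(d, "loci.fa"))
  orig <- lapply(co$genes, function(g) g$model)
  orig <- orig[order(vapply(orig, function(m) m$gene_id, ""))]
  for (i in seq_along(models)) {
    expect_equal(models[[i]]$exons, orig[[i]]$exons,
                 ignore_attr = TRUE)
    expect_equal(models[[i]]$cds, orig[[i]]$cds, ignore_attr = TRUE)
    expect_identical(models[[i]]$strand, orig[[i]]$strand)
    expect_identical(models[[i]]$sequence, orig[[i]]$sequence)
  }
  # second write of the reloaded set is byte-identical
  d2 <- tempfile()
  dir.create(d2)
  write_gff3(models, file.path(d2, "g.gff3"))
  write_gff3(orig, file.path(d2, "o.gff3"))
  expect_identical(readLines(file.path(d2, "g.gff3"))[-3],
                   readLines(file.path(d2, "o.gff3"))[-3])  # [-3]: date line
})

test_that("a GenBank flat file yields the same model as its GFF3 twin", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTLOC                60 bp    DNA     linear   INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(join(5..16,31..42))",
    "                     /gene=\"tg1\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), gb)
  # the hand-written toy sequence has no real splice sites: warning expected
  m <- suppressWarnings(load_gene_models(gb))[[1]]
  expect_identical(m$gene_id, "tg1")
  expect_identical(m$strand, "-")
  expect_equal(m$exons, data.frame(start = c(30L, 4L), end = c(42L, 16L)),
               ignore_attr = TRUE)
  expect_identical(spliced_cds(m), oracle_spliced_cds(m))
})

test_that("format and validation errors are raised with context", {
  bad <- tempfile(fileext = ".gff3")
  writeLines("this is not gff", bad)
  expect_error(load_gene_models(bad))
  orphan <- write_mini_gff3(tempfile(fileext = ".gff3"),
                            "chr1\t.\tCDS\t10\t30\t.\t+\t0\tID=c1")
  expect_error(load_gene_models(orphan), "Parent")
  expect_error(gene_model("g", "s", "?", data.frame(start = 0, end = 3),
                          data.frame(start = 0, end = 3)), "strand")
})

test_that("non-canonical splice dinucleotides warn but load", {
  g <- generate_gene(synthetic_gene_spec("w1", 20, 50,
                                         introns = data.frame(codon = 20,
                                                              phase = 1,
                                                              length = 60)),
                     seed = 4)
  m <- g$model
  iv <- intronsig:::intron_intervals(m)
  substr(m$sequence, iv$start[1] + 1, iv$start[1] + 2) <- "CC"
  d <- tempfile()
  write_cohort(list(genes = list(list(model = m, annotation = g$annotation,
                                      truth = g$truth, protein = g$protein,
                                      signature = g$signature))), d)
  expect_warning(
    load_gene_models(file.path(d, "genes.gff3"), file.path(d, "loci.fa")),
    "non-canonical")
})

test_that("flipping a locus to the other strand leaves the spliced CDS unchanged", {
  set.seed(31)
  for (i in 1:10) {
    g <- generate_gene(random_gene_spec(paste0("f", i)))
    expect_identical(spliced_cds(flip_model(g$model)), spliced_cds(g$model))
  }
})
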