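# minimal hand-built model: two exons, CDS starting mid-first-exon so the
# intron interrupts after `L` coding nucleotides
two_exon_model <- function(L_before) {
  gene_model("g", "s", "+",
             exons = data.frame(start = c(0, 30), end = c(10, 60)),
             cds = data.frame(start = c(10 - L_before, 30),
                              end = c(10, 30 + (12 - L_before) %% 3 + 20)))
}

test_that("phase is the upstream coding length mod 3", {
  m0 <- gene_model("g", "s", "+",
                   exons = data.frame(start = c(0, 20), end = c(10, 40)),
                   cds = data.frame(start = c(7, 20), end = c(10, 26)))
  r0 <- compute_intron_phases(m0)
  expect_equal(r0$upstream_coding_nt, 3L)
  expect_equal(r0$phase, 0L)          # between codons
  expect_equal(r0$interrupted_codon_index, 1L)

  m1 <- gene_model("g", "s", "+",
                   exons = data.frame(start = c(0, 20), end = c(10, 40)),
                   cds = data.frame(start = c(9, 20), end = c(10, 28)))
  r1 <- compute_intron_phases(m1)
  expect_equal(r1$upstream_coding_nt, 1L)
  expect_equal(r1$phase, 1L)          # after the first nucleotide of a codon
  expect_equal(r1$interrupted_codon_index, 0L)
})

test_that("a 5'UTR intron plus a signal-end coding intron classify as in the two-intron topology", {
  spec <- synthetic_gene_spec("p05", signal_len = 28, precursor_len = 56,
                              introns = data.frame(codon = 28, phase = 1,
                                                   length = 70),
                              utr5_intron = c(25, 65))
  g <- generate_gene(spec, seed = 12)
  rec <- compute_intron_phases(g$model)
  expect_equal(rec$region, c("UTR5", "CODING"))
  expect_equal(rec$phase, c(NA_integer_, 1L))
  expect_equal(rec$ordinal, c(1L, 2L))
})

test_that("every inter-exon gap yields exactly one record", {
  set.seed(41)
  for (i in 1:25) {
    g <- generate_gene(random_gene_spec(paste0("c", i)))
    expect_equal(nrow(compute_intron_phases(g$model)),
                 nrow(g$model$exons) - 1L)
  }
})

test_that("precursor mapping places introns in regions with signed cleavage offsets", {
  ann <- precursor_annotation("g", signal_len = 22, precursor_len = 85,
                              propeptide_spans = data.frame(start = 22, end = 28),
                              mature_spans = data.frame(start = 28, end = 85))
  rec <- data.frame(gene_id = "g", ordinal = 1:3, donor = NA, acceptor = NA,
                    length = NA, region = "CODING",
                    upstream_coding_nt = c(67, 73, 31),
                    phase = c(1L, 1L, 1L),
                    interrupted_codon_index = c(22L, 24L, 10L))
  mapped <- map_to_precursor(rec, ann)
  expect_equal(mapped$precursor_region, c("PROPEPTIDE", "PROPEPTIDE", "SIGNAL"))
  expect_equal(mapped$offset_from_cleavage, c(0L, 2L, -12L))
})

test_that("annotation/CDS length mismatches are detected", {
  ann <- precursor_annotation("g", signal_len = 22, precursor_len = 40)
  rec <- data.frame(gene_id = "g", ordinal = 1, donor = NA, acceptor = NA,
                    length = NA, region = "CODING", upstream_coding_nt = 150,
                    phase = 0L, interrupted_codon_index = 50L)
  expect_error(map_to_precursor(rec, ann), "disagree")
  rec$gene_id <- "other"
  expect_error(map_to_precursor(rec, ann), "mismatch")
})

test_that("the boundary call names the nearest phase-1 intron and ignores other phases", {
  ann <- precursor_annotation("g", signal_len = 21, precursor_len = 90)
  mk <- function(codons, phases) {
    rec <- data.frame(gene_id = "g", ordinal = seq_along(codons), donor = NA,
                      acceptor = NA, length = NA, region = "CODING",
                      upstream_coding_nt = 3 * codons + phases,
                      phase = as.integer(phases),
                      interrupted_codon_index = as.integer(codons))
    map_to_precursor(rec, ann)
  }
  # boundary intron plus a deep mature phase-1 intron: the boundary one wins
  call <- call_boundary_signature(mk(c(21, 60), c(1, 1)), ann)
  expect_true(call$has_boundary_phase1)
  expect_equal(call$signature_intron_ordinal, 1L)
  expect_equal(call$offset_from_cleavage, 0L)
  # phase-0 at offset 0 is not the signature
  expect_false(call_boundary_signature(mk(21, 0), ann)$has_boundary_phase1)
  # ties in |offset| break toward the smaller ordinal
  tie <- call_boundary_signature(mk(c(20, 22), c(1, 1)), ann)
  expect_equal(tie$signature_intron_ordinal, 1L)
  expect_error(call_boundary_signature(mk(21, 1), ann, window = -1), "window")
})

test_that("widening the window never loses a signature", {
  set.seed(55)
  for (i in 1:20) {
    g <- generate_gene(random_gene_spec(paste0("w", i)))
    rec <- map_to_precursor(compute_intron_phases(g$model), g$annotation)
    flags <- vapply(0:8, function(w) {
      call_boundary_signature(rec, g$annotation, window = w)$has_boundary_phase1
    }, TRUE)
    expect_true(all(diff(flags) >= 0))
  }
})

test_that("gene-set summaries count signatures and list exceptions", {
  calls <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(gene_id = paste0("g", i), has_boundary_phase1 = i != 7,
               signature_intron_ordinal = 1L, offset_from_cleavage = 0L,
               window = 3L)
  }))
  s <- summarize_gene_set(calls)
  expect_equal(s$fraction, 0.9)
  expect_equal(s$exceptions, "g7")
  calls$has_boundary_phase1 <- TRUE
  expect_equal(summarize_gene_set(calls)$fraction, 1.0)
  expect_error(summarize_gene_set(calls[0, ]), "no boundary")
})

test_that("planted signature frequency is recovered within the binomial bound", {
  co <- generate_cohort(200, signature_prob = 0.8, seed = 101,
                        sequences = FALSE)
  genes <- lapply(co$genes, function(g) {
    rec <- map_to_precursor(g$introns, g$annotation)
    call_boundary_signature(rec, g$annotation)
  })
  frac <- summarize_gene_set(do.call(rbind, genes))$fraction
  halfw <- 2.576 * sqrt(0.8 * 0.2 / 200)
  expect_gt(frac, 0.8 - halfw)
  expect_lt(frac, 0.8 + halfw)
})

test_that("strand flip leaves ordinals, regions, phases and codon indices unchanged", {
  set.seed(61)
  for (i in 1:15) {
    spec <- random_gene_spec(paste0("s", i))
    spec$strand <- "+"
    gp <- generate_gene(spec, seed = 1000 + i)
    spec$strand <- "-"
    gm <- generate_gene(spec, seed = 1000 + i)
    cols <- c("ordinal", "region", "phase", "interrupted_codon_index")
    expect_identical(compute_intron_phases(gp$model)[, cols],
                     compute_intron_phases(gm$model)[, cols])
    # and flipping the same physical locus in place
    recf <- compute_intron_phases(flip_model(gp$model))
    expect_identical(recf[, cols], compute_intron_phases(gp$model)[, cols])
  }
})
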