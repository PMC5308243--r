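# Independent oracles used across the suite. Each is written as a direct,
# brute-force restatement of the quantity it checks, structured differently
# from the package implementation.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

# Splice oracle: reverse-complement the whole locus first (for minus-strand
# genes), transform CDS coordinates into the flipped frame, then extract in
# ascending order.
oracle_spliced_cds <- function(model) {
  seqc <- model$sequence
  cds <- model$cds
  if (model$strand == "-") {
    L <- nchar(seqc)
    seqc <- oracle_revcomp(seqc)
    cds <- data.frame(start = L - cds$end, end = L - cds$start)
  }
  cds <- cds[order(cds$start), , drop = FALSE]
  paste(substring(seqc, cds$start + 1, cds$end), collapse = "")
}

# Phase oracle: walk the transcript nucleotide-by-nucleotide over an
# exon-coordinate map; an intron sits wherever consecutive transcript
# positions have non-adjacent genomic coordinates. The coding count before
# a junction is tallied per nucleotide against the CDS coordinate set.
oracle_intron_phases <- function(model) {
  step <- if (model$strand == "+") 1L else -1L
  gcoords <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    s <- model$exons$start[i]; e <- model$exons$end[i]
    if (step == 1L) s:(e - 1L) else (e - 1L):s
  }))
  cds_set <- unlist(lapply(seq_len(nrow(model$cds)), function(i) {
    model$cds$start[i]:(model$cds$end[i] - 1L)
  }))
  is_coding <- gcoords %in% cds_set
  total <- sum(is_coding)
  junctions <- which(diff(gcoords) != step)
  out <- lapply(seq_along(junctions), function(k) {
    i <- junctions[k]
    L <- sum(is_coding[seq_len(i)])
    if (L == 0L) {
      data.frame(ordinal = k, region = "UTR5", phase = NA_integer_,
                 interrupted_codon_index = NA_integer_)
    } else if (L == total) {
      data.frame(ordinal = k, region = "UTR3", phase = NA_integer_,
                 interrupted_codon_index = NA_integer_)
    } else {
      data.frame(ordinal = k, region = "CODING", phase = L %% 3L,
                 interrupted_codon_index = L %/% 3L)
    }
  })
  if (length(out) == 0) {
    return(data.frame(ordinal = integer(0), region = character(0),
                      phase = integer(0),
                      interrupted_codon_index = integer(0)))
  }
  do.call(rbind, out)
}

# Exact multinomial p by direct enumeration with the log-gamma formula
# (probability-ordering, same tie tolerance as the implementation).
oracle_multinom_p <- function(counts, p) {
  n <- sum(counts)
  lprob <- function(k) {
    lgamma(n + 1) - sum(lgamma(k + 1)) +
      sum(ifelse(k > 0, k * log(p), 0))
  }
  lp_obs <- lprob(counts)
  tot <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    lp <- lprob(c(a, b, n - a - b))
    if (exp(lp) <= exp(lp_obs) * (1 + 1e-7)) tot <- tot + exp(lp)
  }
  min(1, tot)
}

# Fully independent small-n oracle: enumerate every assignment of the n
# introns to the three phase classes.
oracle_multinom_p_assign <- function(counts, p) {
  n <- sum(counts)
  stopifnot(n <= 7)
  grid <- do.call(expand.grid, rep(list(1:3), n))
  seq_prob <- apply(grid, 1, function(a) prod(p[a]))
  key <- apply(grid, 1, function(a) {
    paste(sum(a == 1), sum(a == 2), sum(a == 3), sep = ",")
  })
  class_prob <- tapply(seq_prob, key, sum)
  p_obs <- class_prob[[paste(counts, collapse = ",")]]
  sum(class_prob[class_prob <= p_obs * (1 + 1e-7)])
}

# Position-by-position IUPAC scan of one strand.
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

oracle_iupac_starts <- function(promoter, pattern) {
  pc <- strsplit(promoter, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  m <- length(pat); n <- length(pc)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!pc[s + j] %in% ORACLE_IUPAC[[pat[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Random synthetic gene spec for fuzzing: 1-6 coding introns, both strands,
# optional 5'UTR intron.
random_gene_spec <- function(id, max_introns = 6L) {
  slen <- sample(15:30, 1)
  plen <- slen + sample(30:120, 1)
  k <- sample(seq_len(max_introns), 1)
  juncs <- sort(sample(seq_len(3L * plen - 1L), k))
  utr5_len <- sample(40:80, 1)
  synthetic_gene_spec(
    gene_id = id, signal_len = slen, precursor_len = plen,
    introns = data.frame(codon = juncs %/% 3L, phase = juncs %% 3L,
                         length = sample(60:200, k, replace = TRUE)),
    utr5_intron = if (stats::runif(1) < 0.3) {
      c(sample(5:(utr5_len - 5), 1), sample(60:200, 1))
    },
    utr5_len = utr5_len, utr3_len = sample(30:80, 1),
    strand = sample(c("+", "-"), 1)
  )
}

# Flip a sequence-bearing model to the opposite strand frame: the same gene
# described on the reverse complement of its locus.
flip_model <- function(model) {
  L <- nchar(model$sequence)
  flip <- function(d) data.frame(start = L - d$end, end = L - d$start)
  gene_model(model$gene_id, model$seq_id,
             strand = if (model$strand == "+") "-" else "+",
             exons = flip(model$exons), cds = flip(model$cds),
             sequence = oracle_revcomp(model$sequence),
             complete = model$complete)
}
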