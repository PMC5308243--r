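#' Phase distribution of a set of intron records
#'
#' Counts coding introns by phase; UTR introns are tallied separately and
#' excluded from the proportions.
#'
#' @param introns data.frame from [compute_intron_phases()] (any number of
#'   genes row-bound).
#' @return object of class `phase_distribution` with counts `n0`, `n1`,
#'   `n2`, `n_noncoding` and `proportions` (NULL when there are no coding
#'   introns).
#' @export
phase_distribution <- function(introns) {
  ph <- introns$phase
  n0 <- sum(ph == 0L, na.rm = TRUE)
  n1 <- sum(ph == 1L, na.rm = TRUE)
  n2 <- sum(ph == 2L, na.rm = TRUE)
  nn <- sum(is.na(ph))
  tot <- n0 + n1 + n2
  structure(
    list(n0 = n0, n1 = n1, n2 = n2, n_noncoding = nn,
         proportions = if (tot > 0) c(p0 = n0, p1 = n1, p2 = n2) / tot),
    class = "phase_distribution"
  )
}

#' @export
print.phase_distribution <- function(x, ...) {
  cat("Intron phases: phase-0 ", x$n0, ", phase-1 ", x$n1, ", phase-2 ",
      x$n2, " (", x$n_noncoding, " UTR)\n", sep = "")
  if (!is.null(x$proportions)) {
    cat("  proportions:", paste(sprintf("%.3f", x$proportions),
                                collapse = " / "), "\n")
  }
  invisible(x)
}

#' Reference intron-phase proportions
#'
#' Literature phase frequencies used as the null for enrichment tests:
#' `"secretory_human"` (phase 0/1/2 = 31.36/49.9/18.8 percent, renormalised
#' to sum 1) and `"nonsecretory_human"` (50/30/20), plus `"uniform"` and
#' `"custom"`.
#'
#' @param label one of `"secretory_human"`, `"nonsecretory_human"`,
#'   `"uniform"`, `"custom"`.
#' @param p for `"custom"`, numeric length-3 vector of phase-0/1/2
#'   probabilities (renormalised).
#' @return object of class `reference_proportions`: `label` and `p`
#'   (named p0/p1/p2, summing to 1).
#' @export
reference_proportions <- function(label = c("nonsecretory_human",
                                            "secretory_human",
                                            "uniform", "custom"),
                                  p = NULL) {
  label <- match.arg(label)
  p <- switch(label,
    nonsecretory_human = c(0.50, 0.30, 0.20),
    secretory_human = c(0.3136, 0.499, 0.188),
    uniform = c(1, 1, 1) / 3,
    custom = {
      if (is.null(p) || length(p) != 3 || any(p < 0) || sum(p) <= 0) {
        stop("custom reference needs 3 non-negative probabilities")
      }
      p
    })
  p <- p / sum(p)
  names(p) <- c("p0", "p1", "p2")
  structure(list(label = label, p = p), class = "reference_proportions")
}

#' Test phase counts against reference proportions
#'
#' Goodness-of-fit of the observed phase-0/1/2 counts to a
#' [reference_proportions()] null. For totals up to `exact_max` an exact
#' multinomial test is used: the p-value is the total probability of all
#' outcome triples whose probability does not exceed the observed one.
#' Larger totals use the chi-square goodness-of-fit test (df = 2). Both
#' p-values are two-sided in the sense of the outcome ordering; direction
#' (e.g. phase-1 excess) is left to the caller via the reported counts.
#'
#' @param dist a [phase_distribution()].
#' @param ref a [reference_proportions()].
#' @param exact_max largest total for the exact path (default 30).
#' @return object of class `phase_enrichment`: `method`, `statistic`,
#'   `p_value`, `df`, `reference`, `counts`.
#' @export
phase_enrichment_test <- function(dist, ref = reference_proportions(),
                                  exact_max = 30L) {
  counts <- c(dist$n0, dist$n1, dist$n2)
  n <- sum(counts)
  if (n < 1) stop("need at least one coding intron")
  p <- ref$p
  if (any(p == 0 & counts > 0)) {
    warning("observed count in a zero-probability reference class; p = 0")
    return(structure(list(method = "exact_multinomial", statistic = 0,
                          p_value = 0, df = NULL, reference = ref,
                          counts = counts),
                     class = "phase_enrichment"))
  }
  if (n <= exact_max) {
    p_obs <- stats::dmultinom(counts, prob = p)
    outcomes <- enumerate_triples(n)
    probs <- apply(outcomes, 1, stats::dmultinom, prob = p)
    pval <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    structure(list(method = "exact_multinomial", statistic = p_obs,
                   p_value = min(1, pval), df = NULL, reference = ref,
                   counts = counts),
              class = "phase_enrichment")
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, p = p))
    structure(list(method = "chi_square",
                   statistic = unname(ct$statistic),
                   p_value = unname(ct$p.value), df = 2L, reference = ref,
                   counts = counts),
              class = "phase_enrichment")
  }
}

# All (n0, n1, n2) with n0 + n1 + n2 = n.
enumerate_triples <- function(n) {
  g <- expand.grid(n0 = 0:n, n1 = 0:n)
  g <- g[g$n0 + g$n1 <= n, ]
  cbind(g$n0, g$n1, n - g$n0 - g$n1)
}

#' @export
print.phase_enrichment <- function(x, ...) {
  cat("Phase enrichment vs ", x$reference$label, " (",
      paste(sprintf("%.3f", x$reference$p), collapse = "/"), ")\n", sep = "")
  cat("  counts ", paste(x$counts, collapse = "/"),
      ", method ", x$method,
      if (!is.null(x$df)) paste0(", df ", x$df),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Permutation test for boundary enrichment of phase-1 introns
#'
#' Tests whether more genes carry the boundary signature (a phase-1 intron
#' within `window` residues of the signal-peptide cleavage site) than
#' expected if introns fell uniformly within the coding region. Under the
#' null each gene keeps its intron count but every coding intron's
#' insertion junction is resampled uniformly over the
#' `3 * precursor_len - 1` intra-CDS nucleotide junctions; the junction
#' determines both position and phase.
#'
#' Each gene draws its null junctions from an RNG stream seeded by
#' (`seed`, hash of its gene_id), so the p-value does not depend on the
#' order genes are supplied in.
#'
#' @param genes list of entries, each a list with elements `introns`
#'   (the gene's [map_to_precursor()] records) and `annot`
#'   (its [precursor_annotation()]).
#' @param window residue half-width (default 3).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed (required; recorded in the result).
#' @return object of class `permutation_test`: `observed`, `null_mean`,
#'   `null_counts`, `p_value = (1 + #{null >= observed}) / (1 + n_perm)`,
#'   `n_perm`, `seed`, `window`, `n_genes`.
#' @export
boundary_permutation_test <- function(genes, window = 3L, n_perm = 10000L,
                                      seed) {
  if (missing(seed) || is.na(seed)) stop("seed is required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  per_gene <- lapply(genes, function(g) {
    coding <- g$introns[g$introns$region == "CODING", , drop = FALSE]
    if (nrow(coding) == 0) {
      stop("gene ", g$annot$gene_id, " has no coding intron")
    }
    list(k = nrow(coding),
         plen = g$annot$precursor_len,
         slen = g$annot$signal_len,
         obs = any(coding$phase == 1L &
                     abs(coding$interrupted_codon_index - g$annot$signal_len)
                   <= window),
         id = g$annot$gene_id)
  })
  observed <- sum(vapply(per_gene, function(g) g$obs, TRUE))
  null_counts <- integer(n_perm)
  for (g in per_gene) {
    n_junc <- 3L * g$plen - 1L
    rng <- local_rng(gene_stream_seed(seed, g$id))
    j <- matrix(sample.int(n_junc, g$k * n_perm, replace = TRUE),
                nrow = g$k)
    restore_rng(rng)
    codon <- j %/% 3L
    hit <- (j %% 3L == 1L) & (abs(codon - g$slen) <= window)
    null_counts <- null_counts + (colSums(hit) > 0L)
  }
  structure(
    list(observed = observed, null_mean = mean(null_counts),
         null_counts = null_counts,
         p_value = (1 + sum(null_counts >= observed)) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         window = as.integer(window), n_genes = length(genes)),
    class = "permutation_test"
  )
}

# Deterministic 31-bit stream seed from the global seed and a gene id.
gene_stream_seed <- function(seed, gene_id) {
  h <- 0
  for (v in utf8ToInt(gene_id)) h <- (h * 131 + v) %% 2147483647
  as.integer((h + seed %% 2147483647) %% 2147483647)
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("Boundary-signature permutation test (window ", x$window,
      ", ", x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  cat("  observed ", x$observed, "/", x$n_genes,
      " genes; null mean ", format(x$null_mean, digits = 4),
      "; p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
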