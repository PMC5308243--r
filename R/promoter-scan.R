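IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  # N in a motif matches any base, including an undetermined N in the
  # promoter; promoter Ns match nothing else.
  N = c("A", "C", "G", "T", "N")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Read an IUPAC motif library
#'
#' Two-column TSV (`motif_id`, `pattern`); patterns are validated against
#' the 15-letter IUPAC nucleotide alphabet.
#'
#' @param path motif TSV.
#' @return data.frame with columns `motif_id`, `pattern`.
#' @export
load_motifs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("motif_id", "pattern") %in% names(tab))) {
    stop("motif file '", path, "' must have motif_id and pattern columns")
  }
  for (i in seq_len(nrow(tab))) {
    validate_iupac(tab$pattern[i], tab$motif_id[i])
  }
  tab[, c("motif_id", "pattern")]
}

validate_iupac <- function(pattern, motif_id = "<motif>") {
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("motif ", motif_id, ": empty pattern")
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad)) {
    stop("motif ", motif_id, ": invalid IUPAC letter(s) ",
         paste(bad, collapse = ""))
  }
  pattern
}

iupac_revcomp <- function(pattern) {
  paste(rev(unname(IUPAC_COMPLEMENT[strsplit(pattern, "")[[1]]])),
        collapse = "")
}

# All 0-based starts where `pattern` matches the forward sequence chars.
iupac_match_starts <- function(chars, pattern) {
  m <- nchar(pattern)
  n <- length(chars)
  if (m > n) return(integer(0))
  pl <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & chars[j:(n - m + j)] %in% IUPAC_SETS[[pl[j]]]
  }
  which(ok) - 1L
}

#' Scan a promoter for IUPAC motifs on both strands
#'
#' Reports every (possibly overlapping) position where a motif matches
#' under IUPAC degeneracy, on either strand. Positions are 0-based on the
#' forward strand; `site` is the forward-strand subsequence. An `N` in the
#' promoter is treated as undetermined: only a motif `N` matches it.
#'
#' @param promoter nucleotide string over `A,C,G,T,N`.
#' @param motifs data.frame with `motif_id`, `pattern` (see
#'   [load_motifs()]), or a named character vector of patterns.
#' @param promoter_id identifier recorded in the hits.
#' @return data.frame: `promoter_id`, `motif_id`, `start`, `strand`, `site`.
#' @export
scan_promoter <- function(promoter, motifs, promoter_id = "promoter") {
  if (is.character(motifs)) {
    motifs <- data.frame(motif_id = names(motifs), pattern = unname(motifs))
  }
  promoter <- toupper(promoter)
  if (grepl("[^ACGTN]", promoter)) {
    stop("promoter contains letters outside A,C,G,T,N")
  }
  chars <- strsplit(promoter, "")[[1]]
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- validate_iupac(motifs$pattern[i], motifs$motif_id[i])
    for (strand in c("+", "-")) {
      fwd_pat <- if (strand == "+") pat else iupac_revcomp(pat)
      starts <- iupac_match_starts(chars, fwd_pat)
      if (length(starts)) {
        hits[[length(hits) + 1]] <- data.frame(
          promoter_id = promoter_id, motif_id = motifs$motif_id[i],
          start = starts, strand = strand,
          site = substring(promoter, starts + 1, starts + nchar(pat))
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(promoter_id = character(0), motif_id = character(0),
                      start = integer(0), strand = character(0),
                      site = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif_id, out$strand), , drop = FALSE]
}

#' Scan a promoter FASTA against a motif library
#' @param fasta_path promoter FASTA.
#' @param motifs motif table (see [scan_promoter()]).
#' @return list with `hits` (all promoters row-bound) and `promoter_ids`.
#' @export
scan_promoter_fasta <- function(fasta_path, motifs) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  hits <- do.call(rbind, lapply(names(seqs), function(id) {
    scan_promoter(as.character(seqs[[id]]), motifs, promoter_id = id)
  }))
  list(hits = hits, promoter_ids = names(seqs))
}

#' Module-sharing matrix over promoters
#'
#' Collapses motif hits to binary presence per (promoter, motif) and scores
#' pairwise module sharing with the Jaccard index
#' `|shared motifs| / |union of motifs|` (NA when both promoters lack every
#' motif).
#'
#' @param hits data.frame of [scan_promoter()] hits over all promoters.
#' @param promoter_ids ordered promoter universe (promoters with no hits
#'   must still be listed here).
#' @param motif_ids ordered motif universe; defaults to the motifs seen in
#'   `hits`.
#' @return object of class `module_matrix`: `presence` (logical matrix
#'   promoters x motifs) and `jaccard` (symmetric matrix).
#' @export
module_matrix <- function(hits, promoter_ids, motif_ids = NULL) {
  if (is.null(motif_ids)) motif_ids <- sort(unique(hits$motif_id))
  presence <- matrix(FALSE, length(promoter_ids), length(motif_ids),
                     dimnames = list(promoter_ids, motif_ids))
  if (nrow(hits)) {
    pairs <- unique(hits[, c("promoter_id", "motif_id")])
    presence[cbind(match(pairs$promoter_id, promoter_ids),
                   match(pairs$motif_id, motif_ids))] <- TRUE
  }
  np <- length(promoter_ids)
  jac <- matrix(NA_real_, np, np, dimnames = list(promoter_ids, promoter_ids))
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      u <- sum(presence[i, ] | presence[j, ])
      jac[i, j] <- if (u == 0) NA_real_ else sum(presence[i, ] & presence[j, ]) / u
    }
  }
  structure(list(presence = presence, jaccard = jac), class = "module_matrix")
}

#' @export
print.module_matrix <- function(x, ...) {
  cat("<module_matrix> ", nrow(x$presence), " promoters x ",
      ncol(x$presence), " motifs\n", sep = "")
  print(round(x$jaccard, 3))
  invisible(x)
}

#' Mean sharing score per promoter
#'
#' Average Jaccard similarity of each promoter to all others; promoters
#' lacking the shared module score lowest.
#'
#' @param mm a [module_matrix()].
#' @return named numeric vector.
#' @export
mean_sharing <- function(mm) {
  j <- mm$jaccard
  diag(j) <- NA
  rowMeans(j, na.rm = TRUE)
}
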