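#' Inhibitor cystine knot (ICK) consensus matching
#'
#' Scans a protein sequence for the scorpion-venom ICK consensus
#' `C X6 C X4 D C C X{2-4} [KR] C X3 G X{4-6} C [KR]` (six cysteines
#' C1..C6, knot connectivity C1-C4, C2-C5, C3-C6). The macrocycle "ring" is
#' formed by the two backbone segments C1..C2 and C4..C5 (cysteines
#' included) closed by the C1-C4 and C2-C5 disulfides, so
#' `ring_size = (pos(C2) - pos(C1) + 1) + (pos(C5) - pos(C4) + 1)`; over the
#' spacer lengths the consensus admits this is 13 to 15 residues.
#'
#' @param protein residue string over the 20-letter amino-acid alphabet.
#' @param overlapping scan every start position (`TRUE`) instead of the
#'   default non-overlapping leftmost-first scan.
#' @return data.frame, one row per match: `start`, `end` (0-based
#'   half-open), `c1..c6` (0-based cysteine positions), `spacer1..spacer5`
#'   (inter-cysteine spacer lengths), `ring_size`, `connectivity`
#'   (`"1-4,2-5,3-6"`), `site`.
#' @export
match_ick_consensus <- function(protein, overlapping = FALSE) {
  check_protein(protein)
  pat <- "C.{6}C.{4}DCC.{2,4}[KR]C.{3}G.{4,6}C[KR]"
  starts <- integer(0); lens <- integer(0)
  if (overlapping) {
    m <- gregexpr(paste0("(?=", pat, ")"), protein, perl = TRUE)[[1]]
    if (m[1] != -1) {
      starts <- as.integer(m)
      # at each start take the leftmost (greedy) parse's length
      lens <- vapply(starts, function(s) {
        mm <- regexpr(pat, substr(protein, s, nchar(protein)), perl = TRUE)
        attr(mm, "match.length")
      }, 0L)
    }
  } else {
    m <- gregexpr(pat, protein, perl = TRUE)[[1]]
    if (m[1] != -1) {
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
    }
  }
  if (length(starts) == 0) return(empty_ick())
  out <- lapply(seq_along(starts), function(i) {
    site <- substr(protein, starts[i], starts[i] + lens[i] - 1)
    parse_ick_site(site, starts[i] - 1L)
  })
  do.call(rbind, out)
}

empty_ick <- function() {
  data.frame(start = integer(0), end = integer(0),
             c1 = integer(0), c2 = integer(0), c3 = integer(0),
             c4 = integer(0), c5 = integer(0), c6 = integer(0),
             spacer1 = integer(0), spacer2 = integer(0), spacer3 = integer(0),
             spacer4 = integer(0), spacer5 = integer(0),
             ring_size = integer(0), connectivity = character(0),
             site = character(0))
}

# Decompose one matched site into cysteine positions. Fixed spacers pin
# C1..C4; the greedy parse of the two variable spacers fixes C5 and C6.
parse_ick_site <- function(site, offset) {
  g <- regmatches(site, regexec(
    "^C(.{6})C(.{4})DCC(.{2,4})[KR]C(.{3})G(.{4,6})C[KR]$", site))[[1]]
  if (length(g) != 6) {
    stop("internal error: ICK site failed to re-parse: ", site)
  }
  s <- nchar(g[-1])                       # the five spacer lengths
  c1 <- 0L
  c2 <- c1 + s[1] + 1L
  c3 <- c2 + s[2] + 2L                    # D sits between spacer2 and C3
  c4 <- c3 + 1L
  c5 <- c4 + s[3] + 2L                    # spacer3 then K/R then C5
  c6 <- c5 + s[4] + 1L + s[5] + 1L        # spacer4, G, spacer5, C6
  ring <- (c2 - c1 + 1L) + (c5 - c4 + 1L)
  data.frame(start = offset, end = offset + nchar(site),
             c1 = offset + c1, c2 = offset + c2, c3 = offset + c3,
             c4 = offset + c4, c5 = offset + c5, c6 = offset + c6,
             spacer1 = s[1], spacer2 = s[2], spacer3 = s[3],
             spacer4 = s[4], spacer5 = s[5],
             ring_size = ring, connectivity = "1-4,2-5,3-6", site = site)
}

#' Enumerate ring sizes admitted by the ICK consensus
#'
#' Instantiates the consensus for every combination of the two variable
#' spacer lengths (2-4 and 4-6), runs each instance through
#' [match_ick_consensus()], and collects the resulting ring sizes.
#'
#' @param filler residue used for the fixed `X` positions (default `"A"`);
#'   any non-C/D/G/K/R residue gives identical results.
#' @return data.frame with `spacer3`, `spacer5` and `ring_size` for each
#'   combination.
#' @export
enumerate_ick_ring_sizes <- function(filler = "A") {
  stopifnot(nchar(filler) == 1)
  grid <- expand.grid(s3 = 2:4, s5 = 4:6)
  rs <- vapply(seq_len(nrow(grid)), function(i) {
    seqc <- ick_consensus_instance(grid$s3[i], grid$s5[i], filler)
    hit <- match_ick_consensus(seqc)
    if (nrow(hit) != 1) stop("consensus instance failed to match itself")
    hit$ring_size
  }, 0L)
  data.frame(spacer3 = grid$s3, spacer5 = grid$s5, ring_size = rs)
}

# One concrete instance of the consensus with given variable spacer lengths.
ick_consensus_instance <- function(s3, s5, filler = "A", basic = "K") {
  x <- function(n) strrep(filler, n)
  paste0("C", x(6), "C", x(4), "DCC", x(s3), basic, "C", x(3), "G", x(s5),
         "C", basic)
}

#' CSab-fold motif report
#'
#' Reports every occurrence (overlapping allowed) of the two motifs that
#' anchor the cysteine-stabilised alpha-helix/beta-sheet fold: `CX3C`
#' (helix) and `CXC` (second beta-strand), and whether the protein carries
#' the pair in fold order (a `CX3C` preceding a `CXC`).
#'
#' @param protein residue string.
#' @return list of class `csab_report`: `cx3c_positions`, `cxc_positions`
#'   (0-based starts) and `has_pair`.
#' @export
match_csab_motifs <- function(protein) {
  check_protein(protein)
  scan <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), protein, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  cx3c <- scan("C.{3}C")
  cxc <- scan("C.C")
  structure(
    list(cx3c_positions = cx3c, cxc_positions = cxc,
         has_pair = length(cx3c) > 0 && length(cxc) > 0 &&
           any(outer(cx3c, cxc, function(a, b) a + 4L < b))),
    class = "csab_report"
  )
}

#' @export
print.csab_report <- function(x, ...) {
  cat("CSab motifs: CX3C at {", paste(x$cx3c_positions, collapse = ","),
      "}  CXC at {", paste(x$cxc_positions, collapse = ","),
      "}  pair in fold order: ", x$has_pair, "\n", sep = "")
  invisible(x)
}

#' Count cysteines and the maximum number of pairable disulfide bridges
#' @param protein residue string.
#' @return list with `n_cys` and `max_bridges` (`n_cys %/% 2`).
#' @export
count_cysteines <- function(protein) {
  check_protein(protein)
  n <- sum(strsplit(protein, "")[[1]] == "C")
  list(n_cys = n, max_bridges = n %/% 2L)
}

check_protein <- function(protein) {
  if (length(protein) != 1 || !is.character(protein)) {
    stop("protein must be a single character string")
  }
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWY]", "", protein)
  if (nzchar(bad)) {
    stop("non-residue characters in protein sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  invisible(TRUE)
}

#' Annotate scaffold motifs over a protein FASTA
#'
#' @param fasta_path protein FASTA.
#' @return data.frame of ICK matches (one row per match, with
#'   `protein_id`), suitable for [write_table_tsv()].
#' @export
scan_protein_fasta <- function(fasta_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  names(aa) <- sub("\\s.*", "", names(aa))
  out <- lapply(names(aa), function(id) {
    hits <- match_ick_consensus(as.character(aa[[id]]))
    if (nrow(hits)) cbind(protein_id = id, hits) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) return(cbind(protein_id = character(0), empty_ick()))
  do.call(rbind, out)
}
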