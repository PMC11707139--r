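#' Transposon-end and protein motif scanners
#'
#' Transposon ends of the piggyBac superfamily carry repeated subterminal
#' motifs (e.g. the 5'-GCGGGA hexamer repeated along a left end) and
#' imperfect palindromes that together make up transposase binding sites;
#' transposase N-termini carry minimal casein kinase II (CKII)
#' phosphorylation motifs (S/T-X-X-D/E).  These scanners enumerate all three
#' exhaustively and exactly.
#'
#' @name end_motifs
NULL

# normalize sequence input to a named character vector
as_named_seqs <- function(seq, default_id = "seq1") {
  if (methods::is(seq, "XStringSet")) seq <- setNames(as.character(seq), names(seq))
  if (!is.character(seq)) abort("sequence must be character or an XStringSet")
  if (is.null(names(seq))) {
    names(seq) <- if (length(seq) == 1) default_id else
      paste0(default_id, "_", seq_along(seq))
  }
  toupper(seq)
}

#' Find repeated k-mers in transposon-end DNA
#'
#' Tallies every k-mer occurrence (overlaps allowed); with
#' `both_strands = TRUE`, a k-mer and its reverse complement are merged under
#' a canonical representative (the lexicographically smaller of the two), and
#' each occurrence records the orientation of the plus-strand window relative
#' to that representative.  Motifs observed at least `min_count` times are
#' reported, ranked by total count (descending) then canonical text.
#'
#' @param seq DNA sequence(s): character (optionally named) or `DNAStringSet`.
#' @param k Motif length (>= 4; default 6, the length of the subterminal
#'   GCGGGA repeat).
#' @param min_count Minimum total occurrences to report (default 2).
#' @param both_strands Merge reverse-complement occurrences (default TRUE).
#' @return Tibble with one row per occurrence: `motif` (canonical), `count`
#'   (total for the motif), `seq_id`, `start` (0-based), `orientation`.
#' @export
#' @examples
#' find_repeated_motifs(c(LE = "GCGGGATTTGCGGGA"), k = 6, min_count = 2)
find_repeated_motifs <- function(seq, k = 6L, min_count = 2L, both_strands = TRUE) {
  k <- as.integer(k)
  if (k < 4) abort("k must be >= 4")
  seqs <- as_named_seqs(seq)
  occ <- purrr::imap(seqs, function(s, nm) {
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    win <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", win, fixed = TRUE)
    tibble(seq_id = nm, start = starts[ok] - 1L, window = win[ok])
  })
  occ <- bind_rows(occ)
  if (nrow(occ) == 0) {
    return(tibble(motif = character(), count = integer(), seq_id = character(),
                  start = integer(), orientation = character()))
  }
  if (both_strands) {
    rc <- revcomp(occ$window)
    occ$motif <- pmin(occ$window, rc)
    occ$orientation <- ifelse(occ$window == occ$motif, "+", "-")
  } else {
    occ$motif <- occ$window
    occ$orientation <- "+"
  }
  occ <- occ %>%
    group_by(.data$motif) %>%
    mutate(count = n()) %>%
    ungroup() %>%
    filter(.data$count >= min_count) %>%
    arrange(dplyr::desc(.data$count), .data$motif, .data$seq_id, .data$start)
  occ[, c("motif", "count", "seq_id", "start", "orientation")]
}

wc_complement <- c(A = "T", C = "G", G = "C", T = "A")

palindrome_mismatches <- function(window) {
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  L <- length(ch)
  half <- L %/% 2L
  left <- ch[seq_len(half)]
  right <- ch[L + 1L - seq_len(half)]
  sum(wc_complement[right] != left | is.na(wc_complement[right]))
}

#' Find imperfect palindromes in DNA
#'
#' Scores every even-length window in `[min_len, max_len]` by the number of
#' arm pairs `(i, L-1-i)` that are not Watson-Crick complementary
#' (`score = L/2 - mismatches`), keeps windows with at most `max_mismatches`
#' broken pairs, and (optionally) reduces nested/overlapping hits greedily by
#' descending score, then length, then leftmost start.  Contiguous
#' palindromes only — no spacer/loop.
#'
#' @param seq DNA sequence(s).
#' @param min_len,max_len Even window length bounds (default 8-16, bracketing
#'   the 12-14 bp imperfect palindromes of piggyBac-superfamily left ends).
#' @param max_mismatches Maximum broken arm pairs (default 2).
#' @param reduce Apply the greedy overlap reduction (default TRUE); set FALSE
#'   to obtain every qualifying window.
#' @return Tibble `seq_id`, `start` (0-based), `length`, `mismatches`,
#'   `score`.
#' @export
#' @examples
#' find_imperfect_palindromes("GGAATTCC", min_len = 4, max_len = 8,
#'                            max_mismatches = 0, reduce = FALSE)
find_imperfect_palindromes <- function(seq, min_len = 8L, max_len = 16L,
                                       max_mismatches = 2L, reduce = TRUE) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len < 4 || min_len > max_len) abort("need 4 <= min_len <= max_len")
  if (min_len %% 2L || max_len %% 2L) abort("min_len and max_len must be even")
  seqs <- as_named_seqs(seq)
  hits <- purrr::imap(seqs, function(s, nm) {
    L <- nchar(s)
    res <- list()
    for (w in seq(min_len, max_len, by = 2L)) {
      if (L < w) next
      starts <- seq_len(L - w + 1L)
      win <- substring(s, starts, starts + w - 1L)
      mm <- vapply(win, palindrome_mismatches, integer(1), USE.NAMES = FALSE)
      keep <- mm <= max_mismatches & !grepl("N", win, fixed = TRUE)
      if (any(keep)) {
        res[[length(res) + 1L]] <- tibble(seq_id = nm, start = starts[keep] - 1L,
                                          length = w, mismatches = mm[keep],
                                          score = w %/% 2L - mm[keep])
      }
    }
    bind_rows(res)
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0 || !reduce) {
    return(arrange(hits, .data$seq_id, .data$start, .data$length))
  }
  hits <- arrange(hits, dplyr::desc(.data$score), dplyr::desc(.data$length),
                  .data$start, .data$seq_id)
  kept <- hits[0, ]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    same <- kept[kept$seq_id == h$seq_id, , drop = FALSE]
    if (!nrow(same) ||
        !any(same$start < h$start + h$length & same$start + same$length > h$start)) {
      kept <- bind_rows(kept, h)
    }
  }
  arrange(kept, .data$seq_id, .data$start)
}

#' Scan a protein for minimal CKII phosphorylation motifs
#'
#' Reports every serine or threonine followed by an acidic residue (D/E) at
#' position +3 — the minimal S/T-X-X-D/E casein kinase II consensus.
#' Positions are 1-based residue indices.
#'
#' @param protein_seq Protein sequence (character scalar or `AAString`-like).
#' @return Tibble `residue_index`, `residue`, `window` (the 4-residue motif).
#' @export
#' @examples
#' scan_ckii_sites("MSAAE")
scan_ckii_sites <- function(protein_seq) {
  if (methods::is(protein_seq, "XString") || methods::is(protein_seq, "XStringSet")) {
    protein_seq <- as.character(protein_seq)[1]
  }
  s <- toupper(protein_seq)
  L <- nchar(s)
  if (L < 4) {
    return(tibble(residue_index = integer(), residue = character(),
                  window = character()))
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- which(ch[seq_len(L - 3L)] %in% c("S", "T") & ch[4:L] %in% c("D", "E"))
  if (length(i) == 0) {
    return(tibble(residue_index = integer(), residue = character(),
                  window = character()))
  }
  tibble(residue_index = i, residue = ch[i],
         window = substring(s, i, i + 3L))
}
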