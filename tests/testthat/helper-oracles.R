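# Brute-force oracles kept deliberately independent of the package internals:
# every one works position by position on plain character vectors.

oracle_ttaa_scan <- function(genome_chr) {
  out <- list()
  for (nm in names(genome_chr)) {
    s <- genome_chr[[nm]]
    starts <- integer(0)
    for (p in seq_len(max(nchar(s) - 3L, 0L))) {
      if (substr(s, p, p + 3L) == "TTAA") starts <- c(starts, p - 1L)
    }
    out[[nm]] <- tibble::tibble(contig = nm, start = starts)
  }
  dplyr::bind_rows(out)
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive scan of every position and strand; returns best status/locus
oracle_map <- function(frag, genome_chr, max_mismatches) {
  best <- Inf; hits <- list()
  for (nm in names(genome_chr)) {
    s <- genome_chr[[nm]]
    L <- nchar(s); fl <- nchar(frag)
    if (L < fl) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") frag else oracle_revcomp(frag)
      for (p in seq_len(L - fl + 1L)) {
        d <- oracle_hamming(q, substr(s, p, p + fl - 1L))
        if (d < best) {
          best <- d; hits <- list(list(contig = nm, start = p - 1L, strand = strand))
        } else if (d == best) {
          hits <- c(hits, list(list(contig = nm, start = p - 1L, strand = strand)))
        }
      }
    }
  }
  if (!is.finite(best) || best > max_mismatches) {
    return(list(status = "unmapped"))
  }
  hits <- unique(hits)
  if (length(hits) > 1) return(list(status = "ambiguous", mismatches = best))
  c(list(status = "unique", mismatches = best), hits[[1]])
}

oracle_classify <- function(intervals, contig, pos0) {
  # per-base precedence CDS > UTR > intron > intergenic; gene bodies are
  # introns unless covered by CDS/UTR
  cover <- function(cls) {
    any(intervals$contig == contig & intervals$feature_class %in% cls &
          intervals$start <= pos0 & pos0 < intervals$end)
  }
  if (cover("CDS")) return("CDS")
  if (cover("UTR")) return("UTR")
  if (cover(c("gene", "intron"))) return("intron")
  "intergenic"
}

oracle_kmer_tally <- function(seq_chr, k, both_strands) {
  wins <- character(0); starts <- integer(0)
  for (p in seq_len(nchar(seq_chr) - k + 1L)) {
    wins <- c(wins, substr(seq_chr, p, p + k - 1L)); starts <- c(starts, p - 1L)
  }
  motif <- if (both_strands) pmin(wins, oracle_revcomp(wins)) else wins
  data.frame(motif = motif, start = starts,
             orientation = ifelse(motif == wins, "+", "-"))
}

oracle_palindromes <- function(seq_chr, min_len, max_len, max_mm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (w in seq(min_len, max_len, by = 2)) {
    for (p in seq_len(max(nchar(seq_chr) - w + 1L, 0L))) {
      win <- strsplit(substr(seq_chr, p, p + w - 1L), "")[[1]]
      mm <- 0L
      for (i in seq_len(w %/% 2L)) {
        if (is.na(comp[win[w + 1L - i]]) || comp[win[w + 1L - i]] != win[i]) mm <- mm + 1L
      }
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(start = p - 1L, length = w, mismatches = mm)
      }
    }
  }
  do.call(rbind, out)
}

oracle_ckii <- function(protein) {
  ch <- strsplit(protein, "")[[1]]
  idx <- integer(0)
  for (i in seq_len(max(length(ch) - 3L, 0L))) {
    if (ch[i] %in% c("S", "T") && ch[i + 3L] %in% c("D", "E")) idx <- c(idx, i)
  }
  idx
}

# random DNA helper for fixtures
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

# raw-byte exhaustive mapper oracle (same contract as oracle_map, faster for
# the larger acceptance comparison)
oracle_map_fast <- function(frag, genome_chr, max_mismatches) {
  best <- Inf; hits <- list()
  fl <- nchar(frag)
  for (nm in names(genome_chr)) {
    gr <- charToRaw(genome_chr[[nm]])
    L <- length(gr)
    if (L < fl) next
    for (strand in c("+", "-")) {
      qr <- charToRaw(if (strand == "+") frag else oracle_revcomp(frag))
      for (p in 0:(L - fl)) {
        d <- sum(gr[(p + 1):(p + fl)] != qr)
        if (d < best) {
          best <- d; hits <- list(list(contig = nm, start = p, strand = strand))
        } else if (d == best) {
          hits <- c(hits, list(list(contig = nm, start = p, strand = strand)))
        }
      }
    }
  }
  if (!is.finite(best) || best > max_mismatches) return(list(status = "unmapped"))
  hits <- unique(hits)
  if (length(hits) > 1) return(list(status = "ambiguous", mismatches = best))
  c(list(status = "unique", mismatches = best), hits[[1]])
}
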