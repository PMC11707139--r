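#' Build a plus-strand k-mer index of a genome
#'
#' Records every plus-strand window of length `k` (windows containing `N` are
#' excluded) with its contig and 0-based position.  This desk-scale index
#' backs the seed-and-extend placement in [map_fragments()]; queries for both
#' strands are answered from the plus-strand table by reverse-complementing
#' the query.
#'
#' @param genome Genome (named character or `DNAStringSet`).
#' @param k Seed length (default 15, minimum 8).
#' @return An object of class `kmer_index`: list with `k`, and parallel
#'   vectors `kmer`, `contig`, `pos` (0-based) over all stored windows.
#' @export
build_kmer_index <- function(genome, k = 15L) {
  k <- as.integer(k)
  if (k < 8) abort("seed length k must be >= 8")
  genome <- as_genome(genome)
  chars <- genome_chars(genome)
  lens <- genome_lengths(genome)
  if (all(lens < k)) abort("k is larger than every contig")
  kmer <- contig <- list()
  pos <- list()
  for (nm in names(chars)) {
    L <- lens[[nm]]
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km <- substring(chars[[nm]], starts, starts + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    kmer[[nm]] <- km[ok]
    contig[[nm]] <- rep(nm, sum(ok))
    pos[[nm]] <- starts[ok] - 1L
  }
  structure(list(k = k,
                 kmer = unlist(kmer, use.names = FALSE),
                 contig = unlist(contig, use.names = FALSE),
                 pos = unlist(pos, use.names = FALSE)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", length(x$kmer), " stored windows, ",
      length(unique(x$contig)), " contig(s)\n", sep = "")
  invisible(x)
}

# first window of length k without N, or NA if none
first_clean_seed <- function(frag, k) {
  L <- nchar(frag)
  if (L < k) return(NA_integer_)
  for (off in 0:(L - k)) {
    if (!grepl("N", substr(frag, off + 1L, off + k), fixed = TRUE)) return(off)
  }
  NA_integer_
}

hamming_raw <- function(a, b) sum(a != b)

#' Map trimmed genomic fragments onto the reference
#'
#' Seed-and-extend placement: candidate loci are gathered from the first
#' `N`-free seed of each fragment, on both strands (the minus strand via the
#' reverse-complemented fragment), and every candidate is scored by
#' full-length Hamming distance.  A fragment is `unique` iff exactly one
#' candidate attains the minimum distance and that minimum is within
#' `max_mismatches`; ties are `ambiguous`; no candidate within budget is
#' `unmapped`.  Mapping is fully deterministic.
#'
#' @param fragments A `trim_result`, or a tibble with columns `id` and
#'   `genomic_part` (or `sequence`).
#' @param index A [build_kmer_index()] over the same genome.
#' @param genome The genome.
#' @param max_mismatches Mismatch budget for a unique placement (default 3,
#'   sized for 30-50 nt fragments).
#' @return Object of class `map_result`: list with
#'   * `alignments`: tibble `read_id`, `contig`, `start` (0-based leftmost
#'     reference base), `strand`, `mismatches`, `fragment_length`, `status`;
#'   * `stats`: one-row tibble `unique`, `ambiguous`, `unmapped`.
#' @export
map_fragments <- function(fragments, index, genome, max_mismatches = 3L) {
  stopifnot(inherits(index, "kmer_index"))
  if (inherits(fragments, "trim_result")) fragments <- fragments$trimmed
  fragcol <- if ("genomic_part" %in% names(fragments)) "genomic_part" else "sequence"
  frags <- fragments[[fragcol]]
  ids <- fragments$id
  k <- index$k
  genome <- as_genome(genome)
  raws <- lapply(genome_chars(genome), charToRaw)
  lens <- genome_lengths(genome)

  n <- length(frags)
  rcs <- if (n) revcomp(frags) else character()
  off_f <- vapply(frags, first_clean_seed, integer(1), k = k, USE.NAMES = FALSE)
  off_r <- vapply(rcs, first_clean_seed, integer(1), k = k, USE.NAMES = FALSE)
  seeds_f <- ifelse(is.na(off_f), NA, substr(frags, off_f + 1L, off_f + k))
  seeds_r <- ifelse(is.na(off_r), NA, substr(rcs, off_r + 1L, off_r + k))

  # one hash pass over the index for all queried seeds
  queried <- unique(stats::na.omit(c(seeds_f, seeds_r)))
  hit <- index$kmer %in% queried
  lut <- list2env(split(data.frame(contig = index$contig[hit], pos = index$pos[hit],
                                   stringsAsFactors = FALSE),
                        index$kmer[hit]),
                  hash = TRUE, parent = emptyenv())

  contig_v <- character(n); start_v <- integer(n); strand_v <- character(n)
  mm_v <- integer(n); status_v <- character(n)
  for (i in seq_len(n)) {
    flen <- nchar(frags[i])
    cands <- list()
    gather <- function(seedseq, off, strand, query) {
      tab <- if (exists(seedseq, envir = lut, inherits = FALSE))
        get(seedseq, envir = lut) else NULL
      if (is.null(tab)) return(NULL)
      st <- tab$pos - off
      ok <- st >= 0L & st + flen <= lens[tab$contig]
      if (!any(ok)) return(NULL)
      data.frame(contig = tab$contig[ok], start = st[ok], strand = strand,
                 query = query, stringsAsFactors = FALSE)
    }
    if (!is.na(off_f[i])) cands[[1]] <- gather(seeds_f[i], off_f[i], "+", frags[i])
    if (!is.na(off_r[i])) cands[[2]] <- gather(seeds_r[i], off_r[i], "-", rcs[i])
    cd <- do.call(rbind, cands)
    if (is.null(cd) || nrow(cd) == 0) {
      status_v[i] <- "unmapped"
      contig_v[i] <- NA; start_v[i] <- NA; strand_v[i] <- NA; mm_v[i] <- NA
      next
    }
    cd <- unique(cd)
    mmc <- integer(nrow(cd))
    for (j in seq_len(nrow(cd))) {
      qr <- charToRaw(cd$query[j])
      gr <- raws[[cd$contig[j]]]
      mmc[j] <- hamming_raw(gr[(cd$start[j] + 1L):(cd$start[j] + flen)], qr)
    }
    best <- min(mmc)
    nbest <- sum(mmc == best)
    if (best > max_mismatches) {
      status_v[i] <- "unmapped"
      contig_v[i] <- NA; start_v[i] <- NA; strand_v[i] <- NA; mm_v[i] <- NA
    } else if (nbest > 1) {
      status_v[i] <- "ambiguous"
      contig_v[i] <- NA; start_v[i] <- NA; strand_v[i] <- NA; mm_v[i] <- best
    } else {
      j <- which(mmc == best)
      status_v[i] <- "unique"
      contig_v[i] <- cd$contig[j]; start_v[i] <- cd$start[j]
      strand_v[i] <- cd$strand[j]; mm_v[i] <- best
    }
  }
  alignments <- tibble(read_id = ids, contig = contig_v, start = start_v,
                       strand = strand_v, mismatches = mm_v,
                       fragment_length = nchar(frags), status = status_v)
  stats <- tibble(unique = sum(status_v == "unique"),
                  ambiguous = sum(status_v == "ambiguous"),
                  unmapped = sum(status_v == "unmapped"))
  stopifnot(sum(unlist(stats)) == n)
  structure(list(alignments = alignments, stats = stats), class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat("<map_result>\n")
  print(x$stats)
  invisible(x)
}

#' @export
#' @method tidy map_result
tidy.map_result <- function(x, ...) x$alignments

#' @export
#' @method glance map_result
glance.map_result <- function(x, ...) x$stats
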