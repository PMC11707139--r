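#' Simulation configuration for self-reporting transposon libraries
#'
#' Bundles every knob of the synthetic-data generator.  The defaults describe
#' the standard simulated study used across the package: a 100 kb, 4-contig
#' genome at GC 0.45 with 24 genes, 200 TTAA insertions sampled uniformly over
#' the genome's TTAA sites, and 20 junction reads per insertion.
#'
#' Junction reads mirror the self-reporting library structure: a
#' transposon-derived prefix (amplification primer plus the terminal bases of
#' the terminal inverted repeat), then the duplicated TTAA target site, then
#' the 3' genomic flank.  The default `transposon_prefix` is a synthetic
#' 20-mer stand-in for the real primer (which is instrument/library specific);
#' its last `tir_tail_len` bases play the role of the TIR tip.
#'
#' @param seed Integer seed; every generator stage is deterministic given it.
#' @param genome_length Total genome size in bp, split evenly over contigs.
#' @param n_contigs Number of contigs.
#' @param gc_fraction Genome GC content (probability).
#' @param n_genes Number of non-overlapping gene models to place.
#' @param exons_per_gene Integer range `c(min, max)` of CDS exons per gene.
#' @param exon_length,intron_length,utr5_length,utr3_length Ranges `c(min, max)`
#'   (bp) the corresponding segment lengths are drawn from, uniformly.
#' @param n_insertions Number of distinct TTAA insertion events.
#' @param feature_bias Named non-negative weights (relative per-site sampling
#'   probability) for `CDS`, `UTR`, `intron`, `intergenic`.
#' @param reads_per_insertion Junction reads generated per insertion event.
#' @param read_length Read length (nt); must exceed
#'   `nchar(transposon_prefix) + 4`.
#' @param error_rate Per-base substitution probability.
#' @param background_fraction Fraction of all reads that are random genomic
#'   fragments lacking the transposon prefix.
#' @param transposon_prefix The transposon-derived read prefix (primer + TIR
#'   terminal bases).
#' @param tir_tail_len Number of terminal transposon bases (`K`) retained on
#'   trimmed reads; default 4.
#' @param quality_char Constant placeholder quality character.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_contigs = 4L,
                       gc_fraction = 0.45,
                       n_genes = 24L,
                       exons_per_gene = c(2L, 5L),
                       exon_length = c(90L, 240L),
                       intron_length = c(200L, 800L),
                       utr5_length = c(100L, 250L),
                       utr3_length = c(150L, 400L),
                       n_insertions = 200L,
                       feature_bias = c(CDS = 1, UTR = 1, intron = 1, intergenic = 1),
                       reads_per_insertion = 20L,
                       read_length = 60L,
                       error_rate = 0,
                       background_fraction = 0,
                       transposon_prefix = "CGTACGTCAGTGACGACCCT",
                       tir_tail_len = 4L,
                       quality_char = "I") {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs), gc_fraction = gc_fraction,
              n_genes = as.integer(n_genes), exons_per_gene = exons_per_gene,
              exon_length = exon_length, intron_length = intron_length,
              utr5_length = utr5_length, utr3_length = utr3_length,
              n_insertions = as.integer(n_insertions), feature_bias = feature_bias,
              reads_per_insertion = as.integer(reads_per_insertion),
              read_length = as.integer(read_length), error_rate = error_rate,
              background_fraction = background_fraction,
              transposon_prefix = toupper(transposon_prefix),
              tir_tail_len = as.integer(tir_tail_len),
              quality_char = quality_char)
  probs <- c(gc_fraction = gc_fraction, error_rate = error_rate,
             background_fraction = background_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort(paste0("probability out of [0,1]: ",
                 names(probs)[probs < 0 | probs > 1][1]))
  }
  if (any(cfg$feature_bias < 0) || !any(cfg$feature_bias > 0)) {
    abort("feature_bias weights must be >= 0 with at least one positive")
  }
  if (!all(FEATURE_CLASSES %in% names(cfg$feature_bias))) {
    abort("feature_bias must name all of CDS, UTR, intron, intergenic")
  }
  if (cfg$read_length <= nchar(cfg$transposon_prefix) + 4L) {
    abort("read_length must exceed nchar(transposon_prefix) + 4")
  }
  if (cfg$tir_tail_len < 0 || cfg$tir_tail_len > nchar(cfg$transposon_prefix)) {
    abort("tir_tail_len must be between 0 and nchar(transposon_prefix)")
  }
  if (grepl("[^ACGT]", cfg$transposon_prefix)) {
    abort("transposon_prefix must be over {A,C,G,T}")
  }
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a feature-annotated random genome
#'
#' Draws i.i.d. bases at the configured GC content and overlays non-overlapping
#' gene models (5'UTR, alternating CDS exons and introns, 3'UTR).  Each contig
#' is checked to contain at least one TTAA per kb on average and is redrawn
#' (up to 25 attempts) if not, so downstream insertion sampling always has
#' sites to work with.  Deterministic for a given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (named `DNAStringSet`) and
#'   `annotation` (an `annotation_set`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, "genome"), {
    per <- rep(config$genome_length %/% config$n_contigs, config$n_contigs)
    per[1] <- per[1] + config$genome_length %% config$n_contigs
    contigs <- character(config$n_contigs)
    for (i in seq_len(config$n_contigs)) {
      for (attempt in 1:25) {
        s <- random_dna(per[i], config$gc_fraction)
        n_ttaa <- length(gregexpr("(?=TTAA)", s, perl = TRUE)[[1]])
        if (n_ttaa >= per[i] / 1000) break
        if (attempt == 25) abort("could not generate a contig with >=1 TTAA/kb")
      }
      contigs[i] <- s
    }
    names(contigs) <- sprintf("chr%d", seq_len(config$n_contigs))
    genome <- Biostrings::DNAStringSet(contigs)

    # gene structures first (round-robin over contigs), then placement by
    # stick-breaking of each contig's free space, which always fits when the
    # summed spans do
    runi <- function(rg) if (rg[1] >= rg[2]) rg[1] else sample(rg[1]:rg[2], 1)
    genes <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      n_ex <- runi(config$exons_per_gene)
      body <- integer(0)
      for (e in seq_len(n_ex)) {
        body <- c(body, runi(config$exon_length))
        if (e < n_ex) body <- c(body, runi(config$intron_length))
      }
      lens <- c(runi(config$utr5_length), body, runi(config$utr3_length))
      genes[[g]] <- list(id = sprintf("gene%02d", g),
                         contig_i = ((g - 1L) %% config$n_contigs) + 1L,
                         classes = c("UTR", rep(c("CDS", "intron"),
                                                length.out = 2L * n_ex - 1L), "UTR"),
                         lens = lens, span = sum(lens))
    }
    intervals <- list()
    for (ci in seq_len(config$n_contigs)) {
      mine <- genes[vapply(genes, function(g) g$contig_i, 1L) == ci]
      if (!length(mine)) next
      L <- per[ci]
      spans <- vapply(mine, function(g) g$span, 1L)
      free <- L - sum(spans) - 10L * (length(mine) + 1L)
      if (free < 0) {
        abort(sprintf("gene models cannot fit: contig %d holds %d bp of genes but is %d bp",
                      ci, sum(spans), L))
      }
      cuts <- sort(sample.int(free + 1L, length(mine), replace = TRUE) - 1L)
      gaps <- diff(c(0L, cuts)) + 10L
      st <- cumsum(gaps) + c(0L, cumsum(spans))[seq_along(mine)]
      for (j in seq_along(mine)) {
        gn <- mine[[j]]
        segs_end <- st[j] + cumsum(gn$lens)
        segs_start <- segs_end - gn$lens
        intervals[[length(intervals) + 1L]] <- bind_rows(
          tibble(contig = names(contigs)[ci], start = st[j], end = st[j] + gn$span,
                 feature_class = "gene", gene_id = gn$id, strand = "+"),
          tibble(contig = names(contigs)[ci], start = segs_start, end = segs_end,
                 feature_class = gn$classes, gene_id = gn$id, strand = "+")
        )
      }
    }
    intervals <- if (length(intervals)) bind_rows(intervals) else
      tibble(contig = character(), start = integer(), end = integer(),
             feature_class = character(), gene_id = character(), strand = character())
    list(genome = genome, annotation = flatten_annotation(intervals, genome))
  })
}

#' Enumerate all TTAA sites of a genome
#'
#' Every 0-based start position whose 4-bp window reads exactly `TTAA`
#' (windows containing `N` never match); overlap-tolerant, ascending per
#' contig.  Backed by [Biostrings::matchPattern()].
#'
#' @param genome Genome (named character or `DNAStringSet`).
#' @return Tibble with columns `contig`, `start`.
#' @export
#' @examples
#' enumerate_ttaa_sites(c(c1 = "TTAAGTTAA"))
enumerate_ttaa_sites <- function(genome) {
  genome <- as_genome(genome)
  res <- purrr::map2(names(genome), as.list(genome), function(nm, s) {
    st <- BiocGenerics::start(Biostrings::matchPattern("TTAA", s, fixed = TRUE))
    tibble(contig = nm, start = st - 1L)
  })
  bind_rows(res)
}

#' Sample ground-truth TTAA insertion events
#'
#' Samples `config$n_insertions` distinct TTAA sites without replacement,
#' with per-site probability proportional to the `feature_bias` weight of the
#' site's (flattened) feature class, and assigns each event an `F`/`R`
#' orientation with probability 1/2.  Deterministic for a given seed.
#'
#' @param genome,annotation From [generate_genome()] (or compatible).
#' @param config A [sim_config()].
#' @return Tibble with columns `contig`, `ttaa_start`, `orientation`,
#'   `feature_class`.
#' @export
simulate_insertions <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_genome(genome)
  pool <- enumerate_ttaa_sites(genome)
  pool$feature_class <- flattened_classes(annotation, pool$contig, pool$start)
  pool$w <- unname(config$feature_bias[pool$feature_class])
  eligible <- sum(pool$w > 0)
  if (eligible < config$n_insertions) {
    abort(sprintf(paste0("too few TTAA sites: %d insertions requested but only ",
                         "%d sites with positive weight (of %d TTAA sites total)"),
                  config$n_insertions, eligible, nrow(pool)))
  }
  withr::with_seed(stage_seed(config$seed, "insertions"), {
    idx <- sample(which(pool$w > 0), config$n_insertions,
                  replace = FALSE, prob = pool$w[pool$w > 0])
    ev <- pool[idx, c("contig", "start", "feature_class")]
    names(ev)[2] <- "ttaa_start"
    ev$orientation <- sample(c("F", "R"), nrow(ev), replace = TRUE)
    arrange(as_tibble(ev[, c("contig", "ttaa_start", "orientation", "feature_class")]),
            .data$contig, .data$ttaa_start)
  })
}

apply_substitution_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  hit <- which(matrix(stats::runif(length(m)) < error_rate, nrow = nrow(m)))
  if (length(hit)) {
    # substitute with a uniformly chosen different base
    for (j in hit) {
      m[j] <- sample(setdiff(DNA_BASES, m[j]), 1)
    }
  }
  apply(m, 1, paste, collapse = "")
}

#' Simulate junction reads from insertion events
#'
#' For orientation `F` the read is `transposon_prefix` followed by the
#' plus-strand genomic sequence starting at `ttaa_start`; for orientation `R`
#' it is the prefix followed by the reverse complement of the genomic sequence
#' ending at `ttaa_start + 4`.  Since TTAA is its own reverse complement, both
#' read types begin `prefix + TTAA...`, which is what lets the site caller
#' canonicalize them to a single coordinate.  Events whose genomic window
#' would run past a contig end are skipped (count recorded in the `skipped`
#' attribute of the truth table).  A configurable fraction of background reads
#' (random genomic fragments, no prefix) and per-base substitution errors are
#' layered on top.  Deterministic for a given seed.
#'
#' @param genome Genome.
#' @param events Event tibble from [simulate_insertions()].
#' @param config A [sim_config()].
#' @return A list: `reads` (tibble `id`, `sequence`, `quality`) and `truth`
#'   (tibble `id`, `contig`, `ttaa_start`, `orientation`, `is_background`;
#'   background rows carry `NA` coordinates).  `attr(truth, "skipped")` counts
#'   events dropped at contig ends.
#' @export
simulate_reads <- function(genome, events, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_genome(genome)
  chars <- genome_chars(genome)
  lens <- genome_lengths(genome)
  prefix <- config$transposon_prefix
  glen <- config$read_length - nchar(prefix)

  keep_f <- events$orientation == "F" &
    events$ttaa_start + glen <= lens[events$contig]
  keep_r <- events$orientation == "R" & events$ttaa_start + 4L - glen >= 0L
  keep <- keep_f | keep_r
  skipped <- sum(!keep)
  ev <- events[keep, , drop = FALSE]

  frag <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    s <- chars[[ev$contig[i]]]
    if (ev$orientation[i] == "F") {
      frag[i] <- substr(s, ev$ttaa_start[i] + 1L, ev$ttaa_start[i] + glen)
    } else {
      frag[i] <- revcomp(substr(s, ev$ttaa_start[i] + 5L - glen, ev$ttaa_start[i] + 4L))
    }
  }

  rpi <- config$reads_per_insertion
  n_signal <- nrow(ev) * rpi
  reps <- rep(seq_len(nrow(ev)), each = rpi)
  ids <- sprintf("ins%04d_r%02d", reps, rep(seq_len(rpi), times = nrow(ev)))
  seqs <- paste0(prefix, frag[reps])

  bf <- config$background_fraction
  n_bg <- if (bf > 0) round(n_signal * bf / (1 - bf)) else 0L
  withr::with_seed(stage_seed(config$seed, "background"), {
    if (n_bg > 0) {
      bg_contig <- sample(names(chars), n_bg, replace = TRUE,
                          prob = lens / sum(lens))
      bg_seq <- character(n_bg)
      for (i in seq_len(n_bg)) {
        L <- lens[[bg_contig[i]]]
        st <- sample.int(L - config$read_length + 1L, 1) - 1L
        piece <- substr(chars[[bg_contig[i]]], st + 1L, st + config$read_length)
        if (stats::runif(1) < 0.5) piece <- revcomp(piece)
        bg_seq[i] <- piece
      }
      ids <- c(ids, sprintf("bg%05d", seq_len(n_bg)))
      seqs <- c(seqs, bg_seq)
    }
  })

  withr::with_seed(stage_seed(config$seed, "errors"), {
    seqs <- apply_substitution_errors(seqs, config$error_rate)
  })

  reads <- tibble(id = ids, sequence = seqs,
                  quality = strrep(config$quality_char, nchar(seqs)))
  truth <- bind_rows(
    tibble(id = ids[seq_len(n_signal)], contig = ev$contig[reps],
           ttaa_start = ev$ttaa_start[reps], orientation = ev$orientation[reps],
           is_background = FALSE),
    if (n_bg > 0) tibble(id = ids[n_signal + seq_len(n_bg)],
                         contig = NA_character_, ttaa_start = NA_integer_,
                         orientation = NA_character_, is_background = TRUE)
  )
  attr(truth, "skipped") <- skipped
  list(reads = reads, truth = truth)
}

#' Write simulation truth as BED6 (+ orientation column)
#'
#' @param truth Truth tibble from [simulate_reads()] or an event tibble from
#'   [simulate_insertions()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  ev <- truth %>%
    filter(if ("is_background" %in% names(truth)) !.data$is_background else TRUE) %>%
    distinct(.data$contig, .data$ttaa_start, .data$orientation) %>%
    arrange(.data$contig, .data$ttaa_start)
  bed <- tibble(contig = ev$contig, start = ev$ttaa_start,
                end = ev$ttaa_start + 4L,
                name = sprintf("event_%d", seq_len(nrow(ev))),
                score = 0L, strand = ".", orientation = ev$orientation)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
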