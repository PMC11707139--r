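#' Genomic feature annotation
#'
#' The annotation layer reduces a gene annotation (GFF3 or BED) to the four
#' feature classes used for insertion-profile comparison — `CDS`, `UTR`,
#' `intron`, `intergenic` — and flattens them so that every base of the genome
#' carries exactly one class.  Where intervals overlap, precedence is
#' `CDS > UTR > intron > intergenic`: a base that is coding in any transcript
#' counts as coding.
#'
#' All internal coordinates are 0-based half-open; GFF3's 1-based inclusive
#' convention is converted at the file boundary.
#'
#' @name annotation
NULL

new_annotation_set <- function(intervals, flattened, contig_lengths) {
  structure(
    list(intervals = intervals, flattened = flattened,
         contig_lengths = contig_lengths, classes = FEATURE_CLASSES),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(x$contig_lengths), " contig(s), ",
      nrow(x$intervals), " interval(s)\n", sep = "")
  fr <- genome_feature_fractions(x)
  print(fr)
  invisible(x)
}

#' @export
#' @method tidy annotation_set
tidy.annotation_set <- function(x, ...) x$intervals

#' Flatten feature intervals to one class per base
#'
#' Builds the per-base class map from an interval table, painting classes in
#' increasing precedence (`gene`/`intron` first, then `UTR`, then `CDS`) over
#' an `intergenic` background, so the highest-precedence class wins.
#' Bases inside a `gene` interval but in no `CDS`/`UTR` become `intron`.
#'
#' @param intervals Tibble with columns `contig`, `start`, `end` (0-based
#'   half-open), `feature_class` (one of `gene`, `CDS`, `UTR`, `intron`,
#'   `intergenic`), and optionally `gene_id`, `strand`.
#' @param genome Genome the intervals refer to (named character or
#'   `DNAStringSet`); supplies contig lengths.
#' @return An `annotation_set`: the interval table plus a per-contig integer
#'   vector of class codes (`1=CDS, 2=UTR, 3=intron, 4=intergenic`).
#' @export
flatten_annotation <- function(intervals, genome) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  if (!all(c("contig", "start", "end", "feature_class") %in% names(intervals))) {
    abort("intervals need columns contig, start, end, feature_class")
  }
  bad <- setdiff(unique(intervals$contig), names(lens))
  if (length(bad)) abort(paste0("interval on unknown contig: ", bad[1]))
  oob <- intervals$start < 0 | intervals$end > lens[intervals$contig] |
    intervals$start >= intervals$end
  if (any(oob)) {
    i <- which(oob)[1]
    abort(sprintf("interval out of range on %s: [%d, %d) vs contig length %d",
                  intervals$contig[i], intervals$start[i], intervals$end[i],
                  lens[[intervals$contig[i]]]))
  }
  flattened <- lapply(lens, function(L) rep.int(4L, L))
  paint <- function(cls, code) {
    sel <- intervals[intervals$feature_class %in% cls, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      v <- flattened[[sel$contig[i]]]
      v[(sel$start[i] + 1L):sel$end[i]] <- code
      flattened[[sel$contig[i]]] <<- v
    }
  }
  paint(c("gene", "intron"), 3L)
  paint("UTR", 2L)
  paint("CDS", 1L)
  if (!"gene_id" %in% names(intervals)) intervals$gene_id <- NA_character_
  if (!"strand" %in% names(intervals)) intervals$strand <- "."
  new_annotation_set(as_tibble(intervals), flattened, lens)
}

#' Read a feature annotation from GFF3 or BED
#'
#' Parses the file with `rtracklayer`, converts coordinates to the internal
#' 0-based half-open convention, and flattens against the genome.  For GFF3,
#' `gene`, `CDS`, `five_prime_UTR`/`three_prime_UTR`/`UTR` and `intron`
#' records are used; purely structural types (`mRNA`, `transcript`, `exon`,
#' `region`, `chromosome`) are ignored silently and anything else is skipped
#' with a warning giving the count.  For BED, the name column carries the
#' class directly.
#'
#' @param path Annotation file path.
#' @param genome Genome the annotation refers to.
#' @param dialect `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return An `annotation_set` (see [flatten_annotation()]).
#' @export
read_annotation <- function(path, genome, dialect = c("auto", "gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "bed" else "gff3")
  df <- as.data.frame(gr)
  if (dialect == "bed") {
    type_raw <- df$name
  } else {
    type_raw <- as.character(df$type)
  }
  cls <- dplyr::case_when(
    type_raw == "CDS" ~ "CDS",
    type_raw %in% c("UTR", "five_prime_UTR", "three_prime_UTR") ~ "UTR",
    type_raw == "intron" ~ "intron",
    type_raw == "gene" ~ "gene",
    type_raw == "intergenic" ~ "intergenic",
    TRUE ~ NA_character_
  )
  structural <- c("mRNA", "transcript", "exon", "region", "chromosome")
  unknown <- is.na(cls) & !(type_raw %in% structural)
  if (any(unknown)) {
    warn(paste0("skipped ", sum(unknown), " interval(s) with unknown feature type"))
  }
  keep <- !is.na(cls)
  intervals <- tibble(
    contig = as.character(df$seqnames)[keep],
    start = df$start[keep] - 1L,   # rtracklayer yields 1-based starts
    end = df$end[keep],
    feature_class = cls[keep],
    gene_id = if ("ID" %in% names(df)) as.character(df$ID)[keep] else NA_character_,
    strand = as.character(df$strand)[keep]
  )
  intervals$strand[intervals$strand == "*"] <- "."
  flatten_annotation(intervals, genome)
}

#' Write an annotation's intervals as BED
#'
#' @param annotation An `annotation_set` or an interval tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  iv <- if (inherits(annotation, "annotation_set")) annotation$intervals else annotation
  bed <- tibble(contig = iv$contig, start = iv$start, end = iv$end,
                name = iv$feature_class, score = 0L,
                strand = ifelse(is.na(iv$strand) | iv$strand == "", ".", iv$strand))
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# class code lookup for 0-based positions on one contig
flattened_class_at <- function(annotation, contig, pos0) {
  v <- annotation$flattened[[contig]]
  if (is.null(v)) abort(paste0("position on unknown contig: ", contig))
  if (any(pos0 < 0 | pos0 >= length(v))) {
    abort(paste0("position out of range on contig ", contig))
  }
  FEATURE_CLASSES[v[pos0 + 1L]]
}

# vectorized lookup over paired contig/position vectors
flattened_classes <- function(annotation, contigs, pos0) {
  out <- character(length(contigs))
  for (nm in unique(contigs)) {
    sel <- contigs == nm
    out[sel] <- flattened_class_at(annotation, nm, pos0[sel])
  }
  out
}
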