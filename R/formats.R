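#' Read a reference genome from FASTA
#'
#' Loads a (multi-)FASTA file into a named `DNAStringSet`, upper-casing the
#' sequence and enforcing the conventions the rest of the pipeline relies on:
#' unique non-empty contig names, non-empty sequences, and an alphabet
#' restricted to `A`, `C`, `G`, `T`, `N`.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (one element per contig).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ttaaCGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  gen <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  # headers may carry descriptions; the contig name is the first word
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (any(!nzchar(names(gen)))) abort(paste0("empty FASTA header in ", path))
  dup <- unique(names(gen)[duplicated(names(gen))])
  if (length(dup)) {
    abort(paste0("duplicate contig name(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  if (any(Biostrings::width(gen) == 0)) {
    bad <- names(gen)[Biostrings::width(gen) == 0][1]
    abort(paste0("empty sequence for record '", bad, "' in ", path))
  }
  gen <- Biostrings::DNAStringSet(toupper(as.character(gen)))
  freq <- Biostrings::alphabetFrequency(gen)
  extra <- rowSums(freq) - rowSums(freq[, c(DNA_BASES, "N"), drop = FALSE])
  if (any(extra > 0)) {
    abort(paste0("record '", names(gen)[extra > 0][1], "' in ", path,
                 " contains characters outside {A,C,G,T,N}"))
  }
  gen
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Read junction reads from FASTQ
#'
#' Strict 4-line-record FASTQ reader returning a tibble, the tabular read
#' container used throughout the package.  Sequence/quality length equality is
#' enforced per record; violations raise a format error naming the record and
#' the line where it starts.
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(id = character(), sequence = character(), quality = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort(paste0("truncated FASTQ record at end of ", path,
                 " (line count ", length(lines), " not a multiple of 4)"))
  }
  i <- seq(1, length(lines), by = 4)
  hdr <- lines[i]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(paste0("FASTQ header at line ", i[bad[1]], " of ", path,
                 " does not start with '@'"))
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  seqs <- toupper(lines[i + 1])
  plus <- lines[i + 2]
  quals <- lines[i + 3]
  if (any(!startsWith(plus, "+"))) {
    j <- which(!startsWith(plus, "+"))[1]
    abort(paste0("FASTQ separator line missing for record '", ids[j],
                 "' (line ", i[j] + 2, " of ", path, ")"))
  }
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism)) {
    j <- mism[1]
    abort(paste0("sequence/quality length mismatch for record '", ids[j],
                 "' (line ", i[j], " of ", path, "): ", nchar(seqs[j]),
                 " vs ", nchar(quals[j])))
  }
  if (any(grepl("[^ACGTN]", seqs))) {
    j <- which(grepl("[^ACGTN]", seqs))[1]
    abort(paste0("record '", ids[j], "' (line ", i[j], " of ", path,
                 ") contains characters outside {A,C,G,T,N}"))
  }
  tibble(id = ids, sequence = seqs, quality = quals)
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    abort("sequence/quality length mismatch in reads table")
  }
  out <- character(4 * nrow(reads))
  if (nrow(reads)) {
    out[seq(1, length(out), 4)] <- paste0("@", reads$id)
    out[seq(2, length(out), 4)] <- reads$sequence
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- reads$quality
  }
  writeLines(out, path)
  invisible(path)
}

#' Write called insertion sites as BED6 plus a TSV report
#'
#' One BED6 line per site covering the 4-bp TTAA target-site duplication
#' (`ttaa_start` to `ttaa_start + 4`), with the read count in the score column.
#' The full site table (strand tallies, ppm, TSD validity) goes to a sibling
#' `<path>.report.tsv` with a commented header echoing the tool version.
#'
#' @param sites A site table from [call_sites()] or its `sites` tibble.
#' @param path Output BED path.
#' @return Invisibly, a list with the `bed` and `report` paths.
#' @export
write_sites_bed <- function(sites, path) {
  sites <- sites_tbl(sites)
  report <- paste0(path, ".report.tsv")
  if (nrow(sites)) {
    bed <- tibble(
      contig = sites$contig,
      start = sites$ttaa_start,
      end = sites$ttaa_start + 4L,
      name = sprintf("site_%d", seq_len(nrow(sites))),
      score = sites$read_count,
      strand = "."
    )
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  } else {
    writeLines(character(), path)
  }
  write_report_tsv(sites, report,
                   comments = paste0("n_sites=", nrow(sites)))
  invisible(list(bed = path, report = report))
}

#' Read a BED6 site file back into a tibble
#'
#' Round-trip companion of [write_sites_bed()].
#'
#' @param path BED path written by [write_sites_bed()].
#' @return Tibble with columns `contig`, `ttaa_start`, `name`, `read_count`.
#' @export
read_sites_bed <- function(path) {
  if (length(readLines(path)) == 0) {
    return(tibble(contig = character(), ttaa_start = integer(),
                  name = character(), read_count = integer()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    ttaa_start = BiocGenerics::start(gr) - 1L,
    name = gr$name,
    read_count = as.integer(gr$score)
  )
}
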