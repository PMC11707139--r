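#' Junction position-frequency profile
#'
#' Builds the position frequency matrix over the first `L` nucleotides of the
#' trimmed junction (the retained TIR tail, then the duplicated TTAA target
#' site, then the 3' genomic flank) and computes the Shannon information
#' content per position against a uniform background:
#' `IC_p = 2 + sum_b f_pb * log2(f_pb)` (with `0*log2(0) = 0`), in bits,
#' bounded by \[0, 2\].  No small-sample correction is applied, so a fully
#' conserved position scores exactly 2 bits.
#'
#' @param trimmed A `trim_result` or a tibble with `tir_tail` and
#'   `genomic_part` columns (or a `window`/`sequence` column of ready-made
#'   windows).
#' @param L Window length (default 15: with a 4-base TIR tail, positions 1-4
#'   are the TIR tip, 5-8 the TTAA TSD, 9-15 genomic flank).
#' @return Object of class `position_profile`: list with `L`, `counts`
#'   (4 x L matrix over A,C,G,T), `totals`, `freqs`, `bits`, `n_reads`,
#'   `n_skipped` (reads shorter than `L`).
#' @export
build_position_profile <- function(trimmed, L = 15L) {
  L <- as.integer(L)
  if (inherits(trimmed, "trim_result")) trimmed <- trimmed$trimmed
  windows <- if (all(c("tir_tail", "genomic_part") %in% names(trimmed))) {
    paste0(trimmed$tir_tail, trimmed$genomic_part)
  } else if ("window" %in% names(trimmed)) {
    trimmed$window
  } else if ("sequence" %in% names(trimmed)) {
    trimmed$sequence
  } else {
    abort("need tir_tail+genomic_part, window, or sequence columns")
  }
  usable <- nchar(windows) >= L
  n_skipped <- sum(!usable)
  windows <- substr(windows[usable], 1L, L)
  if (length(windows) == 0) abort("no usable reads of length >= L")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  counts <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
  common <- intersect(rownames(cm), DNA_BASES)
  counts[common, ] <- cm[common, , drop = FALSE]
  totals <- colSums(counts)   # N bases reduce the position total
  freqs <- sweep(counts, 2, pmax(totals, 1L), "/")
  structure(list(L = L, counts = counts, totals = totals, freqs = freqs,
                 bits = ic_bits(freqs, totals), n_reads = length(windows),
                 n_skipped = n_skipped),
            class = "position_profile")
}

ic_bits <- function(freqs, totals) {
  plogp <- freqs * log2(freqs)
  plogp[freqs == 0] <- 0
  bits <- 2 + colSums(plogp)
  bits[totals == 0] <- NA_real_   # undefined where no base was observed
  bits
}

#' Per-position information content of a profile
#'
#' @param profile A `position_profile`.
#' @return Numeric vector of bits per position (`NA` where the position had
#'   no observed base).
#' @export
information_content <- function(profile) {
  stopifnot(inherits(profile, "position_profile"))
  ic_bits(profile$freqs, profile$totals)
}

#' @export
print.position_profile <- function(x, ...) {
  cat("<position_profile> L=", x$L, ", ", x$n_reads, " reads (",
      x$n_skipped, " skipped)\n", sep = "")
  cat("bits:", paste(sprintf("%.2f", x$bits), collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @method tidy position_profile
tidy.position_profile <- function(x, ...) {
  long <- as_tibble(t(x$counts))
  long$position <- seq_len(x$L)
  long <- tidyr::pivot_longer(long, dplyr::all_of(DNA_BASES),
                              names_to = "base", values_to = "count")
  long$freq <- x$freqs[cbind(match(long$base, DNA_BASES), long$position)]
  long$bits <- x$bits[long$position]
  long[, c("position", "base", "count", "freq", "bits")]
}

#' @export
#' @method glance position_profile
glance.position_profile <- function(x, ...) {
  tibble(L = x$L, n_reads = x$n_reads, n_skipped = x$n_skipped,
         mean_bits = mean(x$bits, na.rm = TRUE),
         max_bits = max(x$bits, na.rm = TRUE))
}

#' Write a position profile report
#'
#' TSV with one row per position: base counts, frequencies and information
#' content, under a commented header echoing `L` and the read count.
#'
#' @param profile A `position_profile`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_profile_report <- function(profile, path) {
  df <- tibble(position = seq_len(profile$L))
  for (b in DNA_BASES) df[[paste0("count_", b)]] <- profile$counts[b, ]
  for (b in DNA_BASES) df[[paste0("freq_", b)]] <- profile$freqs[b, ]
  df$total <- profile$totals
  df$bits <- profile$bits
  write_report_tsv(df, path,
                   comments = c(sprintf("L=%d", profile$L),
                                sprintf("n_reads=%d", profile$n_reads)))
  invisible(path)
}

#' Read a position profile report back
#'
#' @param path TSV written by [write_profile_report()].
#' @return The report tibble.
#' @export
read_profile_report <- function(path) read_report_tsv(path)

#' Logo-style plot of a position profile
#'
#' Per-position information content as columns, filled and labelled by the
#' consensus base — a compact summary of the junction logo (TIR tip, TTAA
#' target-site duplication, then variable genomic flank).
#'
#' @param object A `position_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot position_profile
autoplot.position_profile <- function(object, ...) {
  consensus <- DNA_BASES[apply(object$freqs, 2, which.max)]
  df <- tibble(position = seq_len(object$L), bits = object$bits,
               consensus = consensus)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits,
                                   fill = .data$consensus)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$consensus), vjust = -0.3, size = 3) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$L)) +
    ggplot2::ylim(0, 2.2) +
    ggplot2::labs(x = "junction position (nt)", y = "information content (bits)",
                  fill = "consensus") +
    ggplot2::theme_minimal()
}
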