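#' Trimming configuration
#'
#' @param transposon_prefix The transposon-derived prefix expected at the read
#'   start (primer + TIR terminal bases).
#' @param retain_tail Number of terminal transposon bases (`K`) kept on the
#'   trimmed read so the junction logo shows the TIR tip; default 4.
#' @param max_mismatch_rate Fractional mismatch tolerance `e`; the prefix is
#'   accepted with up to `floor(e * nchar(prefix))` mismatches.
#' @param min_genomic_length Minimum genomic fragment length after trimming.
#' @return A validated list of class `trim_config`.
#' @export
trim_config <- function(transposon_prefix,
                        retain_tail = 4L,
                        max_mismatch_rate = 0.10,
                        min_genomic_length = 20L) {
  transposon_prefix <- toupper(transposon_prefix)
  if (grepl("[^ACGT]", transposon_prefix)) abort("transposon_prefix must be over {A,C,G,T}")
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 0.5) {
    abort("max_mismatch_rate must be in [0, 0.5)")
  }
  if (retain_tail < 0 || retain_tail > nchar(transposon_prefix)) {
    abort("retain_tail must be between 0 and nchar(transposon_prefix)")
  }
  if (min_genomic_length < 1) abort("min_genomic_length must be >= 1")
  structure(list(transposon_prefix = transposon_prefix,
                 retain_tail = as.integer(retain_tail),
                 max_mismatch_rate = max_mismatch_rate,
                 min_genomic_length = as.integer(min_genomic_length)),
            class = "trim_config")
}

#' Trim the transposon prefix from junction reads
#'
#' Matches the configured prefix against read positions `[0, nchar(prefix))`
#' by Hamming distance, anchored at the read start (the self-reporting
#' amplicon always begins with the transposon end, so no internal search is
#' needed).  A read is accepted iff its mismatch count is at most
#' `floor(e * nchar(prefix))`; reads shorter than the prefix, or failing the
#' match, are discarded as `no_transposon`, and accepted reads whose genomic
#' remainder is shorter than `min_genomic_length` as `too_short`.
#'
#' The retained `tir_tail` is taken from the *read* (last `K` bases of the
#' matched prefix region), not from the reference prefix, so sequencing errors
#' propagate into the junction logo exactly as sequenced.
#'
#' @param reads Tibble with columns `id`, `sequence` (quality optional).
#' @param config A [trim_config()].
#' @return An object of class `trim_result`: list with
#'   * `trimmed`: tibble `id`, `tir_tail`, `genomic_part`, `n_prefix_mismatches`;
#'   * `discarded`: tibble `id`, `reason` (`no_transposon` or `too_short`);
#'   * `stats`: one-row tibble `input`, `trimmed`, `no_transposon`, `too_short`.
#' @export
trim_reads <- function(reads, config) {
  stopifnot(inherits(config, "trim_config"))
  prefix <- config$transposon_prefix
  P <- nchar(prefix)
  K <- config$retain_tail
  allowed <- floor(config$max_mismatch_rate * P)

  n <- nrow(reads)
  mism <- rep(NA_integer_, n)
  long_enough <- nchar(reads$sequence) >= P
  if (any(long_enough)) {
    sub <- substr(reads$sequence[long_enough], 1L, P)
    pm <- do.call(rbind, strsplit(sub, "", fixed = TRUE))
    pref_chars <- strsplit(prefix, "", fixed = TRUE)[[1]]
    mism[long_enough] <- as.integer(rowSums(pm != matrix(pref_chars, nrow(pm), P, byrow = TRUE)))
  }
  accept <- !is.na(mism) & mism <= allowed
  genomic <- ifelse(accept, substr(reads$sequence, P + 1L, nchar(reads$sequence)), NA)
  too_short <- accept & nchar(genomic) < config$min_genomic_length
  keep <- accept & !too_short

  trimmed <- tibble(
    id = reads$id[keep],
    tir_tail = if (K > 0) substr(reads$sequence[keep], P - K + 1L, P) else "",
    genomic_part = genomic[keep],
    n_prefix_mismatches = mism[keep]
  )
  discarded <- bind_rows(
    tibble(id = reads$id[!accept], reason = "no_transposon"),
    tibble(id = reads$id[too_short], reason = "too_short")
  )
  stats <- tibble(input = n, trimmed = sum(keep),
                  no_transposon = sum(!accept), too_short = sum(too_short))
  stopifnot(stats$input == stats$trimmed + stats$no_transposon + stats$too_short)
  structure(list(trimmed = trimmed, discarded = discarded, stats = stats),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat("<trim_result>\n")
  print(x$stats)
  invisible(x)
}

#' @export
#' @method tidy trim_result
tidy.trim_result <- function(x, ...) x$trimmed

#' @export
#' @method glance trim_result
glance.trim_result <- function(x, ...) x$stats

#' Write trimmed reads and trimming statistics
#'
#' @param trim A `trim_result`.
#' @param path Output TSV path for the trimmed reads.
#' @param stats_path Optional TSV path for the statistics.
#' @return The path, invisibly.
#' @export
write_trimmed_tsv <- function(trim, path, stats_path = NULL) {
  write_report_tsv(trim$trimmed, path,
                   comments = sprintf("trimmed=%d of %d reads",
                                      trim$stats$trimmed, trim$stats$input))
  if (!is.null(stats_path)) write_report_tsv(trim$stats, stats_path)
  invisible(path)
}
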