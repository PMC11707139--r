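#' Insertion-site calling
#'
#' Converts unique alignments of trimmed junction fragments into canonical
#' TTAA insertion sites.  A trimmed fragment begins with the duplicated TTAA
#' target site, so on the plus strand the site coordinate is the alignment
#' start, and on the minus strand it is `start + fragment_length - 4` — the
#' self-reverse-complementarity of TTAA makes both strand cases of one
#' insertion canonicalize to the same `ttaa_start`.
#'
#' @name site_calling
NULL

# accept a site_table or a plain tibble of sites
sites_tbl <- function(x) {
  if (inherits(x, "site_table")) x$sites else as_tibble(x)
}

#' Call TTAA insertion sites from alignments
#'
#' Aggregates unique alignments by canonical TTAA coordinate into a site
#' table with read counts, strand tallies, TSD validation against the
#' reference (`ttaa_valid` iff the 4-bp reference window is exactly `TTAA`),
#' and peaks-per-million normalization
#' `ppm_i = read_count_i / sum(read_count) * 1e6` over the retained sites.
#' Sites failing TSD validation are dropped by default (the junction logo of
#' real libraries shows an essentially invariant TSD, so non-TTAA junctions
#' are treated as artifacts); with `keep_invalid = TRUE` they are kept,
#' flagged, and excluded from the ppm denominator (`ppm = NA` for them).
#'
#' @param alignments A `map_result` or its alignment tibble.
#' @param genome The reference genome.
#' @param keep_invalid Keep sites whose reference window is not TTAA?
#' @return Object of class `site_table`: list with
#'   * `sites`: tibble `contig`, `ttaa_start`, `read_count`, `plus_count`,
#'     `minus_count`, `ppm`, `ttaa_valid`, sorted by (contig, ttaa_start);
#'   * `totals`: list `reads_used`, `sites`, `reads_invalid`, `sites_invalid`,
#'     `rejected_out_of_bounds`.
#' @export
call_sites <- function(alignments, genome, keep_invalid = FALSE) {
  if (inherits(alignments, "map_result")) alignments <- alignments$alignments
  genome <- as_genome(genome)
  chars <- genome_chars(genome)
  lens <- genome_lengths(genome)
  aln <- filter(alignments, .data$status == "unique")
  empty <- tibble(contig = character(), ttaa_start = integer(),
                  read_count = integer(), plus_count = integer(),
                  minus_count = integer(), ppm = double(), ttaa_valid = logical())
  if (nrow(aln) == 0) {
    return(structure(list(sites = empty,
                          totals = list(reads_used = 0L, sites = 0L,
                                        reads_invalid = 0L, sites_invalid = 0L,
                                        rejected_out_of_bounds = 0L)),
                     class = "site_table"))
  }
  aln <- mutate(aln, ttaa_start = ifelse(.data$strand == "+", .data$start,
                                         .data$start + .data$fragment_length - 4L))
  in_bounds <- aln$ttaa_start >= 0 & aln$ttaa_start + 4L <= lens[aln$contig]
  rejected <- sum(!in_bounds)
  aln <- aln[in_bounds, , drop = FALSE]
  aln$ref_window <- substr(chars[aln$contig], aln$ttaa_start + 1L, aln$ttaa_start + 4L)

  sites <- aln %>%
    group_by(.data$contig, .data$ttaa_start) %>%
    summarise(read_count = n(),
              plus_count = sum(.data$strand == "+"),
              minus_count = sum(.data$strand == "-"),
              ttaa_valid = .data$ref_window[1] == "TTAA",
              .groups = "drop") %>%
    arrange(.data$contig, .data$ttaa_start)

  valid <- sites$ttaa_valid
  totals <- list(reads_used = sum(sites$read_count[valid]),
                 sites = sum(valid),
                 reads_invalid = sum(sites$read_count[!valid]),
                 sites_invalid = sum(!valid),
                 rejected_out_of_bounds = rejected)
  denom <- totals$reads_used
  sites$ppm <- ifelse(valid & denom > 0, sites$read_count / denom * 1e6, NA_real_)
  if (!keep_invalid) sites <- sites[valid, , drop = FALSE]
  sites <- sites[, c("contig", "ttaa_start", "read_count", "plus_count",
                     "minus_count", "ppm", "ttaa_valid")]
  structure(list(sites = sites, totals = totals), class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat("<site_table> ", x$totals$sites, " valid site(s), ",
      x$totals$reads_used, " reads used",
      if (x$totals$sites_invalid) paste0(", ", x$totals$sites_invalid,
                                         " invalid-TSD site(s)"), "\n", sep = "")
  print(x$sites)
  invisible(x)
}

#' @export
#' @method tidy site_table
tidy.site_table <- function(x, ...) x$sites

#' @export
#' @method glance site_table
glance.site_table <- function(x, ...) as_tibble(x$totals)

#' Per-chromosome fraction of insertion sites
#'
#' Fraction of distinct insertion sites on each contig (distinct-site
#' counting, matching how genome-wide insertion distributions are reported).
#'
#' @param sites A `site_table` or sites tibble.
#' @return Tibble `contig`, `n_sites`, `fraction`; fractions sum to 1.
#' @export
chromosome_fractions <- function(sites) {
  s <- sites_tbl(sites)
  if (nrow(s) == 0) abort("chromosome_fractions: empty site table")
  out <- s %>%
    distinct(.data$contig, .data$ttaa_start) %>%
    count(.data$contig, name = "n_sites") %>%
    mutate(fraction = .data$n_sites / sum(.data$n_sites))
  out
}

#' Precision and recall of called sites against simulation truth
#'
#' Matches called sites to ground-truth events on (contig, ttaa_start).
#'
#' @param sites A `site_table` or sites tibble.
#' @param truth Truth tibble ([simulate_reads()]) or event tibble
#'   ([simulate_insertions()]).
#' @return One-row tibble `n_called`, `n_truth`, `n_matched`, `precision`,
#'   `recall`.
#' @export
evaluate_site_calls <- function(sites, truth) {
  s <- distinct(sites_tbl(sites), .data$contig, .data$ttaa_start)
  if ("is_background" %in% names(truth)) truth <- filter(truth, !.data$is_background)
  t <- distinct(truth, .data$contig, .data$ttaa_start)
  matched <- nrow(inner_join(s, t, by = c("contig", "ttaa_start")))
  tibble(n_called = nrow(s), n_truth = nrow(t), n_matched = matched,
         precision = if (nrow(s)) matched / nrow(s) else NA_real_,
         recall = if (nrow(t)) matched / nrow(t) else NA_real_)
}
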