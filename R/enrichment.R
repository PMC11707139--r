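#' Feature-class distributions and insertion-profile comparison
#'
#' Insertion preference into TTAA sites means the genome-wide base-pair
#' composition is the wrong null for feature enrichment: the expected class
#' distribution must be computed over TTAA motifs, not bases.  This module
#' produces three comparable distributions over the classes
#' `CDS`, `UTR`, `intron`, `intergenic` — per-base genome composition
#' (`genome_bp`), per-TTAA-motif composition (`ttaa_motifs`), and observed
#' insertion sites (`insertion_sites`) — and compares insertion profiles
#' between conditions with a chi-square homogeneity test.
#'
#' @name feature_enrichment
NULL

feature_distribution <- function(counts, basis) {
  counts <- counts[FEATURE_CLASSES]
  counts[is.na(counts)] <- 0
  names(counts) <- FEATURE_CLASSES
  tibble(feature_class = factor(FEATURE_CLASSES, levels = FEATURE_CLASSES),
         count = as.numeric(counts),
         fraction = as.numeric(counts) / sum(counts),
         basis = basis)
}

#' Feature class of insertion sites
#'
#' Annotates each site with the flattened feature class at its `ttaa_start`
#' base (precedence `CDS > UTR > intron > intergenic` was applied when the
#' annotation was flattened; a TTAA motif spanning two classes is classified
#' by its start base).
#'
#' @param sites A `site_table` or tibble with `contig`, `ttaa_start`.
#' @param annotation An `annotation_set`.
#' @return The sites tibble with a `feature_class` column appended.
#' @export
assign_features <- function(sites, annotation) {
  s <- sites_tbl(sites)
  s$feature_class <- flattened_classes(annotation, s$contig, s$ttaa_start)
  s
}

#' Genome-wide per-base feature composition
#'
#' @param annotation An `annotation_set`.
#' @return Tibble `feature_class`, `count` (bp), `fraction`, `basis =
#'   "genome_bp"`.
#' @export
genome_feature_fractions <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  tab <- table(factor(FEATURE_CLASSES[unlist(annotation$flattened, use.names = FALSE)],
                      levels = FEATURE_CLASSES))
  feature_distribution(setNames(as.numeric(tab), names(tab)), "genome_bp")
}

#' Feature composition of the genome's TTAA motifs
#'
#' Every TTAA motif is assigned the class at its start base; fractions are
#' over all TTAA motifs.  This is the TTAA-normalized expected distribution
#' for insertion-profile comparison.
#'
#' @param genome Genome.
#' @param annotation An `annotation_set`.
#' @return Tibble as in [genome_feature_fractions()] with
#'   `basis = "ttaa_motifs"`.
#' @export
ttaa_feature_distribution <- function(genome, annotation) {
  sites <- enumerate_ttaa_sites(genome)
  if (nrow(sites) == 0) abort("genome contains no TTAA motif")
  cls <- flattened_classes(annotation, sites$contig, sites$start)
  tab <- table(factor(cls, levels = FEATURE_CLASSES))
  feature_distribution(setNames(as.numeric(tab), names(tab)), "ttaa_motifs")
}

#' Feature composition of called insertion sites
#'
#' Distinct-site counting (each site contributes once regardless of read
#' depth), matching how insertion distributions are reported.
#'
#' @param sites A `site_table` or sites tibble.
#' @param annotation An `annotation_set`.
#' @param weight_by_reads Tally reads instead of distinct sites.
#' @return Tibble as in [genome_feature_fractions()] with
#'   `basis = "insertion_sites"`.
#' @export
insertion_feature_distribution <- function(sites, annotation, weight_by_reads = FALSE) {
  s <- sites_tbl(sites)
  if (nrow(s) == 0) abort("insertion_feature_distribution: empty site table")
  s <- assign_features(distinct(s, .data$contig, .data$ttaa_start,
                                .keep_all = TRUE), annotation)
  w <- if (weight_by_reads) s$read_count else rep(1, nrow(s))
  tab <- tapply(w, factor(s$feature_class, levels = FEATURE_CLASSES), sum)
  tab[is.na(tab)] <- 0
  feature_distribution(setNames(as.numeric(tab), FEATURE_CLASSES), "insertion_sites")
}

as_class_counts <- function(x, arg) {
  if (is.data.frame(x)) {
    cc <- if ("count" %in% names(x)) x$count else x$n
    nm <- as.character(x$feature_class)
    x <- setNames(cc, nm)
  }
  if (is.null(names(x))) abort(paste0(arg, " must be a named count vector or ",
                                      "a tibble with feature_class and count columns"))
  x
}

#' Chi-square homogeneity test between two insertion profiles
#'
#' Builds the 2 x C contingency table of class counts for two conditions,
#' computes expected counts `E_ij = row_i * col_j / total`, drops classes
#' whose column total is zero (so `df = nonzero classes - 1`), and evaluates
#' `X^2 = sum (O - E)^2 / E` with the upper-tail chi-square p-value.  Classes
#' with any expected count below 5 are flagged; with
#' `min_expected_policy = "merge_into_other"` they are pooled into a single
#' `other` class before testing.
#'
#' @param counts_a,counts_b Named count vectors over the same classes, or
#'   tibbles with `feature_class` and `count` columns (e.g. from
#'   [insertion_feature_distribution()]).
#' @param min_expected_policy `"warn"` (default) or `"merge_into_other"`.
#' @return Object of class `profile_comparison`: list with `statistic`, `df`,
#'   `p_value`, `observed` and `expected` matrices, `low_expected` (flagged
#'   classes), `policy`.
#' @export
#' @examples
#' compare_profiles(c(CDS = 10, UTR = 20), c(CDS = 20, UTR = 10))
compare_profiles <- function(counts_a, counts_b,
                             min_expected_policy = c("warn", "merge_into_other")) {
  policy <- match.arg(min_expected_policy)
  a <- as_class_counts(counts_a, "counts_a")
  b <- as_class_counts(counts_b, "counts_b")
  if (!identical(sort(names(a)), sort(names(b)))) {
    abort("counts_a and counts_b must cover the same classes")
  }
  b <- b[names(a)]
  if (sum(a) <= 0 || sum(b) <= 0) abort("each condition needs a positive total count")
  obs <- rbind(a = a, b = b)
  nonzero <- colSums(obs) > 0
  obs <- obs[, nonzero, drop = FALSE]
  if (ncol(obs) < 2) abort("need at least two classes with nonzero totals")
  expected_full <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  low <- colnames(obs)[apply(expected_full < 5, 2, any)]
  if (policy == "merge_into_other" && length(low) >= 2) {
    keep <- setdiff(colnames(obs), low)
    obs <- cbind(obs[, keep, drop = FALSE], other = rowSums(obs[, low, drop = FALSE]))
    expected_full <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  } else if (policy == "warn" && length(low)) {
    warn(paste0("expected count < 5 for class(es): ", paste(low, collapse = ", ")))
  }
  ct <- suppressWarnings(stats::chisq.test(obs, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), observed = obs,
                 expected = ct$expected, low_expected = low, policy = policy),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> X-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (length(x$low_expected)) {
    cat("low expected counts (<5):", paste(x$low_expected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
#' @method tidy profile_comparison
tidy.profile_comparison <- function(x, ...) {
  tibble(feature_class = rep(colnames(x$observed), each = 2),
         condition = rep(rownames(x$observed), ncol(x$observed)),
         observed = as.vector(x$observed),
         expected = as.vector(x$expected))
}

#' @export
#' @method glance profile_comparison
glance.profile_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n_a = sum(x$observed["a", ]), n_b = sum(x$observed["b", ]),
         n_low_expected = length(x$low_expected))
}

#' Write the feature-enrichment report
#'
#' One TSV whose columns mirror the standard enrichment table: the per-base
#' genome composition, the TTAA-motif composition, and one column of
#' insertion fractions per condition/replicate, plus an optional chi-square
#' summary appended as commented lines.
#'
#' @param distributions A list of distribution tibbles (from the
#'   `*_feature_*` functions); names become column names, else the `basis`
#'   field is used.
#' @param path Output TSV path.
#' @param comparison Optional `profile_comparison` to append.
#' @return The path, invisibly.
#' @export
enrichment_report <- function(distributions, path, comparison = NULL) {
  if (is.null(names(distributions)) || any(!nzchar(names(distributions)))) {
    names(distributions) <- vapply(distributions, function(d) d$basis[1], "")
  }
  wide <- tibble(feature_class = FEATURE_CLASSES)
  for (nm in names(distributions)) {
    d <- distributions[[nm]]
    wide[[nm]] <- d$fraction[match(wide$feature_class, as.character(d$feature_class))]
    wide[[nm]][is.na(wide[[nm]])] <- 0
  }
  comments <- character()
  if (!is.null(comparison)) {
    comments <- sprintf("chi-square: statistic=%.6g df=%d p=%.6g",
                        comparison$statistic, comparison$df, comparison$p_value)
  }
  write_report_tsv(wide, path, comments = comments)
  invisible(path)
}

#' Read an enrichment report back
#'
#' @param path TSV written by [enrichment_report()].
#' @return The wide fractions tibble.
#' @export
read_enrichment_report <- function(path) read_report_tsv(path)

#' Plot feature-class distributions side by side
#'
#' @param distributions List (optionally named) of distribution tibbles.
#' @return A ggplot of stacked class fractions per basis.
#' @export
plot_feature_distributions <- function(distributions) {
  if (is.null(names(distributions)) || any(!nzchar(names(distributions)))) {
    names(distributions) <- vapply(distributions, function(d) d$basis[1], "")
  }
  df <- bind_rows(distributions, .id = "set")
  df$set <- factor(df$set, levels = names(distributions))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$fraction,
                                   fill = .data$feature_class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "fraction", fill = "feature class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap-style plot of per-chromosome insertion fractions
#'
#' @param fractions Tibble from [chromosome_fractions()], or a named list of
#'   them (one per condition/replicate).
#' @return A ggplot tile plot.
#' @export
plot_chromosome_fractions <- function(fractions) {
  if (is.data.frame(fractions)) fractions <- list(sites = fractions)
  df <- bind_rows(fractions, .id = "set")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$contig,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "fraction of insertions") +
    ggplot2::theme_minimal()
}
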