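toy_annotation <- function() {
  genome <- c(c1 = strrep("A", 50))
  intervals <- tibble::tibble(contig = "c1", start = c(5L, 10L), end = c(30L, 20L),
                              feature_class = c("gene", "CDS"))
  list(genome = genome, ann = flatten_annotation(intervals, genome))
}

test_that("sites are classified under CDS > UTR > intron > intergenic precedence", {
  t <- toy_annotation()
  s <- assign_features(tibble::tibble(contig = "c1", ttaa_start = c(12L, 25L, 2L)),
                       t$ann)
  expect_equal(s$feature_class, c("CDS", "intron", "intergenic"))

  # base covered by CDS of one gene and the body of another stays CDS
  genome <- c(c1 = strrep("A", 40))
  iv <- tibble::tibble(contig = "c1", start = c(0L, 5L, 10L), end = c(20L, 30L, 15L),
                       feature_class = c("gene", "gene", "CDS"))
  ann <- flatten_annotation(iv, genome)
  expect_equal(assign_features(tibble::tibble(contig = "c1", ttaa_start = 12L),
                               ann)$feature_class, "CDS")

  expect_error(assign_features(tibble::tibble(contig = "cX", ttaa_start = 1L), t$ann),
               "unknown contig")
})

test_that("genome composition matches the per-base layout", {
  t <- toy_annotation()
  fr <- genome_feature_fractions(t$ann)
  expect_equal(fr$fraction[fr$feature_class == "intergenic"], 0.5)
  expect_equal(fr$fraction[fr$feature_class == "intron"], 0.3)
  expect_equal(fr$fraction[fr$feature_class == "CDS"], 0.2)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)

  empty_ann <- flatten_annotation(
    tibble::tibble(contig = character(), start = integer(), end = integer(),
                   feature_class = character()),
    c(c1 = "ACGTACGT"))
  fr0 <- genome_feature_fractions(empty_ann)
  expect_equal(fr0$fraction[fr0$feature_class == "intergenic"], 1)
})

test_that("TTAA composition matches examples and the classify-and-count oracle", {
  # all TTAA inside one CDS
  genome <- c(c1 = strrep("TTAA", 10))
  ann <- flatten_annotation(tibble::tibble(contig = "c1", start = 0L, end = 40L,
                                           feature_class = "CDS"), genome)
  d <- ttaa_feature_distribution(genome, ann)
  expect_equal(d$fraction[d$feature_class == "CDS"], 1)

  expect_error(ttaa_feature_distribution(c(c1 = "CCCCGGGG"), ann), "no TTAA")

  # random genome vs brute-force per-position classification
  withr::with_seed(7, {
    s <- rand_dna(50000, gc = 0.45)
  })
  genome2 <- c(chr = s)
  iv <- tibble::tibble(contig = "chr", start = c(1000L, 2000L, 30000L),
                       end = c(12000L, 8000L, 41000L),
                       feature_class = c("gene", "CDS", "UTR"))
  ann2 <- flatten_annotation(iv, genome2)
  got <- ttaa_feature_distribution(genome2, ann2)
  sites <- oracle_ttaa_scan(genome2)
  cls <- vapply(sites$start, function(p) oracle_classify(iv, "chr", p), "")
  exp_counts <- table(factor(cls, levels = c("CDS", "UTR", "intron", "intergenic")))
  expect_equal(got$count, as.numeric(exp_counts))
})

test_that("unbiased insertion sampling converges to the TTAA distribution", {
  cfg <- sim_config(seed = 29, genome_length = 200000, n_contigs = 2,
                    gc_fraction = 0.4, n_genes = 30, n_insertions = 1000,
                    reads_per_insertion = 1)
  gen <- generate_genome(cfg)
  ev <- simulate_insertions(gen$genome, gen$annotation, cfg)
  idist <- insertion_feature_distribution(
    dplyr::rename(ev, dummy = orientation), gen$annotation)
  tdist <- ttaa_feature_distribution(gen$genome, gen$annotation)
  expect_lt(max(abs(idist$fraction - tdist$fraction)), 0.05)
  # a zero-weight class never appears
  cfg0 <- sim_config(seed = 29, genome_length = 200000, n_contigs = 2,
                     gc_fraction = 0.4, n_genes = 30, n_insertions = 200,
                     reads_per_insertion = 1,
                     feature_bias = c(CDS = 0, UTR = 1, intron = 1, intergenic = 1))
  ev0 <- simulate_insertions(gen$genome, gen$annotation, cfg0)
  expect_false(any(ev0$feature_class == "CDS"))
})

test_that("chi-square homogeneity matches hand-checked values and is symmetric", {
  same <- compare_profiles(c(CDS = 10, UTR = 20, intron = 30, intergenic = 40),
                           c(CDS = 10, UTR = 20, intron = 30, intergenic = 40))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  ab <- suppressWarnings(compare_profiles(c(x = 10, y = 20), c(x = 20, y = 10)))
  expect_equal(ab$statistic, 6.6667, tolerance = 1e-4)
  expect_equal(ab$p_value, 0.00982, tolerance = 1e-3)
  expect_equal(ab$df, 1L)
  ba <- suppressWarnings(compare_profiles(c(x = 20, y = 10), c(x = 10, y = 20)))
  expect_equal(ab$statistic, ba$statistic)
  expect_equal(ab$p_value, ba$p_value)

  expect_error(compare_profiles(c(x = 1, y = 2), c(x = 1, z = 2)), "same classes")
})

test_that("zero-total classes drop from df and low counts follow the policy", {
  a <- c(CDS = 0, UTR = 30, intron = 40, intergenic = 50)
  b <- c(CDS = 0, UTR = 25, intron = 45, intergenic = 50)
  res <- compare_profiles(a, b)
  expect_equal(res$df, 2L)  # CDS column dropped entirely

  low_a <- c(CDS = 2, UTR = 1, intron = 50, intergenic = 60)
  low_b <- c(CDS = 1, UTR = 2, intron = 55, intergenic = 58)
  expect_warning(compare_profiles(low_a, low_b), "expected count < 5")
  merged <- compare_profiles(low_a, low_b, min_expected_policy = "merge_into_other")
  expect_true("other" %in% colnames(merged$observed))
  expect_equal(sum(merged$observed), sum(low_a) + sum(low_b))
})

test_that("the enrichment report renders all bases with columns summing to one", {
  t <- toy_annotation()
  genome <- c(c1 = paste0(strrep("TTAA", 5), strrep("C", 30)))
  ann <- flatten_annotation(tibble::tibble(contig = "c1", start = c(5L, 10L),
                                           end = c(30L, 20L),
                                           feature_class = c("gene", "CDS")),
                            genome)
  dists <- list(
    genome_bp = genome_feature_fractions(ann),
    ttaa_motifs = ttaa_feature_distribution(genome, ann),
    rep1 = insertion_feature_distribution(
      tibble::tibble(contig = "c1", ttaa_start = c(0L, 12L)), ann)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  cmp <- suppressWarnings(compare_profiles(dists$rep1, dists$ttaa_motifs))
  enrichment_report(dists, path, comparison = cmp)
  back <- read_enrichment_report(path)
  expect_equal(nrow(back), 4L)  # every class present, zeros never blank
  for (col in c("genome_bp", "ttaa_motifs", "rep1")) {
    expect_equal(sum(back[[col]]), 1, tolerance = 1e-9)
    expect_false(any(is.na(back[[col]])))
  }
  expect_true(any(grepl("chi-square", readLines(path))))
})
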