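small_cfg <- function(...) {
  args <- utils::modifyList(list(seed = 11, genome_length = 20000, n_contigs = 2,
                                 n_genes = 4, n_insertions = 30,
                                 reads_per_insertion = 4),
                            list(...))
  do.call(sim_config, args)
}

test_that("genome generation is seed-deterministic with valid annotation", {
  g1 <- generate_genome(small_cfg())
  g2 <- generate_genome(small_cfg())
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$annotation$intervals, g2$annotation$intervals)

  fr <- genome_feature_fractions(g1$annotation)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  expect_true(all(fr$count >= 0))
  # construction guarantee: at least one TTAA per kb on average per contig
  for (nm in names(g1$genome)) {
    n_ttaa <- sum(enumerate_ttaa_sites(g1$genome)$contig == nm)
    expect_gte(n_ttaa, Biostrings::width(g1$genome)[names(g1$genome) == nm] / 1000)
  }
})

test_that("generated GC content tracks the configured fraction", {
  cfg <- sim_config(seed = 5, genome_length = 100000, n_contigs = 1,
                    gc_fraction = 0.5, n_genes = 0, n_insertions = 10)
  g <- generate_genome(cfg)$genome
  freq <- Biostrings::alphabetFrequency(g)[1, c("C", "G")]
  expect_equal(sum(freq) / 100000, 0.5, tolerance = 0.02)
})

test_that("TTAA enumeration matches examples and the naive scan oracle", {
  expect_equal(enumerate_ttaa_sites(c(c1 = "TTAAGTTAA"))$start, c(0L, 5L))
  expect_equal(enumerate_ttaa_sites(c(c1 = "TTAATTAA"))$start, c(0L, 4L))
  expect_equal(nrow(enumerate_ttaa_sites(c(c1 = "TTNA"))), 0L)

  withr::with_seed(42, {
    s <- rand_dna(10000, gc = 0.4)
  })
  got <- enumerate_ttaa_sites(c(chr = s))
  expect_gt(nrow(got), 0)
  expect_equal(got, oracle_ttaa_scan(c(chr = s)))
})

test_that("insertion sampling respects weights, exhaustiveness and truth invariant", {
  gen <- generate_genome(small_cfg())
  chars <- as.character(gen$genome)

  # every sampled event sits on a genuine TTAA
  ev <- simulate_insertions(gen$genome, gen$annotation, small_cfg())
  tsd <- substr(chars[ev$contig], ev$ttaa_start + 1, ev$ttaa_start + 4)
  expect_true(all(tsd == "TTAA"))
  expect_equal(anyDuplicated(paste(ev$contig, ev$ttaa_start)), 0L)

  # zero-weight class never sampled
  cfg0 <- small_cfg(feature_bias = c(CDS = 0, UTR = 0, intron = 0, intergenic = 1))
  ev0 <- simulate_insertions(gen$genome, gen$annotation, cfg0)
  expect_true(all(ev0$feature_class == "intergenic"))

  # n = all available sites -> every TTAA site chosen exactly once
  pool <- enumerate_ttaa_sites(gen$genome)
  cfg_all <- small_cfg(n_insertions = nrow(pool))
  ev_all <- simulate_insertions(gen$genome, gen$annotation, cfg_all)
  expect_equal(
    dplyr::arrange(ev_all[, c("contig", "ttaa_start")], contig, ttaa_start),
    dplyr::arrange(dplyr::rename(pool, ttaa_start = start), contig, ttaa_start)
  )

  # requesting more insertions than eligible sites names both counts
  expect_error(
    simulate_insertions(gen$genome, gen$annotation,
                        small_cfg(n_insertions = nrow(pool) + 1L)),
    "too few TTAA sites")
})

test_that("weighted sampling reproduces the expected class mixture", {
  # pool with 5000 TTAA per class (intron vs intergenic), bias 9:1
  unit <- "TTAAGGCC"
  contig <- strrep(unit, 10000)
  genome <- c(chr = contig)
  half <- nchar(contig) %/% 2L
  intervals <- tibble::tibble(contig = "chr", start = 0L,
                              end = half, feature_class = "intron")
  ann <- flatten_annotation(intervals, genome)
  fracs <- purrr::map_dbl(1:200, function(i) {
    cfg <- sim_config(seed = i, n_insertions = 500,
                      feature_bias = c(CDS = 0, UTR = 0, intron = 1, intergenic = 9))
    ev <- simulate_insertions(genome, ann, cfg)
    mean(ev$feature_class == "intergenic")
  })
  expect_equal(mean(fracs), 0.9, tolerance = 0.03)
})

test_that("read construction matches the junction layout on both orientations", {
  genome <- c(c1 = paste0(strrep("C", 20), "TTAA", strrep("G", 40)))
  cfg <- sim_config(seed = 1, transposon_prefix = "GATTGCAT", read_length = 28,
                    n_insertions = 1)
  glen <- 28 - 8
  ev_f <- tibble::tibble(contig = "c1", ttaa_start = 20L, orientation = "F")
  rf <- simulate_reads(genome, ev_f, cfg)
  expect_true(all(rf$reads$sequence ==
    paste0("GATTGCAT", substr(genome[["c1"]], 21, 20 + glen))))
  expect_true(all(startsWith(rf$reads$sequence, "GATTGCATTTAA")))

  ev_r <- tibble::tibble(contig = "c1", ttaa_start = 20L, orientation = "R")
  rr <- simulate_reads(genome, ev_r, cfg)
  # TTAA is its own reverse complement: R reads begin prefix + TTAA too
  expect_true(all(startsWith(rr$reads$sequence, "GATTGCATTTAA")))
  expect_equal(substr(rr$reads$sequence[1], 9, 28),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(genome[["c1"]], 25 - glen, 24)))))
})

test_that("events whose window leaves the contig are skipped and counted", {
  genome <- c(c1 = paste0("TTAA", strrep("G", 10)))
  cfg <- sim_config(seed = 1, transposon_prefix = "GATTGCAT", read_length = 28,
                    n_insertions = 1)
  ev <- tibble::tibble(contig = "c1", ttaa_start = 0L, orientation = "R")
  out <- simulate_reads(genome, ev, cfg)   # R needs 20 bp left of TTAA end
  expect_equal(nrow(out$reads), 0L)
  expect_equal(attr(out$truth, "skipped"), 1L)
})

test_that("substitution error rate is realized at the configured frequency", {
  gen <- generate_genome(small_cfg())
  cfg <- small_cfg(error_rate = 0.01, n_insertions = 50, reads_per_insertion = 50)
  ev <- simulate_insertions(gen$genome, gen$annotation, cfg)
  noisy <- simulate_reads(gen$genome, ev, cfg)
  clean <- simulate_reads(gen$genome, ev, small_cfg(error_rate = 0,
                                                    n_insertions = 50,
                                                    reads_per_insertion = 50))
  stopifnot(identical(noisy$truth$id, clean$truth$id))
  a <- unlist(strsplit(noisy$reads$sequence, ""))
  b <- unlist(strsplit(clean$reads$sequence, ""))
  expect_gte(length(a), 100000)
  expect_lt(abs(mean(a != b) - 0.01), 0.002)
})

test_that("simulation output is byte-identical under a fixed seed", {
  gen <- generate_genome(small_cfg())
  cfg <- small_cfg(background_fraction = 0.15, error_rate = 0.005)
  ev <- simulate_insertions(gen$genome, gen$annotation, cfg)
  r1 <- simulate_reads(gen$genome, ev, cfg)
  r2 <- simulate_reads(gen$genome, ev, cfg)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1$reads, f1)
  write_fastq(r2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$truth, r2$truth)
})
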