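#' Run the full insertion-profiling pipeline on a simulated library
#'
#' Executes simulate -> trim -> map -> call-sites -> logo -> annotate in
#' order, writing each stage's outputs and a JSON run manifest into
#' `out_dir`.  With a second configuration (`config_b`) the run is repeated
#' for a second condition and the two insertion class profiles are compared
#' by chi-square homogeneity.  Everything is deterministic for a given
#' configuration: re-running with the same config reproduces byte-identical
#' outputs (no timestamps are written anywhere).
#'
#' @param config A [sim_config()] for the (first) condition.
#' @param out_dir Output directory (created if missing).  `NULL` skips all
#'   file output.
#' @param config_b Optional second-condition [sim_config()]; must describe
#'   the same genome (the first condition's genome is reused).
#' @param trim Optional [trim_config()]; defaults to the simulation's prefix
#'   with standard tolerances.
#' @param k Seed length for the k-mer index.
#' @param max_mismatches Mapping mismatch budget.
#' @param logo_length Junction profile window length `L`.
#' @param min_expected_policy Low-expected-count policy for the chi-square
#'   comparison.
#' @param keep_invalid Keep non-TTAA sites in the site table.
#' @return Invisibly, a result bundle: list with `genome`, `annotation`,
#'   `conditions` (per condition: `truth`, `trim`, `map`, `sites`, `profile`,
#'   `insertion_distribution`), `genome_distribution`, `ttaa_distribution`,
#'   `comparison` (or NULL), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, config_b = NULL,
                         trim = NULL, k = 15L, max_mismatches = 3L,
                         logo_length = 15L,
                         min_expected_policy = "warn", keep_invalid = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (is.null(trim)) trim <- trim_config(config$transposon_prefix)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  gen <- stage("simulate", generate_genome(config))
  genome <- gen$genome
  annotation <- gen$annotation
  index <- stage("map", build_kmer_index(genome, k = k))
  genome_dist <- genome_feature_fractions(annotation)
  ttaa_dist <- ttaa_feature_distribution(genome, annotation)

  run_condition <- function(cfg, label) {
    events <- stage("simulate", simulate_insertions(genome, annotation, cfg))
    sim <- stage("simulate", simulate_reads(genome, events, cfg))
    tr <- stage("trim", trim_reads(sim$reads, trim))
    stopifnot(tr$stats$input == tr$stats$trimmed + tr$stats$no_transposon +
                tr$stats$too_short)
    mp <- stage("map", map_fragments(tr, index, genome,
                                     max_mismatches = max_mismatches))
    stopifnot(sum(unlist(mp$stats)) == tr$stats$trimmed)
    st <- stage("call-sites", call_sites(mp, genome, keep_invalid = keep_invalid))
    pr <- stage("logo", build_position_profile(tr, L = logo_length))
    idist <- stage("annotate", insertion_feature_distribution(st, annotation))
    if (!is.null(out_dir)) {
      write_fastq(sim$reads, file.path(out_dir, paste0(label, "_reads.fastq")))
      write_truth_bed(sim$truth, file.path(out_dir, paste0(label, "_truth.bed")))
      write_trimmed_tsv(tr, file.path(out_dir, paste0(label, "_trimmed.tsv")))
      write_report_tsv(mp$alignments,
                       file.path(out_dir, paste0(label, "_alignments.tsv")))
      write_sites_bed(st, file.path(out_dir, paste0(label, "_sites.bed")))
      write_profile_report(pr, file.path(out_dir, paste0(label, "_profile.tsv")))
    }
    list(truth = sim$truth, trim = tr, map = mp, sites = st, profile = pr,
         insertion_distribution = idist)
  }

  conds <- list(a = run_condition(config, "a"))
  if (!is.null(config_b)) conds$b <- run_condition(config_b, "b")

  comparison <- NULL
  if (length(conds) == 2) {
    comparison <- stage("compare", compare_profiles(
      conds$a$insertion_distribution, conds$b$insertion_distribution,
      min_expected_policy = min_expected_policy))
  }
  if (!is.null(out_dir)) {
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    write_annotation_bed(annotation, file.path(out_dir, "annotation.bed"))
    dists <- c(list(genome_bp = genome_dist, ttaa_motifs = ttaa_dist),
               lapply(conds, `[[`, "insertion_distribution"))
    enrichment_report(dists, file.path(out_dir, "enrichment.tsv"),
                      comparison = comparison)
  }

  manifest <- list(
    version = version_banner(),
    seed = config$seed,
    parameters = list(k = k, max_mismatches = max_mismatches,
                      logo_length = logo_length,
                      transposon_prefix = trim$transposon_prefix,
                      retain_tail = trim$retain_tail,
                      max_mismatch_rate = trim$max_mismatch_rate,
                      min_genomic_length = trim$min_genomic_length),
    counts = lapply(conds, function(cn) {
      c(as.list(cn$trim$stats), as.list(cn$map$stats),
        list(sites = cn$sites$totals$sites,
             reads_used = cn$sites$totals$reads_used))
    })
  )
  if (!is.null(comparison)) {
    manifest$comparison <- list(statistic = comparison$statistic,
                                df = comparison$df, p = comparison$p_value)
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(genome = genome, annotation = annotation, conditions = conds,
                 genome_distribution = genome_dist,
                 ttaa_distribution = ttaa_dist,
                 comparison = comparison, manifest = manifest))
}

#' Run the analysis stages on files
#'
#' File-driven counterpart of [run_pipeline()] for libraries that already
#' exist on disk: reads a genome FASTA, a junction-read FASTQ and a feature
#' annotation (GFF3/BED), then runs trim -> map -> call-sites -> logo ->
#' annotate.  All input paths are validated before any compute.
#'
#' @param genome_path Reference FASTA.
#' @param reads_path Junction reads FASTQ.
#' @param annotation_path Feature annotation (GFF3 or BED).
#' @param trim A [trim_config()] (required: carries the library's transposon
#'   prefix).
#' @param out_dir Output directory, or `NULL` for no file output.
#' @inheritParams run_pipeline
#' @return Invisibly, a result bundle as in [run_pipeline()] (single
#'   condition, no comparison).
#' @export
run_pipeline_files <- function(genome_path, reads_path, annotation_path, trim,
                               out_dir = NULL, k = 15L, max_mismatches = 3L,
                               logo_length = 15L, keep_invalid = FALSE) {
  for (p in c(genome_path, reads_path, annotation_path)) {
    if (!file.exists(p)) abort(paste0("configuration error: input path does not exist: ", p))
  }
  stopifnot(inherits(trim, "trim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  genome <- read_fasta(genome_path)
  annotation <- read_annotation(annotation_path, genome)
  reads <- read_fastq(reads_path)
  index <- build_kmer_index(genome, k = k)
  tr <- trim_reads(reads, trim)
  mp <- map_fragments(tr, index, genome, max_mismatches = max_mismatches)
  st <- call_sites(mp, genome, keep_invalid = keep_invalid)
  pr <- build_position_profile(tr, L = logo_length)
  idist <- insertion_feature_distribution(st, annotation)
  if (!is.null(out_dir)) {
    write_trimmed_tsv(tr, file.path(out_dir, "trimmed.tsv"))
    write_report_tsv(mp$alignments, file.path(out_dir, "alignments.tsv"))
    write_sites_bed(st, file.path(out_dir, "sites.bed"))
    write_profile_report(pr, file.path(out_dir, "profile.tsv"))
    enrichment_report(list(genome_bp = genome_feature_fractions(annotation),
                           ttaa_motifs = ttaa_feature_distribution(genome, annotation),
                           insertion_sites = idist),
                      file.path(out_dir, "enrichment.tsv"))
  }
  invisible(list(genome = genome, annotation = annotation,
                 conditions = list(a = list(trim = tr, map = mp, sites = st,
                                            profile = pr,
                                            insertion_distribution = idist)),
                 comparison = NULL))
}
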