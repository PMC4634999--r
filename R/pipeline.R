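## End-to-end orchestration: simulate -> call -> filter -> quantify ->
## summarize, with a recorded seed and a reproducible output manifest.

#' Default pipeline configuration
#'
#' Every pipeline threshold surfaced as a named key with its default: the
#' two calling tiers (1%; 0.5% + 3 reads; 0.2% + 2 reads), the 50-read
#' redundancy cap, insert-size flagging (1,200 / 2,000) and clustering
#' (500 nt window, 3 large / 5 intermediate pairs), the 20-mer amplicon
#' queries and the 0.43 allelic-distortion threshold.
#'
#' @param seed Run seed; all stage seeds derive from it deterministically.
#' @param outdir Output directory.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L, outdir = tempfile("mosaicscan_run")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    reference_length = 4000L,
    tiers = list(review_af = 0.01, snv_af = 0.005, snv_min_reads = 3L,
                 indel_af = 0.002, indel_min_reads = 2L, redundancy_cap = 50L,
                 min_base_quality = 20L, min_mapping_quality = 20L),
    caller = list(tier = "sensitive", depth = 2000, read_length = 50L,
                  per_base_error = 0.001,
                  variant = list(position = 2000L, alt = "T", af = 0.03)),
    deletion = list(min_insert = 1200L, large_threshold = 2000L,
                    window = 500L, min_large = 3L, min_intermediate = 5L,
                    del_start = 1200L, del_length = 13282L, n_pairs = 20000L,
                    carrier_fraction = 0.03),
    amplicon = list(k = 20L, af = 0.0069, n_reads = 100000L,
                    panel = list(n_controls = 25L,
                                 error_rate_range = c(0.0007, 0.0016),
                                 n_reads = 100000L),
                    p_threshold = 0.01),
    splice = list(ratio_threshold = 0.43)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Run the full pipeline on self-generated inputs
#'
#' Generates a mosaic read set, a deletion pair library, an amplicon pool
#' with its control panel and the packaged cohort table; runs the caller
#' with both artifact filters, the deletion caller, the amplicon
#' quantifier and the cohort summary; writes a VCF of SNV/indel calls, a
#' deletion VCF, an amplicon TSV, a cohort-summary TSV and a JSON manifest
#' recording parameters and the seed.  Re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @return Invisibly, a list with the output paths, the in-memory results
#'   and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tc <- do.call(tier_config, config$tiers)

  # stage 1: mosaic SNV calling on simulated reads
  ref <- random_reference(config$reference_length, name = "TSC2_locus",
                          seed = derive_seed(config$seed, "reference"))
  vpos <- config$caller$variant$position
  ref_base <- substr(ref$sequence, vpos, vpos)
  alt <- config$caller$variant$alt
  if (alt == ref_base) alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
  vs <- variant_spec(ref$name, vpos, ref_base, alt, "SNV",
                     config$caller$variant$af)
  prof <- simulation_profile(depth = config$caller$depth,
                             read_length = config$caller$read_length,
                             per_base_error = config$caller$per_base_error,
                             seed = derive_seed(config$seed, "reads"))
  reads <- simulate_reads(ref, list(vs), prof)
  calls <- call_sample(reads, ref, tc, tier = config$caller$tier,
                       sample_id = "demo")
  vcf_path <- file.path(config$outdir, "calls.vcf")
  write_variant_calls(calls, vcf_path, ref)

  # stage 2: deletion detection from insert sizes
  dcfg <- config$deletion
  del_start <- dcfg$del_start
  del_end <- del_start + dcfg$del_length - 1L
  # coordinates are what matters here; sequence content is a placeholder
  dref <- reference("TSC2_region", strrep("N", del_end + 4000L))
  pairs <- simulate_deletion_library(
    dref, del_start, del_end, dcfg$n_pairs, dcfg$carrier_fraction,
    simulation_profile(seed = derive_seed(config$seed, "pairs")))
  dels <- detect_deletions(pairs, dcfg$min_insert, dcfg$large_threshold,
                           dcfg$window, dcfg$min_large, dcfg$min_intermediate)
  del_vcf <- file.path(config$outdir, "deletions.vcf")
  write_variant_calls(deletion_calls_to_variants(dels, dref, "demo"), del_vcf,
                      dref)

  # stage 3: amplicon quantification against a control panel
  actx <- random_reference(60L, "amplicon",
                           seed = derive_seed(config$seed, "amplicon_ctx"))
  apos <- 30L
  aref <- substr(actx$sequence, apos, apos)
  aalt <- setdiff(c("A", "C", "G", "T"), aref)[1L]
  query <- make_query_kmers(actx$sequence,
                            list(pos = apos, ref = aref, alt = aalt),
                            k = config$amplicon$k)
  mut_seq <- actx$sequence
  substr(mut_seq, apos, apos) <- aalt
  pool <- simulate_amplicon_pool(actx$sequence, mut_seq,
                                 af = config$amplicon$af,
                                 n_reads = config$amplicon$n_reads,
                                 seed = derive_seed(config$seed, "amplicon"))
  amp <- quantify_amplicon(pool, query)
  pcfg <- config$amplicon$panel
  panel <- simulate_control_panel(actx$sequence, query$mut,
                                  n_controls = pcfg$n_controls,
                                  error_rate_range = pcfg$error_rate_range,
                                  n_reads = pcfg$n_reads,
                                  seed = derive_seed(config$seed, "panel"))
  amp <- compare_to_panel(amp, panel, config$amplicon$p_threshold)
  amp_path <- file.path(config$outdir, "amplicon.tsv")
  utils::write.table(
    data.frame(wt_kmer = query$wt, mut_kmer = query$mut,
               mutant_count = amp$mutant_count, wt_count = amp$wt_count,
               af = amp$af, panel_mean = amp$panel_mean,
               panel_max = amp$panel_max, above_noise = amp$above_noise,
               binomial_p = amp$binomial_p),
    amp_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4: cohort summary from the packaged subject table
  cohort <- load_table1_fixture()
  summ <- summarize_cohort(cohort)
  medians <- group_medians(cohort)
  cohort_path <- file.path(config$outdir, "cohort_summary.tsv")
  utils::write.table(
    data.frame(metric = c(names(unclass(summ)),
                          paste0("median_major_features_", names(medians))),
               value = c(unlist(unclass(summ)), unname(medians))),
    cohort_path, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "mosaicscan",
    version = as.character(utils::packageVersion("mosaicscan")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("outdir"))],
    outputs = list(calls = basename(vcf_path), deletions = basename(del_vcf),
                   amplicon = basename(amp_path),
                   cohort = basename(cohort_path)),
    checksums = as.list(tools::md5sum(c(vcf_path, del_vcf, amp_path,
                                        cohort_path)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(paths = list(calls = vcf_path, deletions = del_vcf,
                              amplicon = amp_path, cohort = cohort_path,
                              manifest = manifest_path),
                 calls = calls, deletions = dels, amplicon = amp,
                 summary = summ, manifest = manifest))
}
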