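## End-to-end benchmark pipeline: regularize -> quality filter -> region
## restriction -> per-callset rates -> tool-specific subsets -> combination
## analyses -> clinical overlap, with TSV reports and a reproducibility
## manifest.

#' Read a benchmark run configuration
#'
#' YAML with keys: `callsets` (list of `{label, path}`), `truth`,
#' `reference`, `confident_bed`, `transcript_bed` (optional),
#' `clinical_table` (optional), `min_qual` (default 40), `match_mode`
#' (`coords`/`strict`), `out_dir`, `seed`.
#'
#' @param path YAML path.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$min_qual <- cfg$min_qual %||% 40
  cfg$match_mode <- cfg$match_mode %||% "coords"
  cfg$seed <- cfg$seed %||% 1L
  labels <- vapply(cfg$callsets, function(x) x$label, character(1))
  if (anyDuplicated(labels)) stop_data("callset labels must be unique")
  cfg
}

#' Run the full benchmark
#'
#' Executes the evaluation flow over the configured callsets: read +
#' regularize + deduplicate, apply the quality filter, restrict to confident
#' regions, compute per-callset false-positive/false-negative rates and
#' tool-specific subsets, combine callsets (union, intersection,
#' detection-frequency bins; three-way Venn counts when exactly three
#' callsets are given; a ROC sweep for the union), and overlap with the
#' clinical table when one is configured. Reports are written as TSV into
#' `out_dir` together with a run manifest (config + package version + seed)
#' sufficient to reproduce the run; reruns with the same config produce
#' byte-identical reports.
#'
#' @param config a config list (see [read_run_config()]) or a YAML path.
#' @return invisible list with all in-memory results (comparison,
#'   tool_specific, bins, venn, roc, clinical, paths).
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% stop_data("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed %||% 1L)
  mode <- config$match_mode %||% "coords"

  message("reading reference: ", config$reference)
  reference <- read_reference_fasta(config$reference)
  message("reading truth: ", config$truth)
  truth <- suppressMessages(dedup_callset(
    regularize(read_callset_vcf(config$truth, label = "truth"), reference)))
  confident <- read_bed_regions(config$confident_bed, label = "confident")
  fn_regions <- if (!is.null(config$transcript_bed)) {
    regions_intersect(confident,
                      read_bed_regions(config$transcript_bed, label = "transcripts"),
                      label = "confident&transcripts")
  } else confident

  callsets <- lapply(config$callsets, function(cc) {
    message("processing callset: ", cc$label)
    cs <- read_callset_vcf(cc$path, label = cc$label)
    cs <- regularize(cs, reference)
    cs <- suppressMessages(dedup_callset(cs))
    apply_quality_filter(cs, min_qual = config$min_qual %||% 40)
  })
  labels <- vapply(callsets, function(x) x$label, character(1))
  names(callsets) <- labels

  results <- lapply(callsets, false_rates, truth = truth, confident = confident,
                    fn_regions = fn_regions, mode = mode)
  specific <- if (length(callsets) >= 2L) {
    sp <- tool_specific_variants(callsets, mode = mode)
    lapply(stats::setNames(labels, labels), function(lab) {
      s <- sp[[lab]]; s$label <- lab
      false_rates(s, truth, confident, fn_regions, mode = mode)
    })
  } else NULL
  report <- comparison_report(results, specific)
  write_report_tsv(report, file.path(out_dir, "comparison.tsv"))

  bins <- NULL; venn <- NULL; roc <- NULL
  if (length(callsets) >= 2L) {
    bins <- frequency_bins(callsets, truth, confident, fn_regions, mode = mode)
    bin_tab <- as.data.frame(bins)
    bin_tab$fp_rate <- round_half_up(100 * bin_tab$fp_rate, 2)
    bin_tab$fn_rate <- round_half_up(100 * bin_tab$fn_rate, 2)
    names(bin_tab) <- c("bin", "total_variant_calls", "pct_of_union",
                        "fp_rate_pct", "fn_rate_pct")
    write_report_tsv(bin_tab, file.path(out_dir, "frequency_bins.tsv"))

    u <- restrict_to_regions(union_callsets(callsets, mode = mode), confident)
    roc <- roc_points(u, restrict_to_regions(truth, confident), mode = mode)
    write_report_tsv(as.data.frame(roc), file.path(out_dir, "roc_union.tsv"))
  }
  if (length(callsets) == 3L) {
    venn <- venn_counts(callsets, mode = mode)
    venn_tab <- data.frame(pattern = names(venn$counts), count = venn$counts,
                           row.names = NULL)
    write_report_tsv(venn_tab, file.path(out_dir, "venn.tsv"))
  }

  clinical <- NULL
  if (!is.null(config$clinical_table)) {
    records <- filter_by_significance(read_clinical_table(config$clinical_table))
    clinical <- list(
      report = clinical_report(records, callsets),
      summary = if (length(callsets) >= 2L) unanimity_summary(records, callsets)
    )
    write_report_tsv(clinical$report, file.path(out_dir, "clinical.tsv"))
  }

  manifest <- list(
    package = "vcbench",
    version = as.character(utils::packageVersion("vcbench")),
    seed = config$seed %||% 1L,
    min_qual = config$min_qual %||% 40,
    match_mode = mode,
    callsets = lapply(config$callsets, function(x) x[c("label", "path")]),
    truth = config$truth,
    confident_bed = config$confident_bed,
    transcript_bed = config$transcript_bed,
    clinical_table = config$clinical_table
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(callsets = callsets, truth = truth, comparison = results,
                 tool_specific = specific, report = report, bins = bins,
                 venn = venn, roc = roc, clinical = clinical,
                 out_dir = out_dir))
}

#' Write a complete synthetic input bundle ("paperlike" preset)
#'
#' Generates a repeat-rich reference, a truth set, nine tool-emulating
#' callsets (three emulated aligners crossed with three emulated callers,
#' sensitivities spread over 0.90-0.98 with partially shared false calls),
#' confident/transcript BEDs and a clinical table; writes them as
#' FASTA/VCF/BED/TSV under `dir` plus a ready-to-run YAML config.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param n_snv,n_ins,n_del truth composition (defaults give a compact but
#'   representative run).
#' @param ref_length reference length in bp.
#' @return path of the written config file.
#' @export
paperlike_fixtures <- function(dir, seed = 1L, n_snv = 2000L, n_ins = 250L,
                               n_del = 250L, ref_length = 200000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- generate_reference(ref_length, repeat_fraction = 0.2, seed = seed)
  truth <- generate_truth_set(reference, n_snv, n_ins, n_del, seed = seed)
  regions <- generate_regions(reference, 0.9, 0.6, seed = seed)

  aligners <- c("bwa", "bowtie2", "isaac_aln")
  callers <- c("gatk", "isaac_vc", "samtools")
  labels <- as.vector(outer(aligners, callers, paste, sep = "/"))
  sens <- seq(0.90, 0.98, length.out = 9L)
  n_truth <- nrow(truth$variants)
  profiles <- lapply(seq_along(labels), function(i)
    callset_profile(sensitivity = sens[i], fp_count = 0.06 * n_truth,
                    indel_jitter = 0.3, seed = derive_seed(seed, 10L + i)))
  names(profiles) <- labels
  callsets <- generate_callsets(truth, profiles, reference,
                                shared_fp_fraction = 0.05,
                                correlated_fp_fraction = 0.25,
                                correlated_inclusion = 0.6, seed = seed)
  clinical <- generate_clinical_table(truth, n_pathogenic = 20L, n_risk = 10L,
                                      n_benign = 30L, seed = seed)

  write_reference_fasta(reference, file.path(dir, "reference.fa"))
  write_callset_vcf(truth, file.path(dir, "truth.vcf"))
  write_bed_regions(regions$confident, file.path(dir, "confident.bed"))
  write_bed_regions(regions$transcripts, file.path(dir, "transcripts.bed"))
  write_clinical_table(clinical, file.path(dir, "clinical.tsv"))
  callset_entries <- lapply(labels, function(lab) {
    path <- file.path(dir, paste0(gsub("/", "_", lab), ".vcf"))
    write_callset_vcf(callsets[[lab]], path)
    list(label = lab, path = path)
  })

  cfg <- list(
    callsets = callset_entries,
    truth = file.path(dir, "truth.vcf"),
    reference = file.path(dir, "reference.fa"),
    confident_bed = file.path(dir, "confident.bed"),
    transcript_bed = file.path(dir, "transcripts.bed"),
    clinical_table = file.path(dir, "clinical.tsv"),
    min_qual = 40,
    match_mode = "coords",
    out_dir = file.path(dir, "reports"),
    seed = as.integer(seed)
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
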