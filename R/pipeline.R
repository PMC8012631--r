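# End-to-end orchestration: simulate-or-read -> filter -> thin -> stats ->
# inheritance, with a consolidated JSON report. A single global seed fans
# out to per-stage seeds by fixed offsets so each stage is independently
# reproducible.

STAGE_SEED_OFFSETS <- c(simulate = 101L, thin = 202L, stats = 303L,
                        inherit = 404L)

#' Build a pipeline run configuration
#'
#' Exactly one of `vcf` (with `sample_order`) or `sim` must be supplied.
#'
#' @param vcf Path to an input multi-sample VCF.
#' @param sample_order Sample names, mother first (required with `vcf`).
#' @param sim A [sim_config()] for a simulator-backed run.
#' @param mechanisms Mechanisms for the simulated offspring.
#' @param reference Optional path to a reference FASTA (enables the GC
#'   comparison for VCF-backed runs; simulator-backed runs use the
#'   simulated reference).
#' @param filter A [filter_config()].
#' @param thin_window_bp Thinning window in bp (`NULL` disables thinning).
#' @param n_boot Bootstrap replicates for the summary statistics.
#' @param n_perm Permutations for the Jaccard and GC tests.
#' @param gc_window_bp Flank half-width for the GC comparison.
#' @param seed Global seed.
#' @param out_dir Output directory (`NULL` = nothing written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, sample_order = NULL, sim = NULL,
                       mechanisms = c("TF", "TF"), reference = NULL,
                       filter = filter_config(), thin_window_bp = 50000L,
                       n_boot = 100L, n_perm = 100L, gc_window_bp = 5000L,
                       seed = 1L, out_dir = NULL) {
  if (is.null(vcf) == is.null(sim)) {
    stop("exactly one of 'vcf' or 'sim' must be supplied")
  }
  if (!is.null(vcf) && is.null(sample_order)) {
    stop("sample_order (mother first) is required with a VCF input")
  }
  structure(
    list(vcf = vcf, sample_order = sample_order, sim = sim,
         mechanisms = mechanisms, reference = reference, filter = filter,
         thin_window_bp = thin_window_bp, n_boot = n_boot, n_perm = n_perm,
         gc_window_bp = gc_window_bp, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` and
#' `filter` blocks are passed to [sim_config()] and [filter_config()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  filter <- if (!is.null(y$filter)) do.call(filter_config, y$filter) else
    filter_config()
  run_config(
    vcf = y$vcf, sample_order = y$sample_order, sim = sim,
    mechanisms = y$mechanisms %||% c("TF", "TF"),
    reference = y$reference, filter = filter,
    thin_window_bp = y$thin_window_bp %||% 50000L,
    n_boot = y$n_boot %||% 100L, n_perm = y$n_perm %||% 100L,
    gc_window_bp = y$gc_window_bp %||% 5000L,
    seed = y$seed %||% 1L, out_dir = y$out_dir
  )
}

#' Run the full analysis pipeline
#'
#' Stages: obtain genotypes (simulator or VCF), apply the site filter
#' cascade, thin to one site per window, compute heterozygosity and
#' relatedness with bootstraps, classify maternal-het fates per offspring
#' with the binomial inheritance-bias test, run the Jaccard shared-
#' retention permutation test (when two or more offspring), the GC flank
#' comparison (when a reference is available), and the mechanism call per
#' offspring. Any stage error aborts with the stage name. All stage
#' outputs plus a consolidated JSON report are written when
#' `cfg$out_dir` is set.
#'
#' @param cfg A [run_config()] or path to its YAML file.
#' @return The run report (a list, also serialized as JSON), invisibly
#'   carrying the filtered dataset in `attr(, "data")`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  seeds <- as.list(cfg$seed + STAGE_SEED_OFFSETS)
  names(seeds) <- names(STAGE_SEED_OFFSETS)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input ---------------------------------------------------------------
  ref <- NULL
  truth <- NULL
  if (!is.null(cfg$sim)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- seeds$simulate
    sim <- stage("simulate", simulate_trio(sim_cfg, cfg$mechanisms,
                                           make_reference = TRUE))
    data <- sim$trio
    ref <- sim$ref
    truth <- sim$truth
    if (!is.null(out_dir)) write_sim_trio(sim, file.path(out_dir, "sim"))
  } else {
    data <- stage("read_vcf", read_vcf(cfg$vcf, cfg$sample_order))
    if (!is.null(cfg$reference)) ref <- stage("read_fasta",
                                              read_fasta(cfg$reference))
  }
  n_input <- n_sites(data)

  # --- filter + thin -------------------------------------------------------
  data <- stage("filter", apply_site_filters(data, cfg$filter))
  n_filtered <- n_sites(data)
  if (!is.null(cfg$thin_window_bp)) {
    data <- stage("thin", thin_by_window(data, cfg$thin_window_bp,
                                         seed = seeds$thin))
  }
  n_thinned <- n_sites(data)
  if (!is.null(out_dir)) write_vcf(data, file.path(out_dir, "filtered.vcf"))

  # --- summary statistics --------------------------------------------------
  stats <- stage("stats", trio_summary_stats(data, n_boot = cfg$n_boot,
                                             seed = seeds$stats))

  # --- inheritance ---------------------------------------------------------
  mother <- data$samples[1]
  offspring <- data$samples[-1L]
  fates <- stage("inherit", lapply(offspring, function(s)
    classify_fates(data, s)))
  names(fates) <- offspring
  fate_table <- do.call(rbind, lapply(offspring, function(s) {
    f <- fates[[s]]
    data.frame(offspring = s, n00 = f$n00, n01 = f$n01, n11 = f$n11,
               retained_fraction = retained_fraction(f),
               binomial_p = if (f$n00 + f$n11 > 0) binomial_bias_test(f)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  jaccard <- NULL
  if (length(offspring) >= 2L) {
    mat_het <- site_ids(data)[!is.na(data$gt[, 1L]) & data$gt[, 1L] == GT_HET]
    jaccard <- stage("inherit", jaccard_permutation_test(
      fates[[1L]], fates[[2L]], mat_het, n_perm = cfg$n_perm,
      seed = seeds$inherit))
  }
  gc <- NULL
  if (!is.null(ref) && length(offspring) >= 1L) {
    retained <- unique(unlist(lapply(fates, function(f) f$loci$het)))
    lost <- setdiff(
      unique(unlist(lapply(fates, function(f)
        c(f$loci$hom_ref, f$loci$hom_alt)))),
      retained)
    all_hom <- rowSums(data$gt == GT_HET, na.rm = TRUE) == 0L &
      rowSums(is.na(data$gt)) == 0L
    background <- site_ids(data)[all_hom]
    gc <- stage("inherit", gc_flank_comparison(
      ref, retained, lost, background, window_bp = cfg$gc_window_bp,
      n_perm = cfg$n_perm, seed = seeds$inherit + 1L))
  }
  calls <- stage("inherit", lapply(offspring, function(s)
    diagnose_trio_offspring(data, s)))
  names(calls) <- offspring

  report <- list(
    package_version = as.character(utils::packageVersion("automixr")),
    seed = cfg$seed,
    stage_seeds = seeds,
    counts = list(input_sites = n_input, after_filters = n_filtered,
                  after_thinning = n_thinned),
    filter_log = data$filter_log,
    per_sample = stats$per_sample,
    relatedness = list(samples = data$samples,
                       matrix = unname(stats$relatedness)),
    fate_table = fate_table,
    jaccard = if (!is.null(jaccard)) {
      list(observed_j = jaccard$observed_j, p_emp = jaccard$p_emp,
           null_mean = mean(jaccard$null_j),
           overlap_over_min = jaccard$overlap_over_min)
    },
    gc = if (!is.null(gc)) gc$comparisons,
    mechanism = lapply(calls, function(cl) {
      list(verdict = cl$verdict, clone = cl$clone,
           relatedness = cl$evidence$relatedness,
           oh_ratio = cl$evidence$oh_ratio,
           retained_fraction = cl$evidence$retained_fraction,
           retained_count = cl$evidence$retained_count)
    }),
    truth = if (!is.null(truth)) {
      lapply(truth, function(t) list(mechanism = t$mechanism))
    },
    config = config_echo(cfg)
  )
  if (!is.null(out_dir)) {
    utils::write.table(fate_table, file.path(out_dir, "fate_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stats$per_sample, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rel <- stats$relatedness
    utils::write.table(rel, file.path(out_dir, "relatedness.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(jaccard)) {
      jsonlite::write_json(report$jaccard,
                           file.path(out_dir, "jaccard.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(gc)) {
      utils::write.table(gc$comparisons, file.path(out_dir, "gc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "rows")
  }
  attr(report, "data") <- data
  attr(report, "stats") <- stats
  attr(report, "fates") <- fates
  attr(report, "jaccard_full") <- jaccard
  attr(report, "gc_full") <- gc
  invisible(report)
}

# Plain-list echo of the configuration for the report (drops closures,
# keeps values).
config_echo <- function(cfg) {
  list(
    input = if (is.null(cfg$vcf)) "simulator" else cfg$vcf,
    sample_order = cfg$sample_order,
    mechanisms = if (is.null(cfg$sim)) NULL else cfg$mechanisms,
    sim = if (!is.null(cfg$sim)) {
      lapply(unclass(cfg$sim), function(x) if (is.null(x)) NA else x)
    },
    filter = lapply(unclass(cfg$filter), function(x) {
      if (is.null(x)) return(NA)
      if (is.list(x)) vapply(x, function(t) paste(unlist(t), collapse = " "),
                             character(1)) else x
    }),
    thin_window_bp = cfg$thin_window_bp,
    n_boot = cfg$n_boot, n_perm = cfg$n_perm,
    gc_window_bp = cfg$gc_window_bp
  )
}
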