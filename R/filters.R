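# Site filter cascade and linkage thinning for RADseq-style trio data.

#' Filter configuration for the site filter cascade
#'
#' Defaults mirror a standard hard-filtering recipe for reduced-
#' representation trio data: per-call depth >= 5, site quality >= 30, the
#' GATK-style INFO hard filters, total-depth outlier bounds at 0.5x-2x the
#' dataset mean, biallelic SNPs only, and complete-case genotypes across
#' the trio.
#'
#' @param min_depth Per-sample read depth below which a call is set missing.
#' @param min_qual Minimum Phred site quality.
#' @param snp_gap Drop SNPs within this many bp of an indel in the input.
#' @param indel_gap Indels closer than this are treated as a cluster; the
#'   spanned interval is flagged in the log.
#' @param hard_filters List of `(name, comparator, value)` triples applied
#'   to INFO annotations; a site matching any triple is dropped. Comparators
#'   are one of `"<"`, `">"`, `"<="`, `">="`, `"=="`. Keys absent from the
#'   input are skipped with a logged warning.
#' @param depth_bounds Either `NULL` (bounds derived as
#'   `depth_multipliers * mean(total depth)` of the data reaching that rule,
#'   recorded in the log) or an explicit numeric `c(lo, hi)` on total depth.
#' @param depth_multipliers Multipliers used when `depth_bounds` is `NULL`.
#' @param biallelic_only Drop multi-allelic records.
#' @param complete_case Drop sites with any missing call (applied last).
#' @param exclude_chroms Chromosomes to drop outright (e.g. a Z scaffold
#'   list when hemizygosity is a concern).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 5L,
                          min_qual = 30,
                          snp_gap = 3L,
                          indel_gap = 10L,
                          hard_filters = default_hard_filters(),
                          depth_bounds = NULL,
                          depth_multipliers = c(0.5, 2),
                          biallelic_only = TRUE,
                          complete_case = TRUE,
                          exclude_chroms = character()) {
  cmp_ok <- c("<", ">", "<=", ">=", "==")
  for (hf in hard_filters) {
    if (length(hf) != 3L) stop("hard filter triples must be (name, comparator, value)")
    if (!hf[[2]] %in% cmp_ok) {
      stop("unknown comparator in hard filter: '", hf[[2]], "'")
    }
  }
  structure(
    list(min_depth = min_depth, min_qual = min_qual, snp_gap = snp_gap,
         indel_gap = indel_gap, hard_filters = hard_filters,
         depth_bounds = depth_bounds, depth_multipliers = depth_multipliers,
         biallelic_only = biallelic_only, complete_case = complete_case,
         exclude_chroms = exclude_chroms),
    class = "filter_config"
  )
}

#' Default INFO hard filters
#'
#' The widely used GATK germline hard-filter thresholds:
#' QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5, ReadPosRankSum < -8.
#' @return List of `(name, comparator, value)` triples.
#' @export
default_hard_filters <- function() {
  list(
    list("QD", "<", 2), list("FS", ">", 60), list("MQ", "<", 40),
    list("MQRankSum", "<", -12.5), list("ReadPosRankSum", "<", -8)
  )
}

#' Apply the site filter cascade
#'
#' Filters a trio dataset in a fixed order: (1) indels dropped (their
#' positions are remembered for the adjacency rule); (2) calls with depth
#' below `min_depth` set missing; (3) SNPs within `snp_gap` bp of an input
#' indel dropped, indel clusters flagged; (4) sites below `min_qual`
#' dropped; (5) INFO hard-filter violations dropped; (6) total-depth
#' outliers dropped; (7) non-biallelic sites dropped; finally sites with
#' any missing call in the trio are dropped (complete case). The filter
#' log records the count removed by each rule and the resolved depth
#' bounds, so a run is fully reconstructable.
#'
#' @param data A [trio_dataset()].
#' @param cfg A [filter_config()].
#' @return The filtered `trio_dataset` with an appended filter log and the
#'   resolved configuration in `attr(, "resolved_config")`.
#' @export
apply_site_filters <- function(data, cfg = filter_config()) {
  stopifnot(inherits(data, "trio_dataset"), inherits(cfg, "filter_config"))

  if (length(cfg$exclude_chroms)) {
    drop <- data$sites$chrom %in% cfg$exclude_chroms
    data <- append_log(subset_sites(data, !drop), "exclude_chroms", sum(drop))
  }

  # (1) indels out; keep their spans for rule (3)
  is_indel <- data$sites$is_indel
  indel_spans <- data$sites[is_indel, c("chrom", "pos", "ref"), drop = FALSE]
  data <- append_log(subset_sites(data, !is_indel), "indels", sum(is_indel))

  # (2) low-depth calls set missing
  low <- !is.na(data$dp) & data$dp < cfg$min_depth & !is.na(data$gt)
  data$gt[low] <- NA_integer_
  data <- append_log(data, "low_depth_to_missing", sum(low),
                     sprintf("calls with DP < %d set missing", cfg$min_depth))

  # (3) SNPs near indels; indel clusters flagged
  if (nrow(indel_spans)) {
    note <- ""
    if (nrow(indel_spans) > 1L && !is.null(cfg$indel_gap)) {
      d <- diff(indel_spans$pos)
      same <- indel_spans$chrom[-1L] == indel_spans$chrom[-nrow(indel_spans)]
      n_clust <- sum(same & d <= cfg$indel_gap)
      if (n_clust) note <- sprintf("%d indel cluster(s) within %d bp flagged",
                                   n_clust, cfg$indel_gap)
    }
    near <- rep(FALSE, n_sites(data))
    for (i in seq_len(nrow(indel_spans))) {
      lo <- indel_spans$pos[i] - cfg$snp_gap
      hi <- indel_spans$pos[i] + nchar(indel_spans$ref[i]) - 1L + cfg$snp_gap
      near <- near | (data$sites$chrom == indel_spans$chrom[i] &
                        data$sites$pos >= lo & data$sites$pos <= hi)
    }
    data <- append_log(subset_sites(data, !near), "snp_near_indel",
                       sum(near), note)
  } else {
    data <- append_log(data, "snp_near_indel", 0L)
  }

  # (4) site quality
  lowq <- !is.na(data$sites$qual) & data$sites$qual < cfg$min_qual
  data <- append_log(subset_sites(data, !lowq), "min_qual", sum(lowq))

  # (5) INFO hard filters
  viol <- rep(FALSE, n_sites(data))
  skipped <- character()
  no_info <- is.null(data$info)
  for (hf in cfg$hard_filters) {
    key <- hf[[1]]
    if (no_info || !key %in% names(data$info)) {
      skipped <- c(skipped, key)
      next
    }
    vals <- data$info[[key]]
    hit <- switch(hf[[2]],
                  "<" = vals < hf[[3]], ">" = vals > hf[[3]],
                  "<=" = vals <= hf[[3]], ">=" = vals >= hf[[3]],
                  "==" = vals == hf[[3]],
                  stop("unknown comparator in hard filter: '", hf[[2]], "'"))
    viol <- viol | (!is.na(hit) & hit)
  }
  note <- if (no_info && length(skipped)) {
    "no INFO annotations in input; hard filters skipped"
  } else if (length(skipped)) {
    warning("INFO key(s) absent from input, hard filter skipped: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
    paste("skipped absent keys:", paste(unique(skipped), collapse = ","))
  } else ""
  data <- append_log(subset_sites(data, !viol), "info_hard_filter",
                     sum(viol), note)

  # (6) total-depth outliers
  total_dp <- rowSums(data$dp, na.rm = TRUE)
  bounds <- cfg$depth_bounds
  if (is.null(bounds) && n_sites(data) > 0L) {
    bounds <- cfg$depth_multipliers * mean(total_dp)
  }
  if (!is.null(bounds)) {
    out <- total_dp < bounds[1] | total_dp > bounds[2]
    data <- append_log(subset_sites(data, !out), "total_depth_outlier",
                       sum(out),
                       sprintf("bounds [%.2f, %.2f]", bounds[1], bounds[2]))
  } else {
    data <- append_log(data, "total_depth_outlier", 0L)
  }

  # (7) non-biallelic
  if (cfg$biallelic_only) {
    multi <- data$sites$multiallelic
    data <- append_log(subset_sites(data, !multi), "non_biallelic", sum(multi))
  }

  # complete case across the trio
  if (cfg$complete_case) {
    incomplete <- rowSums(is.na(data$gt)) > 0L
    data <- append_log(subset_sites(data, !incomplete), "complete_case",
                       sum(incomplete))
  }

  resolved <- cfg
  resolved$depth_bounds <- bounds
  attr(data, "resolved_config") <- resolved
  data
}

#' Thin sites to one per genomic window
#'
#' Retains at most one site per non-overlapping window of `window_bp`
#' bases per chromosome (windows anchored at coordinate 0), chosen
#' uniformly at random, to reduce linkage between retained markers.
#' Deterministic for a fixed seed.
#'
#' @param data A [trio_dataset()] with sites sorted by (chrom, pos).
#' @param window_bp Window size in bp (default 50 kb).
#' @param seed Integer seed for the uniform choice within each window.
#' @return The thinned `trio_dataset`, sorted by (chrom, pos).
#' @export
thin_by_window <- function(data, window_bp = 50000L, seed = NULL) {
  stopifnot(inherits(data, "trio_dataset"))
  if (window_bp <= 0) stop("window_bp must be positive")
  ord <- order(data$sites$chrom, data$sites$pos)
  data <- subset_sites(data, ord)
  win <- paste0(data$sites$chrom, "@", data$sites$pos %/% as.integer(window_bp))
  groups <- split(seq_len(n_sites(data)), factor(win, levels = unique(win)))
  keep <- with_seed(seed, vapply(groups, draw_one, numeric(1)))
  keep <- sort(unname(keep))
  n0 <- n_sites(data)
  data <- subset_sites(data, keep)
  append_log(data, "thin_by_window", n0 - length(keep),
             sprintf("window %d bp, <=1 site per window", as.integer(window_bp)))
}
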