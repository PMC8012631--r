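# Individual heterozygosity (OH, HL) and pairwise allele-sharing
# relatedness (B_xy, M_xy) with locus bootstraps.

#' Observed heterozygosity of one sample
#'
#' Proportion of non-missing genotyped loci at which the sample is
#' heterozygous: 0 is complete homozygosity, 1 complete heterozygosity.
#'
#' @param calls Integer genotype codes (0/1/2/`NA`) for one sample, or a
#'   [trio_dataset()] together with `sample`.
#' @param sample Sample name when `calls` is a `trio_dataset`.
#' @return Observed heterozygosity in `[0, 1]`.
#' @export
observed_heterozygosity <- function(calls, sample = NULL) {
  calls <- resolve_calls(calls, sample)
  ok <- !is.na(calls)
  if (!any(ok)) stop("all calls are missing; OH is undefined")
  sum(calls[ok] == GT_HET) / sum(ok)
}

#' Per-locus allele frequencies and expected heterozygosity
#'
#' Computes REF/ALT allele frequencies from the analyzed samples (or an
#' externally supplied frequency table) and the expected heterozygosity
#' `E = 1 - p^2 - q^2` that weights loci in the homozygosity-by-loci
#' estimator. Missing calls are excluded from the allele counts.
#'
#' @param data A [trio_dataset()] or an integer genotype matrix
#'   (sites x samples).
#' @return `data.frame` with columns `p` (REF frequency), `q` (ALT
#'   frequency) and `E`; loci untyped in every sample get `E = NA`.
#' @export
locus_expected_het <- function(data) {
  gt <- if (inherits(data, "trio_dataset")) data$gt else as.matrix(data)
  n_called <- rowSums(!is.na(gt))
  alt <- rowSums(gt, na.rm = TRUE)
  q <- ifelse(n_called > 0L, alt / (2 * n_called), NA_real_)
  p <- 1 - q
  data.frame(p = p, q = q, E = 1 - p^2 - q^2)
}

#' Homozygosity by loci (HL) of one sample
#'
#' HL weights each locus by its expected heterozygosity `E`:
#' `HL = sum(E over loci homozygous in the sample) /
#'       sum(E over homozygous + heterozygous loci)`.
#' 0 means complete heterozygosity, 1 complete homozygosity. Loci missing
#' in the sample are excluded from both sums; monomorphic loci carry
#' `E = 0` and contribute nothing.
#'
#' @param calls Integer genotype codes for one sample, or a
#'   [trio_dataset()] together with `sample`.
#' @param freqs Optional output of [locus_expected_het()] computed on the
#'   same locus set (e.g. from an external reference panel); when omitted
#'   and `calls` is a `trio_dataset`, frequencies come from its samples.
#' @param sample Sample name when `calls` is a `trio_dataset`.
#' @return HL in `[0, 1]`.
#' @export
homozygosity_by_loci <- function(calls, freqs = NULL, sample = NULL) {
  if (inherits(calls, "trio_dataset") && is.null(freqs)) {
    freqs <- locus_expected_het(calls)
  }
  calls <- resolve_calls(calls, sample)
  if (is.null(freqs)) stop("freqs are required when calls is a plain vector")
  if (length(calls) != nrow(freqs)) {
    stop("freqs must cover the same locus set as calls")
  }
  e <- freqs$E
  ok <- !is.na(calls) & !is.na(e)
  hom <- ok & calls != GT_HET
  het <- ok & calls == GT_HET
  denom <- sum(e[hom]) + sum(e[het])
  if (denom == 0) stop("no informative loci (all expected heterozygosity 0)")
  sum(e[hom]) / denom
}

#' Shared-alleles relatedness index (B_xy)
#'
#' Mean over pairwise-complete loci of a per-locus allele-sharing score:
#' 1 for identical genotypes; 0.75 for two heterozygotes sharing exactly
#' one allele (impossible on biallelic data); 0.5 when a homozygote and a
#' heterozygote share one allele; 0 when no allele is shared. 1 means
#' identical genotypes, 0 no relatedness.
#'
#' @param calls_x,calls_y Integer genotype codes for the two samples, or a
#'   [trio_dataset()] with `calls_y`/`pair` naming two samples.
#' @return B_xy in `[0, 1]`.
#' @export
pairwise_bxy <- function(calls_x, calls_y) {
  cc <- resolve_pair(calls_x, calls_y)
  x <- cc$x; y <- cc$y
  score <- ifelse(x == y, 1,
           ifelse(abs(x - y) == 2L, 0, 0.5))
  mean(score)
}

#' Genotype-sharing relatedness index (M_xy)
#'
#' Mean over pairwise-complete loci of (number of alleles shared under the
#' best pairing of the two genotypes) / 2: identical genotypes score 1,
#' one shared allele 0.5, none 0. Computed from ALT-dosage arithmetic
#' (`1 - |dx - dy| / 2` on biallelic codes), an independent route from
#' [pairwise_bxy()]'s case rules; the two coincide on biallelic data.
#'
#' @inheritParams pairwise_bxy
#' @return M_xy in `[0, 1]`.
#' @export
pairwise_mxy <- function(calls_x, calls_y) {
  cc <- resolve_pair(calls_x, calls_y)
  mean(1 - abs(cc$x - cc$y) / 2)
}

#' Bootstrap a heterozygosity or relatedness metric over loci
#'
#' Resamples loci with replacement to the original locus count and
#' recomputes the metric on each replicate; the replicate standard
#' deviation measures sampling variance of the point estimate under the
#' single-family design (loci, not individuals, are the resampling unit).
#' For HL, allele frequencies are recomputed on each replicate's locus
#' multiset. Replicates on which the metric is undefined (e.g. an
#' all-missing draw) are redrawn and the event counted.
#'
#' @param data A [trio_dataset()].
#' @param metric One of `"OH"`, `"HL"`, `"BXY"`, `"MXY"`.
#' @param sample Sample name (for `"OH"`/`"HL"`).
#' @param pair Character vector of two sample names (for `"BXY"`/`"MXY"`).
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; fixed seed gives an identical replicate vector.
#' @return A list of class `metric_bootstrap`: `metric`, `estimate`,
#'   `replicates`, `sd`, and `n_redrawn`.
#' @export
bootstrap_metric <- function(data, metric = c("OH", "HL", "BXY", "MXY"),
                             sample = NULL, pair = NULL, n_boot = 100L,
                             seed = NULL) {
  stopifnot(inherits(data, "trio_dataset"))
  metric <- match.arg(metric)
  if (n_boot < 2L) stop("n_boot must be >= 2")
  f <- metric_fun(data, metric, sample, pair)
  idx_all <- seq_len(n_sites(data))
  estimate <- f(idx_all)
  n_redrawn <- 0L
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    repeat {
      idx <- sample(idx_all, replace = TRUE)
      v <- tryCatch(f(idx), error = function(e) NA_real_)
      if (!is.na(v)) return(v)
      n_redrawn <<- n_redrawn + 1L
      if (n_redrawn > 100L * n_boot) {
        stop("metric undefined on essentially every bootstrap replicate")
      }
    }
  }, numeric(1)))
  structure(
    list(metric = metric, estimate = estimate, replicates = reps,
         sd = stats::sd(reps), n_redrawn = n_redrawn),
    class = "metric_bootstrap"
  )
}

#' @export
print.metric_bootstrap <- function(x, ...) {
  cat(sprintf("%s = %.4f (bootstrap sd %.4g, %d replicates)\n",
              x$metric, x$estimate, x$sd, length(x$replicates)))
  invisible(x)
}

metric_fun <- function(data, metric, sample, pair) {
  if (metric %in% c("OH", "HL")) {
    if (is.null(sample)) stop("metric ", metric, " needs a sample name")
    calls <- data$gt[, match_sample(data, sample)]
    if (metric == "OH") {
      function(idx) observed_heterozygosity(calls[idx])
    } else {
      function(idx) {
        freqs <- locus_expected_het(data$gt[idx, , drop = FALSE])
        homozygosity_by_loci(calls[idx], freqs)
      }
    }
  } else {
    if (is.null(pair) || length(pair) != 2L) {
      stop("metric ", metric, " needs a pair of sample names")
    }
    x <- data$gt[, match_sample(data, pair[1])]
    y <- data$gt[, match_sample(data, pair[2])]
    fun <- if (metric == "BXY") pairwise_bxy else pairwise_mxy
    function(idx) fun(x[idx], y[idx])
  }
}

match_sample <- function(data, sample) {
  i <- match(sample, data$samples)
  if (is.na(i)) stop("sample '", sample, "' not found in dataset")
  i
}

resolve_calls <- function(calls, sample) {
  if (inherits(calls, "trio_dataset")) {
    if (is.null(sample)) stop("a sample name is required with a trio_dataset")
    calls <- calls$gt[, match_sample(calls, sample)]
  }
  as.integer(calls)
}

resolve_pair <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) stop("call vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no pairwise-complete loci")
  list(x = x[ok], y = y[ok])
}

#' Per-sample and pairwise summary table for a trio
#'
#' Convenience wrapper computing OH and HL per sample and B_xy / M_xy for
#' every sample pair, each with a locus bootstrap.
#'
#' @param data A filtered [trio_dataset()].
#' @param n_boot Bootstrap replicates per metric.
#' @param seed Integer seed (per-metric seeds are derived by fixed offsets).
#' @return A list with `per_sample` (`data.frame`: sample, OH, OH_sd, HL,
#'   HL_sd), `relatedness` (square matrix, B_xy above the diagonal, M_xy
#'   below), and `bootstraps` (all `metric_bootstrap` objects).
#' @export
trio_summary_stats <- function(data, n_boot = 100L, seed = NULL) {
  stopifnot(inherits(data, "trio_dataset"))
  boots <- list()
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    if (is.null(seed)) NULL else seed + k
  }
  per_sample <- do.call(rbind, lapply(data$samples, function(s) {
    oh <- bootstrap_metric(data, "OH", sample = s, n_boot = n_boot,
                           seed = next_seed())
    hl <- bootstrap_metric(data, "HL", sample = s, n_boot = n_boot,
                           seed = next_seed())
    boots[[paste0("OH_", s)]] <<- oh
    boots[[paste0("HL_", s)]] <<- hl
    data.frame(sample = s, OH = oh$estimate, OH_sd = oh$sd,
               HL = hl$estimate, HL_sd = hl$sd, stringsAsFactors = FALSE)
  }))
  ns <- length(data$samples)
  rel <- matrix(NA_real_, ns, ns, dimnames = list(data$samples, data$samples))
  if (ns >= 2L) {
    for (i in seq_len(ns - 1L)) {
      for (j in seq((i + 1L), ns)) {
        pr <- c(data$samples[i], data$samples[j])
        bxy <- bootstrap_metric(data, "BXY", pair = pr, n_boot = n_boot,
                                seed = next_seed())
        mxy <- bootstrap_metric(data, "MXY", pair = pr, n_boot = n_boot,
                                seed = next_seed())
        boots[[paste0("BXY_", pr[1], "_", pr[2])]] <- bxy
        boots[[paste0("MXY_", pr[1], "_", pr[2])]] <- mxy
        rel[i, j] <- bxy$estimate  # B_xy above the diagonal
        rel[j, i] <- mxy$estimate  # M_xy below
      }
    }
  }
  list(per_sample = per_sample, relatedness = rel, bootstraps = boots)
}
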