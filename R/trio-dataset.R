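#' Construct a trio genotype dataset
#'
#' The central container for a mother-plus-offspring SNP dataset: per-site
#' metadata, an integer genotype matrix and a read-depth matrix, one column
#' per sample with the mother always first. Genotypes are coded as ALT-allele
#' dosage: 0 = homozygous reference (0/0), 1 = heterozygous (0/1),
#' 2 = homozygous alternate (1/1), `NA` = missing (./.).
#'
#' @param samples Character vector of sample names, mother first.
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`, and logical `is_indel`, `multiallelic`. `alt` may hold a
#'   comma-separated list for multi-allelic records, which the filter stage
#'   removes.
#' @param gt Integer matrix, sites x samples, coded 0/1/2/`NA`.
#' @param dp Integer matrix of per-call read depths, same shape as `gt`.
#' @param info Optional `data.frame` of numeric INFO annotations (one row
#'   per site), e.g. `QD`, `FS`, `MQ`.
#' @param filter_log Optional `data.frame` recording filter attrition.
#' @return An object of class `trio_dataset`.
#' @export
trio_dataset <- function(samples, sites, gt, dp, info = NULL,
                         filter_log = NULL) {
  samples <- as.character(samples)
  if (length(samples) < 1L) stop("at least one sample is required")
  gt <- as.matrix(gt)
  dp <- as.matrix(dp)
  storage.mode(gt) <- "integer"
  storage.mode(dp) <- "integer"
  if (nrow(gt) != nrow(sites) || nrow(dp) != nrow(sites)) {
    stop("gt/dp row count must equal the number of sites")
  }
  if (ncol(gt) != length(samples) || ncol(dp) != length(samples)) {
    stop("gt/dp column count must equal the number of samples")
  }
  colnames(gt) <- samples
  colnames(dp) <- samples
  needed <- c("chrom", "pos", "ref", "alt", "qual")
  miss <- setdiff(needed, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(sites$is_indel)) {
    sites$is_indel <- nchar(sites$ref) > 1L |
      vapply(strsplit(sites$alt, ",", fixed = TRUE),
             function(a) any(nchar(a) > 1L), logical(1))
  }
  if (is.null(sites$multiallelic)) {
    sites$multiallelic <- grepl(",", sites$alt, fixed = TRUE)
  }
  if (any(sites$pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (!is.null(info) && nrow(info) != nrow(sites)) {
    stop("info must have one row per site")
  }
  structure(
    list(
      samples = samples,
      sites = sites,
      gt = gt,
      dp = dp,
      info = info,
      filter_log = filter_log %||%
        data.frame(rule = character(), removed = integer(),
                   note = character(), stringsAsFactors = FALSE)
    ),
    class = "trio_dataset"
  )
}

#' @export
print.trio_dataset <- function(x, ...) {
  cat("trio_dataset:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  cat("  samples (mother first):", paste(x$samples, collapse = ", "), "\n")
  het <- colMeans(x$gt == GT_HET, na.rm = TRUE)
  cat("  per-sample het fraction:",
      paste(sprintf("%s=%.4f", x$samples, het), collapse = ", "), "\n")
  if (nrow(x$filter_log)) {
    cat("  filter log:", nrow(x$filter_log), "rules applied\n")
  }
  invisible(x)
}

#' Number of sites in a trio dataset
#' @param data A `trio_dataset`.
#' @return Integer site count.
#' @export
n_sites <- function(data) {
  stopifnot(inherits(data, "trio_dataset"))
  nrow(data$sites)
}

# Row subset preserving all parallel slots.
subset_sites <- function(data, keep) {
  data$sites <- data$sites[keep, , drop = FALSE]
  rownames(data$sites) <- NULL
  data$gt <- data$gt[keep, , drop = FALSE]
  data$dp <- data$dp[keep, , drop = FALSE]
  if (!is.null(data$info)) {
    data$info <- data$info[keep, , drop = FALSE]
    rownames(data$info) <- NULL
  }
  data
}

# Locus identifiers for all sites.
site_ids <- function(data) locus_id(data$sites$chrom, data$sites$pos)

append_log <- function(data, rule, removed, note = "") {
  data$filter_log <- rbind(
    data$filter_log,
    data.frame(rule = rule, removed = as.integer(removed), note = note,
               stringsAsFactors = FALSE)
  )
  data
}
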