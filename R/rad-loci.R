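# RAD locus footprint derivation from per-base depth tracks.

#' Per-base depth track for one sample on one chromosome
#'
#' @param sample Sample name.
#' @param chrom Chromosome / contig name.
#' @param depth Integer vector of per-base read depth over the interval.
#' @param start 0-based start of the interval covered by `depth`
#'   (default 0, i.e. the chromosome start).
#' @param qual Optional per-base Phred quality (same length as `depth`);
#'   `NULL` means all bases pass the quality requirement.
#' @return A list of class `depth_track`.
#' @export
depth_track <- function(sample, chrom, depth, start = 0L, qual = NULL) {
  depth <- as.integer(depth)
  if (any(depth < 0L)) stop("depths must be non-negative")
  if (!is.null(qual) && length(qual) != length(depth)) {
    stop("qual must match depth length")
  }
  structure(list(sample = sample, chrom = chrom, start = as.integer(start),
                 depth = depth, qual = qual),
            class = "depth_track")
}

#' Derive RAD locus footprints from depth tracks
#'
#' A base passes when its depth is at least `min_depth` in every sample
#' and its quality is at least `min_qual` in every track that carries
#' quality. Passing runs separated by gaps of at most `max_gap` bases are
#' merged into one locus (the gap bases are included in the span), and
#' merged loci shorter than `min_len` are dropped. This reconstructs the
#' restriction-site-associated locus footprint shared by all samples.
#'
#' @param tracks List of [depth_track()] objects, one per sample per
#'   chromosome; tracks on the same chromosome must cover the same
#'   interval.
#' @param min_depth Minimum per-sample depth for a base to pass.
#' @param min_qual Minimum per-base Phred quality.
#' @param max_gap Maximum low-coverage gap (bp) bridged when merging.
#' @param min_len Minimum locus length (bp) after merging.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), non-overlapping and sorted within chromosome.
#' @export
derive_rad_loci <- function(tracks, min_depth = 5L, min_qual = 30,
                            max_gap = 10L, min_len = 100L) {
  stopifnot(length(tracks) >= 1L)
  chroms <- vapply(tracks, function(t) t$chrom, character(1))
  out <- list()
  for (ch in unique(chroms)) {
    tr <- tracks[chroms == ch]
    starts <- vapply(tr, function(t) t$start, integer(1))
    lens <- vapply(tr, function(t) length(t$depth), integer(1))
    if (length(unique(starts)) != 1L || length(unique(lens)) != 1L) {
      stop("depth tracks on chromosome '", ch,
           "' cover mismatched intervals")
    }
    pass <- rep(TRUE, lens[1])
    for (t in tr) {
      pass <- pass & t$depth >= min_depth
      if (!is.null(t$qual)) pass <- pass & t$qual >= min_qual
    }
    if (!any(pass)) next
    ir <- IRanges::IRanges(start = which(pass), width = 1L)
    merged <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L)
    merged <- merged[IRanges::width(merged) >= min_len]
    if (!length(merged)) next
    out[[ch]] <- data.frame(
      chrom = ch,
      start = starts[1] + IRanges::start(merged) - 1L,  # to 0-based
      end = starts[1] + IRanges::end(merged),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
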