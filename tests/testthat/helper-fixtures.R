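# Fixtures are built in code at test time; nothing binary ships with the
# package.

# A small hand-written VCF: 3 samples, 5 records, one ./. call, one
# multi-allelic record, one indel, GT:DP format, GATK-style INFO keys.
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="x">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    "##contig=<ID=chr1>",
    "##contig=<ID=chr2>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "momma", "kidA", "kidB", sep = "\t"),
    "chr1\t100\t.\tA\tG\t60\tPASS\tQD=20;FS=1\tGT:DP\t0/1:30\t0/0:25\t1/1:28",
    "chr1\t250\t.\tC\tT\t45\tPASS\tQD=15;FS=2\tGT:DP\t0/0:20\t./.:0\t0/1:22",
    "chr1\t400\t.\tG\tGA\t80\tPASS\tQD=25;FS=0\tGT:DP\t0/1:30\t0/1:30\t0/0:30",
    "chr2\t150\t.\tT\tA,C\t90\tPASS\tQD=30;FS=1\tGT:DP\t1/2:40\t0/1:35\t0/0:30",
    "chr2\t500\t.\tG\tC\t55\tPASS\tQD=18;FS=3\tGT:DP\t0/1:33\t1/1:31\t0/0:29"
  )
  writeLines(lines, path)
  path
}

# Direct trio builder from genotype-code rows (one row per site).
make_trio <- function(gt_rows, samples = c("mother", "off1", "off2"),
                      chrom = NULL, pos = NULL, qual = NULL, dp = NULL,
                      info = NULL) {
  gt <- do.call(rbind, gt_rows)
  n <- nrow(gt)
  sites <- data.frame(
    chrom = chrom %||% rep("chr1", n),
    pos = pos %||% seq(100L, by = 100L, length.out = n),
    ref = rep("A", n), alt = rep("G", n),
    qual = qual %||% rep(60, n),
    stringsAsFactors = FALSE
  )
  if (is.null(dp)) dp <- matrix(30L, n, length(samples))
  trio_dataset(samples, sites, gt, dp, info = info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force oracle for RAD locus derivation: label each base, scan runs
# with explicit loops, merge across small gaps, drop short loci.
brute_force_rad_loci <- function(depth_mat, qual_mat = NULL, min_depth = 5,
                                 min_qual = 30, max_gap = 10,
                                 min_len = 100, chrom = "chr1") {
  n <- ncol(depth_mat)
  pass <- logical(n)
  for (i in seq_len(n)) {
    ok <- all(depth_mat[, i] >= min_depth)
    if (ok && !is.null(qual_mat)) ok <- all(qual_mat[, i] >= min_qual)
    pass[i] <- ok
  }
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (pass[i]) {
      j <- i
      while (j < n && pass[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(runs)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  merged <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- merged[[length(merged)]]
    gap <- r[1] - last[2] - 1L
    if (gap <= max_gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  keep <- Filter(function(r) r[2] - r[1] + 1L >= min_len, merged)
  if (!length(keep)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  data.frame(chrom = chrom,
             start = vapply(keep, function(r) r[1] - 1L, integer(1)),
             end = vapply(keep, function(r) r[2], integer(1)),
             stringsAsFactors = FALSE)
}

# Exact null expectation of the Jaccard index when two subsets of fixed
# sizes are drawn uniformly from N loci: |A∩B| is hypergeometric, so
# E[J] = sum_k P(k) * k / (na + nb - k).
hypergeom_jaccard_mean <- function(na, nb, N) {
  k <- max(0L, na + nb - N):min(na, nb)
  p <- dhyper(k, na, N - na, nb)
  sum(p * k / (na + nb - k))
}

# Full-enumeration oracle for the exact two-sided binomial test at p = 0.5
# (sums all outcomes with point probability <= that of the observed one,
# with the same relative fuzz binom.test documents).
enum_binom_two_sided <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

expected_verdict <- function(mechanism) {
  switch(mechanism,
         TF = "TERMINAL_FUSION", GD = "GAMETIC_DUPLICATION",
         APOMIXIS = "CENTRAL_FUSION_LIKE", SEXUAL = "SEXUAL",
         CF = "CENTRAL_FUSION_LIKE")
}
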