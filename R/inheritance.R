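# Inference on the fate of maternal heterozygosity: fate tallies,
# inheritance-bias binomial tests, shared-retention Jaccard permutation
# test, GC flank comparison, and the rule-based mechanism call.

#' Classify fates of maternal heterozygous loci in one offspring
#'
#' Restricts to loci heterozygous in the mother and counts how the
#' offspring is genotyped there: `n00` (homozygous reference), `n01`
#' (heterozygous, i.e. retained), `n11` (homozygous alternate). Locus
#' identities are recorded for each class.
#'
#' @param trio A filtered, complete-case [trio_dataset()] (mother first).
#' @param offspring Offspring sample name.
#' @return A list of class `het_fate_table`: `offspring`, `n00`, `n01`,
#'   `n11`, and `loci` (list of `chrom:pos` ids per class).
#' @export
classify_fates <- function(trio, offspring) {
  stopifnot(inherits(trio, "trio_dataset"))
  oi <- match_sample(trio, offspring)
  if (oi == 1L) stop("offspring must differ from the mother (sample 1)")
  mother_het <- !is.na(trio$gt[, 1L]) & trio$gt[, 1L] == GT_HET
  if (!any(mother_het)) stop("mother has no heterozygous loci")
  off <- trio$gt[mother_het, oi]
  ids <- site_ids(trio)[mother_het]
  ok <- !is.na(off)
  off <- off[ok]
  ids <- ids[ok]
  structure(
    list(offspring = offspring,
         n00 = sum(off == GT_HOM_REF),
         n01 = sum(off == GT_HET),
         n11 = sum(off == GT_HOM_ALT),
         loci = list(hom_ref = ids[off == GT_HOM_REF],
                     het = ids[off == GT_HET],
                     hom_alt = ids[off == GT_HOM_ALT])),
    class = "het_fate_table"
  )
}

#' Build a fate table from printed counts
#'
#' For re-analysis of published tallies where only the three counts are
#' available (no locus identities).
#'
#' @param n00,n01,n11 Counts of maternal-het loci genotyped 0/0, 0/1, 1/1
#'   in the offspring.
#' @param offspring Label for the offspring.
#' @return A `het_fate_table`.
#' @export
het_fate_table <- function(n00, n01, n11, offspring = "offspring") {
  stopifnot(n00 >= 0, n01 >= 0, n11 >= 0)
  structure(
    list(offspring = offspring, n00 = as.integer(n00),
         n01 = as.integer(n01), n11 = as.integer(n11), loci = NULL),
    class = "het_fate_table"
  )
}

#' @export
print.het_fate_table <- function(x, ...) {
  total <- x$n00 + x$n01 + x$n11
  cat(sprintf("het_fate_table (%s): n00=%d n01=%d n11=%d (N=%d, %.1f%% retained)\n",
              x$offspring, x$n00, x$n01, x$n11, total,
              100 * x$n01 / total))
  invisible(x)
}

#' Fraction of maternal heterozygosity retained in an offspring
#'
#' @param table A `het_fate_table`.
#' @return `n01 / (n00 + n01 + n11)`.
#' @export
retained_fraction <- function(table) {
  stopifnot(inherits(table, "het_fate_table"))
  total <- table$n00 + table$n01 + table$n11
  if (total == 0L) stop("fate table is empty")
  table$n01 / total
}

#' Exact binomial test for biased inheritance of lost heterozygosity
#'
#' Among maternal-het loci that became homozygous in the offspring,
#' independent inheritance of unlinked loci predicts equal numbers fixed
#' for the reference (0/0) and alternate (1/1) allele. Tests
#' `n00` successes in `n00 + n11` trials against p = 0.5 with the exact
#' two-sided binomial test (all outcomes with point probability at most
#' that of the observed one are summed, which at p = 0.5 equals doubling
#' the smaller tail, capped at 1).
#'
#' @param table A `het_fate_table`, or the `n00` count when `n11` is given.
#' @param n11 Optional `n11` count when `table` is a number.
#' @return The two-sided p-value.
#' @export
binomial_bias_test <- function(table, n11 = NULL) {
  if (inherits(table, "het_fate_table")) {
    n00 <- table$n00
    n11 <- table$n11
  } else {
    n00 <- table
    if (is.null(n11)) stop("supply a het_fate_table or both counts")
  }
  if (n00 + n11 == 0L) stop("no loci lost heterozygosity; test undefined")
  stats::binom.test(n00, n00 + n11, p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Jaccard index of two locus sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`; defined as 0 when both sets
#' are empty (with a message).
#'
#' @param a,b Character vectors of locus identifiers (`chrom:pos`).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    message("both locus sets empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Permutation test for shared retained heterozygosity
#'
#' Observes the Jaccard index of the two offsprings' retained-het locus
#' sets and compares it with a null in which each offspring's retained
#' set is a uniform random subset of the maternal heterozygous loci of
#' the same size (the minimal null preserving both retained counts). The
#' empirical p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)`. Because the retained-set
#' sizes are fixed, the null intersection is hypergeometric, which
#' provides an analytic cross-check of the null mean.
#'
#' @param set_a,set_b Retained-het locus ids of the two offspring (or two
#'   `het_fate_table`s with locus identities).
#' @param maternal_het_loci All maternal-het locus ids; both sets must be
#'   subsets of it.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return A list of class `jaccard_result`: `observed_j`, `null_j`,
#'   `p_emp`, plus `overlap_over_min` (`|A∩B| / min(|A|,|B|)`, an
#'   alternative sharing proportion) and the set sizes.
#' @export
jaccard_permutation_test <- function(set_a, set_b, maternal_het_loci,
                                     n_perm = 100L, seed = NULL) {
  if (inherits(set_a, "het_fate_table")) set_a <- set_a$loci$het
  if (inherits(set_b, "het_fate_table")) set_b <- set_b$loci$het
  if (n_perm < 1L) stop("n_perm must be >= 1")
  maternal_het_loci <- unique(maternal_het_loci)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, maternal_het_loci)) ||
      length(setdiff(set_b, maternal_het_loci))) {
    stop("retained sets must be subsets of the maternal heterozygous loci")
  }
  observed <- jaccard_index(set_a, set_b)
  na <- length(set_a); nb <- length(set_b)
  null_j <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pa <- sample(maternal_het_loci, na)
    pb <- sample(maternal_het_loci, nb)
    jaccard_index(pa, pb)
  }, numeric(1)))
  structure(
    list(observed_j = observed,
         null_j = null_j,
         p_emp = (1 + sum(null_j >= observed)) / (1 + n_perm),
         overlap_over_min = if (min(na, nb) > 0L) {
           length(intersect(set_a, set_b)) / min(na, nb)
         } else 0,
         n_a = na, n_b = nb, n_universe = length(maternal_het_loci)),
    class = "jaccard_result"
  )
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat(sprintf(
    "Jaccard overlap: observed %.3f (|A|=%d, |B|=%d of %d), null mean %.3f, p_emp = %.4g\n",
    x$observed_j, x$n_a, x$n_b, x$n_universe, mean(x$null_j), x$p_emp))
  invisible(x)
}

#' Compare GC content of flanks around locus classes
#'
#' Computes the GC fraction of the ± `window_bp` flank around each locus
#' (N bases excluded from numerator and denominator; windows truncated at
#' contig edges) for up to three classes — retained heterozygosity, lost
#' heterozygosity, and a homozygous background — then compares every pair
#' of non-empty classes with a two-sided Mann-Whitney test and a label
#' permutation of the mean difference (both p-values are reported, since
#' neither is uniquely implied by a claim of indistinguishability).
#'
#' @param ref A named `DNAStringSet` (see [read_fasta()]).
#' @param retained,lost,background Character vectors of `chrom:pos` ids
#'   (empty vectors allowed).
#' @param window_bp Flank half-width in bp.
#' @param n_perm Label permutations per comparison.
#' @param seed Integer seed.
#' @return A list of class `gc_flank_stats`: `window_bp`, `gc` (named list
#'   of per-locus GC fractions per class), and `comparisons` (`data.frame`
#'   with `class_a`, `class_b`, `mean_a`, `mean_b`, `wilcox_p`, `perm_p`).
#' @export
gc_flank_comparison <- function(ref, retained, lost,
                                background = character(),
                                window_bp = 5000L, n_perm = 100L,
                                seed = NULL) {
  if (window_bp <= 0) stop("window_bp must be positive")
  classes <- list(retained = retained, lost = lost, background = background)
  gc <- lapply(classes, function(ids) flank_gc(ref, ids, window_bp))
  nonempty <- names(gc)[vapply(gc, length, integer(1)) > 0L]
  comps <- list()
  if (length(nonempty) >= 2L) {
    prs <- utils::combn(nonempty, 2L, simplify = FALSE)
    comps <- with_seed(seed, lapply(prs, function(pr) {
      x <- gc[[pr[1]]]; y <- gc[[pr[2]]]
      wp <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
      obs <- abs(mean(x) - mean(y))
      pool <- c(x, y)
      nx <- length(x)
      perm <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pool), nx)
        abs(mean(pool[idx]) - mean(pool[-idx]))
      }, numeric(1))
      data.frame(class_a = pr[1], class_b = pr[2],
                 mean_a = mean(x), mean_b = mean(y),
                 wilcox_p = wp,
                 perm_p = (1 + sum(perm >= obs)) / (1 + n_perm),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(window_bp = as.integer(window_bp), gc = gc,
         comparisons = if (length(comps)) do.call(rbind, comps) else
           data.frame(class_a = character(), class_b = character(),
                      mean_a = numeric(), mean_b = numeric(),
                      wilcox_p = numeric(), perm_p = numeric())),
    class = "gc_flank_stats"
  )
}

# GC fraction of the +/- window flank around each chrom:pos id.
flank_gc <- function(ref, ids, window_bp) {
  if (!length(ids)) return(numeric(0))
  loc <- parse_locus_id(ids)
  missing_chrom <- setdiff(unique(loc$chrom), names(ref))
  if (length(missing_chrom)) {
    stop("contig(s) absent from reference FASTA: ",
         paste(missing_chrom, collapse = ", "))
  }
  lens <- Biostrings::width(ref)[match(loc$chrom, names(ref))]
  start <- pmax(1L, loc$pos - as.integer(window_bp))
  end <- pmin(lens, loc$pos + as.integer(window_bp))
  vapply(seq_len(nrow(loc)), function(i) {
    s <- Biostrings::subseq(ref[[loc$chrom[i]]], start[i], end[i])
    counts <- Biostrings::letterFrequency(s, c("G", "C", "A", "T"))
    acgt <- sum(counts)
    if (acgt == 0) return(NA_real_)
    (counts[["G"]] + counts[["C"]]) / acgt
  }, numeric(1))
}

#' Default thresholds for the mechanism classifier
#'
#' All thresholds are heuristic and echoed in every verdict. `rel_high`:
#' mother-offspring relatedness above this is "near 1" (clonal-scale);
#' `sexual_band`: relatedness range compatible with sexual reproduction;
#' `gd_max_fraction` / `gd_max_count`: retained heterozygosity at or below
#' either is consistent with gametic duplication; `cf_min_oh_ratio`:
#' offspring/mother OH ratio at or above this points to a central-
#' fusion-like (or clonal) mechanism; `clone_min_mxy`: genotype sharing at
#' or above this flags a clone.
#'
#' @param rel_high,sexual_band,gd_max_fraction,gd_max_count,cf_min_oh_ratio,clone_min_mxy
#'   Numeric thresholds (see description).
#' @return A named list.
#' @export
mechanism_thresholds <- function(rel_high = 0.95,
                                 sexual_band = c(0.55, 0.92),
                                 gd_max_fraction = 0.005,
                                 gd_max_count = 2L,
                                 cf_min_oh_ratio = 0.8,
                                 clone_min_mxy = 0.999) {
  list(rel_high = rel_high, sexual_band = sexual_band,
       gd_max_fraction = gd_max_fraction, gd_max_count = gd_max_count,
       cf_min_oh_ratio = cf_min_oh_ratio, clone_min_mxy = clone_min_mxy)
}

#' Rule-based automixis mechanism call for one offspring
#'
#' Applies transparent threshold rules to the evidence: near-1 relatedness
#' with essentially no retained heterozygosity means gametic duplication;
#' near-1 relatedness with partial retention means terminal fusion;
#' near-1 relatedness with maternal-level heterozygosity means a central-
#' fusion-like mechanism (a clone flag marks apomixis-compatible genotype
#' identity); relatedness in the sexual band means sexual reproduction;
#' anything else is inconclusive. The thresholds and the full evidence
#' payload always accompany the verdict.
#'
#' @param evidence A list with `oh_mother`, `oh_offspring`, `relatedness`
#'   (mother-offspring B_xy or M_xy), `retained_fraction`,
#'   `retained_count`, and optionally `mxy` (defaults to `relatedness`).
#' @param thresholds A [mechanism_thresholds()] list.
#' @return A list of class `mechanism_call`: `verdict` (one of
#'   `"GAMETIC_DUPLICATION"`, `"TERMINAL_FUSION"`, `"CENTRAL_FUSION_LIKE"`,
#'   `"SEXUAL"`, `"INCONCLUSIVE"`), `clone` flag, `evidence`, `thresholds`.
#' @export
diagnose_mechanism <- function(evidence, thresholds = mechanism_thresholds()) {
  need <- c("oh_mother", "oh_offspring", "relatedness",
            "retained_fraction", "retained_count")
  miss <- setdiff(need, names(evidence))
  if (length(miss)) stop("evidence is missing: ", paste(miss, collapse = ", "))
  ev <- evidence
  ev$mxy <- ev$mxy %||% ev$relatedness
  th <- thresholds
  oh_ratio <- if (ev$oh_mother > 0) ev$oh_offspring / ev$oh_mother else NA_real_
  clone <- ev$mxy >= th$clone_min_mxy
  verdict <- if (ev$relatedness >= th$rel_high) {
    if (ev$retained_fraction <= th$gd_max_fraction ||
        ev$retained_count <= th$gd_max_count) {
      "GAMETIC_DUPLICATION"
    } else if (!is.na(oh_ratio) && oh_ratio >= th$cf_min_oh_ratio) {
      "CENTRAL_FUSION_LIKE"
    } else {
      "TERMINAL_FUSION"
    }
  } else if (ev$relatedness >= th$sexual_band[1] &&
             ev$relatedness <= th$sexual_band[2]) {
    "SEXUAL"
  } else {
    "INCONCLUSIVE"
  }
  ev$oh_ratio <- oh_ratio
  structure(
    list(verdict = verdict, clone = clone, evidence = ev, thresholds = th),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("mechanism call:", x$verdict,
      if (isTRUE(x$clone)) "(clone flag set)" else "", "\n")
  cat(sprintf("  relatedness %.3f | OH ratio %.3f | retained %.3f (n=%d)\n",
              x$evidence$relatedness, x$evidence$oh_ratio,
              x$evidence$retained_fraction, x$evidence$retained_count))
  invisible(x)
}

#' Diagnose the mechanism for one offspring of a trio dataset
#'
#' Computes the evidence (OH for mother and offspring, mother-offspring
#' B_xy and M_xy, fate table) from the genotypes and runs
#' [diagnose_mechanism()].
#'
#' @param trio A filtered [trio_dataset()].
#' @param offspring Offspring sample name.
#' @param thresholds A [mechanism_thresholds()] list.
#' @return A `mechanism_call` whose evidence also carries the
#'   `het_fate_table`.
#' @export
diagnose_trio_offspring <- function(trio, offspring,
                                    thresholds = mechanism_thresholds()) {
  oi <- match_sample(trio, offspring)
  fates <- classify_fates(trio, offspring)
  ev <- list(
    oh_mother = observed_heterozygosity(trio, trio$samples[1]),
    oh_offspring = observed_heterozygosity(trio, offspring),
    relatedness = pairwise_bxy(trio$gt[, 1L], trio$gt[, oi]),
    mxy = pairwise_mxy(trio$gt[, 1L], trio$gt[, oi]),
    retained_fraction = retained_fraction(fates),
    retained_count = fates$n01
  )
  call <- diagnose_mechanism(ev, thresholds)
  call$evidence$fates <- fates
  call
}
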