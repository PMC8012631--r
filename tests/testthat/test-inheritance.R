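test_that("fate classification partitions the maternal heterozygous loci", {
  d <- make_trio(list(c(1L, 0L, 1L), c(1L, 1L, 2L), c(0L, 2L, 0L),
                      c(1L, 2L, 0L), c(1L, 1L, 1L)))
  f1 <- classify_fates(d, "off1")
  expect_s3_class(f1, "het_fate_table")
  expect_equal(c(f1$n00, f1$n01, f1$n11), c(1L, 2L, 1L))
  expect_equal(f1$loci$hom_ref, "chr1:100")
  # partition property: counts sum to the maternal-het locus count
  expect_equal(f1$n00 + f1$n01 + f1$n11, sum(d$gt[, 1] == 1L))
  expect_true(!anyDuplicated(unlist(f1$loci)))
  # clone: every maternal-het locus stays het
  clone <- make_trio(list(c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L)))
  fc <- classify_fates(clone, "off1")
  expect_equal(c(fc$n00, fc$n01, fc$n11), c(0L, 2L, 0L))
  # no maternal heterozygosity -> error
  hom <- make_trio(list(c(0L, 1L, 1L), c(2L, 0L, 0L)))
  expect_error(classify_fates(hom, "off1"), "no heterozygous")
})

test_that("fate partition holds on simulated trios of every mechanism", {
  for (mech in c("TF", "CF", "GD", "APOMIXIS", "SEXUAL")) {
    cfg <- sim_config(n_chrom = 3L, chrom_length = 1e5, n_markers = 600L,
                      maternal_het_fraction = 0.2, missingness = 0.05,
                      seed = match(mech, c("TF", "CF", "GD", "APOMIXIS",
                                           "SEXUAL")))
    sim <- simulate_trio(cfg, mech, make_reference = FALSE)
    d <- apply_site_filters(sim$trio, filter_config(depth_bounds = c(0, Inf)))
    f <- classify_fates(d, "offspring_1")
    expect_equal(f$n00 + f$n01 + f$n11, sum(d$gt[, 1] == 1L), info = mech)
  }
})

test_that("retained fraction is the het share of the fate table", {
  expect_equal(retained_fraction(het_fate_table(10, 5, 5)), 0.25)
  expect_equal(retained_fraction(het_fate_table(0, 7, 0)), 1)
  expect_error(retained_fraction(het_fate_table(0, 0, 0)), "empty")
})

test_that("binomial bias test equals the full-enumeration oracle for n <= 20", {
  for (n in 1:20) {
    for (k in 0:n) {
      expect_equal(binomial_bias_test(k, n - k), enum_binom_two_sided(k, n),
                   tolerance = 1e-12, info = paste(k, n))
    }
  }
  expect_equal(binomial_bias_test(8, 2), 112 / 1024)
  expect_equal(binomial_bias_test(5, 5), 1)
  expect_error(binomial_bias_test(0, 0), "undefined")
})

test_that("binomial bias test is symmetric and monotone in the imbalance", {
  for (n in c(10L, 21L, 40L)) {
    ks <- 0:n
    p <- vapply(ks, function(k) binomial_bias_test(k, n - k), numeric(1))
    expect_equal(p, rev(p))  # symmetry in (n00, n11)
    upper <- p[ks >= ceiling(n / 2)]
    expect_true(all(diff(upper) <= 1e-12))  # decreasing as imbalance grows
  }
})

test_that("Jaccard index covers its edge cases", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_message(j0 <- jaccard_index(character(), character()), "empty")
  expect_equal(j0, 0)
})

test_that("Jaccard permutation test is deterministic with a valid empirical p", {
  universe <- paste0("chr1:", 1:100)
  a <- universe[1:30]
  b <- universe[21:60]
  r1 <- jaccard_permutation_test(a, b, universe, n_perm = 99, seed = 5)
  r2 <- jaccard_permutation_test(a, b, universe, n_perm = 99, seed = 5)
  expect_identical(r1$null_j, r2$null_j)
  expect_equal(r1$observed_j, 10 / 60)
  expect_equal(r1$p_emp, (1 + sum(r1$null_j >= r1$observed_j)) / 100)
  expect_gt(r1$p_emp, 0)
  expect_lte(r1$p_emp, 1)
  expect_equal(r1$overlap_over_min, 10 / 30)
  # degenerate: both offspring retain everything
  r3 <- jaccard_permutation_test(universe, universe, universe,
                                 n_perm = 20, seed = 1)
  expect_equal(r3$observed_j, 1)
  expect_true(all(r3$null_j == 1))
  expect_error(jaccard_permutation_test(c("chrX:1"), b, universe,
                                        n_perm = 10), "subsets")
  expect_error(jaccard_permutation_test(a, b, universe, n_perm = 0),
               "n_perm")
})

test_that("Jaccard null mean matches the hypergeometric expectation", {
  universe <- paste0("chr1:", 1:278)
  set.seed(8)
  a <- sample(universe, 64)
  b <- sample(universe, 75)
  r <- jaccard_permutation_test(a, b, universe, n_perm = 2000, seed = 9)
  exact <- hypergeom_jaccard_mean(64, 75, 278)
  se <- sd(r$null_j) / sqrt(length(r$null_j))
  expect_lt(abs(mean(r$null_j) - exact), 3 * se)
  # the null sits near 0.14 for these sizes, far below an observed 0.38
  expect_lt(max(r$null_j), 0.38)
})

test_that("flank GC is computed over the window with Ns excluded", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "GCGCATATGCGC", chr2 = "GCNNAT"))
  g <- gc_flank_comparison(ref, retained = "chr1:3", lost = "chr1:7",
                           window_bp = 1L, n_perm = 10, seed = 1)
  expect_equal(g$gc$retained, 1)  # bases 2-4 = "CGC"
  expect_equal(g$gc$lost, 0)     # bases 6-8 = "TAT"
  # N bases drop out of numerator and denominator
  gn <- gc_flank_comparison(ref, retained = "chr2:3", lost = character(),
                            window_bp = 2L, n_perm = 10, seed = 1)
  expect_equal(gn$gc$retained, 2 / 3)  # "GCNNA" -> GC=2 of ACGT=3
  expect_error(
    gc_flank_comparison(ref, retained = "chrZ:5", lost = character(),
                        window_bp = 1L),
    "chrZ")
})

test_that("GC comparison is well calibrated under a uniform-GC null", {
  cfg <- sim_config(n_chrom = 2L, chrom_length = 1e5, n_markers = 400L,
                    maternal_het_fraction = 0.5, missingness = 0, seed = 77)
  sim <- simulate_trio(cfg, "TF", make_reference = TRUE)
  ids <- paste0(sim$trio$sites$chrom, ":", sim$trio$sites$pos)
  set.seed(78)
  rejected <- 0L
  for (i in 1:20) {
    pick <- sample(ids, 100)
    g <- gc_flank_comparison(sim$ref, retained = pick[1:50],
                             lost = pick[51:100], window_bp = 2000L,
                             n_perm = 99, seed = i)
    if (g$comparisons$perm_p[1] < 0.05) rejected <- rejected + 1L
  }
  expect_lte(rejected, 4L)  # ~alpha-level rejections only
})

test_that("the mechanism classifier reproduces the canonical verdicts", {
  # a parthenogenetic trio summary: relatedness ~0.99, ~23% retention
  call <- diagnose_mechanism(list(
    oh_mother = 0.011, oh_offspring = 0.007, relatedness = 0.99,
    retained_fraction = 64 / 278, retained_count = 64L))
  expect_equal(call$verdict, "TERMINAL_FUSION")
  expect_false(call$clone)
  # gametic duplication: clonal relatedness, zero retention
  gd <- diagnose_mechanism(list(
    oh_mother = 0.011, oh_offspring = 0, relatedness = 0.99,
    retained_fraction = 0, retained_count = 0L))
  expect_equal(gd$verdict, "GAMETIC_DUPLICATION")
  # sexual: relatedness near the parent-offspring band
  sex <- diagnose_mechanism(list(
    oh_mother = 0.011, oh_offspring = 0.012, relatedness = 0.75,
    retained_fraction = 0.5, retained_count = 139L))
  expect_equal(sex$verdict, "SEXUAL")
  # apomixis-like: clonal relatedness with maternal-level heterozygosity
  apo <- diagnose_mechanism(list(
    oh_mother = 0.011, oh_offspring = 0.011, relatedness = 1, mxy = 1,
    retained_fraction = 1, retained_count = 278L))
  expect_equal(apo$verdict, "CENTRAL_FUSION_LIKE")
  expect_true(apo$clone)
  # out-of-band relatedness is not over-interpreted
  odd <- diagnose_mechanism(list(
    oh_mother = 0.011, oh_offspring = 0.011, relatedness = 0.2,
    retained_fraction = 0.5, retained_count = 10L))
  expect_equal(odd$verdict, "INCONCLUSIVE")
  expect_error(diagnose_mechanism(list(oh_mother = 0.1)), "missing")
})

test_that("thresholds are echoed and drive the verdict", {
  ev <- list(oh_mother = 0.02, oh_offspring = 0.018, relatedness = 0.97,
             retained_fraction = 0.9, retained_count = 90L)
  default <- diagnose_mechanism(ev)
  expect_equal(default$verdict, "CENTRAL_FUSION_LIKE")
  strict <- diagnose_mechanism(
    ev, mechanism_thresholds(cf_min_oh_ratio = 0.99))
  expect_equal(strict$verdict, "TERMINAL_FUSION")
  expect_equal(strict$thresholds$cf_min_oh_ratio, 0.99)
})

test_that("retained loci of a simulated terminal-fusion offspring sit inside truth tracts", {
  cfg <- sim_config(n_chrom = 4L, chrom_length = 2e5, n_markers = 1000L,
                    maternal_het_fraction = 0.2, missingness = 0.02,
                    seed = 83)
  sim <- simulate_trio(cfg, "TF", make_reference = FALSE)
  d <- apply_site_filters(sim$trio, filter_config(depth_bounds = c(0, Inf)))
  f <- classify_fates(d, "offspring_1")
  tracts <- sim$truth$offspring_1$tracts
  loc <- automixr:::parse_locus_id(f$loci$het)
  inside <- vapply(seq_len(nrow(loc)), function(i) {
    tr <- tracts[tracts$chrom == loc$chrom[i], , drop = FALSE]
    any(loc$pos[i] > tr$start & loc$pos[i] <= tr$end)
  }, logical(1))
  expect_true(all(inside))
  expect_gt(nrow(loc), 0)
})
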