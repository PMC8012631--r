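# Test-local oracle: haplotype of origin of a chromatid at 1-based
# positions, read off the segment list directly.
hap_of <- function(seg, pos) seg$hap[findInterval(pos - 0.5, seg$start)]

small_cfg <- function(...) {
  args <- list(n_chrom = 2L, chrom_length = 1e5, n_markers = 400L,
               maternal_het_fraction = 0.5, missingness = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("maternal genome honors the heterozygosity fraction and the map", {
  g0 <- simulate_mother(small_cfg(maternal_het_fraction = 0, seed = 1))
  expect_true(all(vapply(g0$haplotypes,
                         function(h) all(h[1, ] == h[2, ]), logical(1))))
  g1 <- simulate_mother(small_cfg(maternal_het_fraction = 1, seed = 1))
  gt <- unlist(lapply(g1$haplotypes, colSums))
  expect_true(all(gt == 1L))  # OH(mother) = 1
  for (m in g1$map) {
    expect_true(all(diff(m$positions) > 0))
    expect_true(all(m$positions >= 1 & m$positions <= m$length_bp))
  }
  # determinism under seed
  g1b <- simulate_mother(small_cfg(maternal_het_fraction = 1, seed = 1))
  expect_identical(g1, g1b)
  expect_error(simulate_mother(small_cfg(n_markers = 0L)), "n_markers")
})

test_that("without crossovers all four chromatids are pure parental haplotypes", {
  cfg <- small_cfg(obligate_crossover = FALSE, mean_extra_crossovers = 0)
  g <- simulate_mother(cfg, seed = 2)
  out <- simulate_meiosis(g, cfg, seed = 3)
  for (ch in names(out)) {
    haps <- vapply(out[[ch]]$chromatids, function(s) {
      expect_equal(nrow(s), 1L)
      s$hap[1]
    }, integer(1))
    expect_equal(sort(haps), c(1L, 1L, 2L, 2L))
    expect_equal(nrow(out[[ch]]$crossovers), 0L)
  }
})

test_that("a single crossover exchanges exactly the distal segments", {
  cfg <- small_cfg()  # obligate, no extras, telocentric
  g <- simulate_mother(cfg, seed = 4)
  out <- simulate_meiosis(g, cfg, seed = 5)
  for (ch in names(out)) {
    oc <- out[[ch]]
    expect_equal(nrow(oc$crossovers), 1L)
    x <- oc$crossovers$pos[1]
    a <- oc$crossovers$chromatid_a[1]
    b <- oc$crossovers$chromatid_b[1]
    len <- g$map[[ch]]$length_bp
    # involved chromatids carry the partner haplotype distal to x
    expect_equal(oc$chromatids[[a]],
                 data.frame(start = c(0, x), end = c(x, len),
                            hap = c(1L, 2L)))
    expect_equal(oc$chromatids[[b]],
                 data.frame(start = c(0, x), end = c(x, len),
                            hap = c(2L, 1L)))
    # uninvolved chromatids stay pure
    for (i in setdiff(1:4, c(a, b))) {
      expect_equal(nrow(oc$chromatids[[i]]), 1L)
    }
  }
})

test_that("recorded breakpoints account for every boundary observable in segments", {
  # with one crossover the recorded position IS the visible junction;
  # with several, a later exchange can erase a junction (swapping equal
  # material), so visible boundaries are a subset of recorded positions
  cfg1 <- small_cfg()
  g <- simulate_mother(cfg1, seed = 6)
  for (s in 1:5) {
    out <- simulate_meiosis(g, cfg1, seed = 100 + s)
    for (ch in names(out)) {
      boundaries <- sort(unique(unlist(lapply(
        out[[ch]]$chromatids, function(seg) seg$start[-1L]))))
      expect_equal(boundaries, sort(out[[ch]]$crossovers$pos))
    }
  }
  cfg2 <- small_cfg(mean_extra_crossovers = 2)
  for (s in 1:5) {
    out <- simulate_meiosis(g, cfg2, seed = 150 + s)
    for (ch in names(out)) {
      boundaries <- unique(unlist(lapply(
        out[[ch]]$chromatids, function(seg) seg$start[-1L])))
      expect_true(all(boundaries %in% out[[ch]]$crossovers$pos))
    }
  }
})

test_that("each haplotype allele appears exactly twice across the four chromatids", {
  cfg <- small_cfg(mean_extra_crossovers = 3)
  g <- simulate_mother(cfg, seed = 7)
  for (s in 1:10) {
    out <- simulate_meiosis(g, cfg, seed = 200 + s)
    for (ch in names(out)) {
      pos <- g$map[[ch]]$positions
      haps <- vapply(out[[ch]]$chromatids, hap_of, numeric(length(pos)),
                     pos = pos)
      expect_true(all(rowSums(haps == 1L) == 2L))
      expect_true(all(rowSums(haps == 2L) == 2L))
    }
  }
})

test_that("terminal fusion retains heterozygosity exactly distal to a single crossover", {
  cfg <- small_cfg()
  g <- simulate_mother(cfg, seed = 8)
  for (s in 1:10) {
    out <- simulate_meiosis(g, cfg, seed = 300 + s)
    off <- form_offspring(out, "TF", g, cfg, seed = 400 + s)
    i0 <- 0L
    for (ch in names(g$map)) {
      pos <- g$map[[ch]]$positions
      het_mom <- g$haplotypes[[ch]][1, ] != g$haplotypes[[ch]][2, ]
      gt <- off$gt[i0 + seq_along(pos)]
      i0 <- i0 + length(pos)
      x <- off$crossovers$pos[off$crossovers$chrom == ch]
      expect_identical(gt == 1L, het_mom & pos > x)
      # truth tract is [x, len): never includes the centromere side
      tr <- off$tracts[off$tracts$chrom == ch, ]
      expect_equal(nrow(tr), 1L)
      expect_gt(tr$start, 0)
      expect_equal(tr$start, x, tolerance = 1e-3)
      expect_equal(tr$end, g$map[[ch]]$length_bp, tolerance = 1e-3)
    }
  }
})

test_that("central fusion tracts always reach the centromere under one crossover", {
  cfg <- small_cfg()
  g <- simulate_mother(cfg, seed = 9)
  saw_full <- FALSE
  for (s in 1:20) {
    out <- simulate_meiosis(g, cfg, seed = 500 + s)
    off <- form_offspring(out, "CF", g, cfg, seed = 600 + s)
    for (ch in names(g$map)) {
      tr <- off$tracts[off$tracts$chrom == ch, ]
      expect_equal(nrow(tr), 1L)
      expect_equal(tr$start, 0)
      if (abs(tr$end - g$map[[ch]]$length_bp) < 1e-3) saw_full <- TRUE
    }
  }
  # the uninvolved polar chromatid is drawn half the time: the whole
  # chromosome stays heterozygous
  expect_true(saw_full)
})

test_that("expected terminal-fusion retention approaches one half", {
  # with a single uniform crossover and a telocentric chromosome the
  # retained fraction is 1 - x/len, mean one half; a finite marker set
  # adds its own placement error, so both terms enter the SE budget
  n_markers <- 2000L
  cfg <- sim_config(n_chrom = 1L, chrom_length = 1e5, n_markers = n_markers,
                    maternal_het_fraction = 1, missingness = 0)
  g <- simulate_mother(cfg, seed = 10)
  set.seed(11)
  fracs <- vapply(seq_len(2000), function(i) {
    out <- simulate_meiosis(g, cfg)
    off <- form_offspring(out, "TF", g, cfg)
    mean(off$gt == 1L)
  }, numeric(1))
  se_mc <- sd(fracs) / sqrt(length(fracs))
  rel_pos <- g$map[[1]]$positions / g$map[[1]]$length_bp
  se_markers <- sd(rel_pos) / sqrt(n_markers)
  expect_lt(abs(mean(fracs) - 0.5), 3 * sqrt(se_mc^2 + se_markers^2))
})

test_that("mechanism identities: GD fully homozygous, apomixis clonal, sexual shares an allele", {
  cfg <- small_cfg()
  g <- simulate_mother(cfg, seed = 12)
  mom <- unlist(lapply(g$haplotypes, colSums))
  out <- simulate_meiosis(g, cfg, seed = 13)

  gd <- form_offspring(out, "GD", g, cfg, seed = 14)
  expect_true(all(gd$gt %in% c(0L, 2L)))
  expect_equal(observed_heterozygosity(gd$gt), 0)
  expect_equal(nrow(gd$tracts), 0L)

  apo <- form_offspring(NULL, "APOMIXIS", g, cfg)
  expect_equal(apo$gt, as.integer(mom))
  expect_equal(pairwise_mxy(mom, apo$gt), 1)

  sex <- form_offspring(out, "SEXUAL", g, cfg, seed = 15)
  expect_true(all(abs(sex$gt - mom) <= 1L))  # parent and child share an allele
  expect_gte(pairwise_bxy(mom, sex$gt), 0.5)
  expect_null(sex$tracts)

  expect_error(form_offspring(out, "BUDDING", g, cfg), "arg")
})

test_that("simulated trios are reproducible to the byte and respect missingness", {
  cfg <- sim_config(n_chrom = 2L, chrom_length = 5e4, n_markers = 200L,
                    maternal_het_fraction = 0.05, missingness = 0,
                    depth_mean = 50, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_trio(cfg, c("TF", "TF"), make_reference = TRUE, out_dir = d1)
  simulate_trio(cfg, c("TF", "TF"), make_reference = TRUE, out_dir = d2)
  expect_identical(readLines(file.path(d1, "trio.vcf")),
                   readLines(file.path(d2, "trio.vcf")))
  expect_identical(readLines(file.path(d1, "reference.fa")),
                   readLines(file.path(d2, "reference.fa")))
  # missingness 0 + high depth: the complete-case rule removes nothing
  sim <- simulate_trio(cfg, c("TF", "TF"), make_reference = FALSE)
  filt <- apply_site_filters(sim$trio,
                             filter_config(depth_bounds = c(0, Inf)))
  log <- filt$filter_log
  expect_equal(log$removed[log$rule == "complete_case"], 0L)
  expect_equal(log$removed[log$rule == "low_depth_to_missing"], 0L)
  expect_equal(n_sites(filt), n_sites(sim$trio))
  # REF alleles in the VCF match the emitted FASTA
  sim_ref <- simulate_trio(cfg, "TF", make_reference = TRUE)
  fa <- sim_ref$ref
  sites <- sim_ref$trio$sites
  got <- vapply(seq_len(nrow(sites)), function(i) {
    substring(as.character(fa[[sites$chrom[i]]]), sites$pos[i], sites$pos[i])
  }, character(1))
  expect_equal(got, sites$ref)
})
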