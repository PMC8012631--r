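# Chromatid-level automixis simulator. Meiosis is modeled explicitly:
# each chromosome is replicated into four chromatids (two sister pairs),
# crossovers exchange segments between non-sister chromatids, and the
# mechanism (terminal fusion, central fusion, gametic duplication,
# apomixis, or sexual reproduction) decides which meiotic products restore
# diploidy. Every offspring carries a ground-truth list of the intervals
# where maternal heterozygosity is retained, so downstream statistics can
# be checked exactly.

#' Simulator configuration
#'
#' Defaults emulate a RADseq trio study of a snake-sized genome: 18
#' chromosomes, 20,562 markers, and a maternal heterozygous fraction of
#' 278/20,562, with one obligate crossover per chromosome and telocentric
#' chromosomes (centromere at coordinate 0, so "distal" means larger
#' coordinates, toward the telomere). Chromosome length is scaled to 1 Mb
#' per chromosome; crossover geometry and all marker-level statistics are
#' scale-free, so only the reference FASTA size depends on it.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (scalar, recycled).
#' @param centromere_pos Centromere coordinate per chromosome (scalar,
#'   recycled); 0 = telocentric.
#' @param n_markers Total marker (RAD locus) count across the genome.
#' @param maternal_het_fraction Probability a marker is heterozygous in
#'   the mother.
#' @param obligate_crossover If `TRUE` every chromosome receives at least
#'   one crossover per meiosis.
#' @param mean_extra_crossovers Poisson mean of additional crossovers per
#'   chromosome beyond the obligate one.
#' @param missingness Per-call probability a genotype is set missing.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   per call (`mu` and `size`); the default mean of 17 per sample gives a
#'   trio total near 50.
#' @param sexual_alt_freq ALT allele frequency of the unrelated paternal
#'   haplotype used by the sexual-reproduction mechanism.
#' @param gc_content Baseline GC fraction of the simulated reference.
#' @param gc_distal Optional distal-region GC fraction; when set, bases
#'   beyond `gc_boundary_frac` of the centromere-to-telomere span use this
#'   GC level (a positive control for GC-vs-retention comparisons).
#' @param gc_boundary_frac Fraction of the arm at which the distal GC
#'   level starts.
#' @param seed Integer seed; a fixed seed makes every simulator output
#'   byte-identical across runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 18L,
                       chrom_length = 1e6,
                       centromere_pos = 0,
                       n_markers = 20562L,
                       maternal_het_fraction = 278 / 20562,
                       obligate_crossover = TRUE,
                       mean_extra_crossovers = 0,
                       missingness = 0.02,
                       depth_mean = 17,
                       depth_dispersion = 5,
                       sexual_alt_freq = 0.5,
                       gc_content = 0.42,
                       gc_distal = NULL,
                       gc_boundary_frac = 0.5,
                       seed = NULL) {
  if (n_markers < 1L) stop("n_markers must be >= 1")
  rates <- c(maternal_het_fraction, missingness, sexual_alt_freq, gc_content)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  chrom_length <- rep_len(chrom_length, n_chrom)
  centromere_pos <- rep_len(centromere_pos, n_chrom)
  if (any(centromere_pos < 0 | centromere_pos > chrom_length)) {
    stop("centromere_pos must lie within [0, chrom_length]")
  }
  structure(
    list(n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
         centromere_pos = centromere_pos, n_markers = as.integer(n_markers),
         maternal_het_fraction = maternal_het_fraction,
         obligate_crossover = obligate_crossover,
         mean_extra_crossovers = mean_extra_crossovers,
         missingness = missingness, depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         sexual_alt_freq = sexual_alt_freq, gc_content = gc_content,
         gc_distal = gc_distal, gc_boundary_frac = gc_boundary_frac,
         seed = seed),
    class = "sim_config"
  )
}

#' Simulate a diploid maternal genome with a marker map
#'
#' Markers are scattered over the chromosomes proportionally to length;
#' each marker is independently heterozygous with probability
#' `maternal_het_fraction` (the haplotype carrying the ALT allele chosen
#' uniformly) and otherwise homozygous for REF or ALT with equal
#' probability.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed; defaults to `cfg$seed`. `NULL` uses the current RNG
#'   state (as when called inside [simulate_trio()]).
#' @return A list of class `maternal_genome` with elements `map` (per
#'   chromosome: `length_bp`, `centromere_pos`, sorted `positions`) and
#'   `haplotypes` (per chromosome: 2 x markers matrix of 0/1 alleles).
#' @export
simulate_mother <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chrom))
    weights <- cfg$chrom_length / sum(cfg$chrom_length)
    counts <- as.vector(stats::rmultinom(1L, cfg$n_markers, weights))
    map <- vector("list", cfg$n_chrom)
    haplotypes <- vector("list", cfg$n_chrom)
    names(map) <- chrom_names
    names(haplotypes) <- chrom_names
    for (i in seq_len(cfg$n_chrom)) {
      m <- counts[i]
      pos <- sort(sample.int(cfg$chrom_length[i], m))
      map[[i]] <- list(length_bp = cfg$chrom_length[i],
                       centromere_pos = cfg$centromere_pos[i],
                       positions = pos)
      het <- stats::runif(m) < cfg$maternal_het_fraction
      h <- matrix(0L, nrow = 2L, ncol = m)
      # heterozygous: ALT on one haplotype, chosen uniformly
      alt_on_1 <- stats::runif(m) < 0.5
      h[1L, het & alt_on_1] <- 1L
      h[2L, het & !alt_on_1] <- 1L
      # homozygous: REF/REF or ALT/ALT with equal probability
      hom_alt <- !het & stats::runif(m) < 0.5
      h[, hom_alt] <- 1L
      haplotypes[[i]] <- h
    }
    structure(list(map = map, haplotypes = haplotypes),
              class = "maternal_genome")
  })
}

# --- chromatid segment algebra -------------------------------------------
# A chromatid is a data.frame(start, end, hap) of contiguous, sorted,
# half-open segments covering [0, length_bp), hap in {1, 2} naming the
# maternal haplotype of origin.

seg_new <- function(len, hap) {
  data.frame(start = 0, end = len, hap = hap)
}

seg_clip <- function(seg, lo, hi) {
  keep <- seg$end > lo & seg$start < hi
  s <- seg[keep, , drop = FALSE]
  s$start <- pmax(s$start, lo)
  s$end <- pmin(s$end, hi)
  s
}

seg_coalesce <- function(seg) {
  seg <- seg[order(seg$start), , drop = FALSE]
  if (nrow(seg) <= 1L) {
    rownames(seg) <- NULL
    return(seg)
  }
  run <- cumsum(c(TRUE, seg$hap[-1L] != seg$hap[-nrow(seg)]))
  out <- data.frame(
    start = tapply(seg$start, run, min),
    end = tapply(seg$end, run, max),
    hap = tapply(seg$hap, run, function(h) h[1])
  )
  rownames(out) <- NULL
  out
}

# Exchange the material of two chromatids inside [lo, hi).
seg_exchange <- function(a, b, lo, hi, len) {
  a_new <- rbind(seg_clip(a, 0, lo), seg_clip(b, lo, hi), seg_clip(a, hi, len))
  b_new <- rbind(seg_clip(b, 0, lo), seg_clip(a, lo, hi), seg_clip(b, hi, len))
  list(seg_coalesce(a_new), seg_coalesce(b_new))
}

# Haplotype of origin at 1-based marker positions (evaluated at the base
# midpoint so continuous crossover breakpoints never tie with a marker).
hap_at <- function(seg, positions) {
  idx <- findInterval(positions - 0.5, seg$start)
  seg$hap[idx]
}

# --- meiosis --------------------------------------------------------------

#' Simulate one meiosis of the maternal genome
#'
#' Per chromosome, the two haplotypes are replicated into two sister
#' chromatid pairs (chromatids 1,2 from haplotype 1; 3,4 from haplotype
#' 2). The crossover count is drawn (at least one when
#' `obligate_crossover`), each crossover picks a position uniformly along
#' the chromosome and one chromatid from each homolog uniformly, and the
#' material distal to the breakpoint (away from the centromere, on the
#' breakpoint's arm) is exchanged. One homolog's sister pair, chosen
#' uniformly, becomes the egg lineage (egg plus second polar body); the
#' other pair is the first polar body.
#'
#' @param genome A `maternal_genome` from [simulate_mother()].
#' @param cfg A [sim_config()].
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return A list of class `meiosis_outcome`: per chromosome, the four
#'   chromatid segment lists, a `crossovers` data.frame (`pos`,
#'   `chromatid_a`, `chromatid_b`), and `egg_pair` (1 = chromatids 1,2
#'   carry the egg lineage; 2 = chromatids 3,4).
#' @export
simulate_meiosis <- function(genome, cfg, seed = NULL) {
  stopifnot(inherits(genome, "maternal_genome"))
  with_seed(seed, {
    out <- lapply(seq_along(genome$map), function(i) {
      len <- genome$map[[i]]$length_bp
      centro <- genome$map[[i]]$centromere_pos
      chromatids <- list(seg_new(len, 1L), seg_new(len, 1L),
                         seg_new(len, 2L), seg_new(len, 2L))
      n_co <- stats::rpois(1L, cfg$mean_extra_crossovers) +
        as.integer(cfg$obligate_crossover)
      co <- data.frame(pos = numeric(0), chromatid_a = integer(0),
                       chromatid_b = integer(0))
      if (n_co > 0L) {
        for (k in seq_len(n_co)) {
          pos <- stats::runif(1L, 0, len)
          a <- draw_one(1:2)   # sister from homolog 1
          b <- draw_one(3:4)   # sister from homolog 2
          # distal side of the breakpoint relative to the centromere:
          # the part of the breakpoint's arm beyond the breakpoint
          if (pos >= centro) {
            lo <- pos; hi <- len
          } else {
            lo <- 0; hi <- pos
          }
          ex <- seg_exchange(chromatids[[a]], chromatids[[b]], lo, hi, len)
          chromatids[[a]] <- ex[[1]]
          chromatids[[b]] <- ex[[2]]
          co <- rbind(co, data.frame(pos = pos, chromatid_a = a,
                                     chromatid_b = b))
        }
      }
      list(chromatids = chromatids, crossovers = co,
           egg_pair = draw_one(1:2))
    })
    names(out) <- names(genome$map)
    structure(out, class = "meiosis_outcome")
  })
}

#' Form a diploid offspring from meiotic products
#'
#' Mechanisms: `"TF"` (terminal fusion) fuses the egg chromatid with its
#' sister (the second polar body); `"CF"` (central fusion) fuses the egg
#' with a uniformly drawn chromatid of the first polar body pair; `"GD"`
#' (gametic duplication) duplicates the egg chromatid; `"APOMIXIS"` copies
#' the maternal genotypes unchanged; `"SEXUAL"` pairs the egg with an
#' independent haplotype whose ALT frequency is `cfg$sexual_alt_freq`.
#'
#' @param outcome A `meiosis_outcome` (`NULL` allowed for `"APOMIXIS"`).
#' @param mechanism One of `"TF"`, `"CF"`, `"GD"`, `"APOMIXIS"`, `"SEXUAL"`.
#' @param genome The `maternal_genome` the outcome was drawn from.
#' @param cfg A [sim_config()].
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return A list with `gt` (integer genotype codes per marker, in map
#'   order), `tracts` (`data.frame` `chrom`,`start`,`end` of intervals
#'   where the offspring is heterozygous at maternal-het markers; `NULL`
#'   for `"SEXUAL"`, where retention has no tract geometry), and
#'   `crossovers` (per-chromosome breakpoints, `NULL` for apomixis).
#' @export
form_offspring <- function(outcome, mechanism, genome, cfg, seed = NULL) {
  mechanism <- match.arg(mechanism,
                         c("TF", "CF", "GD", "APOMIXIS", "SEXUAL"))
  stopifnot(inherits(genome, "maternal_genome"))
  with_seed(seed, {
    if (mechanism == "APOMIXIS") {
      gt <- unlist(lapply(genome$haplotypes, colSums), use.names = FALSE)
      tracts <- data.frame(
        chrom = names(genome$map),
        start = 0,
        end = vapply(genome$map, function(m) m$length_bp, numeric(1)),
        stringsAsFactors = FALSE
      )
      rownames(tracts) <- NULL
      return(list(gt = as.integer(gt), tracts = tracts, crossovers = NULL))
    }
    stopifnot(inherits(outcome, "meiosis_outcome"))
    gt <- integer(0)
    tract_rows <- list()
    co_rows <- list()
    for (ch in names(genome$map)) {
      m <- genome$map[[ch]]
      h <- genome$haplotypes[[ch]]
      oc <- outcome[[ch]]
      pair <- if (oc$egg_pair == 1L) 1:2 else 3:4
      polar <- if (oc$egg_pair == 1L) 3:4 else 1:2
      egg_idx <- draw_one(pair)
      egg <- oc$chromatids[[egg_idx]]
      mate <- switch(mechanism,
        TF = oc$chromatids[[setdiff(pair, egg_idx)]],
        CF = oc$chromatids[[draw_one(polar)]],
        GD = egg,
        SEXUAL = NULL)
      n_mark <- length(m$positions)
      a1 <- h[cbind(hap_at(egg, m$positions), seq_len(n_mark))]
      if (mechanism == "SEXUAL") {
        a2 <- stats::rbinom(n_mark, 1L, cfg$sexual_alt_freq)
        gt <- c(gt, a1 + a2)
      } else {
        a2 <- h[cbind(hap_at(mate, m$positions), seq_len(n_mark))]
        gt <- c(gt, a1 + a2)
        tract_rows[[ch]] <- hetero_tracts(egg, mate, ch)
      }
      if (nrow(oc$crossovers)) {
        co_rows[[ch]] <- cbind(chrom = ch, oc$crossovers)
      }
    }
    tracts <- if (mechanism == "SEXUAL") {
      NULL
    } else if (length(tract_rows)) {
      out <- do.call(rbind, tract_rows)
      rownames(out) <- NULL
      out
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric())
    }
    crossovers <- if (length(co_rows)) {
      out <- do.call(rbind, co_rows)
      rownames(out) <- NULL
      out
    } else {
      data.frame(chrom = character(), pos = numeric(),
                 chromatid_a = integer(), chromatid_b = integer())
    }
    list(gt = as.integer(gt), tracts = tracts, crossovers = crossovers)
  })
}

# Intervals where two chromatids carry different haplotypes: exactly the
# regions where maternal-het markers stay heterozygous in the fusion
# product.
hetero_tracts <- function(a, b, chrom) {
  breaks <- sort(unique(c(a$start, a$end, b$start, b$end)))
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1L]
  mid <- (lo + hi) / 2
  differ <- hap_at(a, mid + 0.5) != hap_at(b, mid + 0.5)
  if (!any(differ)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  seg <- seg_coalesce(data.frame(start = lo[differ], end = hi[differ],
                                 hap = 1L))
  # drop zero-width pieces and merge touching ones
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  merged <- IRanges::reduce(IRanges::IRanges(
    start = as.integer(floor(seg$start * 1000)),
    end = as.integer(ceiling(seg$end * 1000))
  ))
  data.frame(chrom = chrom,
             start = IRanges::start(merged) / 1000,
             end = IRanges::end(merged) / 1000,
             stringsAsFactors = FALSE)
}

#' Simulate a full mother/offspring trio dataset
#'
#' Runs one independent meiosis per requested offspring, forms the
#' offspring under the requested mechanisms, and assembles a
#' [trio_dataset()] with negative-binomial per-call depths and optional
#' missingness, plus a reference FASTA consistent with the REF alleles and
#' per-offspring truth tables (mechanism, retained-heterozygosity tracts,
#' crossover positions). Fully reproducible under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param mechanisms Character vector of mechanisms, one offspring each
#'   (see [form_offspring()]); `c("TF", "TF")` emulates a two-sibling
#'   parthenogenesis study design.
#' @param make_reference If `TRUE`, generate the reference sequence (needed
#'   for GC analyses and FASTA output); skip for speed in large replicate
#'   sweeps.
#' @param out_dir Optional directory; when given, writes `trio.vcf`,
#'   `reference.fa` (if made), `truth_tracts.tsv`, `crossovers.tsv` and a
#'   `config.yaml` echo.
#' @return A list of class `sim_trio`: `trio` (the [trio_dataset()]),
#'   `truth` (per offspring: mechanism, tracts, crossovers), `genome`,
#'   `ref` (a `DNAStringSet` or `NULL`), and `config`.
#' @export
simulate_trio <- function(cfg, mechanisms = c("TF", "TF"),
                          make_reference = TRUE, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(mechanisms) >= 1L)
  mechanisms <- vapply(mechanisms, function(m) {
    match.arg(m, c("TF", "CF", "GD", "APOMIXIS", "SEXUAL"))
  }, character(1))
  with_seed(cfg$seed, {
    genome <- simulate_mother(cfg, seed = NULL)
    ref <- if (make_reference) simulate_reference(genome, cfg) else NULL

    chrom_names <- names(genome$map)
    chrom_col <- rep(chrom_names,
                     vapply(genome$map, function(m) length(m$positions),
                            integer(1)))
    pos_col <- unlist(lapply(genome$map, function(m) m$positions),
                      use.names = FALSE)
    n <- length(pos_col)

    if (is.null(ref)) {
      ref_base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    } else {
      ref_base <- unlist(lapply(chrom_names, function(ch) {
        p <- genome$map[[ch]]$positions
        if (!length(p)) return(character(0))
        substring(as.character(ref[[ch]]), p, p)
      }), use.names = FALSE)
    }
    alt_base <- vapply(ref_base, function(b) {
      draw_one(setdiff(c("A", "C", "G", "T"), b))
    }, character(1), USE.NAMES = FALSE)

    mother_gt <- as.integer(unlist(lapply(genome$haplotypes, colSums),
                                   use.names = FALSE))
    gt <- matrix(NA_integer_, nrow = n, ncol = 1L + length(mechanisms))
    gt[, 1L] <- mother_gt
    truth <- vector("list", length(mechanisms))
    for (j in seq_along(mechanisms)) {
      mech <- mechanisms[j]
      outcome <- if (mech == "APOMIXIS") NULL else
        simulate_meiosis(genome, cfg, seed = NULL)
      off <- form_offspring(outcome, mech, genome, cfg, seed = NULL)
      gt[, 1L + j] <- off$gt
      truth[[j]] <- list(mechanism = mech, tracts = off$tracts,
                         crossovers = off$crossovers)
    }
    samples <- c("mother", sprintf("offspring_%d", seq_along(mechanisms)))
    names(truth) <- samples[-1L]

    dp <- matrix(stats::rnbinom(n * length(samples),
                                size = cfg$depth_dispersion,
                                mu = cfg$depth_mean),
                 nrow = n, ncol = length(samples))
    if (cfg$missingness > 0) {
      gt[stats::runif(n * length(samples)) < cfg$missingness] <- NA_integer_
    }
    sites <- data.frame(chrom = chrom_col, pos = pos_col,
                        ref = ref_base, alt = alt_base,
                        qual = round(stats::runif(n, 100, 2000), 1),
                        stringsAsFactors = FALSE)
    trio <- trio_dataset(samples, sites, gt, dp)
    res <- structure(
      list(trio = trio, truth = truth, genome = genome, ref = ref,
           config = cfg),
      class = "sim_trio"
    )
    if (!is.null(out_dir)) write_sim_trio(res, out_dir)
    res
  })
}

#' @export
print.sim_trio <- function(x, ...) {
  mechs <- vapply(x$truth, function(t) unname(t$mechanism), character(1))
  cat("sim_trio:", n_sites(x$trio), "markers,",
      length(x$trio$samples) - 1L, "offspring (",
      paste(mechs, collapse = ", "), ")\n")
  cat("  seed:", x$config$seed %||% NA, "| reference:",
      if (is.null(x$ref)) "not generated" else
        paste0(sum(Biostrings::width(x$ref)), " bp"), "\n")
  invisible(x)
}

# Reference sequence with a configurable GC background; when gc_distal is
# set, bases on the distal side of the boundary (away from the
# centromere) use the distal GC level.
simulate_reference <- function(genome, cfg) {
  seqs <- vapply(seq_along(genome$map), function(i) {
    len <- genome$map[[i]]$length_bp
    centro <- genome$map[[i]]$centromere_pos
    base_p <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                             G = gc / 2, T = (1 - gc) / 2)
    if (is.null(cfg$gc_distal)) {
      chars <- sample(names(base_p(0)), len, replace = TRUE,
                      prob = base_p(cfg$gc_content))
    } else {
      # arm-aware distality: distance from the centromere, scaled by the
      # arm length, beyond gc_boundary_frac -> distal GC
      pos <- seq_len(len)
      arm_len <- ifelse(pos > centro, len - centro, centro)
      dist_frac <- abs(pos - centro) / pmax(arm_len, 1)
      distal <- dist_frac > cfg$gc_boundary_frac
      chars <- character(len)
      chars[!distal] <- sample(names(base_p(0)), sum(!distal), replace = TRUE,
                               prob = base_p(cfg$gc_content))
      chars[distal] <- sample(names(base_p(0)), sum(distal), replace = TRUE,
                              prob = base_p(cfg$gc_distal))
    }
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- names(genome$map)
  Biostrings::DNAStringSet(seqs)
}

write_sim_trio <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(sim$trio, file.path(out_dir, "trio.vcf"))
  if (!is.null(sim$ref)) write_fasta(sim$ref, file.path(out_dir, "reference.fa"))
  tracts <- do.call(rbind, lapply(names(sim$truth), function(s) {
    t <- sim$truth[[s]]
    if (is.null(t$tracts) || !nrow(t$tracts)) return(NULL)
    data.frame(offspring = s, mechanism = t$mechanism, t$tracts,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(tracts)) {
    tracts <- data.frame(offspring = character(), mechanism = character(),
                         chrom = character(), start = numeric(),
                         end = numeric())
  }
  utils::write.table(tracts, file.path(out_dir, "truth_tracts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cos <- do.call(rbind, lapply(names(sim$truth), function(s) {
    t <- sim$truth[[s]]
    if (is.null(t$crossovers) || !nrow(t$crossovers)) return(NULL)
    data.frame(offspring = s, t$crossovers, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cos)) {
    cos <- data.frame(offspring = character(), chrom = character(),
                      pos = numeric(), chromatid_a = integer(),
                      chromatid_b = integer())
  }
  utils::write.table(cos, file.path(out_dir, "crossovers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg_list <- unclass(cfg)
  cfg_list <- lapply(cfg_list, function(x) if (is.null(x)) NA else x)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
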