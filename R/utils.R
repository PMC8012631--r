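# Internal helpers shared across modules.

# Genotype codes used throughout: 0 = hom ref (0/0), 1 = het (0/1),
# 2 = hom alt (1/1), NA = missing (./.). Codes count ALT alleles, so
# arithmetic on codes is arithmetic on allele dosage.
GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers never perturb user randomness. A `NULL`
#' seed leaves the RNG alone.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Uniform draw of one element from a vector; immune to the sample()
# scalar-expansion trap when length(x) == 1.
draw_one <- function(x) x[[sample.int(length(x), 1L)]]

# Locus identifier used by the set-based operations: "chrom:pos".
locus_id <- function(chrom, pos) paste0(chrom, ":", pos)

parse_locus_id <- function(ids) {
  m <- regmatches(ids, regexpr(":[0-9]+$", ids))
  if (any(lengths(regmatches(ids, gregexpr(":[0-9]+$", ids))) != 1L)) {
    stop("malformed locus id (expected 'chrom:pos'): ",
         paste(utils::head(ids[!grepl(":[0-9]+$", ids)], 3L), collapse = ", "))
  }
  data.frame(
    chrom = sub(":[0-9]+$", "", ids),
    pos = as.integer(sub("^:", "", m)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
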