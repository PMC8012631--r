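# VCF / FASTA / BED input-output. Reading leans on vcfR and Biostrings;
# writing emits plain text so that identical inputs give byte-identical
# files (important for reproducibility checks on simulator output).

#' Read a multi-sample VCF into a trio dataset
#'
#' Parses GT and DP per-sample fields from a VCF 4.x file. Records are kept
#' in file order; multi-allelic records are retained but flagged so the
#' filter cascade can drop them. Numeric INFO annotations (e.g. the GATK
#' hard-filter keys QD, FS, MQ, MQRankSum, ReadPosRankSum) are parsed into
#' the `info` slot when present.
#'
#' @param path Path to a VCF file (plain or bgzip/gzip).
#' @param sample_order Optional character vector giving the desired sample
#'   order (mother first). Every name must exist in the VCF header.
#' @return A [trio_dataset()].
#' @export
read_vcf <- function(path, sample_order = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # keeps the INFO column, unlike getFIX()
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1)))) {
    stop("VCF lacks a GT field in FORMAT for one or more records")
  }
  samples <- colnames(v@gt)[-1L]
  if (!is.null(sample_order)) {
    missing <- setdiff(sample_order, samples)
    if (length(missing)) {
      stop("sample(s) not present in VCF header: ",
           paste(missing, collapse = ", "))
    }
    samples <- sample_order
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  )
  if (is.null(dp_raw)) dp_raw <- matrix(NA_real_, nrow(gt_raw), ncol(gt_raw))
  gt <- apply(gt_raw[, samples, drop = FALSE], 2L, code_gt_strings)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(gt_raw))
  dp <- dp_raw[, samples, drop = FALSE]
  dp[is.na(dp)] <- 0
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE
  )
  info <- parse_info_numeric(fix[, "INFO"])
  trio_dataset(samples, sites, gt, dp, info = info)
}

# "0/0" -> 0, "0/1"/"0|1" -> 1, "1/1" -> 2, "./." or "." -> NA. Alleles
# above 1 (multi-allelic genotypes) are coded by zygosity relative to
# "carries an ALT allele"; such records are flagged and dropped later.
code_gt_strings <- function(g) {
  u <- unique(g)
  codes <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".") || !length(a)) return(NA_integer_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a)) return(NA_integer_)
    if (length(a) == 1L) a <- c(a, a)  # haploid call treated as homozygous
    if (a[1] == a[2]) {
      if (a[1] == 0L) GT_HOM_REF else GT_HOM_ALT
    } else {
      GT_HET
    }
  }, integer(1))
  unname(codes[match(g, u)])
}

# Parse numeric KEY=value INFO pairs into a data.frame (one row per
# record); non-numeric values become NA for that key.
parse_info_numeric <- function(info_strings) {
  pairs <- strsplit(info_strings, ";", fixed = TRUE)
  keys <- unique(unlist(lapply(pairs, function(p) {
    sub("=.*$", "", p[grepl("=", p, fixed = TRUE)])
  })))
  if (!length(keys)) return(NULL)
  out <- lapply(keys, function(k) {
    vapply(pairs, function(p) {
      hit <- grep(paste0("^", k, "="), p, value = TRUE)
      if (!length(hit)) return(NA_real_)
      suppressWarnings(as.numeric(sub("^[^=]*=", "", hit[1])))
    }, numeric(1))
  })
  names(out) <- keys
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  if (all(vapply(df, function(x) all(is.na(x)), logical(1)))) NULL else df
}

#' Write a trio dataset to VCF
#'
#' Emits a minimal, valid VCF 4.2 with GT and DP per-sample fields and any
#' numeric INFO annotations carried by the dataset. Output is plain text,
#' so two writes of the same object are byte-identical.
#'
#' @param data A [trio_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(data, path) {
  stopifnot(inherits(data, "trio_dataset"))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=automixr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  if (!is.null(data$info)) {
    meta <- c(meta, sprintf(
      '##INFO=<ID=%s,Number=1,Type=Float,Description="Numeric annotation">',
      names(data$info)
    ))
  }
  for (ch in unique(data$sites$chrom)) {
    meta <- c(meta, sprintf("##contig=<ID=%s>", ch))
  }
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", data$samples), collapse = "\t")
  gt_str <- matrix(gt_code_to_string(data$gt), nrow = nrow(data$gt))
  dp_chr <- matrix(as.character(data$dp), nrow = nrow(data$dp))
  dp_chr[is.na(dp_chr)] <- "0"
  calls <- matrix(paste(gt_str, dp_chr, sep = ":"), nrow = nrow(gt_str))
  info_col <- if (is.null(data$info)) {
    rep(".", nrow(data$sites))
  } else {
    apply(data$info, 1L, function(r) {
      ok <- !is.na(r)
      if (!any(ok)) return(".")
      paste(paste0(names(r)[ok], "=", format_num(r[ok])), collapse = ";")
    })
  }
  qual <- ifelse(is.na(data$sites$qual), ".", format_num(data$sites$qual))
  body <- paste(
    data$sites$chrom, data$sites$pos, ".", data$sites$ref, data$sites$alt,
    qual, "PASS", info_col, "GT:DP",
    sep = "\t"
  )
  for (j in seq_len(ncol(calls))) body <- paste(body, calls[, j], sep = "\t")
  writeLines(c(meta, header, body), path)
  invisible(path)
}

gt_code_to_string <- function(code) {
  out <- rep("./.", length(code))
  out[which(code == GT_HOM_REF)] <- "0/0"
  out[which(code == GT_HET)] <- "0/1"
  out[which(code == GT_HOM_ALT)] <- "1/1"
  out
}

format_num <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE, digits = 10),
         character(1))
}

#' Read a FASTA file
#'
#' Reads sequences with Biostrings and upper-cases them (soft-masked
#' lowercase bases carry no meaning for GC counting here; the
#' normalization is noted in an attribute). Names are truncated at the
#' first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  had_lower <- any(grepl("[a-z]", as.character(x)))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- sub("\\s.*$", "", names(x))
  attr(x, "uppercased") <- had_lower
  x
}

#' Write a FASTA file
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write RAD loci as BED3
#'
#' @param loci `data.frame` with columns `chrom`, `start`, `end` in 0-based
#'   half-open coordinates (as produced by [derive_rad_loci()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(loci)))
  utils::write.table(loci[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 file
#' @param path Path to a BED file.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e))
  )
  if (ncol(df) < 3L) stop("malformed BED file '", path, "': fewer than 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  if (anyNA(df$start) || anyNA(df$end)) {
    bad <- which(is.na(df$start) | is.na(df$end))[1]
    stop("malformed BED file '", path, "' at line ", bad)
  }
  df[, c("chrom", "start", "end")]
}
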