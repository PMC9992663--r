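## Minimal PLINK 1 binary (bed/bim/fam) reader and writer.
##
## The bed format stores genotypes SNP-major, 2 bits per sample:
##   00 = homozygous A1 (dosage 2 of the A1 allele), 10 = heterozygous,
##   11 = homozygous A2 (dosage 0), 01 = missing.
## We count the bim A1 allele ("alt"); A2 is "ref". No pre-installed R
## package reads this format, hence the hand-rolled codec.

new_genotype_panel <- function(dosage, variant_meta, sample_ids) {
  stopifnot(ncol(dosage) == nrow(variant_meta), nrow(dosage) == length(sample_ids))
  structure(list(dosage = dosage, variant_meta = variant_meta, sample_ids = sample_ids),
            class = "genotype_panel")
}

#' Construct a genotype panel from a dosage matrix
#'
#' @param dosage n_samples x m_snps matrix of counted-allele dosages in
#'   \{0, 1, 2\} (NA allowed).
#' @param variant_meta data.frame with columns chrom, pos, ref, alt (one row
#'   per SNP column).
#' @param sample_ids character vector of sample identifiers.
#' @return a `genotype_panel` object.
#' @export
genotype_panel <- function(dosage, variant_meta, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosage)))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variant_meta)))
  if (ncol(dosage) < 1) stop("panel must contain at least one SNP")
  new_genotype_panel(dosage, variant_meta, sample_ids)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype panel: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Read a PLINK bed/bim/fam triplet
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   exist.
#' @param region optional `(chrom, start, end)` query (1-based inclusive);
#'   only SNPs inside are loaded into the dosage matrix.
#' @return a `genotype_panel` with dosages counting the bim A1 allele.
#' @export
read_plink <- function(prefix, region = NULL) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop(sprintf("missing PLINK file '%s'", f))
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_df); m <- nrow(bim_df)
  sample_ids <- as.character(fam_df[[2]])

  con <- file(bed, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop(sprintf("'%s' is not a SNP-major PLINK bed file", bed))
  }
  keep <- seq_len(m)
  if (!is.null(region)) {
    keep <- which(as.character(bim_df$chrom) == as.character(region[[1]]) &
                    bim_df$pos >= as.numeric(region[[2]]) &
                    bim_df$pos <= as.numeric(region[[3]]))
    if (length(keep) == 0) stop("no SNPs in requested region")
  }
  bytes_per_snp <- ceiling(n / 4)
  raw_all <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw_all) < bytes_per_snp * m) stop(sprintf("truncated bed file '%s'", bed))

  # decode lookup: 2-bit code -> dosage of A1
  code_map <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  dosage <- matrix(NA_real_, n, length(keep))
  ints <- as.integer(raw_all)
  shifts <- c(1L, 4L, 16L, 64L)
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    b <- ints[((j - 1L) * bytes_per_snp + 1L):(j * bytes_per_snp)]
    codes <- as.vector(vapply(shifts, function(s) (b %/% s) %% 4L, integer(length(b))))
    # vapply above gives bytes x 4; interleave sample-within-byte order
    codes <- as.vector(t(matrix(codes, nrow = bytes_per_snp)))
    dosage[, jj] <- code_map[as.character(codes[seq_len(n)])]
  }
  meta <- data.frame(chrom = as.character(bim_df$chrom[keep]), pos = bim_df$pos[keep],
                     ref = as.character(bim_df$a2[keep]), alt = as.character(bim_df$a1[keep]),
                     id = as.character(bim_df$id[keep]), stringsAsFactors = FALSE)
  new_genotype_panel(dosage, meta, sample_ids)
}

#' Write a genotype panel as a PLINK bed/bim/fam triplet
#'
#' @param panel a `genotype_panel`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$dosage; meta <- panel$variant_meta
  n <- nrow(X); m <- ncol(X)
  ids <- panel$sample_ids
  fam <- data.frame(fid = ids, iid = ids, pat = 0, mat = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  snp_id <- if ("id" %in% names(meta)) meta$id else variant_key(meta$chrom, meta$pos, meta$ref, meta$alt)
  bim <- data.frame(chrom = meta$chrom, id = snp_id, cm = 0, pos = meta$pos,
                    a1 = meta$alt, a2 = meta$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  # dosage of A1 -> 2-bit code
  dose_code <- function(d) {
    code <- integer(length(d))
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 2] <- 0L
    code[!is.na(d) & d == 1] <- 2L
    code[!is.na(d) & d == 0] <- 3L
    code
  }
  for (j in seq_len(m)) {
    codes <- c(dose_code(X[, j]), rep(0L, bytes_per_snp * 4L - n))
    cm <- matrix(codes, nrow = 4)
    bytes <- cm[1, ] + cm[2, ] * 4L + cm[3, ] * 16L + cm[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
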