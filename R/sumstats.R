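## Summary-statistic I/O: eQTL and GWAS summary tables, per-gene weight files.
##
## File dialect: tab-delimited with a header. eQTL files carry
## CHROM POS REF ALT GENE and either Z or (BETA, SE), plus P and N.
## GWAS files carry CHROM POS REF ALT Z N. Weight files carry
## CHROM POS REF ALT GENE METHOD WEIGHT.

STRAND_AMBIGUOUS <- c("A:T", "T:A", "C:G", "G:C")

new_eqtl_sumstats <- function(gene_id, records, n_median) {
  structure(list(gene_id = gene_id, records = records, n_median = n_median),
            class = "eqtl_sumstats")
}

#' @export
print.eqtl_sumstats <- function(x, ...) {
  cat(sprintf("cis-eQTL summary statistics for gene %s: %d SNPs, median n = %s\n",
              x$gene_id, nrow(x$records),
              if (is.na(x$n_median)) "NA" else format(x$n_median)))
  invisible(x)
}

check_required_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
}

#' Read per-gene cis-eQTL summary statistics
#'
#' Reads a tab-delimited eQTL summary file, restricts to one gene and its
#' cis-window, and returns an `eqtl_sumstats` object. A `Z` column is used
#' directly; otherwise `Z = BETA / SE`. Rows with neither are dropped (count
#' reported via message). The per-gene median sample size `n_median` is
#' computed once and reused by all downstream training methods.
#'
#' @param path tab-delimited file with header columns CHROM, POS, REF, ALT,
#'   GENE, P, N and either Z or both BETA and SE.
#' @param gene_id gene identifier to extract.
#' @param cis_window length-3 list/vector `(chrom, start, end)`, 1-based
#'   inclusive; typically TSS +/- 1 Mb.
#' @return an `eqtl_sumstats` object with fields `gene_id`, `records`
#'   (data.frame with chrom, pos, ref, alt, z, beta_marginal, p, n) and
#'   `n_median`. Zero in-window SNPs yields an object with 0 records (an
#'   empty-gene signal, not an error).
#' @export
read_eqtl_sumstats <- function(path, gene_id, cis_window) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_required_columns(df, c("CHROM", "POS", "REF", "ALT", "GENE", "P", "N"), path)
  if (!("Z" %in% names(df)) && !all(c("BETA", "SE") %in% names(df))) {
    stop(sprintf("file '%s' must provide a Z column or both BETA and SE", path))
  }
  df <- df[df$GENE == gene_id, , drop = FALSE]
  chrom <- as.character(cis_window[[1]])
  start <- as.numeric(cis_window[[2]])
  end <- as.numeric(cis_window[[3]])
  df <- df[as.character(df$CHROM) == chrom & df$POS >= start & df$POS <= end, , drop = FALSE]

  if ("Z" %in% names(df)) {
    z <- as.numeric(df$Z)
    if (all(c("BETA", "SE") %in% names(df))) {
      fill <- is.na(z) & !is.na(df$BETA) & !is.na(df$SE) & df$SE > 0
      z[fill] <- as.numeric(df$BETA[fill]) / as.numeric(df$SE[fill])
    }
  } else {
    z <- ifelse(!is.na(df$BETA) & !is.na(df$SE) & df$SE > 0,
                as.numeric(df$BETA) / as.numeric(df$SE), NA_real_)
  }
  drop_n <- sum(is.na(z))
  if (drop_n > 0) {
    message(sprintf("read_eqtl_sumstats: dropped %d row(s) with no usable Z or (BETA, SE)",
                    drop_n))
  }
  keep <- !is.na(z)
  df <- df[keep, , drop = FALSE]
  z <- z[keep]

  records <- data.frame(
    chrom = as.character(df$CHROM), pos = as.integer(df$POS),
    ref = as.character(df$REF), alt = as.character(df$ALT),
    z = z, p = as.numeric(df$P), n = as.integer(df$N),
    stringsAsFactors = FALSE
  )
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate variant key(s) in '%s' for gene %s: %s",
                 path, gene_id, paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  n_median <- if (nrow(records) > 0) as.integer(round(stats::median(records$n))) else NA_integer_
  if (nrow(records) > 0) {
    records$beta_marginal <- marginal_std_beta(records$z, n_median)
  } else {
    records$beta_marginal <- numeric(0)
  }
  new_eqtl_sumstats(gene_id, records, n_median)
}

#' Read GWAS summary statistics
#'
#' @param path tab-delimited file with header columns CHROM, POS, REF, ALT, Z, N.
#' @return data.frame with columns chrom, pos, ref, alt, z, n.
#' @export
read_gwas_sumstats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_required_columns(df, c("CHROM", "POS", "REF", "ALT", "Z", "N"), path)
  out <- data.frame(
    chrom = as.character(df$CHROM), pos = as.integer(df$POS),
    ref = as.character(df$REF), alt = as.character(df$ALT),
    z = as.numeric(df$Z), n = as.integer(df$N),
    stringsAsFactors = FALSE
  )
  key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  if (anyDuplicated(key)) stop(sprintf("duplicate variant key(s) in '%s'", path))
  if (any(!is.finite(out$z))) stop(sprintf("non-finite Z value(s) in '%s'", path))
  out
}

#' Marginal standardized effect size from a Z statistic
#'
#' Converts a single-SNP association Z-score into the marginal effect size on
#' the standardized-genotype, standardized-expression scale via
#' `z / sqrt(n_median)`, where `n_median` is the gene's median cis-eQTL sample
#' size. This is the working scale for all summary-statistic trainers.
#'
#' @param z numeric vector of Z statistics.
#' @param n_median per-gene median sample size (>= 2).
#' @return numeric vector `z / sqrt(n_median)`.
#' @export
marginal_std_beta <- function(z, n_median) {
  if (!is.numeric(n_median) || length(n_median) != 1L || is.na(n_median) || n_median < 2) {
    stop("n_median must be a single number >= 2")
  }
  z / sqrt(n_median)
}

#' Harmonize summary statistics to a reference-panel variant table
#'
#' Matches variants by (chrom, pos). Variants whose alleles match the panel's
#' ref/alt are kept; variants matching with swapped alleles have their `z`
#' (and `beta_marginal`, when present) sign-flipped; strand-ambiguous (A/T,
#' C/G) variants, variants at panel positions with multiple panel alleles
#' (multi-allelic), and unmatched variants are dropped. Applying the function
#' twice equals applying it once.
#'
#' @param sumstats an `eqtl_sumstats` object or a GWAS data.frame as returned
#'   by [read_gwas_sumstats()].
#' @param panel_variants data.frame with columns chrom, pos, ref, alt.
#' @return list with `sumstats` (same type as input, harmonized, with a
#'   `panel_index` column mapping each record to its panel row) and `report`,
#'   a named integer vector counting kept / flipped / ambiguous / multiallelic
#'   / unmatched variants.
#' @export
harmonize <- function(sumstats, panel_variants) {
  is_eqtl <- inherits(sumstats, "eqtl_sumstats")
  rec <- if (is_eqtl) sumstats$records else sumstats
  stopifnot(all(c("chrom", "pos", "ref", "alt", "z") %in% names(rec)))

  pv <- panel_variants
  ppos <- paste(pv$chrom, pv$pos, sep = ":")
  multi <- ppos %in% ppos[duplicated(ppos)]

  spos <- paste(rec$chrom, rec$pos, sep = ":")
  amb <- variant_key("", "", rec$ref, rec$alt)
  ambiguous <- sub("^::", "", amb) %in% STRAND_AMBIGUOUS

  idx <- match(spos, ppos)
  in_multi <- !is.na(idx) & multi[idx]

  status <- rep("unmatched", nrow(rec))
  matched <- !is.na(idx) & !in_multi
  same <- matched & rec$ref == pv$ref[idx] & rec$alt == pv$alt[idx]
  swapped <- matched & rec$ref == pv$alt[idx] & rec$alt == pv$ref[idx] & !same
  status[same] <- "kept"
  status[swapped] <- "flipped"
  status[matched & !same & !swapped] <- "unmatched"
  status[in_multi] <- "multiallelic"
  status[ambiguous] <- "ambiguous"

  keep <- status %in% c("kept", "flipped")
  out <- rec[keep, , drop = FALSE]
  flip <- status[keep] == "flipped"
  out$z[flip] <- -out$z[flip]
  if ("beta_marginal" %in% names(out)) out$beta_marginal[flip] <- -out$beta_marginal[flip]
  ref <- out$ref[flip]
  out$ref[flip] <- out$alt[flip]
  out$alt[flip] <- ref
  out$panel_index <- idx[keep]
  rownames(out) <- NULL

  report <- c(kept = sum(status == "kept"), flipped = sum(status == "flipped"),
              ambiguous = sum(status == "ambiguous"),
              multiallelic = sum(status == "multiallelic"),
              unmatched = sum(status == "unmatched"))
  if (is_eqtl) {
    sumstats$records <- out
    list(sumstats = sumstats, report = report)
  } else {
    list(sumstats = out, report = report)
  }
}

weight_columns <- c("CHROM", "POS", "REF", "ALT", "GENE", "METHOD", "WEIGHT")

new_eqtl_weights <- function(gene_id, method, entries) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "weight") %in% names(entries)))
  structure(list(gene_id = gene_id, method = method, entries = entries),
            class = "eqtl_weights")
}

#' @export
print.eqtl_weights <- function(x, ...) {
  cat(sprintf("eQTL weights for gene %s (%s): %d non-zero SNP(s)\n",
              x$gene_id, x$method, nrow(x$entries)))
  invisible(x)
}

#' Write and read per-gene eQTL weight files
#'
#' Weight files are tab-delimited with columns CHROM, POS, REF, ALT, GENE,
#' METHOD, WEIGHT. `read_weights(write_weights(w))` is an identity. Writing
#' refuses non-finite weights; an empty weight set writes a header-only file.
#'
#' @param weights an `eqtl_weights` object (fields gene_id, method, entries).
#' @param path output/input file path.
#' @param append append to an existing file without re-writing the header.
#' @return `write_weights` returns `path` invisibly; `read_weights` returns a
#'   list of `eqtl_weights` objects (one per gene x method in the file), or a
#'   single object if the file holds exactly one.
#' @export
write_weights <- function(weights, path, append = FALSE) {
  stopifnot(inherits(weights, "eqtl_weights"))
  e <- weights$entries
  if (nrow(e) > 0 && any(!is.finite(e$weight))) {
    stop("refusing to write non-finite weight(s)")
  }
  key <- variant_key(e$chrom, e$pos, e$ref, e$alt)
  if (anyDuplicated(key)) stop("duplicate variant key(s) in weights")
  df <- data.frame(CHROM = e$chrom, POS = e$pos, REF = e$ref, ALT = e$alt,
                   GENE = rep(weights$gene_id, nrow(e)),
                   METHOD = rep(weights$method, nrow(e)),
                   WEIGHT = e$weight, stringsAsFactors = FALSE)
  if (append && file.exists(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_required_columns(df, weight_columns, path)
  if (nrow(df) == 0) {
    return(list())
  }
  out <- list()
  for (g in unique(df$GENE)) {
    for (m in unique(df$METHOD[df$GENE == g])) {
      sub <- df[df$GENE == g & df$METHOD == m, , drop = FALSE]
      entries <- data.frame(chrom = as.character(sub$CHROM), pos = as.integer(sub$POS),
                            ref = as.character(sub$REF), alt = as.character(sub$ALT),
                            weight = as.numeric(sub$WEIGHT), stringsAsFactors = FALSE)
      if (any(!is.finite(entries$weight))) {
        stop(sprintf("malformed weight file '%s': non-finite weight", path))
      }
      out[[paste(g, m, sep = "/")]] <- new_eqtl_weights(g, m, entries)
    }
  }
  if (length(out) == 1L) out[[1L]] else out
}
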