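## File-level orchestration over many genes: the engine behind the
## command-line interface. Per-gene seeds are derived from the master seed
## and the gene id, so results do not depend on execution order.

#' Train Stage-I weights for many genes
#'
#' Reads per-gene cis-eQTL summary statistics and the reference panel,
#' fits the requested methods via [grex_fit()], and writes one weight file
#' per method (`<out_dir>/weights_<METHOD>.tsv`). Genes failing a method are
#' logged and skipped for that method only.
#'
#' @param eqtl_path eQTL summary file (see [read_eqtl_sumstats()]).
#' @param gene_table data.frame with columns gene_id, chrom, tss (cis-window
#'   centre).
#' @param panel_prefix PLINK bed/bim/fam prefix of the LD reference.
#' @param out_dir output directory (created if needed).
#' @param methods Stage-I methods to train.
#' @param cis_radius cis-window half-width in bp (default 1e6).
#' @param seed master seed; per-gene seeds are derived from it.
#' @param ... forwarded to [grex_fit()] (configs, thresholds).
#' @return data.frame with one row per (gene, method): gene_id, method,
#'   n_snps, n_nonzero, status.
#' @export
run_stage1 <- function(eqtl_path, gene_table, panel_prefix, out_dir,
                       methods = ALL_METHODS, cis_radius = 1e6, seed = 1L, ...) {
  if (!file.exists(paste0(panel_prefix, ".bed"))) {
    stop(sprintf("reference panel '%s' not found", panel_prefix))
  }
  if (!file.exists(eqtl_path)) stop(sprintf("eQTL file '%s' not found", eqtl_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- NULL
  first <- stats::setNames(rep(TRUE, length(methods)), methods)
  for (i in seq_len(nrow(gene_table))) {
    g <- gene_table$gene_id[i]
    window <- list(gene_table$chrom[i],
                   max(1, gene_table$tss[i] - cis_radius),
                   gene_table$tss[i] + cis_radius)
    ss <- read_eqtl_sumstats(eqtl_path, g, window)
    if (nrow(ss$records) == 0) {
      message(sprintf("gene %s: no cis-SNPs in window, skipped", g))
      log <- rbind(log, data.frame(gene_id = g, method = methods, n_snps = 0,
                                   n_nonzero = 0, status = "empty"))
      next
    }
    panel <- read_plink(panel_prefix, region = window)
    fit <- tryCatch(
      grex_fit(ss, panel, methods = methods, seed = derive_seed(seed, g), ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      message(sprintf("gene %s: Stage-I failed (%s), skipped", g, conditionMessage(fit)))
      log <- rbind(log, data.frame(gene_id = g, method = methods, n_snps = NA,
                                   n_nonzero = 0, status = "error"))
      next
    }
    for (m in methods) {
      w <- fit$weights[[m]]
      if (is.null(w)) {
        log <- rbind(log, data.frame(gene_id = g, method = m,
                                     n_snps = nrow(fit$variants), n_nonzero = 0,
                                     status = "failed"))
        next
      }
      path <- file.path(out_dir, sprintf("weights_%s.tsv", m))
      write_weights(w, path, append = !first[[m]])
      first[[m]] <- FALSE
      log <- rbind(log, data.frame(gene_id = g, method = m,
                                   n_snps = nrow(fit$variants),
                                   n_nonzero = nrow(w$entries), status = "ok"))
    }
  }
  log
}

#' Stage-II TWAS from weight files and GWAS summary statistics
#'
#' For each (gene, method) weight set, approximates the LD matrix V of the
#' weighted SNPs from the reference panel, computes the gene-based Z test
#' against the GWAS Z-scores, optionally applies per-method genomic control
#' across genes, and combines per-gene method p-values with the Cauchy
#' omnibus test.
#'
#' @param weights_dir directory holding `weights_<METHOD>.tsv` files (from
#'   [run_stage1()]), or a character vector of weight file paths.
#' @param gwas_path GWAS summary file (see [read_gwas_sumstats()]).
#' @param panel_prefix PLINK prefix of the LD reference panel.
#' @param form Z-statistic form, `"fusion"` or `"spredixcan"`.
#' @param gc_correct apply genomic control per method across genes.
#' @return a `twas_result` data.frame (see [twas_scan()]).
#' @export
run_stage2 <- function(weights_dir, gwas_path, panel_prefix,
                       form = c("fusion", "spredixcan"), gc_correct = FALSE) {
  form <- match.arg(form)
  files <- if (dir.exists(weights_dir[1])) {
    list.files(weights_dir, pattern = "^weights_.*\\.tsv$", full.names = TRUE)
  } else {
    weights_dir
  }
  if (length(files) == 0) stop("no weight files found")
  gwas <- read_gwas_sumstats(gwas_path)
  gkey <- variant_key(gwas$chrom, gwas$pos, gwas$ref, gwas$alt)
  gkey_swap <- variant_key(gwas$chrom, gwas$pos, gwas$alt, gwas$ref)

  all_w <- list()
  for (f in files) {
    ws <- read_weights(f)
    if (inherits(ws, "eqtl_weights")) ws <- list(ws)
    all_w <- c(all_w, ws)
  }
  genes <- sort(unique(vapply(all_w, function(w) w$gene_id, character(1))))
  methods <- sort(unique(vapply(all_w, function(w) w$method, character(1))))

  zmat <- matrix(NA_real_, length(genes), length(methods),
                 dimnames = list(genes, methods))
  nsnp <- matrix(0L, length(genes), length(methods),
                 dimnames = list(genes, methods))
  for (w in all_w) {
    e <- w$entries
    if (nrow(e) == 0) next
    region <- list(e$chrom[1], min(e$pos), max(e$pos))
    panel <- read_plink(panel_prefix, region = region)
    std <- standardize(panel)
    pkey <- variant_key(std$meta$chrom, std$meta$pos, std$meta$ref, std$meta$alt)
    wkey <- variant_key(e$chrom, e$pos, e$ref, e$alt)
    cols <- match(wkey, pkey)
    zi <- match(wkey, gkey)
    zs <- match(wkey, gkey_swap)
    z <- ifelse(!is.na(zi), gwas$z[zi], ifelse(!is.na(zs), -gwas$z[zs], NA))
    use <- which(!is.na(cols) & !is.na(z))
    if (length(use) == 0) next
    V <- compute_ld(std$X[, cols[use], drop = FALSE])$R
    sds <- std$sd[cols[use]]
    if (form == "spredixcan") V <- V * tcrossprod(sds)
    res <- twas_z(e$weight[use], z[use], V, form = form,
                  snp_sd = if (form == "spredixcan") sds else NULL)
    if (!is.null(res)) {
      zmat[w$gene_id, w$method] <- res$z
      nsnp[w$gene_id, w$method] <- res$n_snps
    }
  }
  pmat <- z_to_p(zmat)
  lambda <- stats::setNames(rep(1, length(methods)), methods)
  if (gc_correct) {
    for (m in methods) {
      gcres <- genomic_control(zmat[, m])
      zmat[, m] <- gcres$z
      pmat[, m] <- gcres$p
      lambda[m] <- gcres$lambda_gc
    }
  }
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (m in methods) {
    out[[paste0("z_", m)]] <- zmat[, m]
    out[[paste0("p_", m)]] <- pmat[, m]
    out[[paste0("nsnp_", m)]] <- nsnp[, m]
  }
  out$n_valid_methods <- rowSums(!is.na(pmat))
  out$p_acat <- apply(pmat, 1, function(p) {
    v <- acat_o(p)
    if (is.null(v)) NA_real_ else v
  })
  attr(out, "lambda_gc") <- lambda
  class(out) <- c("twas_result", "data.frame")
  out
}
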