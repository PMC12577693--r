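#' Module-score parameters
#'
#' @param nbin number of expression bins for control-gene matching
#'   (default 24)
#' @param ctrl_per_gene control genes sampled per signature gene
#'   (default 100)
#' @param seed integer seed for control sampling
#' @return a `bs_module_params` list
#' @export
module_params <- function(nbin = 24, ctrl_per_gene = 100, seed = 1L) {
  stopifnot(nbin >= 2, ctrl_per_gene >= 1)
  structure(list(nbin = nbin, ctrl_per_gene = ctrl_per_gene,
                 seed = as.integer(seed)),
            class = "bs_module_params")
}

#' Gene-module score with expression-binned control genes
#'
#' Genes are binned into `nbin` bins of equal size by mean log-normalized
#' expression across cells. For each signature gene, `ctrl_per_gene` control
#' genes are drawn from its bin (with replacement when the bin is small)
#' under `seed`. The per-cell score is the mean lognorm of the signature
#' genes minus the mean lognorm of the pooled control draws; scores near
#' zero mean the set is not expressed above its expression-matched
#' background.
#'
#' @param ds a `bs_dataset` with lognorm present
#' @param gene_set character vector of signature genes; absentees are
#'   dropped with a warning (error if all are absent)
#' @param params a `bs_module_params`
#' @return named numeric vector of per-cell scores
#' @export
module_score <- function(ds, gene_set, params = module_params()) {
  require_lognorm(ds)
  present <- gene_set[gene_set %in% ds$genes]
  if (!length(present))
    stop("no gene of the set is present in the dataset: ",
         paste(gene_set, collapse = ", "))
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present),
            " signature gene(s) absent from dataset; dropped")
  bins <- expression_bins(ds, params$nbin)
  ctrl <- with_seed(params$seed, {
    unlist(lapply(present, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      sample(pool, params$ctrl_per_gene, replace = TRUE)
    }), use.names = FALSE)
  })
  set_mean <- Matrix::colMeans(ds$lognorm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(ds$lognorm[ctrl, , drop = FALSE])
  setNames(set_mean - ctrl_mean, ds$cells)
}

# Equal-frequency bins of genes by mean lognorm; named by gene.
expression_bins <- function(ds, nbin) {
  mu <- Matrix::rowMeans(ds$lognorm)
  ord <- order(mu, ds$genes)
  bin <- integer(length(mu))
  bin[ord] <- ceiling(seq_along(mu) / (length(mu) / nbin))
  setNames(pmin(bin, nbin), ds$genes)
}

#' One-vs-rest marker genes per label
#'
#' For each label, a two-sided Wilcoxon rank-sum test per gene compares the
#' label's cells with all other cells on the lognorm layer (exact p-values
#' for small groups without ties, normal approximation with tie and
#' continuity correction otherwise), with Benjamini-Hochberg adjustment
#' across genes within the label. The fold change is computed on de-logged
#' means with pseudocount 1:
#' `log2fc = log2((mean(expm1(ln_in)) + 1) / (mean(expm1(ln_out)) + 1))`.
#' Markers pass with `log2fc > fc_threshold` and `fdr < fdr_threshold`
#' (both strict) and are sorted by descending log2fc.
#'
#' @param ds a `bs_dataset` with lognorm present
#' @param labels per-cell label vector aligned to `ds` cells
#' @param fc_threshold minimum log2 fold change (strict; default 1.5); use
#'   `-Inf` to keep the full ranking
#' @param fdr_threshold maximum FDR (strict; default 0.01); use `Inf` to
#'   keep all genes
#' @return named list: label -> `data.frame` with columns `gene`, `log2fc`,
#'   `p_value`, `fdr`, `pct_in`, `pct_out`
#' @export
find_markers <- function(ds, labels, fc_threshold = 1.5,
                         fdr_threshold = 0.01) {
  require_lognorm(ds)
  stopifnot(length(labels) == n_cells(ds))
  labels <- as.character(labels)
  tab <- table(labels)
  usable <- names(tab)[tab >= 3]
  if (length(usable) < 2)
    stop("need at least 2 labels with >= 3 cells each")
  if (length(usable) < length(tab))
    warning("label(s) with < 3 cells skipped: ",
            paste(setdiff(names(tab), usable), collapse = ", "))
  m <- as.matrix(ds$lognorm)
  expm <- expm1(m)
  res <- list()
  for (lab in usable) {
    grp <- labels == lab
    p <- wilcox_rows(m, grp)
    mean_in <- rowMeans(expm[, grp, drop = FALSE])
    mean_out <- rowMeans(expm[, !grp, drop = FALSE])
    log2fc <- log2((mean_in + 1) / (mean_out + 1))
    fdr <- p.adjust(p, method = "BH")
    df <- data.frame(gene = ds$genes, log2fc = log2fc, p_value = p,
                     fdr = fdr,
                     pct_in = rowMeans(m[, grp, drop = FALSE] > 0),
                     pct_out = rowMeans(m[, !grp, drop = FALSE] > 0),
                     row.names = NULL)
    df <- df[df$log2fc > fc_threshold & df$fdr < fdr_threshold, ,
             drop = FALSE]
    df <- df[order(-df$log2fc, df$gene), , drop = FALSE]
    rownames(df) <- NULL
    res[[lab]] <- df
  }
  res
}

# Row-wise two-sided Wilcoxon rank-sum p-values for group `grp` vs rest.
# Small balanced problems go through stats::wilcox.test (exact where
# possible); larger ones use a vectorized normal approximation with tie and
# continuity correction, matching wilcox.test(exact = FALSE).
wilcox_rows <- function(m, grp) {
  n1 <- sum(grp); n2 <- sum(!grp); n <- n1 + n2
  if (max(n1, n2) <= 10) {
    return(apply(m, 1, function(x) {
      suppressWarnings(wilcox.test(x[grp], x[!grp])$p.value)
    }))
  }
  rk <- t(apply(m, 1, rank))
  r1 <- rowSums(rk[, grp, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  tie_term <- apply(m, 1, function(x) {
    t <- rle(sort.int(x, method = "quick"))$lengths
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- u - n1 * n2 / 2
  correction <- sign(z) * 0.5
  p <- 2 * pnorm(-abs((z - correction) / sqrt(sigma2)))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @return adjusted values aligned to the input order
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Preranked gene-set enrichment
#'
#' Genes are ranked by descending score. The running sum increments by
#' `|score|` (normalized over the set's hits) at set genes and decrements by
#' `1 / (N - |S|)` at non-set genes; the enrichment score (ES) is the
#' signed maximum deviation. The null distribution comes from `n_perm`
#' seeded permutations of set membership; NES is the ES divided by the mean
#' `|ES|` of same-sign null values, and the p-value is
#' `(1 + #same-sign null with |null| >= |ES|) / (1 + #same-sign null)`.
#'
#' @param scores named numeric vector of per-gene scores (e.g. log2fc)
#' @param gene_set character vector; must be a proper non-empty subset of
#'   the scored genes after dropping absentees
#' @param n_perm number of permutations (default 1000)
#' @param seed integer seed
#' @return list of class `bs_gsea` with `es`, `nes`, `p_value`, `n_perm`,
#'   `seed`, `n_genes`, `set_size`
#' @export
preranked_gsea <- function(scores, gene_set, n_perm = 1000, seed = 1L) {
  stopifnot(!is.null(names(scores)))
  hits <- names(scores) %in% gene_set
  if (!any(hits)) stop("gene set is empty after dropping absent genes")
  if (all(hits)) stop("gene set covers all scored genes")
  ord <- order(-scores, names(scores))
  s_sorted <- scores[ord]
  hit_sorted <- hits[ord]
  es <- gsea_es(s_sorted, hit_sorted)
  n <- length(scores)
  k <- sum(hits)
  null_es <- with_seed(derive_seed(seed, "gsea"), {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(n)
      h[sample.int(n, k)] <- TRUE
      gsea_es(s_sorted, h)
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(es = es, nes = nes, p_value = p, n_perm = n_perm,
                 seed = as.integer(seed), n_genes = n, set_size = k),
            class = "bs_gsea")
}

# ES of a pre-sorted score vector: signed maximum of the running sum.
gsea_es <- function(s_sorted, hit_sorted) {
  w <- abs(s_sorted[hit_sorted])
  if (sum(w) == 0) w <- w + 1          # degenerate all-zero scores: flat hits
  inc <- numeric(length(s_sorted))
  inc[hit_sorted] <- w / sum(w)
  inc[!hit_sorted] <- -1 / sum(!hit_sorted)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' @export
print.bs_gsea <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g (|set| = %d of %d genes, %d perms)\n",
              x$es, x$nes, x$p_value, x$set_size, x$n_genes, x$n_perm))
  invisible(x)
}
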