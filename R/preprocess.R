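#' Preprocessing parameters
#'
#' @param scale_factor library-size scale factor for log-normalization
#'   (default 10,000)
#' @param n_hvg number of highly variable genes to keep (default 3000)
#' @param n_pcs number of principal components (default 50)
#' @param clip cap (in SD units) applied to z-scored expression before PCA
#'   (default 10)
#' @return a `bs_preprocess_params` list
#' @export
preprocess_params <- function(scale_factor = 1e4, n_hvg = 3000, n_pcs = 50,
                              clip = 10) {
  stopifnot(scale_factor > 0, n_hvg >= 1, n_pcs >= 1, clip > 0)
  structure(list(scale_factor = scale_factor, n_hvg = n_hvg,
                 n_pcs = n_pcs, clip = clip),
            class = "bs_preprocess_params")
}

#' Log-normalize counts
#'
#' Per cell, counts are scaled to `scale_factor` total and log1p-transformed:
#' `lognorm[g, c] = ln(1 + scale_factor * counts[g, c] / total[c])`. Cells
#' with zero total counts get an all-zero column with a warning. Counts are
#' left untouched.
#'
#' @param ds a `bs_dataset`
#' @param params a `bs_preprocess_params`
#' @return `ds` with the `lognorm` layer filled in
#' @export
log_normalize <- function(ds, params = preprocess_params()) {
  totals <- Matrix::colSums(ds$counts)
  if (any(totals == 0))
    warning(sum(totals == 0), " cell(s) with zero total counts; lognorm set to 0")
  scl <- ifelse(totals > 0, params$scale_factor / totals, 0)
  ln <- ds$counts %*% Matrix::Diagonal(x = scl)
  ln@x <- log1p(ln@x)
  ln <- methods::as(methods::as(ln, "CsparseMatrix"), "generalMatrix")
  dimnames(ln) <- dimnames(ds$counts)
  ds$lognorm <- ln
  ds
}

require_lognorm <- function(ds) {
  if (is.null(ds$lognorm))
    stop("dataset has no lognorm layer; call log_normalize() first")
  invisible(ds)
}

#' Rank genes by variability
#'
#' Default method `"vst"` ranks genes by standardized variance on the
#' log-normalized layer: a loess trend of log10 variance against log10 mean
#' is fit across expressed genes, each gene's values are standardized by the
#' trend-expected SD with clipping at sqrt(N), and the variance of the
#' clipped standardized values is ranked (rank 1 = most variable). Method
#' `"simple"` ranks plain variance of the lognorm values. Ties are broken
#' lexicographically by gene identifier, so the ranking is a deterministic
#' permutation of the genes.
#'
#' @param ds a `bs_dataset` with a lognorm layer
#' @param method `"vst"` or `"simple"`
#' @return named integer vector: per-gene rank, named by gene
#' @export
rank_variable_genes <- function(ds, method = c("vst", "simple")) {
  method <- match.arg(method)
  require_lognorm(ds)
  n <- n_cells(ds)
  if (n < 2) stop("variance undefined with fewer than 2 cells")
  m <- ds$lognorm
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  v <- pmax(v, 0)
  if (method == "simple") {
    score <- v
  } else {
    ok <- mu > 0 & v > 0
    score <- numeric(length(v))
    if (sum(ok) >= 5) {
      fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.3, degree = 2,
                   family = "symmetric")
      exp_sd <- sqrt(10^predict(fit))
      exp_sd[!is.finite(exp_sd) | exp_sd <= 0] <- sqrt(v[ok])[
        !is.finite(exp_sd) | exp_sd <= 0]
      clip_max <- sqrt(n)
      dense <- as.matrix(m[which(ok), , drop = FALSE])
      z <- (dense - mu[ok]) / exp_sd
      z[z > clip_max] <- clip_max
      z[z < -clip_max] <- -clip_max
      score[ok] <- apply(z, 1, var)
    } else {
      score <- v
    }
  }
  names(score) <- ds$genes
  ord <- order(-score, ds$genes)
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  setNames(rk, ds$genes)
}

#' Combine per-dataset variability rankings into a consensus HVG list
#'
#' Genes present in every ranking are ordered by the sum of their ranks
#' (ascending) and truncated to `n_hvg`; ties are broken lexicographically.
#'
#' @param rankings list of named rank vectors from [rank_variable_genes()]
#' @param n_hvg number of genes to keep
#' @return ordered character vector of consensus highly variable genes
#' @export
select_consensus_hvg <- function(rankings, n_hvg = 3000) {
  stopifnot(length(rankings) >= 1)
  common <- Reduce(intersect, lapply(rankings, names))
  if (!length(common)) stop("rankings share no genes")
  sums <- Reduce(`+`, lapply(rankings, function(r) r[common]))
  ord <- order(sums, common)
  common[ord][seq_len(min(n_hvg, length(common)))]
}

#' Fit scaling and PCA on a reference dataset
#'
#' HVG rows of the lognorm layer are z-scored (clipped at `params$clip`) and
#' decomposed by SVD. The sign of each loading column is fixed so that its
#' largest-magnitude entry is positive, making the basis reproducible.
#' Constant genes scale to zero and carry no loading weight.
#'
#' @param ds a `bs_dataset` with lognorm present
#' @param hvg character vector of highly variable genes (those absent from
#'   `ds` are dropped with a warning)
#' @param params a `bs_preprocess_params`
#' @return list with `model` (a `bs_preprocess_model`: `hvg`, `gene_mean`,
#'   `gene_sd`, `loadings`, `explained_variance`) and `embedding` (cells x
#'   n_pcs score matrix)
#' @export
fit_preprocess <- function(ds, hvg, params = preprocess_params()) {
  require_lognorm(ds)
  missing <- setdiff(hvg, ds$genes)
  if (length(missing)) {
    warning(length(missing), " HVG(s) absent from dataset; dropped")
    hvg <- setdiff(hvg, missing)
  }
  if (!length(hvg)) stop("no HVGs left after dropping absentees")
  n <- n_cells(ds)
  n_pcs <- params$n_pcs
  if (n <= n_pcs) {
    warning("fewer cells than requested PCs; reducing n_pcs to ", n - 1L)
    n_pcs <- n - 1L
  }
  x <- as.matrix(ds$lognorm[hvg, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  z <- scale_clip(x, mu, sdv, params$clip)
  sv <- svd(t(z), nu = n_pcs, nv = n_pcs)
  loadings <- sv$v
  flip <- apply(loadings, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- t(z) %*% loadings
  dimnames(loadings) <- list(hvg, paste0("PC", seq_len(n_pcs)))
  dimnames(scores) <- list(ds$cells, colnames(loadings))
  model <- structure(
    list(hvg = hvg, gene_mean = setNames(mu, hvg),
         gene_sd = setNames(sdv, hvg), loadings = loadings,
         explained_variance = sv$d[seq_len(n_pcs)]^2 / (n - 1),
         clip = params$clip, scale_factor = params$scale_factor),
    class = "bs_preprocess_model")
  list(model = model, embedding = scores)
}

# z-score rows with given stats, zeroing constant genes, clipping at +/- clip
scale_clip <- function(x, mu, sdv, clip) {
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

#' Project a query dataset into a fitted reference PC space
#'
#' Query lognorm values for the reference HVGs are scaled with the
#' *reference* per-gene mean and SD (clipped as in the fit); HVGs missing
#' from the query contribute 0 after scaling (i.e. are imputed at the
#' reference mean); the scaled matrix is multiplied by the reference
#' loadings.
#'
#' @param ds query `bs_dataset` with lognorm present
#' @param model a `bs_preprocess_model`
#' @return cells x n_pcs embedding matrix
#' @export
project_query <- function(ds, model) {
  require_lognorm(ds)
  present <- intersect(model$hvg, ds$genes)
  if (length(present) < 0.5 * length(model$hvg))
    stop(sprintf(
      paste0("only %d of %d reference HVGs found in query; ",
             "harmonize gene identifiers before projecting"),
      length(present), length(model$hvg)))
  z <- matrix(0, nrow = length(model$hvg), ncol = n_cells(ds),
              dimnames = list(model$hvg, ds$cells))
  x <- as.matrix(ds$lognorm[present, , drop = FALSE])
  z[present, ] <- scale_clip(x, model$gene_mean[present],
                             model$gene_sd[present], model$clip)
  scores <- t(z) %*% model$loadings
  dimnames(scores) <- list(ds$cells, colnames(model$loadings))
  scores
}

#' Serialize / load a preprocessing model as plain-text files
#'
#' Writes `hvg.txt`, `gene_stats.csv`, `loadings.csv` and
#' `explained_variance.csv` under `directory`.
#'
#' @param model a `bs_preprocess_model`
#' @param directory output directory
#' @return the directory (write) or a `bs_preprocess_model` (read)
#' @export
write_preprocess_model <- function(model, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  writeLines(model$hvg, file.path(directory, "hvg.txt"))
  write.csv(data.frame(gene = model$hvg, mean = model$gene_mean,
                       sd = model$gene_sd, row.names = NULL),
            file.path(directory, "gene_stats.csv"), row.names = FALSE)
  write.csv(data.frame(gene = rownames(model$loadings), model$loadings,
                       row.names = NULL, check.names = FALSE),
            file.path(directory, "loadings.csv"), row.names = FALSE)
  write.csv(data.frame(pc = seq_along(model$explained_variance),
                       explained_variance = model$explained_variance,
                       clip = model$clip, scale_factor = model$scale_factor),
            file.path(directory, "explained_variance.csv"), row.names = FALSE)
  invisible(directory)
}

#' @rdname write_preprocess_model
#' @export
read_preprocess_model <- function(directory) {
  hvg <- readLines(file.path(directory, "hvg.txt"))
  gs <- read.csv(file.path(directory, "gene_stats.csv"))
  ld <- read.csv(file.path(directory, "loadings.csv"), check.names = FALSE)
  ev <- read.csv(file.path(directory, "explained_variance.csv"))
  loadings <- as.matrix(ld[, -1, drop = FALSE])
  rownames(loadings) <- ld$gene
  structure(list(hvg = hvg,
                 gene_mean = setNames(gs$mean, gs$gene),
                 gene_sd = setNames(gs$sd, gs$gene),
                 loadings = loadings,
                 explained_variance = ev$explained_variance,
                 clip = ev$clip[1], scale_factor = ev$scale_factor[1]),
            class = "bs_preprocess_model")
}
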