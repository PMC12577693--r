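#' Train a ventral/dorsal classifier on the midbrain reference
#'
#' A probability random forest (500 trees) is fit on the reference PC
#' coordinates with ventral as the positive class; 20% of cells are held
#' out to record a validation AUC. Everything is seeded.
#'
#' @param mb a midbrain `bs_reference` whose dataset carries `subregion`
#'   labels (>= 50 cells per class)
#' @param seed integer seed
#' @param holdout held-out fraction for the validation AUC (default 0.2)
#' @param num_trees forest size (default 500)
#' @return a `bs_ventral_model` with elements `forest`, `auc`, `n_ventral`,
#'   `n_dorsal`, `seed`
#' @export
train_ventral_model <- function(mb, seed = 1L, holdout = 0.2,
                                num_trees = 500) {
  sub <- mb$dataset$meta$subregion
  ok <- !is.na(sub)
  if (!all(SUBREGIONS %in% sub[ok]))
    stop("both ventral and dorsal labels are required")
  if (min(table(sub[ok])) < 50)
    stop("need >= 50 labeled cells per subregion class")
  x <- mb$embedding[ok, , drop = FALSE]
  y <- factor(sub[ok], levels = SUBREGIONS)
  n <- nrow(x)
  test <- with_seed(derive_seed(seed, "ventral-split"),
                    sample.int(n, round(holdout * n)))
  train <- setdiff(seq_len(n), test)
  df <- data.frame(x, check.names = FALSE)
  fit <- ranger::ranger(
    x = df[train, , drop = FALSE], y = y[train],
    probability = TRUE, num.trees = num_trees,
    seed = derive_seed(seed, "ventral-forest"))
  prob <- predict(fit, df[test, , drop = FALSE])$predictions[, "ventral"]
  structure(list(forest = fit,
                 auc = auc_score(y[test] == "ventral", prob),
                 n_ventral = sum(y[train] == "ventral"),
                 n_dorsal = sum(y[train] == "dorsal"),
                 seed = as.integer(seed)),
            class = "bs_ventral_model")
}

# Rank-based AUC (equivalent to the Mann-Whitney statistic).
auc_score <- function(positive, score) {
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Per-cell ventral score
#'
#' Probability of the ventral class from the trained classifier; higher
#' scores indicate stronger ventral (floor/basal plate) identity.
#'
#' @param model a `bs_ventral_model`
#' @param emb cells x PCs embedding in the midbrain reference PC space
#' @return named numeric vector of scores in `[0, 1]`
#' @export
ventral_score <- function(model, emb) {
  want <- model$forest$forest$independent.variable.names
  if (!all(want %in% colnames(emb)))
    stop("embedding lacks the PC columns the model was trained on")
  p <- predict(model$forest,
               data.frame(emb, check.names = FALSE))$predictions[, "ventral"]
  setNames(p, rownames(emb))
}

#' Cell-type identity strength via preranked GSEA
#'
#' Computes the log2 fold change of every gene between the query cells
#' predicted as `target_type` and all other predicted cells (de-logged
#' means with pseudocount 1), then runs preranked GSEA with the
#' reference's top `n_markers` markers of that type as the gene set. A
#' high positive NES means the predicted cells genuinely up-regulate the
#' type's reference signature.
#'
#' @param query a `bs_dataset` with lognorm present
#' @param predictions per-cell predicted types aligned to query cells
#' @param target_type the predicted cell type of interest
#' @param ref a `bs_reference` carrying markers for `target_type`
#' @param n_markers marker depth for the gene set (default 50)
#' @param n_perm GSEA permutations (default 1000)
#' @param seed integer seed
#' @return a `bs_gsea` result
#' @export
identity_strength <- function(query, predictions, target_type, ref,
                              n_markers = 50, n_perm = 1000, seed = 1L) {
  require_lognorm(query)
  stopifnot(length(predictions) == n_cells(query))
  grp <- predictions == target_type
  if (sum(grp) < 3) stop("target type has fewer than 3 predicted cells")
  if (sum(!grp) < 3) stop("fewer than 3 cells outside the target type")
  genes <- ref$markers$type_markers[[target_type]]
  if (is.null(genes)) stop("reference has no markers for ", target_type)
  gene_set <- head(genes, n_markers)
  if (!any(gene_set %in% query$genes))
    stop("marker set fully absent from query genes")
  expm <- expm1(as.matrix(query$lognorm))
  log2fc <- log2((rowMeans(expm[, grp, drop = FALSE]) + 1) /
                   (rowMeans(expm[, !grp, drop = FALSE]) + 1))
  names(log2fc) <- query$genes
  preranked_gsea(log2fc, gene_set, n_perm = n_perm, seed = seed)
}

#' Proportion table over mapped cells
#'
#' Category proportions (cell type, region, or region.lineage) over the
#' confidently assigned cells (or all cells), optionally split by a
#' per-cell grouping such as timepoint or dataset. The confidently
#' assigned fraction per group is attached as attribute
#' `confident_fraction`.
#'
#' @param result a `bs_tier1` / tier-2 `data.frame` (needs
#'   `predicted_type`, `confident`, and `predicted_region` for
#'   region-based categories)
#' @param category `"cell_type"`, `"region"` or `"region.lineage"`
#' @param confident_only restrict to confident cells (default TRUE)
#' @param group optional per-cell grouping vector (default: one group)
#' @param lineage_map named character vector cell type -> lineage, required
#'   for `"region.lineage"`
#' @return `data.frame` of class `bs_proportions` with columns `group`,
#'   `category`, `value`, `n_cells`, `proportion`
#' @export
proportion_table <- function(result, category = c("cell_type", "region",
                                                  "region.lineage"),
                             confident_only = TRUE, group = NULL,
                             lineage_map = NULL) {
  category <- match.arg(category)
  df <- as.data.frame(result)
  group <- group %||% rep("all", nrow(df))
  stopifnot(length(group) == nrow(df))
  value <- switch(category,
    cell_type = df$predicted_type,
    region = df$predicted_region,
    region.lineage = {
      if (is.null(lineage_map))
        stop("region.lineage requires a lineage_map")
      lin <- unname(lineage_map[df$predicted_type])
      lin[is.na(lin)] <- "other"
      paste(df$predicted_region, lin, sep = ".")
    })
  keep <- if (confident_only) df$confident else rep(TRUE, nrow(df))
  keep <- keep & !is.na(value)
  out <- list(); conf_frac <- c()
  for (g in unique(group)) {
    in_g <- group == g
    sel <- in_g & keep
    conf_frac[g] <- if (confident_only) mean(df$confident[in_g]) else 1
    if (!sum(sel)) {
      out[[length(out) + 1L]] <- data.frame(
        group = g, category = category, value = NA_character_,
        n_cells = 0L, proportion = NA_real_)
      next
    }
    tab <- table(value[sel])
    out[[length(out) + 1L]] <- data.frame(
      group = g, category = category, value = names(tab),
      n_cells = as.integer(tab),
      proportion = as.numeric(tab) / sum(tab), row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "confident_fraction") <- conf_frac
  class(res) <- c("bs_proportions", "data.frame")
  res
}

#' Pearson correlation between query and reference proportion profiles
#'
#' For every (query group, reference group) pair, the category vocabularies
#' are aligned on their union with zero fill and the Pearson correlation of
#' the proportion vectors is computed. Pairs with fewer than 3 aligned
#' categories carrying variance give `NA` with a warning.
#'
#' @param query_props,reference_props `bs_proportions` tables (reference
#'   groups are typically in vivo timepoints)
#' @return `data.frame` with `query_group`, `reference_group`, `pearson_r`
#' @export
correlate_proportions <- function(query_props, reference_props) {
  align <- function(p, g) {
    sub <- p[p$group == g & !is.na(p$value), c("value", "proportion")]
    setNames(sub$proportion, sub$value)
  }
  qg <- unique(query_props$group)
  rg <- unique(reference_props$group)
  out <- expand.grid(query_group = qg, reference_group = rg,
                     stringsAsFactors = FALSE)
  out$pearson_r <- NA_real_
  for (i in seq_len(nrow(out))) {
    a <- align(query_props, out$query_group[i])
    b <- align(reference_props, out$reference_group[i])
    cats <- union(names(a), names(b))
    av <- ifelse(is.na(a[cats]), 0, a[cats])
    bv <- ifelse(is.na(b[cats]), 0, b[cats])
    if (length(cats) < 3 || sd(av) == 0 || sd(bv) == 0) {
      warning("fewer than 3 aligned categories with variance for pair ",
              out$query_group[i], " / ", out$reference_group[i])
      next
    }
    out$pearson_r[i] <- cor(av, bv)
  }
  out
}

#' Two-sided Wilcoxon rank-sum comparison of score distributions
#'
#' Exact for small samples without ties; normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b numeric score vectors (>= 3 values each)
#' @return the two-sided p-value
#' @export
compare_score_distributions <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("each sample needs at least 3 values")
  suppressWarnings(wilcox.test(a, b)$p.value)
}

#' Spearman correlation between mean scores and proportions
#'
#' Used to relate a cell type's mean module score to its detected
#' proportion across timepoints or studies.
#'
#' @param mean_scores,proportions paired numeric vectors (>= 3 points)
#' @return Spearman's rho (NA with a warning for constant input)
#' @export
correlate_score_vs_proportion <- function(mean_scores, proportions) {
  stopifnot(length(mean_scores) == length(proportions))
  if (length(mean_scores) < 3) stop("need at least 3 paired points")
  if (sd(mean_scores) == 0 || sd(proportions) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(mean_scores, proportions, method = "spearman")
}
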