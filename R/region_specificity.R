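#' Region-classifier parameters
#'
#' @param k number of nearest neighbours (default 10)
#' @param specificity_threshold mean-agreement cutoff above which (strictly)
#'   a cell type is called region specific (default 0.65)
#' @return a `bs_region_params` list
#' @export
region_params <- function(k = 10, specificity_threshold = 0.65) {
  stopifnot(k >= 1, specificity_threshold > 0, specificity_threshold < 1)
  structure(list(k = as.integer(k),
                 specificity_threshold = specificity_threshold),
            class = "bs_region_params")
}

#' Quantify brain-region specificity of each cell type by kNN agreement
#'
#' Restricted to the cells of one cell type, each cell's classification
#' probability is the fraction of its `k` nearest neighbours (Euclidean in
#' PC space, self excluded) that share the cell's own region label. A cell
#' type whose mean probability across all its cells exceeds (strictly) the
#' threshold is flagged region specific. Cell types with `<= k` cells are
#' skipped and recorded. The winning-vote probability (weight of the
#' majority region among the neighbours) is also reported as
#' `mean_vote_prob` for comparison.
#'
#' @param emb cells x PCs embedding matrix
#' @param region_labels per-cell region, aligned to `emb` rows
#' @param celltype_labels per-cell cell type, aligned to `emb` rows
#' @param params a `bs_region_params`
#' @return list of class `bs_region_report`: `per_region` data.frame
#'   (cell_type, region, mean_agreement, n_cells), `per_type` data.frame
#'   (cell_type, overall_agreement, mean_vote_prob, n_cells,
#'   region_specific), `skipped` character vector, `params`
#' @export
neighbor_region_agreement <- function(emb, region_labels, celltype_labels,
                                      params = region_params()) {
  stopifnot(nrow(emb) == length(region_labels),
            nrow(emb) == length(celltype_labels))
  region_labels <- as.character(region_labels)
  celltype_labels <- as.character(celltype_labels)
  types <- sort(unique(celltype_labels))
  per_region <- list(); per_type <- list(); skipped <- character()
  for (ct in types) {
    sel <- which(celltype_labels == ct)
    if (length(sel) <= params$k) {
      warning("cell type '", ct, "' has <= k cells; skipped")
      skipped <- c(skipped, ct)
      next
    }
    sub <- emb[sel, , drop = FALSE]
    nn <- nearest_neighbors(sub, sub, params$k,
                            exclude = seq_len(nrow(sub)))
    regs <- region_labels[sel]
    neigh_regs <- matrix(regs[nn$idx], nrow = nrow(sub))
    agree <- rowMeans(neigh_regs == regs)
    vote <- apply(neigh_regs, 1, function(r) max(table(r)) / length(r))
    for (rg in sort(unique(regs))) {
      in_rg <- regs == rg
      per_region[[length(per_region) + 1L]] <- data.frame(
        cell_type = ct, region = rg,
        mean_agreement = mean(agree[in_rg]), n_cells = sum(in_rg))
    }
    per_type[[length(per_type) + 1L]] <- data.frame(
      cell_type = ct, overall_agreement = mean(agree),
      mean_vote_prob = mean(vote), n_cells = length(sel))
  }
  per_type <- do.call(rbind, per_type) %||%
    data.frame(cell_type = character(), overall_agreement = numeric(),
               mean_vote_prob = numeric(), n_cells = integer())
  per_type$region_specific <-
    per_type$overall_agreement > params$specificity_threshold
  structure(list(per_region = do.call(rbind, per_region) %||%
                   data.frame(cell_type = character(), region = character(),
                              mean_agreement = numeric(),
                              n_cells = integer()),
                 per_type = per_type, skipped = skipped, params = params),
            class = "bs_region_report")
}

#' @export
print.bs_region_report <- function(x, ...) {
  cat("region-specificity report:\n")
  print(x$per_type, row.names = FALSE)
  if (length(x$skipped))
    cat("skipped (<= k cells):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Cell types flagged region specific
#'
#' @param report a `bs_region_report`
#' @param threshold agreement cutoff; strictly-greater comparison
#' @return character vector of region-specific cell types
#' @export
flag_region_specific <- function(report,
                                 threshold = report$params$specificity_threshold) {
  pt <- report$per_type
  sort(pt$cell_type[pt$overall_agreement > threshold])
}

#' Infer region identity for unlabeled cells by kNN vote
#'
#' Each unlabeled cell takes the majority region among its `k` nearest
#' labeled neighbours; ties are broken by summed inverse distance, then by
#' lexicographic region name.
#'
#' @param labeled_emb cells x PCs matrix of region-labeled cells
#' @param region_labels regions aligned to `labeled_emb` rows
#' @param unlabeled_emb cells x PCs matrix in the same PC space
#' @param params a `bs_region_params`
#' @return character vector of inferred regions, one per unlabeled cell
#' @export
infer_region <- function(labeled_emb, region_labels, unlabeled_emb,
                         params = region_params()) {
  stopifnot(nrow(labeled_emb) == length(region_labels),
            nrow(labeled_emb) >= 1)
  k <- params$k
  if (k > nrow(labeled_emb)) {
    warning("k exceeds number of labeled cells; reduced to ",
            nrow(labeled_emb))
    k <- nrow(labeled_emb)
  }
  region_labels <- as.character(region_labels)
  nn <- nearest_neighbors(labeled_emb, unlabeled_emb, k)
  vapply(seq_len(nrow(unlabeled_emb)), function(i) {
    regs <- region_labels[nn$idx[i, ]]
    votes <- table(regs)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    inv <- vapply(top, function(rg) {
      d <- nn$dist[i, regs == rg]
      sum(1 / pmax(d, .Machine$double.eps))
    }, numeric(1))
    best <- top[inv == max(inv)]
    sort(best)[[1L]]
  }, character(1))
}
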