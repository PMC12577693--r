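#' Label-transfer parameters
#'
#' @param k_transfer number of reference neighbours per query cell
#'   (default 30)
#' @return a `bs_transfer_params` list
#' @export
transfer_params <- function(k_transfer = 30) {
  stopifnot(k_transfer >= 1)
  structure(list(k_transfer = as.integer(k_transfer)),
            class = "bs_transfer_params")
}

#' Pipeline configuration for two-tier mapping
#'
#' @param marker_depth_confidence markers per predicted type used for the
#'   confidence module score (default 20)
#' @param confidence_threshold module-score cutoff; cells are confident
#'   when their predicted-type score is strictly greater (default 0)
#' @param min_midbrain_cells minimum confidently midbrain-assigned cells
#'   required to proceed to tier 2 (default 1000; queries below the gate
#'   are refused, not errored)
#' @param module_params a `bs_module_params`
#' @param transfer a `bs_transfer_params`
#' @param region_params a `bs_region_params`
#' @param tier2_confidence apply the same confidence filter in tier 2
#'   (default TRUE)
#' @param seed master seed for the pipeline's stochastic stages
#' @return a `bs_pipeline_config` list
#' @export
pipeline_config <- function(marker_depth_confidence = 20,
                            confidence_threshold = 0,
                            min_midbrain_cells = 1000,
                            module_params = NULL,
                            transfer = transfer_params(),
                            region_params = NULL,
                            tier2_confidence = TRUE,
                            seed = 1L) {
  stopifnot(marker_depth_confidence >= 1, min_midbrain_cells >= 0)
  structure(list(
    marker_depth_confidence = as.integer(marker_depth_confidence),
    confidence_threshold = confidence_threshold,
    min_midbrain_cells = as.integer(min_midbrain_cells),
    module_params = module_params %||% module_params(seed = seed),
    transfer = transfer,
    region_params = region_params %||% region_params(),
    tier2_confidence = tier2_confidence,
    seed = as.integer(seed)),
    class = "bs_pipeline_config")
}

#' Build a reference atlas from a labeled dataset
#'
#' Fits preprocessing (HVG selection from the dataset's own variability
#' ranking, scaling, PCA) on the reference, derives full per-type marker
#' rankings (one-vs-rest Wilcoxon, ordered by descending log2 fold change),
#' and — when region labels span more than one region — global per-region
#' marker rankings plus per-(type, region) rankings for cell types flagged
#' region specific by kNN agreement. Cell types with fewer than 3 cells are
#' excluded from the marker panel with a warning.
#'
#' @param ds labeled `bs_dataset` (needs `meta$cell_type`; `meta$region`
#'   enables region markers)
#' @param params a `bs_preprocess_params`
#' @param marker_depth genes stored per marker list (default 50)
#' @param tier `"wholebrain"` or `"midbrain"`
#' @param region_params a `bs_region_params` for the specificity screen
#' @return a `bs_reference` with elements `dataset`, `model`, `embedding`,
#'   `markers`, `tier`, `region_report`
#' @export
build_reference <- function(ds, params = preprocess_params(),
                            marker_depth = 50,
                            tier = c("wholebrain", "midbrain"),
                            region_params = NULL) {
  tier <- match.arg(tier)
  region_params <- region_params %||% brainstem::region_params()
  if (!"cell_type" %in% names(ds$meta) ||
      all(is.na(ds$meta$cell_type)))
    stop("reference dataset needs cell_type labels in meta")
  marker_depth <- max(50L, as.integer(marker_depth))
  if (is.null(ds$lognorm)) ds <- log_normalize(ds, params)
  ranks <- rank_variable_genes(ds)
  hvg <- select_consensus_hvg(list(ranks), params$n_hvg)
  fit <- fit_preprocess(ds, hvg, params)
  labels <- ds$meta$cell_type
  full <- find_markers(ds, labels, fc_threshold = -Inf,
                       fdr_threshold = Inf)
  type_markers <- lapply(full, function(df) head(df$gene, marker_depth))
  region_markers <- list()
  region_report <- NULL
  regions <- unique(stats::na.omit(ds$meta$region))
  if (length(regions) >= 2) {
    keep <- !is.na(ds$meta$region)
    region_report <- neighbor_region_agreement(
      fit$embedding[keep, , drop = FALSE], ds$meta$region[keep],
      labels[keep], region_params)
    specific <- flag_region_specific(region_report)
    multi_region <- character()
    single_region <- character()
    for (ct in specific) {
      sel <- keep & labels == ct
      rt <- table(ds$meta$region[sel])
      if (sum(rt >= 3) < 2) {
        single_region <- c(single_region, ct)
        next
      }
      multi_region <- c(multi_region, ct)
      sub <- subset_cells(ds, sel)
      rl <- find_markers(sub, sub$meta$region, fc_threshold = -Inf,
                         fdr_threshold = Inf)
      region_markers[[ct]] <- lapply(rl, function(df)
        head(df$gene, marker_depth))
    }
    # Region-specific types confined to one region still get a
    # (type, region) marker set for their home region: the markers of
    # those cells against all other reference cells. Other regions fall
    # back to the global sets at assignment time.
    if (length(single_region)) {
      lab2 <- rep("__rest__", n_cells(ds))
      for (ct in single_region) {
        sel <- keep & labels == ct
        rhome <- names(which.max(table(ds$meta$region[sel])))
        lab2[sel & ds$meta$region == rhome] <- paste(ct, rhome, sep = "|")
      }
      combo <- find_markers(ds, lab2, fc_threshold = -Inf,
                            fdr_threshold = Inf)
      for (nm in setdiff(names(combo), "__rest__")) {
        parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
        region_markers[[parts[1L]]] <-
          setNames(list(head(combo[[nm]]$gene, marker_depth)), parts[2L])
      }
    }
    # Global per-region sets are derived from region-specific cell types
    # spanning several regions, so that region-exclusive type programs do
    # not masquerade as regional genes.
    glob_sel <- keep & labels %in% multi_region
    if (!length(multi_region) ||
        sum(table(ds$meta$region[glob_sel]) >= 3) < 2)
      glob_sel <- keep
    glob <- find_markers(subset_cells(ds, glob_sel),
                         ds$meta$region[glob_sel],
                         fc_threshold = -Inf, fdr_threshold = Inf)
    region_markers[["*"]] <- lapply(glob, function(df)
      head(df$gene, marker_depth))
  }
  markers <- bs_marker_panel(
    type_markers, region_markers,
    provenance = sprintf("one-vs-rest Wilcoxon markers, depth %d, %s tier",
                         marker_depth, tier))
  structure(list(dataset = ds, model = fit$model,
                 embedding = fit$embedding, markers = markers,
                 tier = tier, region_report = region_report),
            class = "bs_reference")
}

#' @export
print.bs_reference <- function(x, ...) {
  cat(sprintf("bs_reference (%s tier): %d genes x %d cells, %d cell types\n",
              x$tier, n_genes(x$dataset), n_cells(x$dataset),
              length(x$markers$type_markers)))
  invisible(x)
}

#' Transfer cell-type labels from a reference by weighted kNN vote
#'
#' Each query cell takes a Gaussian-kernel-weighted vote over its
#' `k_transfer` nearest reference cells in the reference PC space. The
#' kernel bandwidth is the cell's median neighbour distance (adaptive). The
#' prediction score is the winning label's share of the total weight; ties
#' go to the lexicographically first label.
#'
#' @param ref a `bs_reference`
#' @param query_emb query embedding from [project_query()] against
#'   `ref$model`
#' @param params a `bs_transfer_params`
#' @return `data.frame` with `cell_id`, `predicted_type`, `prediction_score`
#' @export
transfer_labels <- function(ref, query_emb, params = transfer_params()) {
  if (!n_cells(ref$dataset)) stop("empty reference")
  labels <- ref$dataset$meta$cell_type
  nn <- nearest_neighbors(ref$embedding, query_emb, params$k_transfer)
  out <- vapply(seq_len(nrow(query_emb)), function(i) {
    d <- nn$dist[i, ]
    bw <- median(d)
    w <- if (bw > 0) exp(-d^2 / (2 * bw^2)) else as.numeric(d == 0)
    if (sum(w) == 0) w <- rep(1, length(d))
    votes <- tapply(w, labels[nn$idx[i, ]], sum)
    votes <- votes / sum(votes)
    best <- argmax_lex(votes)
    c(type = best, score = as.character(votes[[best]]))
  }, character(2))
  data.frame(cell_id = rownames(query_emb),
             predicted_type = out["type", ],
             prediction_score = as.numeric(out["score", ]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Module-score confidence filter for transferred labels
#'
#' For every predicted cell type, the query-wide module score of the
#' reference's top `marker_depth_confidence` markers for that type is
#' computed; a cell is confident when the score for its own predicted type
#' strictly exceeds `confidence_threshold`. Cells whose predicted type has
#' no marker list are marked not confident with a warning.
#'
#' @param query a `bs_dataset` with lognorm present
#' @param predictions `data.frame` from [transfer_labels()], row-aligned to
#'   the query cells
#' @param ref a `bs_reference`
#' @param cfg a `bs_pipeline_config`
#' @return `data.frame` with `cell_id`, `type_module_score`, `confident`
#' @export
confidence_filter <- function(query, predictions, ref,
                              cfg = pipeline_config()) {
  stopifnot(nrow(predictions) == n_cells(query))
  score <- rep(NA_real_, n_cells(query))
  for (ct in unique(predictions$predicted_type)) {
    sel <- predictions$predicted_type == ct
    genes <- ref$markers$type_markers[[ct]]
    if (is.null(genes)) {
      warning("predicted type '", ct,
              "' has no reference markers; cells marked not confident")
      score[sel] <- -Inf
      next
    }
    mp <- cfg$module_params
    mp$seed <- derive_seed(mp$seed, paste0("confidence:", ct))
    ms <- module_score(query, head(genes, cfg$marker_depth_confidence), mp)
    score[sel] <- ms[sel]
  }
  data.frame(cell_id = query$cells, type_module_score = score,
             confident = score > cfg$confidence_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign a brain region to each confident cell by marker module scores
#'
#' For each confident query cell, module scores of the three regions'
#' top-`marker_depth_confidence` marker sets are computed — for each
#' region, the (predicted type, region) set when the reference carries
#' one, the global per-region set otherwise (non-region-specific types
#' use the global sets throughout). The predicted region is the argmax,
#' with ties going to the lexicographically first region name.
#'
#' @param query a `bs_dataset` with lognorm present
#' @param predictions predictions data.frame (needs `predicted_type`)
#' @param confident logical vector aligned to query cells
#' @param ref a `bs_reference` with region markers
#' @param cfg a `bs_pipeline_config`
#' @return `data.frame` with `cell_id`, `predicted_region` (NA for
#'   non-confident cells) and one `score_<region>` column per region
#' @export
assign_region <- function(query, predictions, confident, ref,
                          cfg = pipeline_config()) {
  rm_ <- ref$markers$region_markers
  if (!length(rm_)) stop("reference has no region markers")
  regions <- sort(names(rm_[["*"]] %||% rm_[[1L]]))
  score_cache <- new.env(parent = emptyenv())
  region_score <- function(set_key, genes) {
    if (is.null(score_cache[[set_key]])) {
      mp <- cfg$module_params
      mp$seed <- derive_seed(mp$seed, paste0("region:", set_key))
      score_cache[[set_key]] <-
        module_score(query, head(genes, cfg$marker_depth_confidence), mp)
    }
    score_cache[[set_key]]
  }
  n <- n_cells(query)
  scores <- matrix(NA_real_, n, length(regions),
                   dimnames = list(NULL, regions))
  pred_region <- rep(NA_character_, n)
  for (ct in unique(predictions$predicted_type)) {
    sel <- which(predictions$predicted_type == ct & confident)
    if (!length(sel)) next
    for (rg in regions) {
      src <- if (!is.null(rm_[[ct]]) && !is.null(rm_[[ct]][[rg]]))
        ct else "*"
      scores[sel, rg] <- region_score(paste0(src, "|", rg),
                                      rm_[[src]][[rg]])[sel]
    }
  }
  done <- which(confident)
  pred_region[done] <- vapply(done, function(i)
    argmax_lex(scores[i, ]), character(1))
  out <- data.frame(cell_id = query$cells, predicted_region = pred_region,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (rg in regions) out[[paste0("score_", rg)]] <- scores[, rg]
  out
}

#' Tier-1 mapping of a query onto the whole-brain reference
#'
#' Projection into the reference PC space, weighted-kNN label transfer,
#' module-score confidence filtering, then region assignment for confident
#' cells.
#'
#' @param query a `bs_dataset` (log-normalized on the fly if needed)
#' @param ref a whole-brain `bs_reference`
#' @param cfg a `bs_pipeline_config`
#' @return a `bs_tier1` object: per-cell `data.frame` with prediction,
#'   scores, confidence and region columns; the query embedding is attached
#'   as attribute `embedding`
#' @export
tier_one <- function(query, ref, cfg = pipeline_config()) {
  if (is.null(query$lognorm))
    query <- log_normalize(query,
                           preprocess_params(scale_factor = ref$model$scale_factor))
  emb <- project_query(query, ref$model)
  pred <- transfer_labels(ref, emb, cfg$transfer)
  conf <- confidence_filter(query, pred, ref, cfg)
  reg <- assign_region(query, pred, conf$confident, ref, cfg)
  res <- cbind(pred, conf[, c("type_module_score", "confident")],
               reg[, -1, drop = FALSE])
  attr(res, "embedding") <- emb
  class(res) <- c("bs_tier1", "data.frame")
  res
}

#' Extract the confidently midbrain-assigned cells, applying the size gate
#'
#' Queries with fewer than `min_midbrain_cells` confident midbrain cells
#' are refused (a typed outcome, not an error), mirroring the rule that
#' small midbrain fractions do not support a meaningful second-tier
#' mapping.
#'
#' @param query a `bs_dataset`
#' @param tier1 a `bs_tier1` result for `query`
#' @param cfg a `bs_pipeline_config`
#' @return list with `passed` (logical), `n_midbrain`, and — when passed —
#'   `dataset`, the midbrain-cell subset
#' @export
extract_midbrain <- function(query, tier1, cfg = pipeline_config()) {
  mask <- tier1$confident & !is.na(tier1$predicted_region) &
    tier1$predicted_region == "midbrain"
  n_mid <- sum(mask)
  if (n_mid < cfg$min_midbrain_cells)
    return(list(passed = FALSE, n_midbrain = n_mid))
  list(passed = TRUE, n_midbrain = n_mid,
       dataset = subset_cells(query, mask))
}

#' Run the full two-tier mapping pipeline
#'
#' Tier 1 maps the query onto the whole-brain reference (type, confidence,
#' region); the confidently midbrain-assigned subset — if it passes the
#' size gate — is re-projected onto the midbrain reference for fine subtype
#' calls, with the same confidence rule applied symmetrically when
#' `cfg$tier2_confidence` is `TRUE`.
#'
#' @param query a `bs_dataset`
#' @param wb whole-brain `bs_reference` (`tier == "wholebrain"`)
#' @param mb midbrain `bs_reference` (`tier == "midbrain"`)
#' @param cfg a `bs_pipeline_config`
#' @return a `bs_two_tier` list: `tier1`, `midbrain_gate_passed`,
#'   `n_midbrain`, `tier2` (per-midbrain-cell predictions or NULL),
#'   `summary` (region and type proportion tables)
#' @export
run_two_tier <- function(query, wb, mb, cfg = pipeline_config()) {
  stopifnot(wb$tier == "wholebrain", mb$tier == "midbrain")
  if (is.null(query$lognorm))
    query <- log_normalize(query,
                           preprocess_params(scale_factor = wb$model$scale_factor))
  t1 <- tier_one(query, wb, cfg)
  gate <- extract_midbrain(query, t1, cfg)
  tier2 <- NULL
  if (gate$passed) {
    sub <- gate$dataset
    emb2 <- project_query(sub, mb$model)
    pred2 <- transfer_labels(mb, emb2, cfg$transfer)
    if (cfg$tier2_confidence) {
      conf2 <- confidence_filter(sub, pred2, mb, cfg)
      tier2 <- cbind(pred2,
                     conf2[, c("type_module_score", "confident")])
    } else {
      tier2 <- pred2
      tier2$type_module_score <- NA_real_
      tier2$confident <- TRUE
    }
    attr(tier2, "embedding") <- emb2
  }
  res <- structure(list(tier1 = t1, midbrain_gate_passed = gate$passed,
                        n_midbrain = gate$n_midbrain, tier2 = tier2,
                        config = cfg),
                   class = "bs_two_tier")
  res$summary <- list(
    region = proportion_table(t1, "region"),
    cell_type = proportion_table(t1, "cell_type"),
    tier2_cell_type = if (!is.null(tier2))
      proportion_table(tier2, "cell_type"))
  res
}

#' @export
print.bs_two_tier <- function(x, ...) {
  cat(sprintf("two-tier mapping: %d query cells, %d confident (%.1f%%)\n",
              nrow(x$tier1), sum(x$tier1$confident),
              100 * mean(x$tier1$confident)))
  cat(sprintf("midbrain gate: %s (%d midbrain cells)\n",
              if (x$midbrain_gate_passed) "passed" else "refused",
              x$n_midbrain))
  invisible(x)
}

#' Direct mapping (DM) baseline onto a single-region reference
#'
#' The conventional one-step projection: project, transfer labels, apply
#' the confidence filter. No region assignment is performed — a regional
#' reference can only emit its own labels, which is exactly the failure
#' mode the two-tier framework addresses.
#'
#' @param query a `bs_dataset`
#' @param regional_ref a `bs_reference` built from a single region
#' @param cfg a `bs_pipeline_config`
#' @return a `bs_tier1`-style `data.frame` without region columns
#' @export
direct_map <- function(query, regional_ref, cfg = pipeline_config()) {
  if (is.null(query$lognorm))
    query <- log_normalize(
      query, preprocess_params(scale_factor = regional_ref$model$scale_factor))
  emb <- project_query(query, regional_ref$model)
  pred <- transfer_labels(regional_ref, emb, cfg$transfer)
  conf <- confidence_filter(query, pred, regional_ref, cfg)
  res <- cbind(pred, conf[, c("type_module_score", "confident")])
  attr(res, "embedding") <- emb
  class(res) <- c("bs_tier1", "data.frame")
  res
}
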