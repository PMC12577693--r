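# Minimal hand-made reference for transfer-level tests.
fake_reference <- function(emb, types, markers = NULL) {
  meta <- data.frame(cell_id = rownames(emb) %||% character(0),
                     cell_type = types, stringsAsFactors = FALSE)
  counts <- matrix(1, nrow = 1, ncol = nrow(emb),
                   dimnames = list("g1", rownames(emb) %||% character(0)))
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  ds <- bs_dataset(counts, meta = meta)
  structure(list(dataset = ds, model = NULL, embedding = emb,
                 markers = markers %||%
                   bs_marker_panel(setNames(list("g1"), types[1])),
                 tier = "wholebrain", region_report = NULL),
            class = "bs_reference")
}

test_that("a query cell inside a pure cluster gets that type with score 1", {
  set.seed(25)
  emb <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
               matrix(rnorm(40, sd = 0.1), 20, 2) + 40)
  rownames(emb) <- paste0("r", 1:40)
  ref <- fake_reference(emb, rep(c("A", "B"), each = 20))
  q <- emb[3, , drop = FALSE]
  rownames(q) <- "q1"
  res <- transfer_labels(ref, q, transfer_params(k_transfer = 10))
  expect_identical(res$predicted_type, "A")
  expect_equal(res$prediction_score, 1)
})

test_that("an equidistant query splits its vote and ties lexicographically", {
  # perfectly mirrored clusters around the origin
  right <- cbind(seq(9, 11, length.out = 10), seq(-1, 1, length.out = 10))
  left <- -right
  emb <- rbind(left, right)
  rownames(emb) <- paste0("r", 1:20)
  ref <- fake_reference(emb, rep(c("zeta", "alpha"), each = 10))
  q <- matrix(0, 1, 2, dimnames = list("q1", NULL))
  res <- transfer_labels(ref, q, transfer_params(k_transfer = 20))
  expect_equal(res$prediction_score, 0.5, tolerance = 1e-12)
  expect_identical(res$predicted_type, "alpha")
  empty_ref <- ref
  empty_ref$dataset <- subset_cells(ref$dataset, rep(FALSE, 20))
  empty_ref$embedding <- emb[0, , drop = FALSE]
  expect_error(transfer_labels(empty_ref, q), "empty reference")
})

test_that("held-out reference cells are re-labeled accurately", {
  wb <- tiny_wb()
  ds <- wb$dataset
  set.seed(26)
  test_idx <- sample(n_cells(ds), round(0.2 * n_cells(ds)))
  train <- subset_cells(ds, !(seq_len(n_cells(ds)) %in% test_idx))
  test <- subset_cells(ds, seq_len(n_cells(ds)) %in% test_idx)
  ref <- suppressWarnings(build_reference(train, tier = "wholebrain"))
  emb <- project_query(test, ref$model)
  res <- transfer_labels(ref, emb)
  expect_gte(mean(res$predicted_type == test$meta$cell_type), 0.9)
})

test_that("confidence flags are strict against the configured threshold", {
  wb <- tiny_wb()
  spec <- tiny_spec()
  q <- generate_mixture(spec, c(hindbrain = 1, forebrain = 1), 300,
                        seed = 31L)
  t1 <- tier_one(q, wb, pipeline_config(seed = 3L))
  expect_true(all(t1$confident == (t1$type_module_score > 0)))
  # raising the threshold to an observed score must exclude that cell
  thr <- t1$type_module_score[which(t1$confident)[1]]
  t1b <- tier_one(q, wb, pipeline_config(confidence_threshold = thr,
                                         seed = 3L))
  expect_false(t1b$confident[which(t1$confident)[1]])
  expect_true(all(t1b$confident == (t1b$type_module_score > thr)))
  # non-confident cells carry no region call
  expect_true(all(is.na(t1$predicted_region[!t1$confident])))
})

test_that("unknown predicted types are marked not confident with a warning", {
  wb <- tiny_wb()
  spec <- tiny_spec()
  q <- log_normalize(generate_mixture(spec, c(hindbrain = 1), 50,
                                      seed = 32L))
  preds <- data.frame(cell_id = q$cells,
                      predicted_type = "NotAType",
                      prediction_score = 1)
  expect_warning(conf <- confidence_filter(q, preds, wb,
                                           pipeline_config()),
                 "no reference markers")
  expect_false(any(conf$confident))
})

test_that("region assignment is an argmax with a forebrain tie rule", {
  # a perfectly flat expression matrix -> all module scores are exactly 0
  ln <- matrix(1, 8, 12,
               dimnames = list(paste0("g", 1:8), paste0("c", 1:12)))
  ds <- manual_dataset(ln)
  panel <- bs_marker_panel(
    list(T1 = c("g1", "g2")),
    list("*" = list(forebrain = c("g1", "g2"), hindbrain = c("g3", "g4"),
                    midbrain = c("g5", "g6"))))
  ref <- fake_reference(matrix(0, 12, 2,
                               dimnames = list(paste0("c", 1:12), NULL)),
                        rep("T1", 12), markers = panel)
  preds <- data.frame(cell_id = ds$cells, predicted_type = "T1",
                      prediction_score = 1)
  reg <- assign_region(ds, preds, rep(TRUE, 12), ref, pipeline_config())
  expect_true(all(reg$predicted_region == "forebrain"))
  expect_true(all(reg$score_forebrain == 0))
  no_regions <- fake_reference(ref$embedding, rep("T1", 12))
  expect_error(assign_region(ds, preds, rep(TRUE, 12), no_regions,
                             pipeline_config()),
               "no region markers")
})

test_that("the midbrain gate keeps 1000 cells and refuses 999", {
  spec <- tiny_spec()
  q <- generate_mixture(spec, c(midbrain = 1), 1200, seed = 33L)
  fake_t1 <- function(n_mid) {
    df <- data.frame(cell_id = q$cells,
                     predicted_type = "GABA N",
                     prediction_score = 1,
                     type_module_score = 1,
                     confident = TRUE,
                     predicted_region = c(rep("midbrain", n_mid),
                                          rep("forebrain", 1200 - n_mid)))
    class(df) <- c("bs_tier1", "data.frame")
    df
  }
  expect_false(extract_midbrain(q, fake_t1(999), pipeline_config())$passed)
  gate <- extract_midbrain(q, fake_t1(1000), pipeline_config())
  expect_true(gate$passed)
  expect_equal(n_cells(gate$dataset), 1000)
  expect_true(extract_midbrain(q, fake_t1(0),
                               pipeline_config(min_midbrain_cells = 0))$passed)
})

test_that("two-tier mapping is structurally sound on a designed culture", {
  spec <- tiny_spec()
  wb <- tiny_wb(); mb <- tiny_mb()
  comp <- culture_composition(spec, mid_frac = 0.7)
  q <- generate_culture_query(spec, comp, 1800, seed = 34L)
  cfg <- pipeline_config(seed = 4L)
  tt <- run_two_tier(q, wb, mb, cfg)
  t1 <- tt$tier1
  mid_ids <- t1$cell_id[t1$confident & !is.na(t1$predicted_region) &
                          t1$predicted_region == "midbrain"]
  expect_true(tt$midbrain_gate_passed)
  expect_setequal(tt$tier2$cell_id, mid_ids)
  # fine subtypes are called correctly for confident tier-2 cells
  idx <- match(tt$tier2$cell_id, q$cells)
  conf2 <- tt$tier2$confident
  expect_gte(mean(tt$tier2$predicted_type[conf2] ==
                    q$meta$truth_type[idx][conf2]), 0.85)
  # truth-midbrain cells dominate tier 2
  expect_gte(mean(q$meta$truth_region[idx] == "midbrain"), 0.9)
  # same seed, same result
  tt2 <- run_two_tier(q, wb, mb, cfg)
  expect_identical(tt$tier1$predicted_type, tt2$tier1$predicted_type)
  expect_identical(tt$tier2$prediction_score, tt2$tier2$prediction_score)
})

test_that("direct mapping cannot emit labels absent from its reference", {
  spec <- tiny_spec()
  wb <- tiny_wb()
  atlas <- wb$dataset
  hind_ref <- suppressWarnings(build_reference(
    subset_cells(atlas, atlas$meta$region == "hindbrain"),
    tier = "wholebrain"))
  mix <- generate_mixture(spec, c(hindbrain = 5, forebrain = 1), 1200,
                          seed = 35L)
  dm <- direct_map(mix, hind_ref, pipeline_config(seed = 5L))
  expect_false("Glu N" %in% dm$predicted_type)
  expect_true(all(dm$predicted_type %in%
                    hind_ref$dataset$meta$cell_type))
  # DM of a pure in-region query agrees with tier-1 on confident cells
  pure <- generate_mixture(spec, c(hindbrain = 1), 600, seed = 36L)
  dm2 <- direct_map(pure, hind_ref, pipeline_config(seed = 5L))
  t1 <- tier_one(pure, wb, pipeline_config(seed = 5L))
  both <- dm2$confident & t1$confident
  expect_gte(mean(dm2$predicted_type[both] == t1$predicted_type[both]),
             0.95)
})

test_that("reference building is deterministic and validates inputs", {
  spec <- tiny_spec()
  atlas <- generate_atlas(spec)
  r1 <- suppressWarnings(build_reference(atlas, tier = "wholebrain"))
  r2 <- suppressWarnings(build_reference(atlas, tier = "wholebrain"))
  expect_identical(r1$markers$type_markers, r2$markers$type_markers)
  expect_identical(r1$embedding, r2$embedding)
  # designed type-program genes surface among the type's top-20 markers
  for (ct in c("DA N", "GABA N")) {
    top20 <- head(r1$markers$type_markers[[ct]], 20)
    expect_gte(length(intersect(top20, spec$programs$type[[ct]])), 10)
  }
  nolabel <- atlas
  nolabel$meta$cell_type <- NULL
  expect_error(build_reference(nolabel), "cell_type")
  onetype <- subset_cells(atlas, atlas$meta$cell_type == "GABA N")
  expect_error(suppressWarnings(build_reference(onetype)), "2 labels")
})
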