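#' Specification of a synthetic regionalized-brain atlas
#'
#' Defines the generative model used to emulate a fetal whole-brain
#' reference and its midbrain subatlas: disjoint gene programs per cell
#' type, per brain region, and per midbrain subregion, additive on the
#' natural-log scale over a lognormal baseline, with negative-binomial
#' counts at a common dispersion. Cell types flagged region specific carry
#' the full regional program; the others carry it attenuated by
#' `nonspecific_region_attenuation`, reflecting that regional identity in
#' tissue is graded rather than absent for such types.
#'
#' The default cell-type roster mirrors the structure the mapping framework
#' assumes: a midbrain-exclusive dopaminergic type (`DA N`), an excitatory
#' type present in forebrain and midbrain but absent from hindbrain
#' (`Glu N`), a hindbrain-exclusive type (`FSTL4 RELN N`), broadly present
#' region-specific types (`GABA N`, `Radial glia`), and pan-regional types
#' without strong regional signatures (`Ser N`, `Neuroblast`).
#'
#' @param n_genes number of genes (default 2000)
#' @param cells_per_type_per_region reference cells per (type, region)
#'   combination (default 150)
#' @param program_size genes per expression program (default 30)
#' @param type_effect,region_effect,subregion_effect natural-log fold
#'   uplifts of program genes (defaults 2.0, 1.0, 1.0)
#' @param distinguishing_effect natural-log uplift of the rare subtype's
#'   small distinguishing program (default 4.0: discrete-subtype markers
#'   such as the PITX2-like gene are essentially on/off)
#' @param nonspecific_region_attenuation fraction of `region_effect`
#'   retained by non-region-specific cell types (default 0.15)
#' @param nb_dispersion negative-binomial dispersion, variance
#'   `mu + dispersion * mu^2` (default 0.3)
#' @param library_size_mean mean per-cell total count (default 10,000)
#' @param rare_subtype_fraction fraction of midbrain cells belonging to the
#'   rare subthalamic-like dopaminergic subtype (default 0.008)
#' @param n_midbrain_cells cells in the midbrain subatlas (default 4000)
#' @param seed master seed; gene baseline expression depends only on this,
#'   so references and queries built from the same spec share a manifold
#' @return a `bs_atlas_spec` list, including the cell-type roster
#'   (`cell_types`) and the program allocation (`programs`)
#' @export
synthetic_atlas_spec <- function(n_genes = 2000,
                                 cells_per_type_per_region = 150,
                                 program_size = 30,
                                 type_effect = 2.0,
                                 region_effect = 1.0,
                                 subregion_effect = 1.0,
                                 distinguishing_effect = 4.0,
                                 nonspecific_region_attenuation = 0.15,
                                 nb_dispersion = 0.3,
                                 library_size_mean = 10000,
                                 rare_subtype_fraction = 0.008,
                                 n_midbrain_cells = 4000,
                                 seed = 1L) {
  stopifnot(n_genes >= 1, program_size >= 1, type_effect >= 0,
            region_effect >= 0, subregion_effect >= 0,
            distinguishing_effect >= 0,
            nonspecific_region_attenuation >= 0,
            nonspecific_region_attenuation <= 1,
            nb_dispersion > 0, library_size_mean > 0,
            rare_subtype_fraction > 0, rare_subtype_fraction < 1)
  cell_types <- data.frame(
    cell_type = c("DA N", "Glu N", "FSTL4 RELN N", "GABA N", "Ser N",
                  "Radial glia", "Neuroblast"),
    region_specific = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    lineage = c("neuron", "neuron", "neuron", "neuron", "neuron",
                "progenitor", "progenitor"),
    stringsAsFactors = FALSE)
  cell_types$regions <- list("midbrain", c("forebrain", "midbrain"),
                             "hindbrain", BRAIN_REGIONS, BRAIN_REGIONS,
                             BRAIN_REGIONS, BRAIN_REGIONS)
  fine_types <- data.frame(
    cell_type = c("hDA", "hDA.STN", "hRN", "hvGaba", "hdGaba", "hGlu",
                  "hNProg"),
    parent = c("DA N", "DA N", "Glu N", "GABA N", "GABA N", "Glu N",
               "Radial glia"),
    subregion = c("ventral", "ventral", "ventral", "ventral", "dorsal",
                  "dorsal", NA),
    lineage = c("neuron", "neuron", "neuron", "neuron", "neuron", "neuron",
                "progenitor"),
    stringsAsFactors = FALSE)
  spec <- structure(
    list(n_genes = n_genes,
         regions = BRAIN_REGIONS,
         cell_types = cell_types,
         fine_types = fine_types,
         cells_per_type_per_region = cells_per_type_per_region,
         program_size = program_size,
         type_effect = type_effect,
         region_effect = region_effect,
         subregion_effect = subregion_effect,
         distinguishing_effect = distinguishing_effect,
         nonspecific_region_attenuation = nonspecific_region_attenuation,
         nb_dispersion = nb_dispersion,
         library_size_mean = library_size_mean,
         rare_subtype_fraction = rare_subtype_fraction,
         n_midbrain_cells = n_midbrain_cells,
         seed = as.integer(seed)),
    class = "bs_atlas_spec")
  spec$programs <- allocate_programs(spec)
  spec
}

# Deterministically carve disjoint gene blocks for every program.
# hDA.STN shares 80% of the hDA program and adds a small distinguishing
# block (its first gene plays the role of a PITX2-like marker).
allocate_programs <- function(spec) {
  ps <- spec$program_size
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  cursor <- 0L
  take <- function(n) {
    if (cursor + n > spec$n_genes)
      stop("program sizes exceed n_genes")
    block <- genes[(cursor + 1L):(cursor + n)]
    cursor <<- cursor + n
    block
  }
  type_prog <- list()
  for (ct in spec$cell_types$cell_type) type_prog[[ct]] <- take(ps)
  region_prog <- list()
  for (rg in spec$regions) region_prog[[rg]] <- take(ps)
  sub_prog <- list()
  for (sr in SUBREGIONS) sub_prog[[sr]] <- take(ps)
  # Regional identity is partly cell-type-specific in tissue: each
  # region-specific type carries its own (type, region) interaction program
  # on top of the shared regional program.
  interaction_prog <- list()
  for (i in seq_len(nrow(spec$cell_types))) {
    if (!spec$cell_types$region_specific[i]) next
    ct <- spec$cell_types$cell_type[i]
    for (rg in spec$cell_types$regions[[i]])
      interaction_prog[[paste(ct, rg, sep = "|")]] <- take(ps)
  }
  n_shared <- ceiling(0.8 * ps)
  n_dist <- max(1L, ps - n_shared)
  fine_prog <- list(hDA = take(ps))
  stn_dist <- take(n_dist)
  fine_prog[["hDA.STN"]] <- c(fine_prog$hDA[seq_len(n_shared)], stn_dist)
  for (ct in c("hRN", "hvGaba", "hdGaba", "hGlu", "hNProg"))
    fine_prog[[ct]] <- take(ps)
  list(type = type_prog, region = region_prog, subregion = sub_prog,
       interaction = interaction_prog, fine = fine_prog,
       stn_distinguishing = stn_dist, genes = genes)
}

# Lognormal baseline relative expression; depends only on spec$seed.
baseline_weights <- function(spec) {
  with_seed(derive_seed(spec$seed, "baseline"),
            exp(rnorm(spec$n_genes, mean = 0, sd = 1)))
}

# Natural-log uplift vector for one cell condition.
condition_uplift <- function(spec, cell_type, region, subregion,
                             is_noise = FALSE, subregion_scale = 1) {
  u <- numeric(spec$n_genes)
  names(u) <- spec$programs$genes
  if (is_noise) return(u)
  pr <- spec$programs
  fine <- spec$fine_types
  if (cell_type %in% fine$cell_type) {
    row <- fine[fine$cell_type == cell_type, ]
    u[pr$fine[[cell_type]]] <- u[pr$fine[[cell_type]]] + spec$type_effect
    if (cell_type == "hDA.STN")
      u[pr$stn_distinguishing] <- spec$distinguishing_effect
    u[pr$type[[row$parent]]] <- u[pr$type[[row$parent]]] + spec$type_effect
    region_scale <- 1
    anchor_type <- row$parent
  } else {
    ct <- spec$cell_types[spec$cell_types$cell_type == cell_type, ]
    if (!nrow(ct)) stop("unknown cell type: ", cell_type)
    u[pr$type[[cell_type]]] <- u[pr$type[[cell_type]]] + spec$type_effect
    region_scale <- if (ct$region_specific) 1 else
      spec$nonspecific_region_attenuation
    anchor_type <- cell_type
  }
  if (!is.na(region) && region %in% spec$regions) {
    u[pr$region[[region]]] <- u[pr$region[[region]]] +
      spec$region_effect * region_scale
    ia <- pr$interaction[[paste(anchor_type, region, sep = "|")]]
    if (!is.null(ia))
      u[ia] <- u[ia] + spec$region_effect
  }
  if (!is.na(region) && region == "midbrain" && !is.na(subregion))
    u[pr$subregion[[subregion]]] <- u[pr$subregion[[subregion]]] +
      spec$subregion_effect * subregion_scale
  u
}

# Simulate NB counts for a cell table with columns cell_type, region,
# subregion, is_noise and optional subregion_scale. Returns genes x cells
# sparse matrix (columns in cell-table order).
simulate_counts <- function(spec, cells, seed) {
  w <- baseline_weights(spec)
  if (!"subregion_scale" %in% names(cells)) cells$subregion_scale <- 1
  key <- paste(cells$cell_type, cells$region, cells$subregion,
               cells$is_noise, cells$subregion_scale, sep = "\r")
  n <- nrow(cells)
  counts <- with_seed(derive_seed(seed, "counts"), {
    sdlog <- 0.35
    lib <- exp(rnorm(n, mean = log(spec$library_size_mean) - sdlog^2 / 2,
                     sd = sdlog))
    out <- matrix(0L, nrow = spec$n_genes, ncol = n)
    for (k in unique(key)) {
      cols <- which(key == k)
      r1 <- cells[cols[1L], ]
      u <- condition_uplift(spec, r1$cell_type, r1$region, r1$subregion,
                            r1$is_noise, r1$subregion_scale)
      p <- w * exp(u)
      p <- p / sum(p)
      mu <- outer(p, lib[cols])
      out[, cols] <- rnbinom(length(mu), mu = mu,
                             size = 1 / spec$nb_dispersion)
    }
    out
  })
  rownames(counts) <- spec$programs$genes
  Matrix::Matrix(counts, sparse = TRUE)
}

# Largest-remainder apportionment of n among non-negative weights.
# Deterministic: remainder ties go to the earlier component.
largest_remainder <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic whole-brain reference atlas
#'
#' One cell block per (cell type, region) combination of the roster, with
#' `cells_per_type_per_region` cells each. Midbrain cells receive a random
#' ventral/dorsal subregion label with the corresponding program. Truth
#' labels are recorded both as `cell_type`/`region`/`subregion` (reference
#' annotation) and as `truth_*` columns.
#'
#' @param spec a `bs_atlas_spec`
#' @param seed seed for this draw (defaults to `spec$seed`)
#' @return a `bs_dataset`
#' @export
generate_atlas <- function(spec, seed = spec$seed) {
  rows <- list()
  for (i in seq_len(nrow(spec$cell_types))) {
    ct <- spec$cell_types$cell_type[i]
    for (rg in spec$cell_types$regions[[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, region = rg,
        n = spec$cells_per_type_per_region,
        lineage = spec$cell_types$lineage[i])
  }
  blocks <- do.call(rbind, rows)
  cells <- blocks[rep(seq_len(nrow(blocks)), blocks$n), , drop = FALSE]
  cells$n <- NULL
  cells$is_noise <- FALSE
  cells$subregion <- NA_character_
  mid <- which(cells$region == "midbrain")
  cells$subregion[mid] <- with_seed(
    derive_seed(seed, "subregion"),
    sample(SUBREGIONS, length(mid), replace = TRUE))
  finalize_dataset(spec, cells, seed, prefix = "wb")
}

#' Generate a synthetic midbrain subatlas
#'
#' Midbrain-only fine cell types with ventral/dorsal truth labels. The
#' rare subthalamic-like type (`hDA.STN`) is drawn at
#' `rare_subtype_fraction` of the cells and shares 80% of the dopaminergic
#' (`hDA`) program plus a small distinguishing program. Progenitors
#' (`hNProg`) are split between subregions.
#'
#' @param spec a `bs_atlas_spec`
#' @param seed seed for this draw (defaults to `spec$seed`)
#' @param n_cells number of cells (defaults to `spec$n_midbrain_cells`)
#' @return a `bs_dataset`
#' @export
generate_midbrain_subatlas <- function(spec, seed = spec$seed,
                                       n_cells = spec$n_midbrain_cells) {
  rare <- spec$rare_subtype_fraction
  if (rare * n_cells < 10)
    warning("fewer than 10 rare-subtype cells expected; ",
            "the subtype may be undetectable")
  props <- c(hDA = 0.25 * (1 - rare / 0.25), hDA.STN = rare, hRN = 0.10,
             hvGaba = 0.15, hdGaba = 0.15, hGlu = 0.15, hNProg = 0.20)
  props["hDA"] <- 1 - sum(props[-1])
  n_per <- largest_remainder(n_cells, props[spec$fine_types$cell_type])
  cells <- spec$fine_types[rep(seq_len(nrow(spec$fine_types)), n_per), ,
                           drop = FALSE]
  cells$region <- "midbrain"
  cells$is_noise <- FALSE
  prog_rows <- which(is.na(cells$subregion))
  cells$subregion[prog_rows] <- with_seed(
    derive_seed(seed, "subregion"),
    sample(SUBREGIONS, length(prog_rows), replace = TRUE))
  finalize_dataset(spec, cells, seed, prefix = "mb")
}

#' Generate a synthetic two-region mixture query
#'
#' Mirrors mixture benchmarks in which cells of two brain regions with
#' known identity are combined at a designed ratio (e.g. 5:1
#' hindbrain:forebrain). Cell counts follow the ratio exactly via
#' largest-remainder rounding; within a component, cells are spread evenly
#' over the cell types present in that region. Optional off-manifold noise
#' cells express no program at all.
#'
#' Components draw from the region-specific cell types present in each
#' region (`types = "region_specific"`, the default), mirroring benchmark
#' mixtures built from cells whose regional identity is transcriptomically
#' defined; `types = "all"` also includes the pan-regional types, whose
#' regional identity is only weakly encoded in expression.
#'
#' @param spec a `bs_atlas_spec`
#' @param ratio named numeric vector of region weights, e.g.
#'   `c(hindbrain = 5, forebrain = 1)`
#' @param n_cells total cells (noise cells included)
#' @param noise_fraction fraction of off-manifold noise cells (default 0)
#' @param types `"region_specific"` or `"all"`
#' @param seed seed for this draw
#' @return a `bs_dataset` with `truth_*` metadata
#' @export
generate_mixture <- function(spec, ratio, n_cells, noise_fraction = 0,
                             types = c("region_specific", "all"),
                             seed = spec$seed) {
  types <- match.arg(types)
  stopifnot(!is.null(names(ratio)), all(ratio > 0),
            noise_fraction >= 0, noise_fraction < 1)
  bad <- setdiff(names(ratio), spec$regions)
  if (length(bad))
    stop("ratio names absent from spec regions: ", paste(bad, collapse = ", "))
  n_noise <- round(noise_fraction * n_cells)
  n_signal <- n_cells - n_noise
  per_region <- largest_remainder(n_signal, ratio)
  rows <- list()
  for (j in seq_along(ratio)) {
    rg <- names(ratio)[j]
    tlist <- types_in_region(spec, rg,
                             specific_only = types == "region_specific")
    n_per <- largest_remainder(per_region[j], rep(1, length(tlist)))
    for (t in seq_along(tlist))
      if (n_per[t] > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = tlist[t], region = rg, n = n_per[t],
          lineage = lineage_of(spec, tlist[t]))
  }
  blocks <- do.call(rbind, rows)
  cells <- blocks[rep(seq_len(nrow(blocks)), blocks$n), , drop = FALSE]
  cells$n <- NULL
  cells$is_noise <- FALSE
  if (n_noise > 0)
    cells <- rbind(cells, data.frame(
      cell_type = "noise", region = NA_character_,
      lineage = NA_character_, is_noise = TRUE)[rep(1, n_noise), ])
  cells$subregion <- NA_character_
  mid <- which(cells$region %in% "midbrain")
  if (length(mid))
    cells$subregion[mid] <- with_seed(
      derive_seed(seed, "subregion"),
      sample(SUBREGIONS, length(mid), replace = TRUE))
  finalize_dataset(spec, cells, seed, prefix = "mix")
}

types_in_region <- function(spec, region, specific_only = FALSE) {
  keep <- vapply(spec$cell_types$regions, function(r) region %in% r,
                 logical(1))
  if (specific_only) keep <- keep & spec$cell_types$region_specific
  spec$cell_types$cell_type[keep]
}

lineage_of <- function(spec, cell_type) {
  i <- match(cell_type, spec$cell_types$cell_type)
  if (!is.na(i)) return(spec$cell_types$lineage[i])
  j <- match(cell_type, spec$fine_types$cell_type)
  if (!is.na(j)) return(spec$fine_types$lineage[j])
  NA_character_
}

#' Generate a synthetic culture-like query with a designed composition
#'
#' Emulates an in vitro differentiation dataset whose regional and
#' cell-type make-up is fully designed, e.g. mixtures of on-target midbrain
#' and off-target non-midbrain cells. Compositions may name whole-brain
#' cell types (with their region) or midbrain fine types (region must be
#' `midbrain`); fractions must sum to 1. Cell counts follow the fractions
#' exactly (largest remainder).
#'
#' @param spec a `bs_atlas_spec`
#' @param composition `data.frame` with columns `region`, `cell_type`,
#'   `fraction`
#' @param n_cells total number of cells
#' @param timepoint free-text tag recorded in the metadata
#' @param noise_fraction fraction of additional off-manifold noise cells
#' @param seed seed for this draw
#' @return a `bs_dataset`
#' @export
generate_culture_query <- function(spec, composition, n_cells,
                                   timepoint = NA_character_,
                                   noise_fraction = 0, seed = spec$seed) {
  stopifnot(all(c("region", "cell_type", "fraction") %in%
                  names(composition)))
  if (abs(sum(composition$fraction) - 1) > 1e-9)
    stop("composition fractions must sum to 1 (got ",
         signif(sum(composition$fraction), 6), ")")
  fine <- composition$cell_type %in% spec$fine_types$cell_type
  if (any(fine & composition$region != "midbrain"))
    stop("fine midbrain types must have region 'midbrain'")
  n_noise <- round(noise_fraction * n_cells)
  n_signal <- n_cells - n_noise
  n_per <- largest_remainder(n_signal, composition$fraction)
  cells <- composition[rep(seq_len(nrow(composition)), n_per), ,
                       drop = FALSE]
  cells$fraction <- NULL
  cells$lineage <- vapply(cells$cell_type, lineage_of, character(1),
                          spec = spec)
  cells$is_noise <- FALSE
  if (n_noise > 0)
    cells <- rbind(cells, data.frame(
      region = NA_character_, cell_type = "noise",
      lineage = NA_character_, is_noise = TRUE)[rep(1, n_noise), ])
  cells$subregion <- NA_character_
  idx <- match(cells$cell_type, spec$fine_types$cell_type)
  cells$subregion <- ifelse(is.na(idx), NA_character_,
                            spec$fine_types$subregion[idx])
  mid_open <- which(cells$region %in% "midbrain" & is.na(cells$subregion) &
                      !cells$is_noise)
  if (length(mid_open))
    cells$subregion[mid_open] <- with_seed(
      derive_seed(seed, "subregion"),
      sample(SUBREGIONS, length(mid_open), replace = TRUE))
  ds <- finalize_dataset(spec, cells, seed, prefix = "q")
  ds$meta$timepoint <- timepoint
  ds
}

#' Generate midbrain cells along a designed ventral-dorsal gradient
#'
#' Dopaminergic-type midbrain cells whose ventral program is scaled by
#' `levels` (0 = none, 1 = full `subregion_effect`), for checking that the
#' ventral score responds monotonically to ventral identity.
#'
#' @param spec a `bs_atlas_spec`
#' @param levels numeric vector of ventral-program scales in `[0, 1]`
#' @param n_per_level cells per level
#' @param seed seed for this draw
#' @return a `bs_dataset`; the designed scale is in `meta$truth_ventral_scale`
#' @export
generate_ventral_gradient <- function(spec, levels = c(0, 0.5, 1),
                                      n_per_level = 100, seed = spec$seed) {
  stopifnot(all(levels >= 0), all(levels <= 1))
  cells <- data.frame(
    cell_type = "hDA", region = "midbrain", subregion = "ventral",
    lineage = "neuron", is_noise = FALSE,
    subregion_scale = rep(levels, each = n_per_level))
  ds <- finalize_dataset(spec, cells, seed, prefix = "grad")
  ds$meta$truth_ventral_scale <- rep(levels, each = n_per_level)
  ds
}

# Shared tail of all generators: counts, ids, truth metadata.
finalize_dataset <- function(spec, cells, seed, prefix) {
  rownames(cells) <- NULL
  counts <- simulate_counts(spec, cells, seed)
  ids <- sprintf("%s_%05d", prefix, seq_len(nrow(cells)))
  colnames(counts) <- ids
  meta <- data.frame(
    cell_id = ids,
    batch = prefix,
    cell_type = ifelse(cells$is_noise, NA_character_, cells$cell_type),
    region = cells$region,
    subregion = cells$subregion,
    lineage = cells$lineage,
    truth_type = ifelse(cells$is_noise, "noise", cells$cell_type),
    truth_region = cells$region,
    truth_subregion = cells$subregion,
    truth_noise = cells$is_noise,
    stringsAsFactors = FALSE)
  bs_dataset(counts, meta = meta)
}
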