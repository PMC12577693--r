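# Shared fixtures, built once per test run and memoized.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small atlas spec for unit tests: same structure as the default, scaled
# down so reference builds take seconds.
tiny_spec <- function(seed = 42L, ...) {
  synthetic_atlas_spec(n_genes = 600, cells_per_type_per_region = 40,
                       program_size = 10, n_midbrain_cells = 800,
                       seed = seed, ...)
}

tiny_wb <- function() memo("tiny_wb", function() {
  suppressWarnings(build_reference(generate_atlas(tiny_spec()),
                                   tier = "wholebrain"))
})

tiny_mb <- function() memo("tiny_mb", function() {
  suppressWarnings(build_reference(
    generate_midbrain_subatlas(tiny_spec(), seed = 43L),
    tier = "midbrain"))
})

# A small hand-made dataset with a prescribed lognorm layer.
manual_dataset <- function(lognorm, meta = NULL) {
  counts <- Matrix::Matrix(round(expm1(lognorm)), sparse = TRUE)
  dimnames(counts) <- dimnames(lognorm)
  ds <- bs_dataset(counts, meta = meta)
  ln <- Matrix::Matrix(lognorm, sparse = TRUE)
  dimnames(ln) <- dimnames(lognorm)
  ds$lognorm <- methods::as(methods::as(ln, "CsparseMatrix"),
                            "generalMatrix")
  ds
}

random_count_dataset <- function(n_genes, n_cells, seed = 1L,
                                 lambda = 5) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("c%03d", seq_len(n_cells))))
  bs_dataset(Matrix::Matrix(counts, sparse = TRUE))
}

# Study-scale fixtures for the acceptance suite (defaults of the
# synthetic module; built once).
accept_spec <- function() memo("accept_spec", function() {
  synthetic_atlas_spec(seed = 101L)
})

accept_wb <- function() memo("accept_wb", function() {
  suppressWarnings(build_reference(generate_atlas(accept_spec()),
                                   tier = "wholebrain"))
})

accept_mb <- function() memo("accept_mb", function() {
  suppressWarnings(build_reference(
    generate_midbrain_subatlas(accept_spec(), seed = 202L),
    tier = "midbrain"))
})

accept_cfg <- function(seed = 7L) pipeline_config(seed = seed)

# Designed culture composition: midbrain fine types at `mid_frac` plus
# off-target forebrain/hindbrain cells, rare subtype at the spec fraction.
culture_composition <- function(spec, mid_frac = 0.65,
                                mid_props = c(hDA = 0.25, hDA.STN = NA,
                                              hRN = 0.10, hvGaba = 0.15,
                                              hdGaba = 0.15, hGlu = 0.15,
                                              hNProg = 0.20)) {
  rare <- spec$rare_subtype_fraction
  mid_props["hDA.STN"] <- rare
  mid_props["hDA"] <- 1 - sum(mid_props[-1])
  mid <- data.frame(region = "midbrain", cell_type = names(mid_props),
                    fraction = mid_frac * unname(mid_props))
  off <- data.frame(
    region = c("forebrain", "forebrain", "hindbrain", "hindbrain"),
    cell_type = c("Glu N", "Radial glia", "GABA N", "Radial glia"),
    fraction = rep((1 - mid_frac) / 4, 4))
  rbind(mid, off)
}
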