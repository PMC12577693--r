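#' Marker panel container
#'
#' Ordered marker-gene lists per cell type (`type_markers`, descending
#' log2 fold change) and per cell type and brain region (`region_markers`),
#' used for module-score confidence filtering and region assignment. The
#' `region_markers` entry keyed `"*"` holds global per-region marker sets
#' used for cell types without region-resolved markers.
#'
#' @param type_markers named list: cell type -> ordered character vector of
#'   genes
#' @param region_markers named list: cell type (or `"*"`) -> named list:
#'   region -> ordered character vector of genes
#' @param provenance free-text description of how the panel was derived
#' @return an object of class `bs_marker_panel`
#' @export
bs_marker_panel <- function(type_markers, region_markers = list(),
                            provenance = "") {
  check_lists <- function(lists, where) {
    for (nm in names(lists)) {
      g <- lists[[nm]]
      if (!is.character(g) || any(!nzchar(g)))
        stop("marker list ", where, "/", nm, " must be non-empty strings")
      if (anyDuplicated(g))
        stop("duplicate genes in marker list ", where, "/", nm)
    }
  }
  check_lists(type_markers, "type_markers")
  for (ct in names(region_markers)) {
    regs <- names(region_markers[[ct]])
    bad <- setdiff(regs, BRAIN_REGIONS)
    if (length(bad))
      stop("unknown region name(s) in region_markers: ",
           paste(bad, collapse = ", "))
    check_lists(region_markers[[ct]], paste0("region_markers/", ct))
  }
  structure(list(type_markers = type_markers,
                 region_markers = region_markers,
                 provenance = provenance),
            class = "bs_marker_panel")
}

#' @export
print.bs_marker_panel <- function(x, ...) {
  cat(sprintf("bs_marker_panel: %d cell types, %d region-resolved entries\n",
              length(x$type_markers), length(x$region_markers)))
  invisible(x)
}

#' Truncate every marker list of a panel to its top n genes
#' @param panel a `bs_marker_panel`
#' @param n number of leading genes to keep per list
#' @return a truncated `bs_marker_panel`
#' @export
truncate_panel <- function(panel, n) {
  stopifnot(n >= 1)
  top <- function(g) g[seq_len(min(n, length(g)))]
  panel$type_markers <- lapply(panel$type_markers, top)
  panel$region_markers <- lapply(panel$region_markers,
                                 function(rl) lapply(rl, top))
  panel
}

#' Read a marker panel from JSON
#'
#' Expects an object with key `type_markers` (cell type -> gene array) and
#' optionally `region_markers` (cell type -> region -> gene array). Gene
#' order is preserved.
#'
#' @param file path to a JSON file
#' @return a `bs_marker_panel`
#' @export
read_marker_panel <- function(file) {
  if (!file.exists(file)) stop("marker panel file not found: ", file)
  j <- jsonlite::read_json(file, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (is.null(j$type_markers)) stop("marker panel JSON lacks 'type_markers'")
  tm <- lapply(j$type_markers, as.character)
  rm_ <- lapply(j$region_markers %||% list(),
                function(rl) lapply(rl, as.character))
  bs_marker_panel(tm, rm_, provenance = j$provenance %||% "")
}

#' Write a marker panel to JSON
#' @param panel a `bs_marker_panel`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_marker_panel <- function(panel, file) {
  jsonlite::write_json(list(type_markers = panel$type_markers,
                            region_markers = panel$region_markers,
                            provenance = panel$provenance),
                       file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
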