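#' @keywords internal
"_PACKAGE"

# Columns every cell table must carry; n_patches, x, y are optional on input.
.cell_required_cols <- c("cell_id", "district_id", "area", "d0",
                         "tc_first", "tc_within")
.cell_optional_cols <- c("n_patches", "x", "y")
.district_required_cols <- c("district_id", "mean_profit")

#' Construct a landscape object
#'
#' A landscape is the unit of analysis for the simulator: a set of grid cells
#' (typically 20 x 20 km, i.e. 40,000 ha) nested in districts. Each cell
#' carries its baseline annual deforestation and the cost of inspecting it;
#' each district carries the mean per-hectare profit of deforestation (the
#' conservation opportunity cost) that is later disaggregated to cells.
#'
#' @param cells data.frame with columns `cell_id`, `district_id`, `area` (ha),
#'   `d0` (baseline deforestation, ha/yr), `tc_first` (cost of inspecting the
#'   first deforestation patch, BRL), `tc_within` (average cost per additional
#'   patch, BRL), and optionally `n_patches`, `x`, `y` (cell centroids, km).
#'   A missing `n_patches` column is filled from `d0` via [patches_from_area()].
#' @param districts data.frame with columns `district_id`, `mean_profit`
#'   (BRL/ha).
#' @param metadata free-form provenance list (source, seed, generator
#'   parameters).
#' @param patches_per_ha coefficient used when `n_patches` must be derived.
#' @return An object of class `landscape`.
#' @seealso [read_landscape()], [generate_synthetic_landscape()]
#' @export
landscape <- function(cells, districts, metadata = list(),
                      patches_per_ha = 0.035) {
  cells <- as.data.frame(cells)
  districts <- as.data.frame(districts)
  if (!"n_patches" %in% names(cells)) {
    cells$n_patches <- patches_from_area(cells$d0, patches_per_ha)
  }
  na_patch <- is.na(cells$n_patches)
  if (any(na_patch)) {
    cells$n_patches[na_patch] <- patches_from_area(cells$d0[na_patch],
                                                   patches_per_ha)
  }
  obj <- structure(list(cells = cells, districts = districts,
                        metadata = metadata),
                   class = "landscape")
  validate_landscape(obj)
  obj
}

#' Validate a landscape object
#'
#' Checks the schema and the cell/district invariants: positive areas,
#' `0 <= d0 <= area`, non-negative inspection costs, unique identifiers, and
#' referential integrity between cells and districts. Violations raise an
#' error listing the offending columns or rows.
#'
#' @param x a `landscape`.
#' @return `x`, invisibly, if valid.
#' @export
validate_landscape <- function(x) {
  stopifnot(inherits(x, "landscape"))
  cells <- x$cells
  districts <- x$districts
  miss <- setdiff(.cell_required_cols, names(cells))
  if (length(miss) > 0L) {
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(.district_required_cols, names(districts))
  if (length(miss) > 0L) {
    stop("district table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(cells) < 1L) stop("landscape must contain at least one cell",
                             call. = FALSE)
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell_id values: ",
         paste(unique(cells$cell_id[duplicated(cells$cell_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(districts$district_id)) {
    stop("duplicate district_id values in district table", call. = FALSE)
  }
  orphan <- !(cells$district_id %in% districts$district_id)
  if (any(orphan)) {
    stop("cell(s) reference unknown district_id: cell_id ",
         paste(cells$cell_id[orphan], collapse = ", "), call. = FALSE)
  }
  bad <- which(!(cells$area > 0) |
                 cells$d0 < 0 | cells$d0 > cells$area |
                 cells$tc_first < 0 | cells$tc_within < 0 |
                 cells$n_patches < 0)
  if (length(bad) > 0L) {
    stop("cell invariant violated (need area > 0, 0 <= d0 <= area, ",
         "non-negative costs and patch counts) in row(s): ",
         paste(bad, collapse = ", "), " (cell_id ",
         paste(cells$cell_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  deforesting <- tapply(cells$d0, cells$district_id, function(d) any(d > 0))
  mp <- districts$mean_profit[match(names(deforesting),
                                    districts$district_id)]
  bad_d <- names(deforesting)[deforesting & !(mp > 0)]
  if (length(bad_d) > 0L) {
    stop("district(s) with deforesting cells must have mean_profit > 0: ",
         paste(bad_d, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", nrow(x$cells), " cells in ", nrow(x$districts),
      " district(s)\n", sep = "")
  cat("  total baseline deforestation: ",
      format(sum(x$cells$d0), big.mark = ","), " ha/yr\n", sep = "")
  if (!is.null(x$metadata$source)) {
    cat("  source: ", x$metadata$source, "\n", sep = "")
  }
  invisible(x)
}

#' Expected number of deforestation patches in a cell
#'
#' Patch counts scale linearly with cleared area; the default coefficient of
#' 0.035 patches per hectare reflects the historical patch density of Amazon
#' deforestation. Values are kept fractional (expected counts): the patch
#' term in the inspection-cost budget is an expected cost, and rounding would
#' introduce artificial discontinuities in parameter sweeps.
#'
#' @param d0 deforestation, ha (vectorized).
#' @param patches_per_ha patches per hectare of deforestation.
#' @return expected patch count(s).
#' @examples
#' patches_from_area(1000)  # 35
#' @export
patches_from_area <- function(d0, patches_per_ha = 0.035) {
  if (any(d0 < 0, na.rm = TRUE)) {
    stop("d0 must be non-negative", call. = FALSE)
  }
  patches_per_ha * d0
}

#' Read a landscape from delimited text files
#'
#' Reads the canonical tabular landscape format: a cell table and a district
#' table, both CSV with a header row and columns named exactly as the
#' `landscape()` fields. A missing `n_patches` column is derived from `d0`.
#'
#' @param cells_path path to the cell CSV.
#' @param districts_path path to the district CSV.
#' @param patches_per_ha coefficient for derived patch counts.
#' @return a validated `landscape`.
#' @export
read_landscape <- function(cells_path, districts_path,
                           patches_per_ha = 0.035) {
  for (p in c(cells_path, districts_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  districts <- utils::read.csv(districts_path, stringsAsFactors = FALSE)
  landscape(cells, districts,
            metadata = list(source = "file", cells_path = cells_path,
                            districts_path = districts_path),
            patches_per_ha = patches_per_ha)
}

#' Write a landscape to delimited text files
#'
#' Inverse of [read_landscape()]; numeric fields round-trip at better than
#' 1e-9 relative precision.
#'
#' @param x a `landscape`.
#' @param cells_path,districts_path output CSV paths.
#' @return `x`, invisibly.
#' @export
write_landscape <- function(x, cells_path, districts_path) {
  validate_landscape(x)
  utils::write.csv(x$cells, cells_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$districts, districts_path, row.names = FALSE,
                   quote = FALSE)
  invisible(x)
}
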