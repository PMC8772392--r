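#' Land-class code table
#'
#' Integer codes used on disk and in `land_class` matrices. Urban fractions
#' follow the standard land-cover convention: 50% for low-intensity
#' residential, 90% for high-intensity residential, 95% for
#' industrial/commercial, and 0% for open water and vegetation.
#'
#' @format Named integer vector mapping class name to code.
#' @export
land_class_codes <- c(
  open_water                 = 0L,
  vegetation                 = 1L,
  low_intensity_residential  = 2L,
  high_intensity_residential = 3L,
  industrial_commercial      = 4L
)

#' Canonical urban fraction for each land class
#' @format Named numeric vector (dimensionless fraction in \[0, 1\]).
#' @export
class_urban_fraction <- c(
  open_water                 = 0,
  vegetation                 = 0,
  low_intensity_residential  = 0.50,
  high_intensity_residential = 0.90,
  industrial_commercial      = 0.95
)

#' Construct an urban surface grid
#'
#' Static per-cell description of the domain: urban fraction (URB_FRC) and a
#' categorical land class. Grid coordinates are 0-based `(row, col)` with row
#' 0 at the north edge; there is no geographic projection.
#'
#' @param urban_fraction numeric matrix (n_y x n_x), values in \[0, 1\].
#' @param land_class character matrix of the same shape with values from
#'   `names(land_class_codes)`.
#' @param cell_size cell edge length in km (metadata only).
#' @return An object of class `urban_surface`: list with `n_y`, `n_x`,
#'   `cell_size`, `urban_fraction`, `land_class`.
#' @export
urban_surface <- function(urban_fraction, land_class, cell_size = 1) {
  if (!is.matrix(urban_fraction) || !is.matrix(land_class))
    stop("urban_fraction and land_class must be matrices", call. = FALSE)
  if (!identical(dim(urban_fraction), dim(land_class)))
    stop("urban_fraction and land_class dimensions differ", call. = FALSE)
  bad <- !(land_class %in% names(land_class_codes))
  if (any(bad))
    stop("unknown land class: ", paste(unique(land_class[bad]), collapse = ", "),
         call. = FALSE)
  if (any(urban_fraction < 0 | urban_fraction > 1, na.rm = TRUE))
    stop("urban_fraction outside [0, 1]", call. = FALSE)
  zero_cls <- land_class %in% c("open_water", "vegetation")
  if (any(urban_fraction[zero_cls] != 0))
    stop("urban_fraction must be 0 on open_water and vegetation cells",
         call. = FALSE)
  structure(
    list(n_y = nrow(urban_fraction), n_x = ncol(urban_fraction),
         cell_size = cell_size, urban_fraction = urban_fraction,
         land_class = land_class),
    class = "urban_surface")
}

#' Generate a categorical synthetic urban surface
#'
#' Lays out concentric land-class rings around an urban core — industrial/
#' commercial, high-intensity residential, low-intensity residential, then
#' vegetation — with the canonical urban fractions 0.95/0.90/0.50/0, and an
#' open-water lake band on the easternmost columns (fraction 0). Emulates an
#' aggregated land-cover map of a coastal city.
#'
#' @param n_y,n_x grid rows and columns.
#' @param urban_center `(row, col)` of the urban core, 0-based.
#' @param class_radii four strictly increasing radii (in cells): outer edge of
#'   the industrial, high-residential and low-residential rings, plus the
#'   nominal rural extent (validated but every cell beyond the third radius is
#'   vegetation).
#' @param lake_cols number of easternmost columns set to open water.
#' @param cell_size cell edge length in km.
#' @param seed accepted for interface uniformity with the other generators;
#'   the categorical layout is deterministic, so it is unused.
#' @return An `urban_surface`.
#' @export
generate_surface <- function(n_y, n_x,
                             urban_center = c(round(n_y / 2), round(n_x * 0.8)),
                             class_radii = c(4, 7, 10, 14),
                             lake_cols = 2, cell_size = 1, seed = NULL) {
  if (length(class_radii) != 4 || any(diff(class_radii) <= 0))
    stop("class_radii must be four strictly increasing values", call. = FALSE)
  if (max(class_radii) > max(n_y, n_x))
    stop("class_radii exceed the grid size", call. = FALSE)
  if (lake_cols >= n_x)
    stop("lake_cols must be smaller than n_x", call. = FALSE)

  row0 <- urban_center[1]; col0 <- urban_center[2]
  d <- sqrt(outer((seq_len(n_y) - 1 - row0)^2, (seq_len(n_x) - 1 - col0)^2, "+"))
  cls <- matrix("vegetation", n_y, n_x)
  cls[d <= class_radii[3]] <- "low_intensity_residential"
  cls[d <= class_radii[2]] <- "high_intensity_residential"
  cls[d <= class_radii[1]] <- "industrial_commercial"
  if (lake_cols > 0) cls[, seq(n_x - lake_cols + 1, n_x)] <- "open_water"
  frac <- matrix(class_urban_fraction[cls], n_y, n_x)
  urban_surface(frac, cls, cell_size = cell_size)
}

#' @export
print.urban_surface <- function(x, ...) {
  tab <- table(factor(x$land_class, levels = names(land_class_codes)))
  cat(sprintf("urban_surface: %d x %d cells (%.3g km)\n", x$n_y, x$n_x, x$cell_size))
  for (nm in names(tab)) cat(sprintf("  %-27s %d\n", nm, tab[[nm]]))
  invisible(x)
}

# logical matrix of land (non-water) cells
is_land <- function(surface) surface$land_class != "open_water"
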