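#' Voxel grid of activity concentration
#'
#' The basic image container: a 3D scalar field with voxel spacing and a
#' world-coordinate origin. Values are activity concentration in Bq/ml for
#' ground-truth and reconstructed images, or expected/observed counts after
#' [to_counts()]. Coordinates are world millimetres, right-handed; voxel
#' index `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 1) * spacing`, and a voxel's value is the mean
#' concentration over its cube.
#'
#' @param values 3D numeric array. All values must be finite.
#' @param spacing Voxel spacing in mm; length 1 (isotropic) or 3.
#' @param origin World coordinate (mm) of the centre of voxel `(1, 1, 1)`.
#'   Default centres the grid on the world origin.
#' @param units Either `"Bq/ml"` or `"counts"`.
#' @return An object of class `voxel_grid` with fields `values`, `spacing`,
#'   `origin` and `units`.
#' @seealso [total_activity()], [voxelize()], [read_volume()]
#' @export
voxel_grid <- function(values, spacing, origin = NULL, units = "Bq/ml") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!all(is.finite(values)))
    stop("voxel values must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 1 or 3 positive finite numbers (mm)")
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  units <- match.arg(units, c("Bq/ml", "counts"))
  structure(
    list(values = values, spacing = spacing, origin = origin, units = units),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Voxel volume in millilitres
#'
#' @param grid A [voxel_grid()].
#' @return `prod(spacing) / 1000` (mm^3 to ml).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing) / 1000
}

#' Total activity on a grid
#'
#' Sum of all voxel values times the voxel volume. For a concentration grid
#' (Bq/ml) this is the total activity in Bq; for a counts grid it is the sum
#' of counts times voxel volume and is mainly useful as a conservation
#' check.
#'
#' @param grid A [voxel_grid()].
#' @return A scalar (Bq for concentration grids).
#' @export
total_activity <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  sum(grid$values) * voxel_volume_ml(grid)
}

# World coordinates of voxel centres along one axis.
axis_centers <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

# TRUE if the two grids share shape, spacing and origin (to tolerance).
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "), x$units))
  cat(sprintf("  origin (%s) mm; total = %.6g %s\n",
              paste(signif(x$origin, 5), collapse = ", "),
              total_activity(x),
              if (x$units == "Bq/ml") "Bq" else "counts*ml"))
  invisible(x)
}
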