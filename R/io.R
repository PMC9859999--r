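#' Read / write a voxel grid as NIfTI-1
#'
#' Volumes are stored float32 with voxel spacing in the header `pixdim`
#' (mm) and the grid origin in the qform offset. Intensity is activity
#' concentration in Bq/ml unless `units = "counts"` is given at read time
#' (the format itself does not carry a unit). In-memory math is float64,
#' so a write/read round trip agrees to float32 storage tolerance.
#'
#' @param grid A [voxel_grid()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param units Unit tag to attach on read (`"Bq/ml"` or `"counts"`).
#' @return `read_volume` returns a [voxel_grid()]; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  n <- dim(grid$values)
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, n, 1L, 1L, 1L, 1L),
    pixdim = c(1, grid$spacing, 1, 1, 1, 1),
    qform_code = 1L, quatern_b = 0, quatern_c = 0, quatern_d = 0,
    qoffset_x = grid$origin[1], qoffset_y = grid$origin[2],
    qoffset_z = grid$origin[3]))
  img <- RNifti::asNifti(grid$values, reference = hdr, internal = FALSE)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, units = "Bq/ml") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got %d dimensions", length(d)))
  hdr <- RNifti::niftiHeader(img)
  spacing <- as.numeric(hdr$pixdim[2:4])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume header is missing positive voxel spacing")
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (hdr$qform_code == 0L) origin <- -(d - 1) / 2 * spacing
  voxel_grid(array(as.numeric(img), d), spacing, origin, units = units)
}

#' Write a quantification table as CSV
#'
#' Fixed column order, header row included; round-trips losslessly
#' through [utils::read.csv()].
#'
#' @param table A data.frame (e.g. from [quantify_phantom()] or a study).
#' @param path Output path.
#' @export
write_quant_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
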