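# Volumetric I/O through RNifti. Maps on a volume_grid store one value per
# masked-in voxel (column-major voxel order); on disk the full grid is
# written with NaN outside the mask, which NIFTI float data preserve.

#' Read and write volumetric scalar maps (NIFTI)
#'
#' @param path a `.nii` or `.nii.gz` file path.
#' @param grid optional [volume_grid()]; when omitted the grid is rebuilt
#'   from the file (mask = finite, non-NaN voxels).
#' @return [read_volume_map()] returns a list with elements `map` (a
#'   [scalar_map()]) and `grid` (a [volume_grid()]).
#' @export
read_volume_map <- function(path, grid = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop_format(path, ": not readable as NIFTI: ", conditionMessage(e))
  })
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop_format(path, ": expected a 3-D volume, got dimensionality ",
                length(dim(arr)))
  }
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (is.null(grid)) {
    mask <- is.finite(arr)
    grid <- volume_grid(dim(arr), affine, mask)
  } else {
    if (!all(dim(arr) == grid$shape)) {
      stop_format(path, ": volume shape ", paste(dim(arr), collapse = "x"),
                  " does not match declared grid ",
                  paste(grid$shape, collapse = "x"))
    }
  }
  values <- arr[grid$mask]
  list(map = scalar_map(values, grid,
                        name = sub("\\.nii(\\.gz)?$", "", basename(path))),
       grid = grid)
}

#' @param map a [scalar_map()] on a [volume_grid()].
#' @rdname read_volume_map
#' @export
write_volume_map <- function(map, path) {
  grid <- map$space
  if (!inherits(grid, "volume_grid")) {
    stop_invalid("write_volume_map() needs a map on a volume_grid")
  }
  arr <- array(NaN, dim = grid$shape)
  values <- map$values
  values[!map$mask] <- NaN
  arr[grid$mask] <- values
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
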