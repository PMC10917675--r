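#' Read a NIfTI-1 volume
#'
#' Loads a single 3D NIfTI volume (`.nii` / `.nii.gz`) as a [voxel_volume()].
#' NaN voxels (a common background convention) are replaced by 0 with a
#' warning, so downstream statistics never see non-finite values. A units tag
#' written by [save_volume()] is recovered from the sidecar JSON when present.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [voxel_volume()].
#' @seealso [save_volume()]
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read '", path, "' as NIfTI: ",
                                           conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L)
    stop("'", path, "' is not a single 3D volume (dims: ",
         paste(dim(arr), collapse = "x"), ")")
  nbad <- sum(!is.finite(arr))
  if (nbad > 0) {
    warning(sprintf("%d non-finite voxel(s) in '%s' set to 0", nbad, path))
    arr[!is.finite(arr)] <- 0
  }
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  units <- "unitless"
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$units)) units <- meta$units
  }
  voxel_volume(unclass(arr), affine, units)
}

#' Write a volume as NIfTI-1
#'
#' Writes float32 data with the volume's affine as sform/qform, plus a small
#' JSON sidecar (`<file>.json`) carrying the units tag so that
#' [load_volume()] round-trips it.
#'
#' @param volume a [voxel_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  img <- RNifti::asNifti(volume$data)
  # sform only: a general affine (possibly sheared) has no exact quaternion
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  tryCatch(RNifti::writeNifti(img, path, datatype = "float"),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  jsonlite::write_json(list(units = volume$units), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}
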