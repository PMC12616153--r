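#' Volumetric containers
#'
#' Lightweight containers for 3D maps, 4D BOLD series, and integer-labeled
#' atlases. `volume3d` wraps a 3D array plus voxel size (mm); `volume4d`
#' additionally carries the repetition time `tr` (seconds); `atlas_volume`
#' wraps an integer label array plus a `label_map` data frame (`label`,
#' `roi`, `hemisphere`) with 0 reserved for background.
#'
#' @param data Numeric array (3D, or 3D x time for `volume4d`).
#' @param voxel_mm Numeric length-3 voxel size in mm, all > 0.
#' @param tr Repetition time in seconds (> 0), `volume4d` only.
#' @return An object of the corresponding class.
#' @name volumes
NULL

#' @rdname volumes
#' @export
volume3d <- function(data, voxel_mm = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(voxel_mm) == 3L, all(voxel_mm > 0))
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm)),
            class = "volume3d")
}

#' @rdname volumes
#' @export
volume4d <- function(data, tr, voxel_mm = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            length(voxel_mm) == 3L, all(voxel_mm > 0))
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive", call. = FALSE)
  if (dim(data)[4] < 8L) {
    stop("4D volumes need >= 8 time points for spectral estimation",
         call. = FALSE)
  }
  structure(list(data = data, tr = as.numeric(tr),
                 voxel_mm = as.numeric(voxel_mm)),
            class = "volume4d")
}

#' @param label_map Data frame with columns `label` (nonzero integers),
#'   `roi`, `hemisphere` ("L"/"R").
#' @rdname volumes
#' @export
atlas_volume <- function(data, label_map, voxel_mm = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.data.frame(label_map) ||
      !all(c("label", "roi", "hemisphere") %in% names(label_map))) {
    stop("label_map needs columns label, roi, hemisphere", call. = FALSE)
  }
  present <- setdiff(unique(as.vector(data)), 0)
  unknown <- setdiff(present, label_map$label)
  if (length(unknown)) {
    stop("atlas labels missing from label_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(data = data, label_map = tibble::as_tibble(label_map),
                 voxel_mm = as.numeric(voxel_mm)),
            class = "atlas_volume")
}

as_vol_array <- function(vol) {
  if (inherits(vol, c("volume3d", "volume4d", "atlas_volume"))) {
    vol$data
  } else if (is.array(vol)) {
    vol
  } else {
    stop("expected a volume object or an array", call. = FALSE)
  }
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over \pkg{RNifti}. Writing stores voxel size (and TR for 4D
#' series) in the NIfTI `pixdim`; reading recovers them. The affine is an
#' isotropic diagonal map built from the voxel size.
#'
#' @param vol A `volume3d`, `volume4d`, or `atlas_volume`.
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; `read_volume3d` /
#'   `read_volume4d` return the corresponding container.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_volume <- function(vol, path) {
  arr <- as_vol_array(vol)
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- vol$voxel_mm
  if (inherits(vol, "volume4d")) pd[4] <- vol$tr
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume3d <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  volume3d(arr, voxel_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname nifti_io
#' @export
read_volume4d <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  pd <- RNifti::pixdim(img)
  volume4d(arr, tr = pd[4], voxel_mm = pd[1:3])
}
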