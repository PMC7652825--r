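#' Read a scalar NIfTI volume
#'
#' Reads a 3-D NIfTI file and derives the grid geometry from its header:
#' voxel sizes from pixdim and the B0 direction from the affine (the
#' component of the scanner inferior-superior axis along each array axis),
#' unless overridden.
#'
#' @param path NIfTI-1/2 file.
#' @param larmor_mhz Larmor frequency to attach to the geometry.
#' @param b0 optional override of the B0 direction in array coordinates.
#' @return list with `data` (numeric array) and `geometry`
#'   (a [vol_geometry()]).
#' @export
read_volume <- function(path, larmor_mhz = 123.2, b0 = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D volume: ", path)
  geom <- geometry_from_header(img, larmor_mhz, b0)
  list(data = arr, geometry = geom)
}

geometry_from_header <- function(img, larmor_mhz, b0 = NULL) {
  vox <- abs(RNifti::pixdim(img))[1:3]
  A <- unclass(RNifti::xform(img))[1:3, 1:3]
  if (!all(is.finite(A)) || abs(det(A)) < 1e-12) {
    stop("NIfTI affine is missing or degenerate; cannot derive geometry")
  }
  if (is.null(b0)) b0 <- b0_from_affine(A)
  vol_geometry(dim(img)[1:3], vox, b0 = b0, larmor_mhz = larmor_mhz)
}

# B0 (scanner z) direction expressed along the (normalized) array axes
b0_from_affine <- function(A) {
  cols <- sweep(A, 2, sqrt(colSums(A^2)), `/`)
  b <- as.numeric(t(cols) %*% c(0, 0, 1))
  nb <- sqrt(sum(b^2))
  if (nb < 1e-9) stop("cannot derive a B0 direction from the affine")
  b / nb
}

#' Write a scalar volume as NIfTI
#'
#' @param data 3-D numeric array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param geometry a [vol_geometry()] supplying the voxel size.
#' @return the path, invisibly.
#' @export
write_volume <- function(data, path, geometry) {
  stopifnot_geometry(geometry)
  img <- RNifti::asNifti(data + 0) # force numeric storage
  RNifti::pixdim(img) <- geometry$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read multi-echo GRE data as magnitude/phase NIfTI pairs
#'
#' The complex data are stored as two 5-D NIfTI files indexed
#' `(x, y, z, echo, channel)`: magnitude and phase (radians).
#'
#' @param gre a [multiecho_gre()].
#' @param mag_path,phase_path output files.
#' @return the two paths, invisibly.
#' @export
write_multiecho_gre <- function(gre, mag_path, phase_path) {
  if (!inherits(gre, "multiecho_gre")) stop("`gre` must be a multiecho_gre")
  mag <- RNifti::asNifti(Mod(gre$data))
  ph <- RNifti::asNifti(Arg(gre$data))
  RNifti::pixdim(mag) <- gre$geometry$voxel_mm
  RNifti::pixdim(ph) <- gre$geometry$voxel_mm
  RNifti::writeNifti(mag, mag_path)
  RNifti::writeNifti(ph, phase_path)
  invisible(c(mag_path, phase_path))
}

#' @rdname write_multiecho_gre
#' @param te_s echo times in seconds (must match the echo dimension).
#' @param larmor_mhz,b0 geometry overrides, as in [read_volume()].
#' @export
read_multiecho_gre <- function(mag_path, phase_path, te_s,
                               larmor_mhz = 123.2, b0 = NULL) {
  mag <- RNifti::readNifti(mag_path)
  ph <- RNifti::readNifti(phase_path)
  am <- as.array(mag)
  ap <- as.array(ph)
  if (!identical(dim(am), dim(ap))) stop("magnitude and phase dimensions differ")
  d <- dim(am)
  if (length(d) == 4L) {
    dim(am) <- c(d, 1L)
    dim(ap) <- c(d, 1L)
  } else if (length(d) != 5L) {
    stop("expected 4-D or 5-D multi-echo data (x, y, z, echo[, channel])")
  }
  geom <- geometry_from_header(mag, larmor_mhz, b0)
  multiecho_gre(am * exp(1i * ap), te_s, geom)
}

#' JSON sidecar helpers
#'
#' Every artifact written by the pipeline is accompanied by a JSON sidecar
#' recording the parameters (and seed) needed to reproduce it.
#'
#' @param x a list of parameters.
#' @param path sidecar path (`.json`).
#' @return `write_sidecar` returns the path invisibly; `read_sidecar` the
#'   parsed list.
#' @export
write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
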