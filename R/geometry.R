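#' Volume geometry
#'
#' Describes the 3-D sampling grid shared by all maps in the pipeline: grid
#' shape, voxel size, the main-field (B0) direction expressed in array
#' coordinates, and the proton Larmor frequency used to convert between field
#' shifts in Hz and susceptibility-scale shifts in ppm.
#'
#' Array axis conventions used throughout the package: axis 1 runs left to
#' right (LR), axis 2 anterior to posterior (AP, increasing index = more
#' posterior), axis 3 inferior to superior (IS). "Axial slice" always means a
#' fixed index along axis 3.
#'
#' @param shape integer vector of length 3, grid dimensions.
#' @param voxel_mm numeric vector of length 3, voxel edge lengths in mm.
#' @param b0 unit 3-vector, static field direction in array coordinates.
#' @param larmor_mhz proton Larmor frequency in MHz (123.2 at 3 T). With this
#'   convention `field_hz = chi_ppm * larmor_mhz`.
#' @param axis_roles character vector naming the anatomical role of each axis.
#' @return an object of class `vol_geometry`.
#' @export
vol_geometry <- function(shape, voxel_mm = c(0.53, 0.53, 0.8),
                         b0 = c(0, 0, 1), larmor_mhz = 123.2,
                         axis_roles = c("LR", "AP", "IS")) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be 3 positive integers")
  }
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0)) {
    stop("`voxel_mm` must be 3 positive reals")
  }
  nb <- sqrt(sum(b0^2))
  if (abs(nb - 1) > 1e-6) {
    stop("`b0` must be a unit vector (|b0| = 1)")
  }
  b0 <- b0 / nb
  if (larmor_mhz <= 0) stop("`larmor_mhz` must be positive")
  structure(
    list(shape = shape, voxel_mm = as.numeric(voxel_mm), b0 = as.numeric(b0),
         larmor_mhz = larmor_mhz, axis_roles = axis_roles),
    class = "vol_geometry"
  )
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat("<vol_geometry> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_mm, 3), collapse = " x "),
      " mm, B0 = (", paste(signif(x$b0, 3), collapse = ", "),
      "), f0 = ", x$larmor_mhz, " MHz\n", sep = "")
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param geometry a [vol_geometry()].
#' @export
voxel_volume_mm3 <- function(geometry) prod(geometry$voxel_mm)

#' In-plane (2-D) ROI volume
#'
#' Volume of an axial single-slice ROI given its voxel count, i.e.
#' `n * prod(voxel_mm)`.
#' @param n_voxels voxel count (may be fractional, e.g. a cohort average).
#' @param geometry a [vol_geometry()].
#' @export
roi_volume_mm3 <- function(n_voxels, geometry) n_voxels * voxel_volume_mm3(geometry)

stopifnot_geometry <- function(geometry) {
  if (!inherits(geometry, "vol_geometry")) stop("expected a `vol_geometry` object")
  invisible(geometry)
}

## ---- internal FFT helpers -------------------------------------------------

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

# Padded FFT dimensions: next power of two holding the grid plus at least
# 8 voxels of margin, to suppress circular wrap-around in convolutions.
pad_dims <- function(shape, margin = 8L) next_pow2(as.integer(shape) + margin)

fftn <- function(x) stats::fft(x)
ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

pad3 <- function(x, pdims) {
  d <- dim(x)
  out <- array(0, dim = pdims)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

unpad3 <- function(x, shape) {
  x[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), drop = FALSE]
}

# FFT sample frequencies along one axis, in cycles/mm.
fft_freq <- function(n, voxel) {
  i <- seq_len(n) - 1L
  ifelse(i <= n %/% 2, i, i - n) / (n * voxel)
}

# Broadcast a per-axis vector into a 3-D array along `along`.
axis_array <- function(v, dims, along) {
  switch(along,
         array(v, dim = dims),
         array(rep(rep(v, each = dims[1]), times = dims[3]), dim = dims),
         array(rep(v, each = dims[1] * dims[2]), dim = dims))
}

# Unit dipole kernel on the padded grid, i.e. the transfer function whose
# continuum limit is D(k) = 1/3 - (k.b0)^2/|k|^2 with D(0) = 0. It is
# generated in image space -- the Lorentz-corrected point dipole
# d(r) = (3 cos^2(theta) - 1) / (4 pi r^3) sampled at voxel offsets, zero at
# the origin, scaled by the voxel volume -- and transformed. This makes FFT
# convolution agree with the direct spatial dipole sum to machine precision
# (sampling the analytic D(k) instead aliases badly near the principal
# axes for point-like sources). The k = 0 sample is forced to zero.
dipole_kernel <- function(dims, voxel_mm, b0) {
  rx <- wrapped_offsets(dims[1], voxel_mm[1])
  ry <- wrapped_offsets(dims[2], voxel_mm[2])
  rz <- wrapped_offsets(dims[3], voxel_mm[3])
  RX <- axis_array(rx, dims, 1)
  RY <- axis_array(ry, dims, 2)
  RZ <- axis_array(rz, dims, 3)
  R2 <- RX^2 + RY^2 + RZ^2
  RB <- RX * b0[1] + RY * b0[2] + RZ * b0[3]
  R2[R2 == 0] <- Inf # origin voxel carries no self-shift
  d <- (3 * RB^2 / R2 - 1) / (4 * pi * R2^1.5) * prod(voxel_mm)
  D <- Re(fftn(d)) # d is even-symmetric, so its DFT is real
  D[1, 1, 1] <- 0
  D
}

# signed voxel-centre offsets (mm) of a wrapped FFT grid axis
wrapped_offsets <- function(n, voxel) {
  i <- seq_len(n) - 1L
  ifelse(i <= n %/% 2, i, i - n) * voxel
}

# Squared spatial frequency magnitude (2*pi*k)^2, for spectral Laplacians.
laplace_k2 <- function(dims, voxel_mm) {
  kx <- fft_freq(dims[1], voxel_mm[1])
  ky <- fft_freq(dims[2], voxel_mm[2])
  kz <- fft_freq(dims[3], voxel_mm[3])
  (2 * pi)^2 * (axis_array(kx, dims, 1)^2 +
                axis_array(ky, dims, 2)^2 +
                axis_array(kz, dims, 3)^2)
}

# Normalized spherical kernel of physical radius r (mm), centred at the
# origin voxel of a padded grid (wrapped), ready for FFT convolution.
sphere_kernel <- function(dims, voxel_mm, radius_mm) {
  rx <- seq_len(dims[1]) - 1L
  rx <- ifelse(rx <= dims[1] %/% 2, rx, rx - dims[1]) * voxel_mm[1]
  ry <- seq_len(dims[2]) - 1L
  ry <- ifelse(ry <= dims[2] %/% 2, ry, ry - dims[2]) * voxel_mm[2]
  rz <- seq_len(dims[3]) - 1L
  rz <- ifelse(rz <= dims[3] %/% 2, rz, rz - dims[3]) * voxel_mm[3]
  R2 <- axis_array(rx^2, dims, 1) + axis_array(ry^2, dims, 2) +
    axis_array(rz^2, dims, 3)
  ker <- (R2 <= radius_mm^2) * 1
  s <- sum(ker)
  if (s == 0) stop("sphere kernel radius smaller than one voxel")
  ker / s
}
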