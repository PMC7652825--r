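#' Multi-echo gradient-echo data
#'
#' Container for complex multi-echo GRE data. The data array is indexed
#' `(x, y, z, echo, channel)`; echo times are in seconds and strictly
#' ascending.
#'
#' @param data complex 5-D array `(x, y, z, echo, channel)`.
#' @param te_s numeric vector of echo times in seconds.
#' @param geometry a [vol_geometry()].
#' @export
multiecho_gre <- function(data, te_s, geometry) {
  stopifnot_geometry(geometry)
  d <- dim(data)
  if (length(d) == 4L) {
    dim(data) <- c(d, 1L)
    d <- dim(data)
  }
  if (length(d) != 5L) stop("`data` must be a 4-D or 5-D array")
  if (!all(d[1:3] == geometry$shape)) stop("data grid does not match geometry")
  if (d[4] != length(te_s)) stop("echo dimension must match length(te_s)")
  if (length(te_s) > 1 && any(diff(te_s) <= 0)) stop("`te_s` must be strictly increasing")
  if (any(te_s <= 0)) stop("`te_s` must be positive")
  structure(list(data = data, te_s = as.numeric(te_s), geometry = geometry),
            class = "multiecho_gre")
}

#' @export
print.multiecho_gre <- function(x, ...) {
  d <- dim(x$data)
  cat("<multiecho_gre> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " echoes (TE ", signif(min(x$te_s) * 1e3, 3), "-",
      signif(max(x$te_s) * 1e3, 3), " ms), ", d[5], " channel(s)\n", sep = "")
  invisible(x)
}

n_channels <- function(gre) dim(gre$data)[5]
n_echoes <- function(gre) dim(gre$data)[4]

#' Field map container
#'
#' A scalar field-offset volume in Hz with a validity mask and simple
#' inhomogeneity diagnostics (standard deviation over the mask and the
#' maximum in-mask field gradient in Hz/cm).
#'
#' @param values 3-D numeric array, field offset in Hz.
#' @param mask logical array of the same shape.
#' @param geometry a [vol_geometry()].
#' @param diagnostics optional list; computed from `values`/`mask` if `NULL`.
#' @export
field_map <- function(values, mask = NULL, geometry, diagnostics = NULL) {
  stopifnot_geometry(geometry)
  if (is.null(mask)) mask <- array(TRUE, dim = geometry$shape)
  mask <- array(as.logical(mask), dim = geometry$shape)
  if (any(!is.finite(values[mask]))) stop("field values must be finite inside the mask")
  if (is.null(diagnostics)) diagnostics <- field_diagnostics(values, mask, geometry)
  structure(list(values = values, mask = mask, geometry = geometry,
                 diagnostics = diagnostics),
            class = "field_map")
}

field_diagnostics <- function(values, mask, geometry) {
  grad_max <- 0
  for (ax in 1:3) {
    dv <- subset_along(values, ax, -1L) - subset_along(values, ax, 1L)
    dm <- subset_along(mask, ax, -1L) & subset_along(mask, ax, 1L)
    if (any(dm)) {
      grad_max <- max(grad_max,
                      max(abs(dv[dm])) / (geometry$voxel_mm[ax] / 10)) # Hz/cm
    }
  }
  list(sigma_b0_hz = stats::sd(values[mask]), max_gradient_hz_per_cm = grad_max)
}

# drop the first (`side = 1`) or last (`side = -1`) plane along axis `ax`
subset_along <- function(x, ax, side) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[ax]] <- if (side > 0) seq_len(d[ax] - 1L) else seq_len(d[ax] - 1L) + 1L
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @export
print.field_map <- function(x, ...) {
  cat("<field_map> sigma_B0 = ", signif(x$diagnostics$sigma_b0_hz, 4),
      " Hz, max gradient = ", signif(x$diagnostics$max_gradient_hz_per_cm, 4),
      " Hz/cm over ", sum(x$mask), " voxels\n", sep = "")
  invisible(x)
}

#' Susceptibility map container
#'
#' @param values 3-D array, susceptibility in ppm.
#' @param mask logical array (eroded brain mask after background removal).
#' @param geometry a [vol_geometry()].
#' @param method character tag of the inversion method.
#' @param reference CSF reference value already subtracted (ppm), or `NULL`
#'   if the map is unreferenced.
#' @export
susceptibility_map <- function(values, mask, geometry, method = "unknown",
                               reference = NULL) {
  stopifnot_geometry(geometry)
  mask <- array(as.logical(mask), dim = geometry$shape)
  if (any(!is.finite(values[mask]))) stop("susceptibility values must be finite inside the mask")
  structure(list(values = values, mask = mask, geometry = geometry,
                 method = method, reference = reference),
            class = "susceptibility_map")
}

#' @export
print.susceptibility_map <- function(x, ...) {
  cat("<susceptibility_map> method = ", x$method, ", ",
      sum(x$mask), " voxels in mask, reference = ",
      if (is.null(x$reference)) "none" else paste0(signif(x$reference, 4), " ppm"),
      "\n", sep = "")
  invisible(x)
}

#' R2* map container
#'
#' @param values 3-D array of R2* in 1/s; `NA` at flagged voxels.
#' @param s0 fitted TE = 0 magnitude.
#' @param noise_sd noise standard deviation used for the Rician correction.
#' @param fit_residual root-mean-square fit residual per voxel.
#' @param flagged logical array, `TRUE` where fewer than 3 usable echoes
#'   remained after noise-floor exclusion.
#' @param geometry a [vol_geometry()].
#' @export
r2star_map <- function(values, s0, noise_sd, fit_residual, flagged, geometry) {
  stopifnot_geometry(geometry)
  ok <- !flagged & is.finite(values)
  if (any(values[ok] < 0)) stop("fitted R2* must be nonnegative where the fit succeeded")
  structure(list(values = values, s0 = s0, noise_sd_estimate = noise_sd,
                 fit_residual = fit_residual, flagged = flagged,
                 geometry = geometry),
            class = "r2star_map")
}

#' @export
print.r2star_map <- function(x, ...) {
  ok <- !x$flagged & is.finite(x$values)
  cat("<r2star_map> median R2* = ", signif(stats::median(x$values[ok]), 4),
      " 1/s, ", sum(x$flagged), " flagged voxel(s), sigma = ",
      signif(x$noise_sd_estimate, 4), "\n", sep = "")
  invisible(x)
}

# axial slice extraction used across roi/metrics code
axial_slice <- function(volume, z) volume[, , z]
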