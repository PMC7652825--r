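#' Phantom specification
#'
#' Parameters of the digital habenula phantom: a thalamus-like tissue block
#' containing a bilateral pair of ellipsoidal habenulae abutting the midline
#' plane, a posteriorly elevated susceptibility subregion, 1-2 voxel wide
#' paramagnetic vein tubes, a triangular CSF reference prism spanning several
#' axial slices, and a smooth harmonic background field. Susceptibility and
#' R2* are generated from iron and myelin concentration fields through the
#' two-source model `chi = background + a*c_Fe - b*c_m` and
#' `R2* = base + f*c_Fe + g*c_m` with nonnegative coefficients, so that iron
#' variation moves the two maps together and myelin variation moves them
#' apart.
#'
#' Default acquisition parameters emulate a 3 T protocol: 8 echoes with TE
#' 7-42 ms in 5 ms steps and 0.53 x 0.53 x 0.8 mm voxels. The default
#' habenula ellipsoid (semi-axes 1.6 x 2.2 x 2.0 mm) has a volume of about
#' 30 mm^3 per side; the posterior subregion is the posterior 40% of the AP
#' extent.
#'
#' @param grid_shape 3 positive integers.
#' @param voxel_mm voxel size in mm.
#' @param b0 unit B0 direction in array coordinates.
#' @param larmor_mhz Larmor frequency in MHz.
#' @param te_s strictly ascending echo times in seconds.
#' @param n_channels number of receiver channels.
#' @param noise_sd complex channel noise standard deviation per real/imaginary
#'   part, in signal units (tissue M0 is 100 by default). The default of 5
#'   was calibrated once so that the reconstructed outer-ROI susceptibility
#'   noise is of order 0.011 ppm, the scale reported for this protocol.
#' @param habenula list: `semi_axes_mm` (LR, AP, SI ellipsoid semi-axes),
#'   `gap_mm` (distance from the midline plane to the medial ellipsoid edge),
#'   `posterior_fraction` (AP fraction forming the posterior subregion).
#' @param chi_params list of susceptibility targets in ppm: `background`
#'   (thalamus), `anterior_dchi`, `posterior_dchi` (habenula elevations over
#'   background), `vein`, `csf`, and `jitter_sd` (voxelwise iron-driven
#'   susceptibility heterogeneity).
#' @param iron_myelin list: coefficients `a`, `b` (ppm per unit
#'   concentration), `f`, `g` (1/s per unit concentration), `base_r2star`
#'   (1/s), myelin concentrations `c_m_habenula`, `c_m_background`, and
#'   `c_m_jitter_sd` (voxelwise myelin heterogeneity, applied after the
#'   iron solve so that myelin variation moves susceptibility and R2* in
#'   opposite directions).
#' @param m0 list of TE = 0 magnitudes per region: `tissue`, `habenula`,
#'   `csf`, `vein`.
#' @param vein list: `radius_mm`, `lateral_offset_mm`, `posterior_offset_mm`
#'   (tube position relative to each habenula), `z_extent` fraction of the
#'   brain height spanned (tubes run inferior-superior through the upper part
#'   of the volume so inferior slices lie farther from them).
#' @param background_field_sd_hz standard deviation over the brain of the
#'   harmonic background field added at simulation time (the deep-brain B0
#'   inhomogeneity scale at 3 T is of order 16 Hz).
#' @param brain_margin_mm gap between the brain ellipsoid and the grid edge.
#' @param seed integer; same seed and spec give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 36L),
                         voxel_mm = c(0.53, 0.53, 0.8),
                         b0 = c(0, 0, 1),
                         larmor_mhz = 123.2,
                         te_s = seq(0.007, 0.042, by = 0.005),
                         n_channels = 4L,
                         noise_sd = 5,
                         habenula = list(),
                         chi_params = list(),
                         iron_myelin = list(),
                         m0 = list(),
                         vein = list(),
                         background_field_sd_hz = 16,
                         brain_margin_mm = 1.5,
                         seed = 42L) {
  habenula <- utils::modifyList(
    list(semi_axes_mm = c(1.6, 2.2, 2.0), gap_mm = 0.5, posterior_fraction = 0.4),
    habenula)
  chi_params <- utils::modifyList(
    list(background = 0, anterior_dchi = 0.01, posterior_dchi = 0.045,
         vein = 0.3, csf = 0.005, jitter_sd = 0.005),
    chi_params)
  iron_myelin <- utils::modifyList(
    list(a = 1, b = 1, f = 95.8, g = 40, base_r2star = 18,
         c_m_habenula = 0.03, c_m_background = 0.003, c_m_jitter_sd = 0),
    iron_myelin)
  m0 <- utils::modifyList(
    list(tissue = 100, habenula = 92, csf = 130, vein = 70), m0)
  vein <- utils::modifyList(
    list(radius_mm = 0.4, lateral_offset_mm = 1.2, posterior_offset_mm = 1.4,
         z_extent = 0.5),
    vein)

  if (length(te_s) < 1L) stop("`te_s` must not be empty")
  if (length(te_s) > 1 && any(diff(te_s) <= 0)) stop("`te_s` must be strictly increasing")
  with(iron_myelin, {
    if (any(c(a, b, f, g) < 0)) stop("iron/myelin coefficients a, b, f, g must be nonnegative")
  })
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (n_channels < 1L) stop("`n_channels` must be positive")

  geometry <- vol_geometry(grid_shape, voxel_mm, b0, larmor_mhz)
  half_extent <- geometry$shape * geometry$voxel_mm / 2
  hb_reach <- habenula$gap_mm + 2 * habenula$semi_axes_mm[1]
  if (hb_reach > half_extent[1] ||
      habenula$semi_axes_mm[2] > half_extent[2] ||
      habenula$semi_axes_mm[3] > half_extent[3]) {
    stop("habenula geometry does not fit inside the grid")
  }
  if (any(habenula$semi_axes_mm <= 0)) stop("habenula has zero volume")

  structure(list(geometry = geometry, te_s = as.numeric(te_s),
                 n_channels = as.integer(n_channels), noise_sd = noise_sd,
                 habenula = habenula, chi_params = chi_params,
                 iron_myelin = iron_myelin, m0 = m0, vein = vein,
                 background_field_sd_hz = background_field_sd_hz,
                 brain_margin_mm = brain_margin_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid ", paste(x$geometry$shape, collapse = "x"),
      ", ", length(x$te_s), " echoes, ", x$n_channels, " channels, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# label codes used in the truth volume
PHANTOM_LABELS <- c(outside = 0L, thalamus = 1L, habenula_left = 2L,
                    habenula_right = 3L, habenula_posterior = 4L,
                    vein = 5L, csf = 6L)

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# centred physical coordinates (mm) of every voxel, as three 3-D arrays
coord_arrays <- function(geometry) {
  s <- geometry$shape
  v <- geometry$voxel_mm
  cx <- (seq_len(s[1]) - (s[1] + 1) / 2) * v[1]
  cy <- (seq_len(s[2]) - (s[2] + 1) / 2) * v[2]
  cz <- (seq_len(s[3]) - (s[3] + 1) / 2) * v[3]
  list(x = axis_array(cx, s, 1), y = axis_array(cy, s, 2),
       z = axis_array(cz, s, 3))
}

#' Build the ground-truth phantom
#'
#' Generates susceptibility (ppm), R2* (1/s), M0, label, coil-sensitivity and
#' background-field volumes from a [phantom_spec()]. The construction is
#' fully deterministic given the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth` with elements `chi`, `r2star`,
#'   `m0`, `labels`, `label_codes`, `masks` (brain, per-side habenula true
#'   and "segmentation" variants with posterior-edge misses, posterior
#'   subregion, vein, csf), `c_fe`, `c_m`, `coil_sens` (complex
#'   `(x, y, z, channel)` array), `background_field_hz`, `geometry`, `spec`.
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  geom <- spec$geometry
  s <- geom$shape
  co <- coord_arrays(geom)
  half_extent <- s * geom$voxel_mm / 2

  brain_semi <- half_extent - spec$brain_margin_mm
  if (any(brain_semi <= 0)) stop("grid too small for the requested brain margin")
  brain <- (co$x / brain_semi[1])^2 + (co$y / brain_semi[2])^2 +
    (co$z / brain_semi[3])^2 <= 1

  ax <- spec$habenula$semi_axes_mm
  gap <- spec$habenula$gap_mm
  ctr_x <- gap + ax[1]
  hb_side <- function(sgn) {
    ((co$x - sgn * ctr_x) / ax[1])^2 + (co$y / ax[2])^2 + (co$z / ax[3])^2 <= 1
  }
  hb_left <- hb_side(-1) & brain
  hb_right <- hb_side(1) & brain
  if (!any(hb_left) || !any(hb_right)) stop("habenula has zero volume on this grid")

  target_vol <- 4 / 3 * pi * prod(ax)
  for (m in list(hb_left, hb_right)) {
    vol <- sum(m) * voxel_volume_mm3(geom)
    if (abs(vol - target_vol) / target_vol > 0.2) {
      stop(sprintf("voxelized habenula volume %.1f mm^3 deviates more than 20%% from target %.1f mm^3",
                   vol, target_vol))
    }
  }

  # posterior subregion: posterior `posterior_fraction` of the AP extent
  pf <- spec$habenula$posterior_fraction
  y_thr <- (1 - 2 * pf) * ax[2]
  hb_post <- (hb_left | hb_right) & co$y > y_thr

  # CSF: triangular prism at the midline, anterior to the habenulae, apex
  # pointing posterior, spanning the habenula's axial slice range; clipped
  # to the brain on small grids
  y_apex <- -ax[2] - 1
  y_base <- max(y_apex - 3, -brain_semi[2] + max(geom$voxel_mm))
  tri_halfwidth <- 1.5
  frac <- (co$y - y_base) / (y_apex - y_base)
  csf <- co$y >= y_base & co$y <= y_apex &
    abs(co$x) <= tri_halfwidth * (1 - frac) &
    abs(co$z) <= ax[3] & brain

  # vein tubes: one per side, posterior-lateral to the habenula, spanning the
  # superior part of the volume only
  vr <- spec$vein$radius_mm
  vx <- ctr_x + spec$vein$lateral_offset_mm
  vy <- ax[2] + spec$vein$posterior_offset_mm
  # keep the tubes inside the brain ellipsoid on small grids
  rad2 <- (vx / brain_semi[1])^2 + (vy / brain_semi[2])^2
  if (rad2 >= 0.8) {
    scale <- sqrt(0.8 / rad2)
    vx <- vx * scale
    vy <- vy * scale
  }
  z_top <- brain_semi[3]
  z_bot <- z_top * (1 - 2 * spec$vein$z_extent) # top `z_extent` fraction
  vein <- (((co$x - vx)^2 + (co$y - vy)^2 <= vr^2) |
             ((co$x + vx)^2 + (co$y - vy)^2 <= vr^2)) &
    co$z >= z_bot & co$z <= z_top & brain
  if (!any(vein)) stop("vein tubes do not intersect the grid")

  labels <- array(PHANTOM_LABELS[["outside"]], dim = s)
  labels[brain] <- PHANTOM_LABELS[["thalamus"]]
  labels[hb_left] <- PHANTOM_LABELS[["habenula_left"]]
  labels[hb_right] <- PHANTOM_LABELS[["habenula_right"]]
  labels[hb_post] <- PHANTOM_LABELS[["habenula_posterior"]]
  labels[csf] <- PHANTOM_LABELS[["csf"]]
  labels[vein] <- PHANTOM_LABELS[["vein"]]
  # recompute region masks after precedence so classes are disjoint
  csf <- labels == PHANTOM_LABELS[["csf"]]
  vein <- labels == PHANTOM_LABELS[["vein"]]
  hb_post <- labels == PHANTOM_LABELS[["habenula_posterior"]]
  hb_left <- labels == PHANTOM_LABELS[["habenula_left"]] | (hb_post & co$x < 0)
  hb_right <- labels == PHANTOM_LABELS[["habenula_right"]] | (hb_post & co$x >= 0)
  thal <- labels == PHANTOM_LABELS[["thalamus"]]

  im <- spec$iron_myelin
  cp <- spec$chi_params
  c_m <- array(0, dim = s)
  c_m[thal] <- im$c_m_background
  c_m[hb_left | hb_right] <- im$c_m_habenula

  # iron concentration solved so that tissue susceptibility hits its regional
  # target through chi = background + a c_Fe - b c_m; veins and CSF get their
  # chi the same way (deoxyhemoglobin iron / near-water CSF)
  dchi_target <- array(NA_real_, dim = s)
  dchi_target[thal] <- 0
  dchi_target[(hb_left | hb_right) & !hb_post] <- cp$anterior_dchi
  dchi_target[hb_post] <- cp$posterior_dchi
  dchi_target[vein] <- cp$vein
  dchi_target[csf] <- cp$csf
  a_safe <- if (im$a > 0) im$a else 1
  c_fe <- ifelse(is.na(dchi_target), 0, (dchi_target + im$b * c_m) / a_safe)

  jitter <- with_seed(spec$seed, array(stats::rnorm(prod(s)), dim = s))
  tissue <- thal | hb_left | hb_right
  c_fe[tissue] <- pmax(c_fe[tissue] + jitter[tissue] * cp$jitter_sd / a_safe, 0)
  # myelin heterogeneity is injected after the iron solve, so it moves chi
  # and R2* in opposite directions (uncompensated)
  if (im$c_m_jitter_sd > 0) {
    jm <- with_seed(spec$seed + 5L, array(stats::rnorm(prod(s)), dim = s))
    c_m[tissue] <- pmax(c_m[tissue] + jm[tissue] * im$c_m_jitter_sd, 0)
  }

  chi <- array(0, dim = s)
  chi[brain] <- cp$background + im$a * c_fe[brain] - im$b * c_m[brain]
  r2star <- array(0, dim = s)
  r2star[brain] <- im$base_r2star + im$f * c_fe[brain] + im$g * c_m[brain]

  m0 <- array(0, dim = s)
  m0[thal] <- spec$m0$tissue
  m0[hb_left | hb_right] <- spec$m0$habenula
  m0[csf] <- spec$m0$csf
  m0[vein] <- spec$m0$vein

  coil_sens <- make_coil_maps(geom, spec$n_channels, spec$seed)
  bg <- make_background_field(co, brain, spec$background_field_sd_hz)

  # "segmentation" masks emulating initial coronal-plane delineation that
  # misses voxels on the posterior edge of the trigone: a seeded random half
  # of the posterior boundary voxels is dropped (recovered downstream by the
  # posterior edge adjustment)
  seg_left <- drop_posterior_edge(hb_left, spec$seed + 3L)
  seg_right <- drop_posterior_edge(hb_right, spec$seed + 4L)

  structure(list(chi = chi, r2star = r2star, m0 = m0, labels = labels,
                 label_codes = PHANTOM_LABELS,
                 masks = list(brain = brain, habenula_left = hb_left,
                              habenula_right = hb_right,
                              habenula_posterior = hb_post,
                              habenula_left_seg = seg_left,
                              habenula_right_seg = seg_right,
                              vein = vein, csf = csf),
                 c_fe = c_fe, c_m = c_m, coil_sens = coil_sens,
                 background_field_hz = bg, geometry = geom, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  v <- voxel_volume_mm3(x$geometry)
  cat("<phantom_truth> habenula ", signif(sum(x$masks$habenula_left) * v, 3),
      " / ", signif(sum(x$masks$habenula_right) * v, 3),
      " mm^3 (L/R), ", sum(x$masks$vein), " vein voxels, ",
      sum(x$masks$csf), " CSF voxels\n", sep = "")
  invisible(x)
}

# drop a seeded random fraction of the posterior boundary voxels (those
# whose posterior 4-neighbour lies outside the mask) on every axial slice
drop_posterior_edge <- function(mask, seed, frac = 0.35) {
  d <- dim(mask)
  shifted <- array(FALSE, dim = d)
  shifted[, seq_len(d[2] - 1L), ] <- mask[, seq_len(d[2] - 1L) + 1L, ]
  boundary <- which(mask & !shifted) # posterior neighbour outside the mask
  if (length(boundary) == 0L) return(mask)
  drop <- with_seed(seed, boundary[stats::runif(length(boundary)) < frac])
  out <- mask
  out[drop] <- FALSE
  out
}

# smooth per-channel complex sensitivities: Gaussian magnitude bumps centred
# beyond the volume corners plus low-order polynomial receiver phases
make_coil_maps <- function(geometry, n_channels, seed) {
  s <- geometry$shape
  co <- coord_arrays(geometry)
  half <- s * geometry$voxel_mm / 2
  angles <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  width <- 1.5 * max(half)
  pars <- with_seed(seed + 1L,
                    matrix(stats::runif(n_channels * 5, -1, 1), n_channels, 5))
  sens <- array(0 + 0i, dim = c(s, n_channels))
  for (ch in seq_len(n_channels)) {
    px <- 1.3 * half[1] * cos(angles[ch])
    py <- 1.3 * half[2] * sin(angles[ch])
    mag <- 0.3 + exp(-(((co$x - px)^2 + (co$y - py)^2 + co$z^2) / (2 * width^2)))
    phi <- pars[ch, 1] + 0.5 * (pars[ch, 2] * co$x / half[1] +
                                  pars[ch, 3] * co$y / half[2] +
                                  pars[ch, 4] * co$z / half[3]) +
      0.2 * pars[ch, 5] * (co$x * co$y) / (half[1] * half[2])
    sens[, , , ch] <- mag * exp(1i * phi)
  }
  sens
}

# fixed-shape harmonic polynomial (satisfies Laplace's equation) scaled to a
# target standard deviation over the brain
make_background_field <- function(co, brain, target_sd_hz) {
  h <- 0.5 * co$x + 0.8 * co$y + 0.3 * co$z +
    0.02 * (co$x^2 - co$z^2) + 0.015 * co$x * co$y
  if (target_sd_hz <= 0) return(array(0, dim = dim(h)))
  h * (target_sd_hz / stats::sd(h[brain]))
}

#' Simulate multi-channel multi-echo GRE data from a phantom
#'
#' Per channel `c`, echo `e` and voxel `r` the complex signal is
#' `m0(r) sens_c(r) exp(-R2*(r) TE_e) exp(i (phi_c0(r) + 2 pi f_B(r) TE_e))`
#' plus complex Gaussian noise of standard deviation `noise_sd` per
#' real/imaginary part. The field `f_B` is the forward dipole field of the
#' true susceptibility plus the phantom's harmonic background field.
#'
#' @param truth a [build_phantom()] result.
#' @param spec the matching [phantom_spec()]; defaults to `truth$spec`.
#' @return a [multiecho_gre()] with `n_channels` channels.
#' @export
simulate_multiecho_gre <- function(truth, spec = truth$spec) {
  if (!inherits(truth, "phantom_truth")) stop("`truth` must be a phantom_truth")
  if (!identical(truth$geometry$shape, spec$geometry$shape)) {
    stop("truth and spec are geometrically inconsistent")
  }
  if (length(spec$te_s) < 1L) stop("TE list must not be empty")
  geom <- truth$geometry
  s <- geom$shape
  ne <- length(spec$te_s)
  nc <- spec$n_channels
  f_b <- forward_dipole_field(truth$chi, geom)$values + truth$background_field_hz
  data <- array(0 + 0i, dim = c(s, ne, nc))
  for (e in seq_len(ne)) {
    te <- spec$te_s[e]
    decayed <- truth$m0 * exp(-truth$r2star * te) * exp(2i * pi * f_b * te)
    for (ch in seq_len(nc)) {
      data[, , , e, ch] <- decayed * truth$coil_sens[, , , ch]
    }
  }
  if (spec$noise_sd > 0) {
    n <- length(data)
    noise <- with_seed(spec$seed + 2L,
                       complex(real = stats::rnorm(n, sd = spec$noise_sd),
                               imaginary = stats::rnorm(n, sd = spec$noise_sd)))
    data <- data + array(noise, dim = dim(data))
  }
  multiecho_gre(data, spec$te_s, geom)
}
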