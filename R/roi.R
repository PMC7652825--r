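#' Vein candidate detection
#'
#' Veins appear as elongated, typically one or two voxel wide, bright
#' features in the susceptibility or R2* map. Voxels exceeding the
#' background mean by `k` standard deviations (in either map) are grouped
#' into 26-connected components; components whose principal-axis elongation
#' is at least `elongation_min` and whose minor width is at most
#' `max_width_vox` voxels are flagged as veins.
#'
#' @param chi a [susceptibility_map()] (or plain 3-D array).
#' @param r2star optional [r2star_map()] (or array) on the same grid.
#' @param background_mask logical array defining the reference tissue whose
#'   mean/SD set the brightness threshold.
#' @param k threshold in background SDs (default 3).
#' @param elongation_min minimum length/width ratio (default 3).
#' @param max_width_vox maximum minor width in voxels (default 2).
#' @return an object of class `vein_mask`: logical `mask` of flagged voxels
#'   and a `components` data frame (one row per bright component with its
#'   size, elongation, width and flag).
#' @export
detect_vein_candidates <- function(chi, r2star = NULL, background_mask,
                                   k = 3, elongation_min = 3, max_width_vox = 2) {
  chi_v <- if (inherits(chi, "susceptibility_map")) chi$values else chi
  if (!any(background_mask)) stop("background region is empty")
  bright <- bright_voxels(chi_v, background_mask, k)
  if (!is.null(r2star)) {
    r2_v <- if (inherits(r2star, "r2star_map")) r2star$values else r2star
    if (!all(dim(r2_v) == dim(chi_v))) stop("maps are not co-registered (shape mismatch)")
    bright <- bright | bright_voxels(r2_v, background_mask, k)
  }
  labels <- label_components_26(bright)
  ncomp <- max(labels)
  mask <- array(FALSE, dim = dim(chi_v))
  comp <- data.frame(id = integer(0), n = integer(0), elongation = numeric(0),
                     width = numeric(0), flagged = logical(0))
  for (id in seq_len(ncomp)) {
    vox <- which(labels == id, arr.ind = TRUE)
    sh <- component_shape(vox)
    flag <- sh$elongation >= elongation_min && sh$width <= max_width_vox
    if (flag) mask[labels == id] <- TRUE
    comp <- rbind(comp, data.frame(id = id, n = nrow(vox),
                                   elongation = sh$elongation,
                                   width = sh$width, flagged = flag))
  }
  structure(list(mask = mask, components = comp), class = "vein_mask")
}

bright_voxels <- function(v, background_mask, k) {
  vals <- v[background_mask]
  vals <- vals[is.finite(vals)]
  thr <- mean(vals) + k * stats::sd(vals)
  out <- is.finite(v) & v > thr
  out & !background_mask
}

# principal-axis extents of a voxel coordinate set: length and width are the
# ranges (in voxels, +1) of the projections onto the PCA axes
component_shape <- function(vox) {
  if (nrow(vox) == 1L) return(list(elongation = 1, width = 1))
  xc <- scale(vox, scale = FALSE)
  pc <- stats::prcomp(xc, center = FALSE)
  proj <- xc %*% pc$rotation
  ranges <- apply(proj, 2, function(p) diff(range(p))) + 1
  len <- ranges[1]
  wid <- if (length(ranges) > 1) max(ranges[-1]) else 1
  list(elongation = len / wid, width = wid)
}

# 26-connected component labelling by breadth-first search
label_components_26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  cur <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      vi <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(vi), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin) > 0L) {
        labels[lin] <- cur
        queue <- c(queue, lin)
      }
    }
  }
  labels
}

#' Minimum-vein slice selection
#'
#' Among axial slices whose in-plane ROI has at least `min_pixels` voxels and
#' contains no vein voxel, selects the slice whose ROI lies farthest (minimum
#' Euclidean distance in mm, computed in 3-D against all vein voxels) from
#' any vein; ties are broken by the larger in-plane ROI area, then by the
#' lower slice index. If every eligible slice has vein intrusion, the
#' maximum-distance slice is returned with `warning = TRUE`.
#'
#' @param mask3d logical 3-D ROI mask.
#' @param veins a `vein_mask` (or logical array).
#' @param geometry a [vol_geometry()].
#' @param min_pixels minimum in-plane ROI size (default 16).
#' @return list with `slice` (index along axis 3), `distance_mm`, `area`,
#'   `warning`, and the per-slice candidate table `scores`.
#' @export
select_minimum_vein_slice <- function(mask3d, veins, geometry, min_pixels = 16) {
  vein_mask <- if (inherits(veins, "vein_mask")) veins$mask else veins
  if (!any(mask3d)) stop("ROI mask is empty")
  d <- dim(mask3d)
  vein_xyz <- voxel_mm_coords(which(vein_mask), d, geometry)
  areas <- apply(mask3d, 3, sum)
  eligible <- which(areas >= min_pixels)
  if (length(eligible) == 0L) {
    stop(sprintf("no axial slice has an ROI of at least %d voxels", min_pixels))
  }
  scores <- data.frame(slice = eligible, area = areas[eligible],
                       intruded = FALSE, distance_mm = Inf)
  for (r in seq_len(nrow(scores))) {
    z <- scores$slice[r]
    m2 <- mask3d[, , z]
    lin <- which(m2) + d[1] * d[2] * (z - 1L)
    scores$intruded[r] <- any(vein_mask[, , z] & m2)
    if (nrow(vein_xyz) > 0L) {
      roi_xyz <- voxel_mm_coords(lin, d, geometry)
      scores$distance_mm[r] <- min_set_distance(roi_xyz, vein_xyz)
    }
  }
  cand <- scores[!scores$intruded, , drop = FALSE]
  warn <- FALSE
  if (nrow(cand) == 0L) {
    cand <- scores
    warn <- TRUE
  }
  ord <- order(-cand$distance_mm, -cand$area, cand$slice)
  best <- cand[ord[1L], ]
  list(slice = best$slice, distance_mm = best$distance_mm, area = best$area,
       warning = warn, scores = scores)
}

voxel_mm_coords <- function(lin, d, geometry) {
  if (length(lin) == 0L) return(matrix(numeric(0), 0, 3))
  ai <- arrayInd(lin, d)
  sweep(ai, 2, geometry$voxel_mm, `*`)
}

min_set_distance <- function(a, b) {
  # smallest pairwise Euclidean distance between two point sets (mm)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    dd <- sqrt(colSums((t(b) - a[i, ])^2))
    best <- min(best, min(dd))
  }
  best
}

#' Posterior edge adjustment of a single-slice habenula ROI
#'
#' Automated surrogate for manually conforming the 2-D ROI to the posterior
#' edge of the habenula trigone on the first-echo magnitude image: one
#' iteration adds posterior 4-neighbours of the ROI whose magnitude lies
#' within `nsigma` SDs of the current ROI mean; growth is capped at
#' `max_growth` of the ROI size (candidates closest in magnitude to the ROI
#' mean are kept when the cap binds).
#'
#' @param mask2d logical matrix (LR x AP) for the selected slice.
#' @param mag_slice first-echo GRE magnitude on the same slice.
#' @param nsigma acceptance window half-width in ROI SDs (default 2).
#' @param max_growth growth cap as a fraction of the ROI size (default 0.15).
#' @return the adjusted logical matrix (input returned unchanged if no
#'   neighbour qualifies).
#' @export
adjust_posterior_edge <- function(mask2d, mag_slice, nsigma = 2, max_growth = 0.15) {
  if (!any(mask2d)) stop("`mask2d` is empty")
  d <- dim(mask2d)
  mu <- mean(mag_slice[mask2d])
  sd0 <- stats::sd(mag_slice[mask2d])
  if (!is.finite(sd0)) sd0 <- 0
  # posterior 4-neighbours: voxels (i, j) outside the ROI with (i, j-1) inside
  inside <- which(mask2d, arr.ind = TRUE)
  cand <- inside
  cand[, 2] <- cand[, 2] + 1L
  cand <- cand[cand[, 2] <= d[2], , drop = FALSE]
  cand <- cand[!mask2d[cand], , drop = FALSE]
  cand <- unique(cand)
  if (nrow(cand) == 0L) return(mask2d)
  mag <- mag_slice[cand]
  ok <- abs(mag - mu) <= nsigma * sd0
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(mask2d)
  cap <- floor(max_growth * sum(mask2d))
  if (nrow(cand) > cap) {
    dev <- abs(mag_slice[cand] - mu)
    ord <- order(dev, cand[, 2], cand[, 1])
    cand <- cand[ord[seq_len(cap)], , drop = FALSE]
  }
  out <- mask2d
  out[cand] <- TRUE
  out
}

#' Outer (noise-reference) ROI
#'
#' Shifts the habenula ROI by half its bounding-box extent laterally (away
#' from the midline) and anteriorly, then subtracts the original ROI. The
#' susceptibility standard deviation over this region defines the noise in
#' all CNR calculations.
#'
#' @param mask2d logical matrix (LR x AP).
#' @param side `"left"` or `"right"`; with the LR axis increasing to the
#'   right, lateral means decreasing index for the left side and increasing
#'   index for the right side.
#' @return logical matrix, disjoint from `mask2d`.
#' @export
make_outer_roi <- function(mask2d, side = c("left", "right")) {
  side <- match.arg(side)
  if (!any(mask2d)) stop("`mask2d` is empty")
  d <- dim(mask2d)
  vox <- which(mask2d, arr.ind = TRUE)
  w <- diff(range(vox[, 1])) + 1L
  h <- diff(range(vox[, 2])) + 1L
  di <- round(w / 2) * if (side == "left") -1L else 1L
  dj <- -round(h / 2) # anterior = decreasing AP index
  shifted <- vox
  shifted[, 1] <- shifted[, 1] + di
  shifted[, 2] <- shifted[, 2] + dj
  keep <- shifted[, 1] >= 1 & shifted[, 1] <= d[1] &
    shifted[, 2] >= 1 & shifted[, 2] <= d[2]
  shifted <- shifted[keep, , drop = FALSE]
  out <- array(FALSE, dim = d)
  out[shifted] <- TRUE
  out <- out & !mask2d
  if (!any(out)) stop("outer ROI is empty after subtracting the original ROI")
  out
}

#' Greedy five-voxel peak cluster
#'
#' Seeds at the maximum-susceptibility voxel inside the ROI and repeatedly
#' adds the highest-valued in-ROI voxel 8-adjacent to the current cluster
#' until `size` voxels are collected. Ties are broken deterministically by
#' (row, column) order.
#'
#' @param chi_slice numeric matrix of susceptibility values on the slice.
#' @param mask2d logical ROI matrix; must contain at least `size` voxels.
#' @param size cluster size (default 5).
#' @return integer matrix `size x 2` of voxel coordinates (row = LR index,
#'   col = AP index), in growth order.
#' @export
grow_peak_cluster <- function(chi_slice, mask2d, size = 5L) {
  n <- sum(mask2d)
  if (n < size) stop(sprintf("ROI has %d voxels; need at least %d", n, size))
  d <- dim(mask2d)
  in_cluster <- array(FALSE, dim = d)
  vals <- ifelse(mask2d, chi_slice, -Inf)
  seed <- which(vals == max(vals), arr.ind = TRUE)
  seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, , drop = FALSE]
  cluster <- seed
  in_cluster[seed] <- TRUE
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  while (nrow(cluster) < size) {
    nb <- do.call(rbind, lapply(seq_len(nrow(cluster)), function(r) {
      sweep(offs, 2, as.integer(cluster[r, ]), `+`)
    }))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2], ,
             drop = FALSE]
    nb <- unique(nb)
    nb <- nb[mask2d[nb] & !in_cluster[nb], , drop = FALSE]
    if (nrow(nb) == 0L) stop("cluster cannot grow further inside the ROI")
    v <- chi_slice[nb]
    ord <- order(-v, nb[, 1], nb[, 2])
    add <- nb[ord[1L], , drop = FALSE]
    cluster <- rbind(cluster, add)
    in_cluster[add] <- TRUE
  }
  dimnames(cluster) <- NULL
  cluster
}

#' Geometric halving of the 2-D habenula ROI
#'
#' Divides the ROI into two equal-count halves along the anterior-posterior
#' axis or the medial-lateral axis (distance from the midline plane). Odd
#' counts give the extra voxel to the posterior (resp. lateral) half; ties
#' in the sort coordinate are broken by the orthogonal coordinate.
#'
#' @param mask2d logical matrix (LR x AP).
#' @param axis `"ap"` or `"ml"`.
#' @param side `"left"` or `"right"` (defines the lateral direction).
#' @param midline_i midline plane position along the LR axis, in (possibly
#'   fractional) matrix row units; defaults to the matrix centre.
#' @return for `"ap"` a list with `anterior` and `posterior` masks; for
#'   `"ml"` a list with `medial` and `lateral` masks.
#' @export
split_halves <- function(mask2d, axis = c("ap", "ml"), side = c("left", "right"),
                         midline_i = NULL) {
  axis <- match.arg(axis)
  side <- match.arg(side)
  n <- sum(mask2d)
  if (n < 2L) stop("ROI must contain at least 2 voxels")
  d <- dim(mask2d)
  if (is.null(midline_i)) midline_i <- (d[1] + 1) / 2
  vox <- which(mask2d, arr.ind = TRUE)
  if (axis == "ap") {
    key <- vox[, 2] # anterior (small j) first
    tie <- vox[, 1]
  } else {
    key <- abs(vox[, 1] - midline_i) # medial (near midline) first
    tie <- vox[, 2]
  }
  ord <- order(key, tie)
  n_first <- floor(n / 2) # extra voxel goes to the posterior/lateral half
  first <- array(FALSE, dim = d)
  second <- array(FALSE, dim = d)
  first[vox[ord[seq_len(n_first)], , drop = FALSE]] <- TRUE
  second[vox[ord[seq_len(n - n_first) + n_first], , drop = FALSE]] <- TRUE
  if (axis == "ap") list(anterior = first, posterior = second)
  else list(medial = first, lateral = second)
}

#' CSF reference ROI
#'
#' Restricts a CSF mask to exactly three contiguous axial slices centred on
#' the minimum-vein slice, the region whose mean susceptibility serves as
#' the susceptibility zero reference.
#'
#' @param csf_mask3d logical 3-D CSF mask.
#' @param slice centre (minimum-vein) slice index.
#' @return logical 3-D mask spanning slices `slice - 1 .. slice + 1`.
#' @export
csf_reference_roi <- function(csf_mask3d, slice) {
  d <- dim(csf_mask3d)
  if (slice < 2L || slice > d[3] - 1L) {
    stop("centre slice must leave room for one slice on each side")
  }
  out <- array(FALSE, dim = d)
  zr <- (slice - 1L):(slice + 1L)
  out[, , zr] <- csf_mask3d[, , zr]
  per_slice <- apply(out[, , zr, drop = FALSE], 3, sum)
  if (any(per_slice == 0)) stop("CSF reference must be nonempty on each of the 3 slices")
  out
}

#' CSF referencing of a susceptibility map
#'
#' Subtracts the mean susceptibility over the CSF reference ROI from the
#' whole map and records the reference. Maps can be referenced only once;
#' contrasts and CNRs are invariant under this global offset.
#'
#' @param chi a [susceptibility_map()].
#' @param csf_roi logical 3-D mask (see [csf_reference_roi()]).
#' @return the referenced [susceptibility_map()].
#' @export
csf_reference <- function(chi, csf_roi) {
  if (!inherits(chi, "susceptibility_map")) stop("`chi` must be a susceptibility_map")
  if (!is.null(chi$reference)) stop("map is already CSF-referenced")
  if (!any(csf_roi)) stop("CSF ROI is empty")
  if (any(csf_roi & !chi$mask)) stop("CSF ROI extends outside the susceptibility mask")
  ref <- mean(chi$values[csf_roi])
  susceptibility_map(values = chi$values - ref, mask = chi$mask,
                     geometry = chi$geometry, method = chi$method,
                     reference = ref)
}

#' Single-side habenula ROI analysis
#'
#' Runs the full ROI pipeline for one hemisphere: minimum-vein slice
#' selection, optional posterior edge adjustment on the first-echo
#' magnitude, anterior/posterior and medial/lateral halving, greedy peak
#' cluster, and outer-ROI construction. Invariants (partitions tile the ROI,
#' the cluster lies inside it, the outer ROI is disjoint, at least 16
#' voxels) are asserted on every run.
#'
#' @param chi a [susceptibility_map()].
#' @param mask3d logical 3-D habenula mask for one side.
#' @param veins a `vein_mask` (or logical array).
#' @param side `"left"` or `"right"`.
#' @param mag_first_echo 3-D first-echo GRE magnitude (for edge adjustment);
#'   `NULL` disables the adjustment.
#' @param min_pixels minimum in-plane ROI size (default 16).
#' @param edge_adjust logical; apply [adjust_posterior_edge()] (default TRUE
#'   when a magnitude volume is supplied).
#' @param midline_i midline position along the LR axis (matrix row units).
#' @param slice optional axial slice index; when given it overrides the
#'   minimum-vein selection (used to analyse both hemispheres on a common
#'   slice).
#' @return an object of class `habenula_roi`.
#' @export
analyze_habenula_roi <- function(chi, mask3d, veins, side = c("left", "right"),
                                 mag_first_echo = NULL, min_pixels = 16,
                                 edge_adjust = !is.null(mag_first_echo),
                                 midline_i = NULL, slice = NULL) {
  side <- match.arg(side)
  geom <- chi$geometry
  sel <- if (is.null(slice)) {
    select_minimum_vein_slice(mask3d, veins, geom, min_pixels = min_pixels)
  } else {
    list(slice = slice, distance_mm = NA_real_,
         area = sum(mask3d[, , slice]), warning = FALSE, scores = NULL)
  }
  z <- sel$slice
  mask2d_initial <- mask3d[, , z]
  mask2d <- mask2d_initial
  if (edge_adjust) {
    if (is.null(mag_first_echo)) stop("edge adjustment requires `mag_first_echo`")
    mask2d <- adjust_posterior_edge(mask2d, mag_first_echo[, , z])
  }
  chi_slice <- chi$values[, , z]
  ap <- split_halves(mask2d, "ap", side, midline_i)
  ml <- split_halves(mask2d, "ml", side, midline_i)
  peak <- grow_peak_cluster(chi_slice, mask2d)
  outer <- make_outer_roi(mask2d, side)

  stopifnot(
    sum(mask2d) >= min_pixels,
    identical(ap$anterior | ap$posterior, mask2d),
    !any(ap$anterior & ap$posterior),
    identical(ml$medial | ml$lateral, mask2d),
    !any(ml$medial & ml$lateral),
    nrow(peak) == 5L, all(mask2d[peak]),
    !any(outer & mask2d)
  )
  structure(list(side = side, mask3d = mask3d, selected_slice = z,
                 slice_selection = sel, mask2d = mask2d,
                 mask2d_initial = mask2d_initial,
                 partitions = list(anterior = ap$anterior, posterior = ap$posterior,
                                   medial = ml$medial, lateral = ml$lateral),
                 peak_cluster = peak, outer_roi = outer,
                 chi_slice = chi_slice,
                 voxel_volume_mm3 = voxel_volume_mm3(geom),
                 geometry = geom),
            class = "habenula_roi")
}

#' @export
print.habenula_roi <- function(x, ...) {
  cat("<habenula_roi> side = ", x$side, ", slice ", x$selected_slice,
      ", ", sum(x$mask2d), " voxels (",
      signif(sum(x$mask2d) * x$voxel_volume_mm3, 3), " mm^3), outer ROI ",
      sum(x$outer_roi), " voxels\n", sep = "")
  invisible(x)
}
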