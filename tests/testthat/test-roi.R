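test_that("vein detection flags thin elongated bright features only", {
  g <- vol_geometry(c(24, 24, 24), c(1, 1, 1))
  vals <- array(0, g$shape)
  bg <- array(TRUE, g$shape)
  set.seed(5)
  vals[bg] <- stats::rnorm(sum(bg), sd = 0.005)
  # uniform-ish map: nothing above mean + 3 sd outside background
  v0 <- detect_vein_candidates(vals, background_mask = bg)
  expect_equal(sum(v0$mask), 0)

  # 1-voxel-wide, 10-voxel-long tube at +0.3: flagged
  bg2 <- bg
  vals2 <- vals
  vals2[12, 12, 6:15] <- 0.3
  bg2[12, 12, 6:15] <- FALSE
  v1 <- detect_vein_candidates(vals2, background_mask = bg2)
  expect_true(all(v1$mask[12, 12, 6:15]))
  expect_gte(max(v1$components$elongation[v1$components$flagged]), 3)

  # compact 3x3x3 bright blob: fails the elongation rule
  vals3 <- vals
  vals3[10:12, 10:12, 10:12] <- 0.3
  bg3 <- bg
  bg3[10:12, 10:12, 10:12] <- FALSE
  v2 <- detect_vein_candidates(vals3, background_mask = bg3)
  expect_equal(sum(v2$mask), 0)
  expect_true(any(!v2$components$flagged))

  expect_error(detect_vein_candidates(vals, background_mask = bg & FALSE),
               "empty")
})

test_that("minimum-vein slice selection follows the distance/area/index rules", {
  g <- vol_geometry(c(20, 20, 6), c(1, 1, 1))
  mask <- array(FALSE, g$shape)
  # three candidate slices with controlled areas
  mask[3:8, 3:5, 2] <- TRUE              # 18 voxels
  mask[3:7, 3:6, 3] <- TRUE              # 20 voxels
  mask[3:8, 3:6, 4] <- TRUE              # 24 voxels
  veins <- array(FALSE, g$shape)
  veins[15, 15, 2] <- TRUE # distances differ per slice via z offset
  # craft equal distances for slices 3 and 4 by a second vein voxel
  # (both have nearest vein sqrt((15-8)^2+(15-6)^2+dz^2)); dz makes slice 2 closest
  sel <- select_minimum_vein_slice(mask, veins, g, min_pixels = 16)
  sc <- sel$scores
  # verified against the independent per-slice scoring oracle
  o <- oracle_slice_choice(mask, veins, g, min_pixels = 16)
  expect_equal(sel$slice, o$slice)
  expect_equal(sel$distance_mm, o$dist)

  # a slice with fewer than 16 voxels is excluded no matter how far it is
  mask15 <- mask
  mask15[, , 5] <- FALSE
  mask15[3:7, 3:5, 5] <- TRUE # 15 voxels, farthest from the vein
  sel15 <- select_minimum_vein_slice(mask15, veins, g, min_pixels = 16)
  expect_false(sel15$slice == 5)
  expect_false(5 %in% sel15$scores$slice)

  # no veins at all: ties on Inf distance resolved by largest area
  sel_nv <- select_minimum_vein_slice(mask, array(FALSE, g$shape), g,
                                      min_pixels = 16)
  expect_equal(sel_nv$slice, 4)

  # all candidates intruded: warning flag, max-distance slice returned
  vein_in <- array(FALSE, g$shape)
  vein_in[4, 4, 2:4] <- TRUE
  sel_w <- select_minimum_vein_slice(mask, vein_in, g, min_pixels = 16)
  expect_true(sel_w$warning)

  expect_error(select_minimum_vein_slice(array(FALSE, g$shape), veins, g),
               "empty")
  expect_error(select_minimum_vein_slice(mask, veins, g, min_pixels = 100),
               "at least 100")
})

test_that("minimum-vein slice equals exhaustive scoring on the phantom", {
  res <- default_pipeline()
  truth <- res$truth
  hb <- (truth$masks$habenula_left_seg | truth$masks$habenula_right_seg) &
    res$recon$mask_eroded
  sel <- select_minimum_vein_slice(hb, res$veins, truth$geometry,
                                   min_pixels = 32)
  o <- oracle_slice_choice(hb, res$veins$mask, truth$geometry, min_pixels = 32)
  expect_equal(sel$slice, o$slice)
  expect_equal(sel$distance_mm, o$dist, tolerance = 1e-12)
})

test_that("posterior edge adjustment adds only matching posterior neighbours", {
  mask <- matrix(FALSE, 12, 12)
  mask[4:9, 4:7] <- TRUE
  mag <- matrix(100, 12, 12) + matrix(stats::rnorm(144, sd = 1), 12, 12)
  set.seed(8)
  # three posterior voxels with matching magnitude, excluded from the mask
  mask[c(5, 6, 7), 8] <- FALSE # (already FALSE) posterior row j = 8
  mag[, 8] <- 160 # posterior row is CSF-bright...
  mag[c(5, 6, 7), 8] <- 100 # ...except three habenula-like voxels
  out <- adjust_posterior_edge(mask, mag)
  added <- which(out & !mask, arr.ind = TRUE)
  expect_equal(nrow(added), 3)
  expect_true(all(added[, 2] == 8))
  expect_setequal(added[, 1], c(5, 6, 7))

  # ROI surrounded by much brighter voxels: unchanged
  mag2 <- matrix(100, 12, 12)
  mag2[mask] <- 50
  expect_identical(adjust_posterior_edge(mask, mag2), mask)

  # growth cap: a full matching posterior row cannot exceed 15% of the ROI
  mag3 <- matrix(100, 12, 12)
  out3 <- adjust_posterior_edge(mask, mag3)
  expect_lte(sum(out3) - sum(mask), floor(0.15 * sum(mask)))
})

test_that("outer ROI is the half-size lateral+anterior shift minus the original", {
  mask <- matrix(FALSE, 24, 24)
  mask[10:15, 10:13] <- TRUE # 6 x 4 rectangle
  outer_l <- make_outer_roi(mask, side = "left")
  # shift (3 lateral, 2 anterior): 24 voxels shifted, 6 overlap -> 18 remain
  expect_equal(sum(outer_l), 18)
  expect_false(any(outer_l & mask))
  vox <- which(outer_l, arr.ind = TRUE)
  expect_true(all(vox[, 1] >= 7 & vox[, 1] <= 12)) # shifted toward low i
  # mirror symmetry of the lateral direction
  outer_r <- make_outer_roi(mask, side = "right")
  expect_equal(sum(outer_r), 18)
  expect_true(all(which(outer_r, arr.ind = TRUE)[, 1] >= 13))
  expect_error(make_outer_roi(matrix(FALSE, 4, 4), "left"), "empty")
})

test_that("greedy peak cluster reproduces the hand-simulated rule", {
  # 4x4 grid, values 16..1 in raster order (row-major)
  vals <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) vals[i, j] <- 16 - ((i - 1) * 4 + (j - 1))
  mask <- matrix(TRUE, 4, 4)
  cl <- grow_peak_cluster(vals, mask)
  got <- sort(vals[cl])
  expect_equal(got, c(12, 13, 14, 15, 16))

  # a 5-voxel ROI is returned whole
  m5 <- matrix(FALSE, 6, 6)
  m5[2, 2:6] <- TRUE
  cl5 <- grow_peak_cluster(matrix(stats::runif(36), 6, 6), m5)
  expect_equal(sum(m5[cl5]), 5)
  expect_error(grow_peak_cluster(vals, m5 & FALSE), "at least 5")
})

test_that("greedy cluster is optimal on smooth peaked fields (exhaustive check)", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 6
    cx <- stats::runif(1, 2, 5)
    cy <- stats::runif(1, 2, 5)
    vals <- outer(1:n, 1:n, function(i, j) {
      exp(-((i - cx)^2 + (j - cy)^2) / 4)
    }) + matrix(stats::rnorm(n * n, sd = 0.05), n)
    mask <- matrix(TRUE, n, n)
    cl <- grow_peak_cluster(vals, mask)
    best <- oracle_best_cluster_mean(vals, mask, 5L)
    expect_equal(mean(vals[cl]), best, tolerance = 1e-12)
  }
})

test_that("geometric halving obeys the parity and direction rules", {
  # 6 x 4 axis-aligned rectangle, AP split: front 12 / back 12
  mask <- matrix(FALSE, 20, 20)
  mask[5:10, 5:8] <- TRUE
  ap <- split_halves(mask, "ap", "left")
  expect_equal(sum(ap$anterior), 12)
  expect_equal(sum(ap$posterior), 12)
  expect_true(all(which(ap$anterior, arr.ind = TRUE)[, 2] <= 6))
  expect_identical(ap$anterior | ap$posterior, mask)
  expect_false(any(ap$anterior & ap$posterior))

  # 31 voxels: posterior (resp. lateral) half gets 16
  m31 <- matrix(FALSE, 20, 20)
  m31[which(mask)[1:23]] <- TRUE
  m31[2, 1:8] <- TRUE # make it 31 total
  expect_equal(sum(m31), 31)
  ap31 <- split_halves(m31, "ap", "left")
  expect_equal(sum(ap31$posterior), 16)
  ml31 <- split_halves(m31, "ml", "left", midline_i = 19)
  expect_equal(sum(ml31$lateral), 16)
  # medial voxels are nearer the midline than lateral voxels
  med_d <- abs(which(ml31$medial, arr.ind = TRUE)[, 1] - 19)
  lat_d <- abs(which(ml31$lateral, arr.ind = TRUE)[, 1] - 19)
  expect_lte(max(med_d), min(lat_d) + 1)

  expect_error(split_halves(matrix(FALSE, 3, 3), "ap", "left"), "at least 2")
})

test_that("CSF referencing subtracts the 3-slice CSF mean exactly once", {
  res <- default_pipeline()
  chi <- res$recon$chi
  csf <- res$truth$masks$csf & res$recon$mask_eroded
  roi3 <- csf_reference_roi(csf, res$slice)
  zr <- (res$slice - 1):(res$slice + 1)
  expect_true(all(apply(roi3[, , zr], 3, sum) > 0))
  expect_equal(sum(roi3[, , -zr]), 0)

  ref <- csf_reference(chi, roi3)
  expect_equal(mean(ref$values[roi3]), 0, tolerance = 1e-12)
  expect_equal(ref$values[chi$mask] - chi$values[chi$mask],
               rep(-ref$reference, sum(chi$mask)), tolerance = 1e-12)
  expect_error(csf_reference(ref, roi3), "already")

  # CNRs are invariant under referencing
  cnr_before <- compute_cnrs(chi$values[, , res$slice], res$roi_left)
  cnr_after <- compute_cnrs(ref$values[, , res$slice], res$roi_left)
  num <- vapply(cnr_before, is.numeric, TRUE)
  expect_equal(as.numeric(cnr_after[num]), as.numeric(cnr_before[num]),
               tolerance = 1e-10)
})
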