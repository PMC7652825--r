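# Independent oracles used to cross-check the FFT / greedy / selection code.
# These deliberately avoid the implementation paths they verify.

# Brute-force spatial dipole sum: field in ppm at every voxel from the
# Lorentz-corrected point-dipole formula, summed over all source voxels.
oracle_dipole_sum <- function(chi_ppm, geometry) {
  d <- dim(chi_ppm)
  vx <- geometry$voxel_mm
  b0 <- geometry$b0
  vvol <- prod(vx)
  src <- which(chi_ppm != 0, arr.ind = TRUE)
  out <- array(0, dim = d)
  tgt <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  pos <- sweep(tgt, 2, vx, `*`)
  for (s in seq_len(nrow(src))) {
    rp <- (tgt[, 1] - src[s, 1]) * vx[1]
    rq <- (tgt[, 2] - src[s, 2]) * vx[2]
    rr <- (tgt[, 3] - src[s, 3]) * vx[3]
    r2 <- rp^2 + rq^2 + rr^2
    rb <- rp * b0[1] + rq * b0[2] + rr * b0[3]
    contrib <- ifelse(r2 == 0, 0,
                      (3 * rb^2 / r2 - 1) / (4 * pi * r2^1.5) * vvol *
                        chi_ppm[src[s, 1], src[s, 2], src[s, 3]])
    out <- out + array(contrib, dim = d)
  }
  out
}

# Exhaustive search over all 8-connected voxel subsets of a given size that
# contain the seed; returns the maximum achievable mean value.
oracle_best_cluster_mean <- function(vals, mask, size = 5L) {
  d <- dim(mask)
  v <- ifelse(mask, vals, -Inf)
  seed_idx <- which(v == max(v), arr.ind = TRUE)
  seed_idx <- seed_idx[order(seed_idx[, 1], seed_idx[, 2]), , drop = FALSE][1, ]
  lin <- function(ij) ij[1] + d[1] * (ij[2] - 1L)
  in_mask_lin <- which(mask)
  adj <- function(a, b) {
    ia <- c((a - 1L) %% d[1] + 1L, (a - 1L) %/% d[1] + 1L)
    ib <- c((b - 1L) %% d[1] + 1L, (b - 1L) %/% d[1] + 1L)
    max(abs(ia - ib)) == 1L
  }
  best <- -Inf
  seed_l <- lin(seed_idx)
  # depth-first enumeration of connected supersets of the seed
  recurse <- function(current, candidates) {
    if (length(current) == size) {
      m <- mean(vals[current])
      if (m > best) best <<- m
      return(invisible())
    }
    if (length(candidates) == 0L) return(invisible())
    for (n in seq_along(candidates)) {
      cand <- candidates[n]
      # keep ordering to avoid duplicate enumeration: candidates after n,
      # plus new neighbours of cand
      newnb <- in_mask_lin[vapply(in_mask_lin, function(x) {
        !(x %in% current) && !(x %in% candidates[seq_len(n)]) && adj(x, cand)
      }, TRUE)]
      recurse(c(current, cand), c(candidates[-seq_len(n)], setdiff(newnb, candidates)))
    }
  }
  nb0 <- in_mask_lin[vapply(in_mask_lin, function(x) x != seed_l && adj(x, seed_l), TRUE)]
  recurse(seed_l, nb0)
  best
}

# Direct per-slice re-scoring of the minimum-vein-slice rule.
oracle_slice_choice <- function(mask3d, vein_mask, geometry, min_pixels = 16) {
  d <- dim(mask3d)
  vein_idx <- which(vein_mask, arr.ind = TRUE)
  vein_mm <- sweep(vein_idx, 2, geometry$voxel_mm, `*`)
  best <- NULL
  for (z in seq_len(d[3])) {
    m2 <- mask3d[, , z]
    area <- sum(m2)
    if (area < min_pixels) next
    if (any(vein_mask[, , z] & m2)) next
    dist <- Inf
    if (nrow(vein_mm) > 0) {
      roi_idx <- which(m2, arr.ind = TRUE)
      roi_mm <- cbind(roi_idx[, 1] * geometry$voxel_mm[1],
                      roi_idx[, 2] * geometry$voxel_mm[2],
                      z * geometry$voxel_mm[3])
      dist <- min(apply(roi_mm, 1, function(p) {
        min(sqrt(rowSums(sweep(vein_mm, 2, p)^2)))
      }))
    }
    cand <- list(slice = z, dist = dist, area = area)
    if (is.null(best) || cand$dist > best$dist ||
        (cand$dist == best$dist && cand$area > best$area)) {
      best <- cand
    }
  }
  best
}

# ICC(2,1) from the two-way ANOVA table fitted by aov()
oracle_icc2_aov <- function(m) {
  df <- data.frame(score = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(score ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
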