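#' Four habenula susceptibility contrasts and CNRs
#'
#' Computes the susceptibility differences and contrast-to-noise ratios used
#' for habenula conspicuity analysis, all normalized by the susceptibility
#' standard deviation in the outer ROI:
#' \describe{
#'   \item{mean}{mean(Hb) - mean(outer ROI)}
#'   \item{peak}{mean(peak 5-voxel cluster) - mean(rest of the ROI)}
#'   \item{ap}{mean(posterior half) - mean(anterior half)}
#'   \item{ml}{mean(lateral half) - mean(medial half)}
#' }
#' CNRs are invariant under a global susceptibility offset (such as CSF
#' referencing) and under a common rescaling of the slice.
#'
#' @param chi_slice numeric matrix of susceptibility on the analysis slice;
#'   defaults to the slice stored in `roi`.
#' @param roi a `habenula_roi` from [analyze_habenula_roi()].
#' @return a one-row data frame with `dchi_mean`, `cnr_mean`, `dchi_peak`,
#'   `cnr_peak`, `dchi_ap`, `cnr_ap`, `dchi_ml`, `cnr_ml` (ppm and
#'   dimensionless) plus `sigma_outer` and `side`.
#' @export
compute_cnrs <- function(chi_slice = NULL, roi) {
  if (!inherits(roi, "habenula_roi")) stop("`roi` must be a habenula_roi")
  if (is.null(chi_slice)) chi_slice <- roi$chi_slice
  mask <- roi$mask2d
  outer <- roi$outer_roi
  sigma <- stats::sd(chi_slice[outer])
  if (!is.finite(sigma) || sigma == 0) stop("degenerate noise: sd over the outer ROI is zero")
  peak_mask <- array(FALSE, dim = dim(mask))
  peak_mask[roi$peak_cluster] <- TRUE
  rest <- mask & !peak_mask

  dchi_mean <- mean(chi_slice[mask]) - mean(chi_slice[outer])
  dchi_peak <- mean(chi_slice[peak_mask]) - mean(chi_slice[rest])
  dchi_ap <- mean(chi_slice[roi$partitions$posterior]) -
    mean(chi_slice[roi$partitions$anterior])
  dchi_ml <- mean(chi_slice[roi$partitions$lateral]) -
    mean(chi_slice[roi$partitions$medial])
  data.frame(side = roi$side,
             dchi_mean = dchi_mean, cnr_mean = dchi_mean / sigma,
             dchi_peak = dchi_peak, cnr_peak = dchi_peak / sigma,
             dchi_ap = dchi_ap, cnr_ap = dchi_ap / sigma,
             dchi_ml = dchi_ml, cnr_ml = dchi_ml / sigma,
             sigma_outer = sigma,
             stringsAsFactors = FALSE)
}

#' Voxelwise susceptibility-R2* correlation in the habenula
#'
#' Pearson correlation (two-sided p from the t distribution with n - 2
#' degrees of freedom) and ordinary least-squares regression of R2* on
#' susceptibility over the in-ROI voxels of the analysis slice. A positive
#' slope indicates an iron-like (paramagnetic) source of susceptibility
#' variation; a negative slope indicates a myelin-like source.
#'
#' @param chi_slice,r2star_slice numeric matrices on the analysis slice.
#' @param mask2d logical ROI matrix with at least 3 voxels.
#' @return a one-row data frame with `n`, `r`, `p`, `slope` (1/s per ppm),
#'   `intercept` (1/s) and `degenerate` (TRUE when either variable has zero
#'   variance, in which case `r`, `p` and `slope` are `NA`).
#' @export
chi_r2star_correlation <- function(chi_slice, r2star_slice, mask2d) {
  x <- chi_slice[mask2d]
  y <- r2star_slice[mask2d]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("correlation needs at least 3 in-mask voxels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(n = n, r = NA_real_, p = NA_real_, slope = NA_real_,
                      intercept = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  data.frame(n = n, r = unname(ct$estimate), p = ct$p.value,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             degenerate = FALSE)
}

#' Intraclass correlation coefficient for rater agreement
#'
#' Two-way ANOVA-based ICC for a complete subjects x raters score table.
#' The default variant is the two-way random-effects, absolute-agreement,
#' single-measure coefficient ICC(2,1),
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`;
#' the consistency variant ICC(3,1) is also available.
#'
#' @param scores numeric matrix or data frame, rows = subjects, columns =
#'   raters; no missing cells.
#' @param variant `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return the ICC value (scalar).
#' @export
icc_raters <- function(scores, variant = c("ICC2", "ICC3")) {
  variant <- match.arg(variant)
  m <- as.matrix(scores)
  if (any(!is.finite(m))) stop("score table has missing cells")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (variant == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Representative-scan selection for repeated sessions
#'
#' Given one row of summary parameters per scan (bilateral habenula volume,
#' mean susceptibility, mean first-echo magnitude, mean R2*), selects the
#' scan minimizing the sum over parameters of |value - across-scan mean| /
#' across-scan SD. Parameters with zero variance contribute nothing; ties go
#' to the lowest scan index.
#'
#' @param params numeric matrix or data frame, rows = scans, columns =
#'   parameters (any number of columns >= 1).
#' @return the 1-based index of the representative scan.
#' @export
select_representative_scan <- function(params) {
  m <- as.matrix(params)
  if (nrow(m) == 0L) stop("need at least one scan")
  if (nrow(m) == 1L) return(1L)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  dev <- abs(sweep(m, 2, mu))
  dev <- sweep(dev, 2, ifelse(sdv > 0, sdv, Inf), `/`)
  score <- rowSums(dev)
  which.min(score) # first minimum = lowest index on ties
}

#' Bilateral averaging of per-side contrast rows
#'
#' Averages the left and right [compute_cnrs()] rows quantity by quantity
#' (each side's CNR keeps its own outer-ROI noise before averaging).
#'
#' @param left,right one-row data frames from [compute_cnrs()].
#' @return a one-row data frame with `side = "bilateral"`.
#' @export
bilateral_average <- function(left, right) {
  num <- vapply(left, is.numeric, TRUE)
  out <- left
  out[num] <- (as.numeric(left[num]) + as.numeric(right[num])) / 2
  out$side <- "bilateral"
  out
}

#' Group summary of per-subject contrast records
#'
#' Computes the group-level statistics for a table of bilaterally averaged
#' subject records: column means and SDs, the Pearson correlation (with
#' two-sided p) between the visual conspicuity score and each of the four
#' CNRs, and a paired t-test of the lateral-medial susceptibility difference
#' against zero. When per-scan repeats are supplied, per-subject scan-rescan
#' standard deviations are added.
#'
#' @param records data frame with columns `visual_score`, `dchi_mean`,
#'   `cnr_mean`, `dchi_peak`, `cnr_peak`, `dchi_ap`, `cnr_ap`, `dchi_ml`,
#'   `cnr_ml` (one row per subject, as in the packaged contrast table).
#' @param repeats optional named list of data frames (same columns), one per
#'   repeated subject, holding that subject's per-scan rows.
#' @return a list with `n`, `column_means`, `column_sds`,
#'   `score_cnr_correlations` (data frame: cnr, r, p, flagged),
#'   `ml_ttest` (statistic, p), and optionally `scan_rescan_sd`.
#' @export
summarize_group <- function(records, repeats = NULL) {
  num_cols <- c("visual_score", "dchi_mean", "cnr_mean", "dchi_peak",
                "cnr_peak", "dchi_ap", "cnr_ap", "dchi_ml", "cnr_ml")
  missing <- setdiff(num_cols, names(records))
  if (length(missing) > 0) {
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(records[num_cols])
  n <- nrow(m)
  means <- colMeans(m)
  sds <- apply(m, 2, stats::sd)

  cnr_cols <- c("cnr_mean", "cnr_peak", "cnr_ap", "cnr_ml")
  cors <- do.call(rbind, lapply(cnr_cols, function(cc) {
    flagged <- n < 3L || sds["visual_score"] == 0 || sds[cc] == 0
    if (flagged) {
      data.frame(cnr = cc, r = NA_real_, p = NA_real_, flagged = TRUE)
    } else {
      ct <- stats::cor.test(m[, "visual_score"], m[, cc], method = "pearson")
      data.frame(cnr = cc, r = unname(ct$estimate), p = ct$p.value,
                 flagged = FALSE)
    }
  }))

  ml <- if (n >= 2L && sds["dchi_ml"] > 0) {
    tt <- stats::t.test(m[, "dchi_ml"])
    list(statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }

  out <- list(n = n, column_means = means, column_sds = sds,
              score_cnr_correlations = cors, ml_ttest = ml)
  if (!is.null(repeats)) {
    out$scan_rescan_sd <- do.call(rbind, lapply(names(repeats), function(id) {
      rm <- as.matrix(repeats[[id]][intersect(num_cols, names(repeats[[id]]))])
      data.frame(subject = id, t(apply(rm, 2, stats::sd)))
    }))
  }
  out
}
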