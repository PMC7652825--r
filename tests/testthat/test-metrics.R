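test_that("CNRs follow the four contrast definitions and their invariances", {
  res <- default_pipeline()
  roi <- res$roi_left
  z <- res$slice
  chi_slice <- res$chi_ref$values[, , z]
  cnr <- compute_cnrs(chi_slice, roi)
  # definitional identity: CNR = dchi / sigma(outer), exactly
  expect_equal(cnr$cnr_mean, cnr$dchi_mean / cnr$sigma_outer)
  expect_equal(cnr$cnr_peak, cnr$dchi_peak / cnr$sigma_outer)
  expect_equal(cnr$cnr_ap, cnr$dchi_ap / cnr$sigma_outer)
  expect_equal(cnr$cnr_ml, cnr$dchi_ml / cnr$sigma_outer)
  expect_equal(cnr$sigma_outer, stats::sd(chi_slice[roi$outer_roi]))

  # global offset leaves everything unchanged; scaling leaves CNRs unchanged
  cnr_off <- compute_cnrs(chi_slice + 0.05, roi)
  expect_equal(as.numeric(cnr_off[c("cnr_mean", "cnr_peak", "cnr_ap", "cnr_ml",
                                    "dchi_mean", "dchi_peak", "dchi_ap", "dchi_ml")]),
               as.numeric(cnr[c("cnr_mean", "cnr_peak", "cnr_ap", "cnr_ml",
                                "dchi_mean", "dchi_peak", "dchi_ap", "dchi_ml")]),
               tolerance = 1e-10)
  cnr_sc <- compute_cnrs(chi_slice * 2, roi)
  expect_equal(cnr_sc$dchi_mean, 2 * cnr$dchi_mean, tolerance = 1e-10)
  expect_equal(as.numeric(cnr_sc[c("cnr_mean", "cnr_peak", "cnr_ap", "cnr_ml")]),
               as.numeric(cnr[c("cnr_mean", "cnr_peak", "cnr_ap", "cnr_ml")]),
               tolerance = 1e-10)

  # uniform slice: degenerate noise is an error
  expect_error(compute_cnrs(matrix(1, nrow(chi_slice), ncol(chi_slice)), roi),
               "degenerate")

  # consistency with a published per-subject row: sigma back-computed from
  # the printed pair (0.0637, 7.6586) reproduces the printed CNR
  sigma16 <- 0.0637 / 7.6586
  expect_equal(0.0637 / sigma16, 7.6586, tolerance = 1e-4)
  expect_equal(sigma16, 0.008317, tolerance = 1e-4)
})

test_that("susceptibility-R2* correlation handles exact and degenerate input", {
  set.seed(2)
  chi <- matrix(stats::runif(64, 0, 0.1), 8)
  mask <- matrix(TRUE, 8, 8)
  r2 <- 50 + 100 * chi
  out <- chi_r2star_correlation(chi, r2, mask)
  expect_equal(out$r, 1)
  expect_equal(out$slope, 100)
  expect_equal(out$intercept, 50)
  # degenerate: constant R2*
  outd <- chi_r2star_correlation(chi, matrix(30, 8, 8), mask)
  expect_true(outd$degenerate)
  expect_true(is.na(outd$r))
  expect_error(chi_r2star_correlation(chi, r2, mask & FALSE), "at least 3")
  # p value matches the t distribution with n - 2 df
  set.seed(9)
  noisy <- r2 + matrix(stats::rnorm(64, sd = 5), 8)
  o2 <- chi_r2star_correlation(chi, noisy, mask)
  tval <- o2$r * sqrt((o2$n - 2) / (1 - o2$r^2))
  expect_equal(o2$p, 2 * stats::pt(-abs(tval), o2$n - 2), tolerance = 1e-12)
})

test_that("ICC matches the two-way ANOVA closed form", {
  # identical raters: perfect agreement
  m <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc_raters(m), 1)
  # constant offset breaks absolute agreement but not consistency
  m2 <- cbind(1:6, 1:6 + 1)
  expect_lt(icc_raters(m2, "ICC2"), 1)
  expect_equal(icc_raters(m2, "ICC3"), 1)
  # synthetic 6 x 3 tables against the aov() oracle
  for (seed in 1:5) {
    set.seed(seed)
    tab <- matrix(stats::runif(18, 1, 3), 6, 3)
    expect_equal(icc_raters(tab), oracle_icc2_aov(tab), tolerance = 1e-10)
  }
  expect_error(icc_raters(cbind(c(1, NA, 3), 1:3)), "missing")
  expect_error(icc_raters(matrix(1, 1, 3)), "at least 2")
})

test_that("representative scan minimizes the normalized L1 distance to the mean", {
  expect_equal(select_representative_scan(matrix(1:4, 1)), 1L)
  # hand-crafted: scan 2 closest to the 3-scan average
  p <- rbind(c(30, 0.040, 300, 25),
             c(33, 0.045, 310, 26),
             c(40, 0.060, 350, 30))
  mu <- colMeans(p)
  sdv <- apply(p, 2, stats::sd)
  scores <- rowSums(abs(sweep(sweep(p, 2, mu), 2, sdv, `/`)))
  expect_equal(select_representative_scan(p), which.min(scores))
  expect_equal(select_representative_scan(p), 2L)
  # identical scans: tie goes to the first
  expect_equal(select_representative_scan(matrix(5, 4, 4)), 1L)
  # zero-variance parameter contributes nothing (no NaN poisoning)
  p0 <- cbind(p[, 1:3], 7)
  expect_equal(select_representative_scan(p0), 2L)
})

test_that("group summary recomputes its own statistics exactly", {
  tab <- load_table1_fixture()
  gs <- summarize_group(tab)
  expect_equal(gs$n, 21)
  expect_equal(unname(gs$column_means["cnr_peak"]), mean(tab$cnr_peak))
  expect_equal(unname(gs$column_sds["dchi_ap"]), stats::sd(tab$dchi_ap))
  ct <- stats::cor.test(tab$visual_score, tab$cnr_ap)
  row <- gs$score_cnr_correlations[gs$score_cnr_correlations$cnr == "cnr_ap", ]
  expect_equal(row$r, unname(ct$estimate))
  expect_equal(row$p, ct$p.value)

  # duplicated record: zero SDs, flagged correlations
  dup <- tab[rep(3, 5), ]
  gsd <- summarize_group(dup)
  expect_true(all(gsd$column_sds == 0))
  expect_true(all(gsd$score_cnr_correlations$flagged))

  # scan-rescan SDs for repeated subjects
  reps <- list(v1 = tab[c(1, 2, 3), ], v3 = tab[c(4, 5, 6), ])
  gsr <- summarize_group(tab, repeats = reps)
  expect_equal(gsr$scan_rescan_sd$dchi_ap[1], stats::sd(tab$dchi_ap[1:3]))
  expect_error(summarize_group(tab[, 1:3]), "missing columns")
})

test_that("bilateral averaging combines per-side rows quantity by quantity", {
  res <- default_pipeline()
  bil <- bilateral_average(res$cnrs$left, res$cnrs$right)
  expect_equal(bil$side, "bilateral")
  expect_equal(bil$dchi_ap,
               (res$cnrs$left$dchi_ap + res$cnrs$right$dchi_ap) / 2)
  expect_equal(bil$cnr_peak,
               (res$cnrs$left$cnr_peak + res$cnrs$right$cnr_peak) / 2)
})
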