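test_that("the import gate opens at exactly 34 of 300 volumes", {
  expect_false(import_gate(33)$pass)
  expect_true(import_gate(34)$pass)
  expect_equal(import_gate(34)$pct, 100 * 34 / 300)
  g <- import_gate(300)
  expect_true(g$pass)
  expect_equal(g$pct, 100)
})

test_that("motion metrics match closed-form rigid displacements", {
  d <- c(12, 12, 8)
  mask <- array(TRUE, d)
  tr <- matrix(0, 10, 6,
               dimnames = list(NULL, c("tx", "ty", "tz",
                                       "rx", "ry", "rz")))
  trace <- structure(tr, reference = 1L, class = "motion_trace")
  mm0 <- motion_metrics(trace, mask, voxel = 1.5)
  expect_equal(mm0$abs_motion, 0)
  expect_equal(mm0$rel_motion, 0)
  # one 2 mm translation among 10 volumes: every in-mask voxel moves
  # exactly 2 mm, so abs average = 2/10 and rel counts two transitions
  tr[5, "tx"] <- 2
  trace <- structure(tr, reference = 1L, class = "motion_trace")
  mm <- motion_metrics(trace, mask, voxel = 1.5)
  expect_equal(mm$abs_motion, 0.2, tolerance = 1e-12)
  expect_equal(mm$rel_motion, 0.4, tolerance = 1e-12)
  # pure rotation about the volume centre still moves off-centre voxels
  tr[5, ] <- c(0, 0, 0, 0, 0, 0.1)
  trace <- structure(tr, reference = 1L, class = "motion_trace")
  mmr <- motion_metrics(trace, mask, voxel = 1.5)
  expect_gt(mmr$abs_motion, 0)
  # metrics depend only on transforms and geometry, never intensities
  expect_identical(motion_metrics(trace, mask, voxel = 1.5)$abs_motion,
                   mmr$abs_motion)
})

test_that("outlier percentages recompose across every stratification", {
  run <- outlier_run()
  st <- outlier_stats(run$res$table, run$inj$ds$gtab)
  expect_equal(st$total_pct,
               100 * st$n_flagged / st$n_scored)
  tb <- run$res$table
  # strata recompose to the total flag count
  shell <- run$inj$ds$gtab$shell[tb$volume]
  n_by_shell <- tapply(tb$flagged, shell, sum)
  expect_equal(sum(n_by_shell), st$n_flagged)
  pe <- run$inj$ds$gtab$pe_index[tb$volume]
  expect_equal(sum(tapply(tb$flagged, pe, sum)), st$n_flagged)
  expect_equal(sum(st$per_slice_count), st$n_flagged)
  # per-shell percentages match a brute-force recount
  for (sh in names(st$per_shell_pct)) {
    jj <- shell == as.numeric(sh)
    expect_equal(st$per_shell_pct[[sh]], 100 * mean(tb$flagged[jj]))
  }
  # a flag-free table reports zeros throughout
  tb0 <- tb; tb0$flagged <- FALSE
  st0 <- outlier_stats(tb0, run$inj$ds$gtab)
  expect_equal(st0$total_pct, 0)
  expect_true(all(unlist(st0$per_shell_pct) == 0))
})

test_that("prediction-based SNR matches the generator noise level", {
  ph <- noisy_phantom()
  mask <- ph$truth$brain_mask
  pred <- suppressMessages(predict_signal(ph$ds, mask))
  met <- cnr_snr(pred, ph$ds$data, ph$truth$wm_mask, ph$truth$gm_mask,
                 ph$ds$gtab)
  # generator: WM b0 = 700, sigma = 35 -> SNR 20 within 10%
  expect_lt(abs(met$snr_wm - 700 / 35) / (700 / 35), 0.10)
  expect_gt(met$snr_gm, met$snr_wm)   # GM has higher S0 here
  # anisotropic WM has positive CNR on every shell
  expect_true(all(unlist(met$cnr_wm) > 0))
})

test_that("degenerate inputs give null-with-reason, not infinities", {
  sc <- tiny_scheme()
  sim <- simulate_voxels(6, "dki", list(md = 1e-3, fa_ratio = 1, K = 0),
                         sc, snr = Inf)
  wm <- array(TRUE, c(6, 1, 1)); gm <- array(FALSE, c(6, 1, 1))
  # residuals identically zero: prediction equals the data
  met <- cnr_snr(sim$ds$data, sim$ds$data, wm, gm, sc$gtab)
  expect_true("snr" %in% names(met$nulls) ||
                length(met$cnr_wm) == 0 || is.null(met$snr_wm))
  # isotropic noise-free signal: constant prediction over the shell
  pred <- suppressMessages(predict_signal(sim$ds, wm, loo = FALSE))
  noisy <- sim$ds
  set.seed(2)
  noisy$data <- noisy$data + array(abs(rnorm(length(noisy$data), 0, 5)),
                                   dim(noisy$data))
  met2 <- cnr_snr(pred, noisy$data, wm, gm, sc$gtab)
  expect_lt(unlist(met2$cnr_wm)[1], 0.2)
})

test_that("registration QC is the masked Pearson correlation", {
  ph <- clean_phantom()
  mask <- ph$truth$brain_mask
  b0 <- ph$ds$data[, , , 1]
  expect_equal(registration_qc(b0, b0, mask), 1.0)
  expect_equal(registration_qc(b0, -b0, mask), -1.0)
  # a monotone intensity remap of the b0 stands in for a T2 volume
  t2 <- sqrt(b0 + 50)
  expect_gte(registration_qc(b0, t2, mask), 0.8)
  expect_null(registration_qc(b0, b0 * 0, mask))
})

test_that("the QC report carries every metric and survives gate failure", {
  run <- outlier_run()
  ph <- noisy_phantom()
  mask <- ph$truth$brain_mask
  tr <- matrix(0, dim(ph$ds)[4], 6,
               dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry",
                                       "rz")))
  trace <- structure(tr, reference = 1L, class = "motion_trace")
  met <- cnr_snr(run$pred, run$inj$ds$data, ph$truth$wm_mask,
                 ph$truth$gm_mask, ph$ds$gtab)
  out_dir <- withr::local_tempdir()
  rep <- assemble_report(import_gate(dim(ph$ds)[4], 60, 34),
                         motion = motion_metrics(trace, mask, 1.5),
                         outliers = outlier_stats(run$res$table,
                                                  ph$ds$gtab),
                         cnr = met,
                         t2_correlation = 0.93,
                         provenance = list(seed = 3),
                         ds = ph$ds, wm_mask = ph$truth$wm_mask,
                         gm_mask = ph$truth$gm_mask, out_dir = out_dir)
  expect_s3_class(rep, "qc_report")
  for (field in c("acquired_volumes_pct", "import_gate_pass",
                  "abs_motion_mm", "rel_motion_mm", "outlier_pct",
                  "cnr_wm", "snr_wm", "snr_gm", "wm_sq_residuals",
                  "t2_b0_correlation"))
    expect_false(is.null(rep[[field]]))
  expect_true(file.exists(file.path(out_dir, "qc_report.json")))
  expect_true(file.exists(file.path(out_dir, "shell_mean_signal.png")))
  expect_true(file.exists(file.path(out_dir, "wm_gm_boundary.png")))
  parsed <- jsonlite::read_json(file.path(out_dir, "qc_report.json"))
  expect_equal(parsed$t2_b0_correlation, 0.93)
  # gate-failed session: report still produced, later stages null
  rep0 <- assemble_report(import_gate(20, 300, 34))
  expect_false(rep0$import_gate_pass)
  expect_null(rep0$abs_motion_mm)
  expect_true(any(grepl("not run", unlist(rep0$nulls))))
})
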