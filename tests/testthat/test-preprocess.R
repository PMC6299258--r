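test_that("b0 pair selection keeps the best-correlating pair per PE", {
  ph <- noisy_phantom()
  mask <- ph$truth$brain_mask
  # exactly 2 b0s per PE: both must be selected regardless of scores
  sel <- select_b0_pairs(ph$ds, mask, align = FALSE)
  b0s <- which(ph$ds$gtab$b0)
  pe <- ph$ds$gtab$pe_index[b0s]
  for (row in names(sel$pairs))
    expect_setequal(sel$pairs[[row]], b0s[pe == as.integer(row)])
  expect_true(sel$reference %in% unlist(sel$pairs))
  # corrupt one b0 of a 3-b0 PE group: it must be excluded
  ds2 <- ph$ds
  extra <- which(!ph$ds$gtab$b0)[1]
  ds2$gtab$bvals[extra] <- 0
  ds2$gtab$b0[extra] <- TRUE
  ds2$gtab$shell[extra] <- 0
  ds2$gtab$pe_index[extra] <- 1L
  ds2$data[, , , extra] <- ds2$data[, , , b0s[pe == 1][1]]
  ds2$data[, , 8:12, extra] <- ds2$data[, , 8:12, extra] * 0.15
  sel2 <- select_b0_pairs(ds2, mask, align = FALSE)
  expect_false(extra %in% sel2$pairs[["1"]])
  # a single b0 in every PE direction is a hard error
  one <- ph$ds
  keep <- c(which(one$gtab$b0)[1], which(!one$gtab$b0))
  one$data <- one$data[, , , keep, drop = FALSE]
  one$gtab <- gradient_table(one$gtab$bvals[keep],
                             one$gtab$bvecs[keep, ],
                             one$gtab$pe_index[keep])
  expect_error(suppressWarnings(select_b0_pairs(one, mask,
                                                align = FALSE)),
               "field estimation impossible|two b0")
})

test_that("reversed-PE field estimation recovers a known displacement", {
  ph <- noisy_phantom()
  mask <- ph$truth$brain_mask
  d <- dim(mask)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                   z = seq_len(d[3]))
  fld <- array(3 * sin(pi * g$y / d[2]) * sin(pi * g$z / d[3]) *
                 sin(pi * g$x / d[1]), d)
  b0a <- ph$ds$data[, , , 1]
  b0b <- ph$ds$data[, , , 2]
  up <- neodwi:::pe_shift(b0a, fld, 2, 1.5, sign = +1)
  down <- neodwi:::pe_shift(b0b, fld, 2, 1.5, sign = -1)
  est <- estimate_pe_field(up, down, ph$ds$acq, c(1, 2), mask)
  expect_gt(stats::cor(est[mask], fld[mask]), 0.9)
  expect_true(all(est[!mask] == 0))
  # identical images give a (near-)zero field
  z <- estimate_pe_field(b0a, b0a, ph$ds$acq, c(1, 2), mask)
  expect_lt(max(abs(z)), 0.05)
  # infinite regularisation drives the in-mask field to a constant
  hi <- estimate_pe_field(up, down, ph$ds$acq, c(1, 2), mask,
                          lambda_reg = 1e5)
  expect_lt(stats::sd(hi[mask]), 0.01 * stats::sd(est[mask]))
  # parallel (non-opposite) PE rows are rejected
  expect_error(estimate_pe_field(up, down, ph$ds$acq, c(1, 1), mask),
               "opposite")
})

test_that("PE unwarping inverts the distortion model", {
  ph <- clean_phantom()
  mask <- ph$truth$brain_mask
  d <- dim(mask)
  b0 <- neodwi:::smooth3(ph$ds$data[, , , 1], 1.2)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                   z = seq_len(d[3]))
  fld <- array(3 * sin(pi * g$y / d[2]) * sin(pi * g$z / d[3]) *
                 sin(pi * g$x / d[1]), d)
  pef <- structure(fld, axis = 2L, voxel = 1.5, class = "pe_field")
  # zero field is the identity
  zf <- structure(fld * 0, axis = 2L, voxel = 1.5, class = "pe_field")
  expect_equal(apply_pe_unwarp(b0, zf, ph$ds$acq, 1), b0,
               tolerance = 1e-12)
  # constant +1 voxel field shifts the image one voxel against PE
  cf <- structure(array(1.5, d), axis = 2L, voxel = 1.5,
                  class = "pe_field")
  shifted <- apply_pe_unwarp(b0, cf, ph$ds$acq, 1)
  expect_equal(shifted[, 1:(d[2] - 1), ][mask[, 2:d[2], ]],
               b0[, 2:d[2], ][mask[, 2:d[2], ]], tolerance = 1e-6)
  # distort-then-undistort returns the smooth image within 1% of range
  up <- neodwi:::pe_shift(b0, fld, 2, 1.5, sign = +1)
  unw <- apply_pe_unwarp(up, pef, ph$ds$acq, 1)
  interior <- mask & neodwi:::smooth3(mask * 1, 1.5) > 0.95
  rel <- sqrt(mean((unw - b0)[interior]^2)) / diff(range(b0[mask]))
  expect_lt(rel, 0.01)
  expect_error(apply_pe_unwarp(b0[1:10, , ], pef, ph$ds$acq, 1),
               "grid mismatch")
})

test_that("realignment recovers injected motion and rotates b-vectors", {
  ra <- realigned_artefacts()
  inj <- artefact_phantom()
  # 2 mm translation on a b0 volume recovered within 0.1 mm
  expect_equal(unname(ra$trace[3, "tx"]), 2, tolerance = 0.05)
  expect_lt(max(abs(ra$trace[3, 2:3])), 0.15)
  # 10 degree z-rotation on a weighted volume: b-vector rotated to match
  Rz <- neodwi::rigid_rotation(c(0, 0, 0, 0, 0, 10 * pi / 180))
  expect_lt(angle_deg(ra$ds$gtab$bvecs[15, ],
                      Rz %*% inj$ds$gtab$bvecs[15, ]), 1)
  # unmoved b0 volumes sit at (essentially) zero
  b0s <- setdiff(which(inj$ds$gtab$b0), c(1, 3))
  expect_lt(max(abs(ra$trace[b0s, 1:3])), 0.1)
  expect_lt(max(abs(ra$trace[b0s, 4:6])) * 180 / pi, 0.1)
  # the reference row is exactly zero
  expect_equal(unname(ra$trace[1, ]), rep(0, 6))
  # rotation preserved b-value and unit norms
  expect_equal(ra$ds$gtab$bvals, inj$ds$gtab$bvals)
  w <- !ra$ds$gtab$b0
  expect_equal(sqrt(rowSums(ra$ds$gtab$bvecs[w, ]^2)),
               rep(1, sum(w)), tolerance = 1e-9)
})

test_that("spherical-harmonic prediction reproduces the angular signal", {
  # isotropic data: the prediction equals the shell mean everywhere
  sc <- tiny_scheme()
  sim <- simulate_voxels(6, "dki", list(md = 1e-3, fa_ratio = 1, K = 0),
                         sc, snr = Inf)
  mask <- array(TRUE, c(6, 1, 1))
  pred <- suppressMessages(predict_signal(sim$ds, mask, sh_order = 4,
                                          loo = FALSE))
  ii <- shell_indices(sc$gtab)[["1000"]]
  for (v in ii)
    expect_equal(pred[, , , v], sim$ds$data[, , , ii[1]],
                 tolerance = 1e-6)
  # single-tensor voxels at service scale: R^2 > 0.95 against the
  # noise-free signal
  scf <- full_scheme()
  simn <- simulate_voxels(30, "dki", list(md = 1e-3, fa_ratio = 0.3,
                                          K = 0.6),
                          scf, snr = 20, seed = 6)
  maskn <- array(TRUE, c(30, 1, 1))
  predn <- suppressMessages(predict_signal(simn$ds, maskn, sh_order = 4))
  dwi <- which(!scf$gtab$b0)
  p <- matrix(predn, 30)[, dwi]
  cl <- simn$clean[, dwi]
  r2 <- 1 - sum((p - cl)^2) / sum((cl - mean(cl))^2)
  expect_gt(r2, 0.95)
  # order 0 collapses to the spherical mean per shell
  pred0 <- suppressMessages(predict_signal(simn$ds, maskn, sh_order = 0,
                                           loo = FALSE))
  sh1000 <- shell_indices(scf$gtab)[["1000"]]
  expect_equal(pred0[1, 1, 1, sh1000[1]],
               mean(simn$ds$data[1, 1, 1, sh1000]), tolerance = 1e-8)
})

test_that("outlier slices are detected, replaced, and nothing else", {
  run <- outlier_run()
  tb <- run$res$table
  dro <- artefact_config()$dropout
  keys <- paste(tb$volume, tb$slice)
  inj_keys <- paste(dro$volume, dro$slice)
  hits <- sum(tb$flagged[keys %in% inj_keys])
  expect_gte(hits, ceiling(0.95 * nrow(dro)))
  fp <- sum(tb$flagged[!(keys %in% inj_keys)])
  expect_lte(fp / (nrow(tb) - nrow(dro)), 0.001)
  # flagged slices were replaced and moved towards the clean signal
  expect_true(all(tb$replaced[tb$flagged]))
  expect_true(all(tb$replaced <= tb$flagged))
  clean <- clean_phantom()$ds$data
  mask <- run$mask
  errs <- vapply(seq_len(nrow(dro)), function(i) {
    s <- dro$slice[i]; v <- dro$volume[i]
    m <- mask[, , s]
    c(before = mean(abs(run$inj$ds$data[, , s, v][m] -
                          clean[, , s, v][m])),
      after = mean(abs(run$res$ds$data[, , s, v][m] -
                         clean[, , s, v][m])))
  }, numeric(2))
  # replacement removes most of the dropout error on average and always
  # improves every slice
  expect_lt(mean(errs["after", ]), 0.3 * mean(errs["before", ]))
  expect_true(all(errs["after", ] < errs["before", ]))
  # flags live only on weighted volumes
  expect_true(all(!run$inj$ds$gtab$b0[tb$volume]))
  # infinite threshold leaves the data untouched
  oI <- detect_replace_outliers(run$inj$ds, run$pred, mask,
                                z_thresh = Inf)
  expect_identical(oI$ds$data, run$inj$ds$data)
  expect_false(any(oI$table$flagged))
})

test_that("outlier detection is invariant to global intensity scaling", {
  run <- outlier_run()
  ds2 <- run$inj$ds
  ds2$data <- ds2$data * 7.3
  pred2 <- suppressMessages(predict_signal(ds2, run$mask))
  o2 <- detect_replace_outliers(ds2, pred2, run$mask)
  expect_identical(o2$table$flagged, run$res$table$flagged)
})

test_that("a mostly-corrupted volume is marked unusable, not replaced", {
  ph <- noisy_phantom()
  mask <- ph$truth$brain_mask
  nz <- dim(ph$ds)[3]
  dro <- data.frame(volume = 20, slice = 2:(nz - 1), factor = 0.15)
  inj <- inject_artifacts(ph$ds, ph$truth, dropout = dro)
  pred <- suppressMessages(predict_signal(inj$ds, mask))
  res <- detect_replace_outliers(inj$ds, pred, mask)
  expect_true(20 %in% res$unusable)
  tb <- res$table
  expect_false(any(tb$replaced[tb$volume == 20]))
})

test_that("super-resolution inverts the thick-slice forward model", {
  ph <- clean_phantom()
  hi <- neodwi:::smooth3(ph$ds$data[, , , 1], 0.8)
  mask <- ph$truth$brain_mask
  # delta profile at thickness = spacing: the unregularised inverse is
  # the identity
  stack0 <- sample_thick_slices(hi, 1.5, 1.5, "delta", voxel = 1.5)
  expect_equal(superresolve(stack0, 1.5, 1.5, "delta", lambda_reg = 0),
               hi, tolerance = 1e-8)
  # boxcar 3 mm at 1.5 mm: reconstruction beats the blurred stack and
  # stays within 5% of the dynamic range
  stack <- sample_thick_slices(hi, 3, 1.5, "boxcar", voxel = 1.5)
  rec <- superresolve(stack, 3, 1.5, "boxcar")
  rmse_rec <- sqrt(mean((rec[mask] - hi[mask])^2))
  rmse_stack <- sqrt(mean((stack[mask] - hi[mask])^2))
  expect_lt(rmse_rec, rmse_stack)
  expect_lt(rmse_rec / diff(range(hi[mask])), 0.05)
  # a constant input is reproduced exactly (flux conservation)
  cst <- array(3, dim(hi))
  expect_equal(superresolve(sample_thick_slices(cst, 3, 1.5), 3, 1.5),
               cst, tolerance = 1e-9)
  # 4-D stacks are handled volume by volume
  st4 <- array(0, c(dim(stack), 2))
  st4[, , , 1] <- stack; st4[, , , 2] <- stack
  rec4 <- superresolve(st4, 3, 1.5, "boxcar")
  expect_equal(rec4[, , , 1], rec, tolerance = 1e-12)
})

test_that("preprocessing lowers the in-mask error of corrupted data", {
  ra <- realigned_artefacts()
  inj <- artefact_phantom()
  clean <- clean_phantom()$ds$data
  mask <- inj$truth$brain_mask
  pred <- suppressMessages(predict_signal(ra$ds, mask))
  fixed <- detect_replace_outliers(ra$ds, pred, mask)$ds
  m4 <- array(mask, dim(clean))
  rmse_raw <- sqrt(mean((inj$ds$data[m4] - clean[m4])^2))
  rmse_fix <- sqrt(mean((fixed$data[m4] - clean[m4])^2))
  expect_lt(rmse_fix, rmse_raw)
})
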