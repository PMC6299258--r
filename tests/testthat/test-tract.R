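test_that("mask warping follows the displacement field", {
  d <- c(16, 16, 10)
  m <- array(FALSE, d)
  m[6:9, 6:9, 4:6] <- TRUE
  # identity warp returns the identical mask
  w0 <- array(0, c(d, 3))
  expect_identical(warp_mask(m, w0, voxel = 1.5), m)
  # a pure +3 mm x-translation shifts the mask 2 voxels
  wt <- w0; wt[, , , 1] <- 3
  shifted <- warp_mask(m, wt, voxel = 1.5)
  expect_identical(shifted[8:11, 6:9, 4:6], m[6:9, 6:9, 4:6])
  expect_false(any(shifted[6:7, , ]))
  # smooth random warp then its numeric inverse: Dice >= 0.9
  set.seed(3)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                   z = seq_len(d[3]))
  ws <- array(0, c(d, 3))
  for (k in 1:3)
    ws[, , , k] <- array(2 * sin(pi * g$x / d[1] + k) *
                           sin(pi * g$y / d[2]), d)
  fwd <- warp_mask(m, ws, voxel = 1.5)
  back <- warp_mask(fwd, warp_invert(ws, voxel = 1.5), voxel = 1.5)
  expect_gte(dice_coef(back, m), 0.9)
  expect_error(warp_mask(m, w0[1:8, , , , drop = FALSE], voxel = 1.5),
               "grid")
})

test_that("the default protocol library holds 16 tracts, 13 bilateral", {
  dir <- withr::local_tempdir()
  write_default_protocols(dir)
  prots <- load_protocols(dir)
  expect_length(prots, 16)
  expect_equal(sum(vapply(prots, function(p) p$bilateral, logical(1))),
               13)
  nm <- vapply(prots, function(p) p$name, character(1))
  expect_setequal(nm, c("cst", "ar", "atr", "str", "ptr", "slf", "ilf",
                        "ifo", "unc", "fmi", "fma", "mcp", "ml", "fx",
                        "cgc", "cgh"))
  # bilateral protocols expand into left/right mask sets
  bil <- prots[[which(nm == "cst")]]
  expect_false(is.null(bil$left))
  expect_false(is.null(bil$right))
  expect_gt(sum(bil$left$seed), 0)
  expect_gt(sum(bil$right$seed), 0)
  # commissural tracts carry no mid-sagittal exclusion
  fmi <- prots[[which(nm == "fmi")]]
  expect_equal(sum(fmi$masks$exclusion), 0)
  cst_excl <- bil$left$exclusion
  expect_gt(sum(cst_excl), 0)
})

test_that("protocol loading fails informatively on broken descriptors", {
  dir <- withr::local_tempdir()
  write_default_protocols(dir)
  # remove one mask file: error names the tract
  file.remove(file.path(dir, "fx_l_seed.nii.gz"))
  expect_error(load_protocols(dir), "fx")
  # empty seed mask is a validation error
  expect_error(tract_protocol("empty", array(FALSE, c(4, 4, 4))),
               "empty seed")
})

test_that("streamlines follow the bundle and honour the protocol masks", {
  bf <- bundle_fixture()
  pr <- tract_protocol("bundle", bf$seed_full, list(bf$way), bf$stop)
  tm <- track(bf$fod, pr, n_samples = 60, seed = 5)
  expect_equal(tm$seeded, 60 * sum(bf$seed_full))
  expect_gte(tm$successful / tm$seeded, 0.8)
  nt <- normalise_threshold(tm)
  expect_gte(dice_coef(nt$mask, bf$bundle), 0.6)
  # probability along the bundle core from a core seed
  pc <- tract_protocol("core", bf$seed_core, list(bf$way), bf$stop)
  tc <- track(bf$fod, pc, n_samples = 200, seed = 6)
  lane <- (tc$counts / tc$successful)[bf$xs[1]:bf$mid, bf$core_y,
                                      bf$core_z]
  expect_true(all(lane >= 0.5))
  # an exclusion mask covering the bundle kills every streamline
  pk <- tract_protocol("kill", bf$seed_full, list(bf$way), bf$stop,
                       exclusion = bf$way)
  tk <- track(bf$fod, pk, n_samples = 20, seed = 5)
  expect_equal(tk$successful, 0)
  expect_equal(sum(tk$counts), 0)
  # seeding inside the stop mask yields zero-length failures
  ps <- tract_protocol("stopseed", bf$stop, list(bf$way), bf$stop)
  ts <- track(bf$fod, ps, n_samples = 10, seed = 5)
  expect_equal(ts$successful, 0)
  # streamline accounting
  expect_equal(tm$successful + (tm$seeded - tm$successful), tm$seeded)
})

test_that("tracking is deterministic given the seed", {
  bf <- bundle_fixture()
  pr <- tract_protocol("bundle", bf$seed_core, list(bf$way), bf$stop)
  t1 <- track(bf$fod, pr, n_samples = 40, seed = 77)
  t2 <- track(bf$fod, pr, n_samples = 40, seed = 77)
  expect_identical(t1$counts, t2$counts)
})

test_that("probability maps normalise, threshold and average correctly", {
  d <- c(6, 6, 4)
  counts <- array(0, d)
  counts[3, 3, 2] <- 100
  tm <- structure(list(counts = counts, seeded = 120L,
                       successful = 100L, prob = counts / 100,
                       name = "toy", params = list()),
                  class = "tract_map")
  nt <- normalise_threshold(tm)
  expect_equal(nt$prob[3, 3, 2], 1.0)
  # threshold 0: support equals the visited set
  nt0 <- normalise_threshold(tm, thresholds = 0)
  expect_identical(nt0$thresholded[[1]] > 0, counts > 0)
  # zero successful: defined empty output with a warning
  tm0 <- structure(list(counts = counts * 0, seeded = 10L,
                        successful = 0L, prob = counts * 0,
                        name = "toy0", params = list()),
                   class = "tract_map")
  expect_warning(nt_empty <- normalise_threshold(tm0), "no successful")
  expect_equal(sum(nt_empty$mask), 0)
  # group averaging: identical maps unchanged; adding a zero map halves
  m <- nt$prob
  expect_equal(group_average(list(m, m)), m)
  expect_equal(group_average(list(m, m * 0)), m / 2)
  expect_error(group_average(list(m, m[1:3, , ])), "grid")
})

test_that("tract-wise regression recovers constructed age effects", {
  d <- c(8, 8, 4)
  masks <- list(a = array(c(rep(TRUE, 32), rep(FALSE, 224)), d),
                b = array(c(rep(FALSE, 224), rep(TRUE, 32)), d))
  ages <- c(38, 39, 40, 41, 42, 43, 44, 45)
  vols <- rep(400, 8) + c(-2, 3, 1, -1, 0, 2, -3, 0)
  # tract a: metric = 2 + 0.1 (age - mean); tract b: age-independent
  maps <- lapply(seq_along(ages), function(i) {
    m <- array(0, d)
    m[masks$a] <- 2 + 0.1 * (ages[i] - mean(ages))
    m[masks$b] <- 5
    m
  })
  # the constructed metrics fit exactly; summary.lm warns about that
  res <- suppressWarnings(tract_metric_regression(maps, masks, ages,
                                                  vols))
  ra <- res[res$tract == "a", ]
  expect_equal(ra$beta_age, 0.1, tolerance = 1e-10)
  expect_equal(ra$beta_age_norm, 0.05, tolerance = 1e-10)
  expect_equal(ra$beta0, 2, tolerance = 1e-10)
  expect_true(ra$significant)
  rb <- res[res$tract == "b", ]
  expect_equal(rb$beta_age, 0, tolerance = 1e-10)
  expect_false(rb$significant)
  # Bonferroni correction across tracts
  expect_equal(res$p_corrected,
               stats::p.adjust(res$p, method = "bonferroni"))
  expect_error(tract_metric_regression(maps[1:2], masks, ages[1:2],
                                       vols[1:2]),
               "3 subjects")
  expect_error(tract_metric_regression(maps, masks, ages, ages),
               "rank-deficient")
})

test_that("noisy recovery of a programmed FA slope stays within 2 SE", {
  d <- c(8, 8, 4)
  mask <- list(core = array(c(rep(TRUE, 48), rep(FALSE, 208)), d))
  ages <- seq(37, 45, length.out = 14)
  vols <- 380 + 5 * (ages - 41) + rnorm(14, 0, 2)
  slope <- 0.012
  set.seed(21)
  maps <- lapply(seq_along(ages), function(i) {
    m <- array(0, d)
    m[mask$core] <- 0.25 + slope * (ages[i] - mean(ages)) +
      rnorm(sum(mask$core), 0, 0.02)
    m
  })
  res <- tract_metric_regression(maps, mask, ages, vols)
  se <- abs(res$beta_age - slope) /
    max(summary(stats::lm(vapply(maps, function(m) mean(m[mask$core]),
                                 numeric(1)) ~ I(ages - mean(ages)) +
                            I(vols - mean(vols))))$coefficients[2, 2],
        1e-12)
  expect_lt(se, 2)
})
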