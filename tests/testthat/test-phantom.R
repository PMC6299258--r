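test_that("noise-free signals follow the closed-form compartment model", {
  ph <- clean_phantom()
  ds <- ph$ds; tr <- ph$truth
  # b0 in the bundle equals the white-matter S0 exactly
  wmv <- arrayInd(which(tr$bundle1 & !tr$periventricular)[1],
                  dim(tr$tissue))
  b0v <- which(ds$gtab$b0)[1]
  expect_equal(ds$data[wmv[1], wmv[2], wmv[3], b0v], 700)
  # an isotropic CSF voxel attenuates as exp(-b d): e^-3 at b = 1000
  csf <- arrayInd(which(tr$csf_mask)[3], dim(tr$tissue))
  v1000 <- which(ds$gtab$shell == 1000)[1]
  expect_equal(ds$data[csf[1], csf[2], csf[3], v1000] / 1000, exp(-3),
               tolerance = 1e-12)
  # per-shell mean WM signal matches the analytic mean of the generating
  # model (Rician mean of the clean signal) within 3 standard errors
  sigma <- 20
  spec <- phantom_spec(scheme = desk_scheme(), sigma = sigma, seed = 7)
  phn <- build_phantom(spec)
  core <- tr$bundle1 & !tr$periventricular
  rice_mean <- function(S, s) {
    x <- S^2 / (2 * s^2)
    m <- s * sqrt(pi / 2) *
      ((1 + x) * besselI(x / 2, 0, TRUE) + x * besselI(x / 2, 1, TRUE))
    hi <- x > 350
    m[hi] <- sqrt(S[hi]^2 + s^2)
    m
  }
  for (sh in c("1000", "2600")) {
    ii <- shell_indices(ds$gtab)[[sh]]
    clean_vals <- ds$data[, , , ii][array(core, dim(tr$tissue))]
    expected <- mean(rice_mean(clean_vals, sigma))
    vals <- phn$ds$data[, , , ii][array(core, dim(tr$tissue))]
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - expected), 3 * se)
  }
})

test_that("the phantom is deterministic given spec and seed", {
  s <- phantom_spec(scheme = tiny_scheme(), sigma = 30, seed = 42)
  a <- build_phantom(s)
  b <- build_phantom(s)
  expect_identical(a$ds$data, b$ds$data)
  c <- build_phantom(phantom_spec(scheme = tiny_scheme(), sigma = 30,
                                  seed = 43))
  expect_false(identical(a$ds$data, c$ds$data))
})

test_that("Rician noise shows positive bias and the configured variance", {
  n <- 10000
  s0 <- 500; sigma <- 80   # SNR > 5
  set.seed(1)
  draws <- sqrt((s0 + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  expect_gt(mean(draws), s0)
  expect_lt(abs(stats::var(draws) - sigma^2) / sigma^2, 0.10)
})

test_that("artefact injection records exactly what it applies", {
  ph <- clean_phantom()
  # zero-amplitude config returns the input bit-wise
  out0 <- inject_artifacts(ph$ds, ph$truth,
                           motion = data.frame(volume = 1, tx = 0, ty = 0,
                                               tz = 0, rx = 0, ry = 0,
                                               rz = 0)[0, ])
  expect_identical(out0$ds$data, ph$ds$data)
  # dropout factor scales the slice mean exactly (before noise)
  inj <- inject_artifacts(ph$ds, ph$truth,
                          dropout = data.frame(volume = 5, slice = 10,
                                               factor = 0.2),
                          spin_history = data.frame(volume = 7, slice = 4,
                                                    gain = 1.2))
  expect_equal(mean(inj$ds$data[, , 10, 5]),
               0.2 * mean(ph$ds$data[, , 10, 5]))
  expect_equal(mean(inj$ds$data[, , 4, 7]),
               1.2 * mean(ph$ds$data[, , 4, 7]))
  # bookkeeping: corrupted slices in data equal the truth records
  expect_equal(nrow(inj$truth$dropout) + nrow(inj$truth$spin_history), 2)
  expect_error(inject_artifacts(ph$ds, ph$truth,
                                dropout = data.frame(volume = 1, slice = 1,
                                                     factor = 1.5)),
               "\\(0, 1\\]")
})

test_that("thick-slice sampling implements the slice-profile integral", {
  ramp <- array(0, c(4, 4, 20))
  for (k in 1:20) ramp[, , k] <- k
  # delta profile at thickness = spacing is the identity
  expect_equal(sample_thick_slices(ramp, 1.5, 1.5, "delta", voxel = 1.5),
               ramp)
  # a constant volume is conserved by any normalised profile
  cst <- array(7, c(4, 4, 20))
  expect_equal(sample_thick_slices(cst, 3, 1.5, "boxcar", voxel = 1.5),
               cst, tolerance = 1e-12)
  # 3 mm boxcar on a ramp: each sample is the slab mean of the ramp,
  # which equals the ramp value at the slab centre (interior slices)
  ts <- sample_thick_slices(ramp, 3, 1.5, "boxcar", voxel = 1.5)
  expect_equal(ts[1, 1, 5:15], ramp[1, 1, 5:15], tolerance = 1e-12)
  # un-normalised numeric profile is rejected
  expect_error(sample_thick_slices(ramp, 3, 1.5, c(1, 1, 1), voxel = 1.5),
               "normalised")
})

test_that("voxel simulator rejects over-full compartment fractions", {
  expect_error(simulate_voxels(2, "fibres",
                               list(fractions = c(0.6, 0.5),
                                    dirs = list(c(1, 0, 0), c(0, 1, 0)),
                                    f_iso = 0.1),
                               tiny_scheme()),
               "exceed")
})
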