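test_that("kurtosis tensor fit is exact on noise-free signals", {
  sc <- full_scheme()
  # isotropic, K = 0: MD exact, MK and FA zero
  sim <- simulate_voxels(3, "dki", list(md = 1e-3, fa_ratio = 1, K = 0),
                         sc, snr = Inf)
  fit <- fit_dki(sim$ds, array(TRUE, c(3, 1, 1)))
  maps <- tensor_derived_maps(fit)
  expect_equal(maps$MD[1, 1, 1], 1.0, tolerance = 1e-6)
  expect_lt(abs(maps$MK[1, 1, 1]), 1e-6)
  expect_lt(maps$FA[1, 1, 1], 1e-6)
  # anisotropic with kurtosis: all parameters recovered exactly
  sim2 <- simulate_voxels(2, "dki", list(md = 1e-3, fa_ratio = 0.3,
                                         K = 0.6), sc, snr = Inf)
  fit2 <- fit_dki(sim2$ds, array(TRUE, c(2, 1, 1)))
  expect_equal(fit2$MK[1], 0.6, tolerance = 1e-4)
  # single-shell input is a precondition error
  one_shell <- dhcp_scheme(n_b0 = 4, shells = c(`1000` = 12))
  sim3 <- simulate_voxels(2, "dki", list(), one_shell, snr = Inf)
  expect_error(fit_dki(sim3$ds, array(TRUE, c(2, 1, 1))), "two")
})

test_that("kurtosis and diffusivity are recovered under noise", {
  sc <- full_scheme()
  sim <- simulate_voxels(300, "dki", list(md = 1e-3, fa_ratio = 0.3,
                                          K = 0.6), sc, snr = 20,
                         seed = 4)
  fit <- fit_dki(sim$ds, array(TRUE, c(300, 1, 1)))
  maps <- tensor_derived_maps(fit)
  expect_lt(abs(mean(fit$MK) - 0.6), 0.1)
  expect_lt(abs(mean(maps$MD) - 1.0) / 1.0, 0.03)
  # principal eigenvector parallel to the generating fibre within 2 deg
  vbar <- colMeans(abs(matrix(maps$V1, 300, 3)))
  expect_lt(angle_deg(vbar, c(1, 0, 0)), 2)
})

test_that("fitting kurtosis-free data yields negligible mean kurtosis", {
  sc <- full_scheme()
  sim <- simulate_voxels(200, "dki", list(md = 1e-3, fa_ratio = 0.3,
                                          K = 0), sc, snr = 30, seed = 5)
  fit <- fit_dki(sim$ds, array(TRUE, c(200, 1, 1)))
  expect_lt(abs(stats::median(fit$MK)), 0.05)
})

test_that("derived maps match an independent implementation of FA", {
  sc <- full_scheme()
  sim <- simulate_voxels(2, "dki", list(md = 1e-3, fa_ratio = 0.2,
                                        K = 0.3, dir = c(0, 1, 0)),
                         sc, snr = Inf)
  fit <- fit_dki(sim$ds, array(TRUE, c(2, 1, 1)))
  maps <- tensor_derived_maps(fit)
  # brute-force oracle from the generating eigenvalues
  l1 <- 3e-3 / (1 + 2 * 0.2); l23 <- 0.2 * l1
  l <- c(l1, l23, l23)
  fa_ref <- sqrt(3 / 2) * sqrt(sum((l - mean(l))^2)) / sqrt(sum(l^2))
  expect_equal(maps$FA[1, 1, 1], fa_ref, tolerance = 1e-4)
  expect_equal(maps$AD[1, 1, 1], l1 * 1e3, tolerance = 1e-3)
  expect_equal(maps$RD[1, 1, 1], l23 * 1e3, tolerance = 1e-3)
  expect_gte(maps$AD[1, 1, 1], maps$RD[1, 1, 1])
  expect_lt(angle_deg(maps$V1[1, 1, 1, ], c(0, 1, 0)), 1)
})

test_that("NODDI-Bingham recovers fractions and dispersion", {
  sc <- full_scheme()
  # pure free water pins the isotropic fraction
  simw <- simulate_voxels(4, "noddi", list(f_iso = 1), sc, snr = 25,
                          seed = 2)
  fw <- fit_noddi_bingham(simw$ds, array(TRUE, c(4, 1, 1)))
  expect_true(all(fw$f_iso >= 0.95))
  # parameter recovery at SNR 25 (medians over voxels)
  sim <- simulate_voxels(50, "noddi",
                         list(f_in = 0.5, f_iso = 0.1, odi = 0.2,
                              mu = c(1, 0, 0)), sc, snr = 25, seed = 3)
  ft <- fit_noddi_bingham(sim$ds, array(TRUE, c(50, 1, 1)))
  expect_lt(abs(stats::median(ft$f_in) - 0.5), 0.1)
  expect_lt(abs(stats::median(ft$odi_primary) - 0.2), 0.1)
  # simplex constraints hold voxel-wise
  expect_true(all(ft$f_in >= 0 & ft$f_in <= 1))
  expect_true(all(ft$f_iso >= 0 & ft$f_iso <= 1))
  extra <- (1 - ft$f_iso) * (1 - ft$f_in)
  expect_true(all(extra >= 0))
  expect_true(all(ft$kappa1 >= ft$kappa2))
})

test_that("equal Bingham concentrations give equal dispersion indices", {
  sc <- full_scheme()
  simk <- simulate_voxels(2, "noddi",
                          list(f_in = 0.6, f_iso = 0.05, kappa1 = 5,
                               kappa2 = 5, mu = c(0, 0, 1)),
                          sc, snr = Inf)
  fk <- fit_noddi_bingham(simk$ds, array(TRUE, c(2, 1, 1)))
  expect_equal(fk$odi_primary[1], fk$odi_secondary[1], tolerance = 0.02)
  # and the ODI matches the generating kappa
  expect_equal(fk$odi_primary[1], odi_from_kappa(5), tolerance = 0.05)
})

test_that("NODDI requires multi-shell data", {
  one_shell <- dhcp_scheme(n_b0 = 4, shells = c(`1000` = 12))
  sim <- simulate_voxels(2, "noddi", list(), one_shell, snr = Inf)
  expect_error(fit_noddi_bingham(sim$ds, array(TRUE, c(2, 1, 1))),
               "multi-shell")
})
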