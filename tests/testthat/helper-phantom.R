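# Shared fixtures, built lazily and cached for the whole test run so the
# expensive phantoms and fits are computed once.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(fixture_env[[name]]))
    assign(name, builder(), envir = fixture_env)
  fixture_env[[name]]
}

# full service-scale sampling scheme (300 volumes)
full_scheme <- function() memo("full_scheme", function() dhcp_scheme())

# desk-scale scheme for the artefact phantom: 60 volumes, two shells with
# enough directions for stable spherical-harmonic references
desk_scheme <- function() memo("desk_scheme", function()
  dhcp_scheme(n_b0 = 8, shells = c(`1000` = 26, `2600` = 26)))

# small scheme for cheap geometric tests
tiny_scheme <- function() memo("tiny_scheme", function()
  dhcp_scheme(n_b0 = 4, shells = c(`1000` = 12)))

# noise-free desk phantom + matching noisy one (seed 3)
clean_phantom <- function() memo("clean_phantom", function()
  build_phantom(phantom_spec(scheme = desk_scheme(), sigma = 0)))

noisy_phantom <- function() memo("noisy_phantom", function()
  build_phantom(phantom_spec(scheme = desk_scheme(), sigma = 35,
                             seed = 3)))

# artefact phantom: rigid motion on one b0 and one weighted volume plus
# multiplicative dropouts spread over shells and slices
artefact_config <- function() {
  list(motion = data.frame(volume = c(3, 15), tx = c(2, 0), ty = 0,
                           tz = 0, rx = 0, ry = 0,
                           rz = c(0, 10 * pi / 180)),
       dropout = data.frame(volume = c(12, 20, 33, 44, 51, 58),
                            slice = c(8, 10, 12, 9, 11, 10),
                            factor = 0.2))
}

artefact_phantom <- function() memo("artefact_phantom", function() {
  ph <- noisy_phantom()
  cfg <- artefact_config()
  inject_artifacts(ph$ds, ph$truth, motion = cfg$motion,
                   dropout = cfg$dropout)
})

# realignment of the artefact phantom (the most expensive fixture)
realigned_artefacts <- function() memo("realigned_artefacts", function() {
  inj <- artefact_phantom()
  mask <- inj$truth$brain_mask
  suppressMessages(realign_volumes(inj$ds, reference_index = 1,
                                   mask = mask))
})

# outlier detection on the dropout-injected (but unmoved) phantom
outlier_run <- function() memo("outlier_run", function() {
  ph <- noisy_phantom()
  cfg <- artefact_config()
  inj <- inject_artifacts(ph$ds, ph$truth, dropout = cfg$dropout)
  mask <- inj$truth$brain_mask
  suppressMessages({
    pred <- predict_signal(inj$ds, mask)
    res <- detect_replace_outliers(inj$ds, pred, mask)
  })
  list(inj = inj, pred = pred, res = res, mask = mask)
})

# bundle phantom + truth-derived FOD for tractography
bundle_fixture <- function() memo("bundle_fixture", function() {
  ph <- build_phantom(phantom_spec(scheme = tiny_scheme(), sigma = 0))
  tr <- ph$truth
  d <- dim(tr$tissue)
  fr <- array(0, d)
  fr[tr$bundle1] <- 0.7
  fod <- fod_from_truth(tr$orientation, fr, ph$ds$affine,
                        angle_sd = 0.03)
  b1 <- tr$bundle1
  xs <- range(which(apply(b1, 1, any)))
  mid <- round(mean(xs))
  seed_full <- array(FALSE, d)
  seed_full[xs[1]:(xs[1] + 1), , ] <- b1[xs[1]:(xs[1] + 1), , ]
  way <- array(FALSE, d)
  way[(mid - 1):(mid + 1), , ] <- b1[(mid - 1):(mid + 1), , ]
  stp <- array(FALSE, d)
  stp[(xs[2] - 1):xs[2], , ] <- b1[(xs[2] - 1):xs[2], , ]
  c0y <- round((d[2] + 1) / 2)
  zb <- floor((d[3] + 1) / 2) - max(3, round(d[3] / 6))
  seed_core <- array(FALSE, d)
  seed_core[xs[1], c0y, zb] <- TRUE
  list(ph = ph, fod = fod, bundle = b1, xs = xs, mid = mid,
       seed_full = seed_full, seed_core = seed_core, way = way,
       stop = stp, core_y = c0y, core_z = zb)
})

# reduced-schedule FOD fits (cached; sampling dominates runtime)
fod_single <- function() memo("fod_single", function() {
  sim <- simulate_voxels(12, "fibres",
                         list(fractions = 0.6, dirs = list(c(1, 0, 0)),
                              f_iso = 0.1),
                         full_scheme(), snr = 20, seed = 2)
  fit <- fit_fod(sim$ds, array(TRUE, c(12, 1, 1)), n_burn = 400,
                 n_keep = 400, thin = 10, seed = 11)
  list(sim = sim, fit = fit)
})

fod_crossing <- function() memo("fod_crossing", function() {
  sim <- simulate_voxels(8, "fibres",
                         list(fractions = c(0.4, 0.4),
                              dirs = list(c(1, 0, 0), c(0, 1, 0)),
                              f_iso = 0.1),
                         full_scheme(), snr = 20, seed = 3)
  fit <- fit_fod(sim$ds, array(TRUE, c(8, 1, 1)), n_burn = 400,
                 n_keep = 400, thin = 10, seed = 12)
  list(sim = sim, fit = fit)
})

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

angle_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}

write_phantom_files <- function(ds, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  prefix <- file.path(dir, "ph")
  write_dataset(ds, prefix)
  prefix
}
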