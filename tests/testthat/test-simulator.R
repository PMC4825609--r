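test_that("bar-target scenes lay out bright and dark bars as specified", {
  sc <- make_bar_target_scene(10, 10, 4, "vertical")
  bright_cols <- which(colSums(sc$weights) > 0) - 1L
  expect_identical(bright_cols, c(0L, 1L, 4L, 5L, 8L, 9L))
  expect_true(all(sc$weights %in% c(0, 1)))
  # uniform sentinel
  expect_true(all(make_bar_target_scene(6, 4)$weights == 1))
  # fraction of bright pixels is exactly 1/2 when the width divides 2p
  sc2 <- make_bar_target_scene(24, 8, 8, "vertical")
  expect_equal(mean(sc2$weights), 0.5)
  sc3 <- make_bar_target_scene(8, 24, 6, "horizontal")
  expect_equal(mean(sc3$weights), 0.5)
  expect_error(make_bar_target_scene(10, 10, 1), "bar_period")
  expect_error(make_bar_target_scene(10, 10, 12), "degenerate")
})

test_that("event sampling is Poisson in count and scene-weighted in space", {
  sc <- make_bar_target_scene(16, 16)
  expect_identical(nrow(sample_events(sc, 0, 5, seed = 1)), 0L)
  # empirical mean within 3 SE of the Poisson mean
  ev <- sample_events(sc, 15, 4000, seed = 2)
  se <- sqrt(15 / 4000)
  expect_lt(abs(nrow(ev) / 4000 - 15), 3 * se)
  # delta-function scene: all positions inside the single bright pixel
  sc$weights[] <- 0
  sc$weights[4, 7] <- 1   # pixel ix = 6, iy = 3
  ev <- sample_events(sc, 10, 50, seed = 3)
  expect_true(all(ev$x_px >= 6 & ev$x_px < 7))
  expect_true(all(ev$y_px >= 3 & ev$y_px < 4))
  # determinism under fixed seed
  expect_identical(sample_events(sc, 10, 20, seed = 9),
                   sample_events(sc, 10, 20, seed = 9))
})

test_that("rendered events integrate to their amplitude and keep symmetry", {
  sym <- event_shape_model(sigma_x = 1, sigma_y = 1, profile = "gauss")
  r <- render_photon_event(10.5, 8.5, 6000, sym)   # at a pixel centre
  expect_equal(sum(r$patch) / 6000, 1, tolerance = 1e-3)
  # symmetric under x/y reflection for a centred symmetric event
  expect_equal(r$patch, r$patch[, ncol(r$patch):1], tolerance = 1e-12)
  expect_equal(r$patch, r$patch[nrow(r$patch):1, ], tolerance = 1e-12)
  # peaked profile and smear keep the integral
  r2 <- render_photon_event(10.3, 7.8, 5000, event_shape_model())
  expect_equal(sum(r2$patch) / 5000, 1, tolerance = 1e-3)
  expect_error(render_photon_event(5, 5, -10, sym), "amplitude")
  expect_error(event_shape_model(sigma_x = 0), "invalid shape")
  expect_error(event_shape_model(sigma_x = 0.5, sigma_y = 1), "sigma_x")
})

test_that("horizontal widening raises the x marginal SD above y", {
  for (widening in c("smear", "elliptical")) {
    sh <- event_shape_model(sigma_x = 1.5, sigma_y = 1.0, widening = widening,
                            profile = "gauss")
    r <- render_photon_event(12.37, 12.81, 6000, sh)
    p <- r$patch
    xs <- r$origin[1L] + seq_len(ncol(p)) - 0.5
    ys <- r$origin[2L] + seq_len(nrow(p)) - 0.5
    sd_of <- function(w, c) {
      mu <- sum(w * c) / sum(w)
      sqrt(sum(w * (c - mu)^2) / sum(w))
    }
    sdx <- sd_of(colSums(p), xs)
    sdy <- sd_of(rowSums(p), ys)
    expect_gt(sdx, sdy)
    # the marginal x SD tracks sigma_x (pixelation adds ~1/12 variance)
    expect_equal(sdx, sqrt(1.5^2 + 1 / 12), tolerance = 0.05)
  }
})

test_that("simulated stacks obey the camera chain and are reproducible", {
  sc <- make_bar_target_scene(32, 32)
  calib <- camera_calibration(base_level_adu = 120)
  # no events, no noise: constant base level
  sim0 <- simulate_stack(sc, mean_events = 0, n_frames = 3,
                         noise_sd_adu = 0, calibration = calib, seed = 1)
  expect_true(all(vapply(sim0$stack$frames,
                         function(f) all(f == 120), logical(1))))
  # bitwise reproducibility
  s1 <- simulate_stack(sc, mean_events = 20, n_frames = 3, seed = 7)
  s2 <- simulate_stack(sc, mean_events = 20, n_frames = 3, seed = 7)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth, s2$truth)
})

test_that("summed signal above base tracks summed ground-truth amplitude", {
  sc <- make_bar_target_scene(48, 48)
  calib <- camera_calibration(base_level_adu = 120)
  sim <- simulate_stack(sc, mean_events = 10, n_frames = 12,
                        noise_sd_adu = 0, calibration = calib, seed = 21)
  sig <- vapply(seq_along(sim$stack$frames), function(k)
    sum(sim$stack$frames[[k]] - 120) * calib$pe_per_adu, numeric(1))
  amp <- vapply(seq_along(sim$stack$frames), function(k)
    sum(sim$truth$amplitude_pe[sim$truth$frame == k]), numeric(1))
  expect_gt(stats::cor(sig, amp), 0.99)
  # and the per-frame totals agree up to edge truncation and rounding
  expect_equal(sig[amp > 0] / amp[amp > 0], rep(1, sum(amp > 0)),
               tolerance = 0.1)
})

test_that("pulse-height distribution of rendered events is narrow and unbiased", {
  set.seed(31)
  sh <- event_shape_model(amplitude_mean = 6000, amplitude_cv = 0.1)
  sc <- make_bar_target_scene(64, 64)
  sim <- simulate_stack(sc, shape = sh, mean_events = 3, n_frames = 150,
                        noise_sd_adu = 0, seed = 31)
  amps <- sim$truth$amplitude_pe
  expect_lt(abs(mean(amps) - 6000), 3 * 600 / sqrt(length(amps)))
  expect_lt(abs(stats::sd(amps) / mean(amps) - 0.1), 0.025)
  expect_true(all(amps > 0))
})

test_that("ion events obey their rate and exceed photon peaks when expected", {
  sc <- make_bar_target_scene(48, 48)
  ion <- ion_event_model(rate_per_frame = 1 / 3, amplitude_factor = 1400,
                         size_factor = 3)
  sim <- simulate_stack(sc, ion_model = ion, mean_events = 5, n_frames = 600,
                        seed = 41)
  n_ion <- sum(sim$truth$kind == "ion")
  expect_lt(abs(n_ion - 200), 3 * sqrt(200))
  # at equal size, a 5x amplitude factor makes the ion peak exceed the
  # photon-event maximum pixel by construction
  sh <- event_shape_model()
  ion_small <- ion_event_model(rate_per_frame = 1, amplitude_factor = 5,
                               size_factor = 1)
  set.seed(42)
  ph <- render_photon_event(10.5, 10.5, 6000, sh)
  io <- render_photon_event(10.5, 10.5, 5 * 6000,
                            event_shape_model(sigma_x = sh$sigma_y,
                                              sigma_y = sh$sigma_y,
                                              widening = "elliptical"))
  expect_gt(max(io$patch), max(ph$patch))
  expect_error(ion_event_model(amplitude_factor = 1), "amplitude_factor")
  expect_error(ion_event_model(size_factor = 0.5), "size_factor")
})
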