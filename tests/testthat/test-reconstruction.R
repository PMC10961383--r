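test_that("a flat scene demodulates to a flat phase", {
  opt <- test_optics()
  ref <- reference_hologram(opt, c(128, 128), noise = noise_meta(NULL))
  field <- extract_sideband(ref, opt)
  ph <- Arg(field$values)
  flat <- holoqpi:::remove_plane(ph)$values
  expect_lt(sd(flat), 0.02)
})

test_that("detected carrier matches the synthesis carrier", {
  opt <- test_optics(carrier_cycles_per_px = c(0.25, 0))
  ref <- reference_hologram(opt, c(128, 128), noise = noise_meta(NULL))
  field <- extract_sideband(ref, opt)
  expect_equal(attr(field, "carrier_cycles_per_px"), c(0.25, 0),
               tolerance = 1e-12)
})

test_that("carrier detection fails loudly on carrier-free input", {
  opt <- test_optics()
  holo <- structure(list(intensity = matrix(128L, 64, 64), optics = opt,
                         role = "object", axial_offset_um = 0,
                         noise_meta = NULL),
                    class = "hologram_frame")
  expect_error(extract_sideband(holo, opt), "no carrier")
})

test_that("demodulated wrapped phase matches the wrapped truth", {
  opt <- test_optics()
  sc <- simulate_scene(small_scene_params(seed = 12, field = 128))
  pair <- holo_pair(sc, opt)
  O <- extract_sideband(pair$object, opt)
  R <- extract_sideband(pair$reference, opt)
  d <- Arg(O$values * Conj(R$values))
  err <- wrap_phase(d - sc$true_phase)
  err <- holoqpi:::remove_plane(err)$values
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("reference selection prefers the matched reference", {
  opt <- test_optics()
  flat <- phase_to_field(matrix(0, 64, 64), opt)
  # corrupt candidate: additional tilt across the field
  tilt <- outer(seq(0, 4, length.out = 64), rep(1, 64))
  bad <- phase_to_field(tilt, opt)
  sel <- select_reference(flat, list(bad, flat))
  expect_equal(sel$index, 2)
  expect_lt(sel$roughness[2], sel$roughness[1])
  # self-difference is identically zero
  sc <- simulate_scene(small_scene_params(seed = 13, field = 96, n_cells = 2))
  f <- phase_to_field(sc$true_phase, opt)
  self <- select_reference(f, list(f))
  expect_equal(self$index, 1)
  expect_equal(max(abs(self$phase_diff$values)), 0, tolerance = 1e-12)
  expect_error(select_reference(f, list()), "at least one")
})

test_that("autofocus recovers synthesized defocus", {
  opt <- test_optics()
  sc <- simulate_scene(small_scene_params(seed = 14, field = 256, n_cells = 8))
  # already focused: z_best within half a grid step of 0
  pair0 <- holo_pair(sc, opt)
  O0 <- extract_sideband(pair0$object, opt)
  af0 <- autofocus(O0, c(-100, 100), 21)
  expect_lt(abs(af0$z_best_um), 5)
  # 50 um synthesis defocus refocuses at -50 +- 5
  holo <- suppressWarnings(
    synthesize_hologram(phase_to_field(sc$true_phase, opt), opt,
                        defocus_um = 50, noise = noise_meta(NULL)))
  O <- extract_sideband(holo, opt)
  af <- autofocus(O, c(-100, 100), 21)
  expect_lt(abs(af$z_best_um + 50), 5)
  # the curve is locally minimal at the optimum
  i <- which.min(af$focus_curve$metric)
  expect_true(i > 1 && i < nrow(af$focus_curve))
})

test_that("median filter removes spikes and respects wrap seams", {
  px <- 0.26
  const <- phase_map(matrix(1, 32, 32), wrapped = FALSE, sampling_um = px)
  expect_equal(filter_phase(const, 3)$values, const$values)
  spike <- matrix(0, 32, 32); spike[16, 16] <- pi / 2
  f <- filter_phase(phase_map(spike, wrapped = FALSE, sampling_um = px), 3)
  expect_equal(max(abs(f$values)), 0)
  expect_error(filter_phase(const, 4), "odd")
  # wrapped ramp crossing +-pi: circular filter tracks the unwrapped oracle
  truth <- matrix(rep(seq(0, 6 * pi, length.out = 100), 40), 100, 40)
  wrapped <- phase_map(wrap_phase(truth), wrapped = TRUE, sampling_um = px)
  filt <- filter_phase(wrapped, 3)
  # oracle: plain median filter applied to the unwrapped truth, re-wrapped
  oracle <- wrap_phase(holoqpi:::median_filter_cpp(truth, 3L))
  expect_lt(max(abs(wrap_phase(filt$values - oracle))), 0.1)
  # noisy level sitting exactly on the +-pi seam: filtering on the unit
  # circle still matches the oracle computed on the unwrapped truth
  noisy <- withr::with_seed(1, matrix(pi - 0.01 + rnorm(1600, 0, 0.05), 40))
  w2 <- phase_map(wrap_phase(noisy), wrapped = TRUE, sampling_um = px)
  oracle2 <- wrap_phase(holoqpi:::median_filter_cpp(noisy, 3L))
  filt2 <- filter_phase(w2, 3)
  expect_lt(max(abs(wrap_phase(filt2$values - oracle2))), 0.1)
})

test_that("unwrapping is exact on residue-free fields", {
  px <- 0.26
  # wrapped constant comes back unchanged
  const <- phase_map(matrix(0.7, 16, 16), wrapped = TRUE, sampling_um = px)
  expect_equal(unwrap_phase(const)$values, const$values, tolerance = 1e-12)
  # 0 -> 6 pi linear ramp recovered up to a 2 pi k constant
  ramp <- matrix(rep(seq(0, 6 * pi, length.out = 100), 50), 100, 50)
  uw <- unwrap_phase(phase_map(wrap_phase(ramp), TRUE, px))
  dev <- uw$values - ramp
  expect_lt(max(dev) - min(dev), 1e-9)
  expect_equal((dev[1, 1] / (2 * pi)) %% 1, 0, tolerance = 1e-9)
  # tall cap (peak 9 rad, high-contrast cell) through wrap/unwrap
  sc <- simulate_scene(scene_params(field_size_px = c(96, 96), n_cells = 1,
                                    cell_radius_um = c(8, 8),
                                    cell_height_um = c(7.6, 7.6),
                                    cell_refractive_index = 1.455, seed = 1))
  expect_gt(max(sc$true_phase), 8.9)
  uw2 <- unwrap_phase(phase_map(wrap_phase(sc$true_phase), TRUE, px))
  dev2 <- uw2$values - sc$true_phase
  expect_lt(sqrt(mean((dev2 - mean(dev2))^2)), 1e-6)
  expect_equal(attr(uw2, "residues"), 0)
})

test_that("unwrap(wrap(x)) = x + 2 pi k on random smooth fields", {
  for (seed in 1:20) {
    truth <- smooth_random_phase(n = 64, seed = seed, amplitude_rad = 9)
    w <- phase_map(wrap_phase(truth), wrapped = TRUE, sampling_um = 0.26)
    expect_equal(count_residues(w$values), 0)
    uw <- unwrap_phase(w)
    dev <- uw$values - truth
    expect_lt(max(dev) - min(dev), 1e-9)
    k <- (dev[1, 1] / (2 * pi)) %% 1
    expect_lt(min(k, 1 - k), 1e-9)
  }
})

test_that("phase converts to height by the QPI relation", {
  px <- 0.26
  zero <- phase_map(matrix(0, 8, 8), wrapped = FALSE, sampling_um = px)
  expect_true(all(phase_to_height(zero, 0.05)$values == 0))
  one_wrap <- phase_map(matrix(2 * pi, 8, 8), wrapped = FALSE, sampling_um = px)
  h <- phase_to_height(one_wrap, 0.05, 0.6328)
  expect_equal(h$values[1, 1], 12.656, tolerance = 1e-12)
  # linearity
  phi <- phase_map(matrix(runif(64, 0, 5), 8, 8), FALSE, px)
  phi2 <- phase_map(2 * phi$values, FALSE, px)
  expect_equal(phase_to_height(phi2, 0.05)$values,
               2 * phase_to_height(phi, 0.05)$values, tolerance = 1e-12)
  wrapped <- phase_map(matrix(0.1, 8, 8), TRUE, px)
  expect_error(phase_to_height(wrapped, 0.05), "unwrapped")
  expect_error(phase_to_height(zero, -0.1), "delta_n")
})

test_that("end-to-end reconstruction recovers an empty field and cell volumes", {
  opt <- test_optics()
  # empty field: |h| < 0.02 um everywhere
  p0 <- scene_params(field_size_px = c(128, 128), n_cells = 0)
  sc0 <- simulate_scene(p0)
  pair0 <- holo_pair(sc0, opt)
  rec0 <- reconstruct(pair0$object, pair0$reference, opt, fast_recon_options())
  expect_lt(max(abs(rec0$height$values)), 0.02)
  # 4-cell noise-free scene: volumes within 5% of truth
  sc <- simulate_scene(small_scene_params(seed = 15, field = 128))
  pair <- holo_pair(sc, opt)
  rec <- reconstruct(pair$object, pair$reference, opt, fast_recon_options())
  rep <- measure_cells(segment_cells(rec$height), rec$height)
  expect_equal(rep$cell_count, 4)
  idx <- match_regions(rep$regions, sc$cells)
  rel <- rep$regions$volume_um3[idx] / sc$true_cell_volumes_um3 - 1
  expect_lt(max(abs(rel)), 0.05)
  expect_equal(rec$qc$residue_count, 0)
})

test_that("reconstruction holds to 10% per-cell volume error under detector noise", {
  opt <- test_optics()
  sc <- simulate_scene(small_scene_params(seed = 16, field = 128))
  for (seed in 1:3) {
    pair <- holo_pair(sc, opt, noise = noise_meta(1000, 1, seed = seed))
    rec <- reconstruct(pair$object, pair$reference, opt, fast_recon_options())
    rep <- measure_cells(segment_cells(rec$height), rec$height)
    idx <- match_regions(rep$regions, sc$cells)
    rel <- rep$regions$volume_um3[idx] / sc$true_cell_volumes_um3 - 1
    expect_lt(max(abs(rel)), 0.10)
  }
})

test_that("stage errors are tagged with the failing stage", {
  opt <- test_optics()
  holo <- structure(list(intensity = matrix(128L, 64, 64), optics = opt,
                         role = "object", axial_offset_um = 0,
                         noise_meta = NULL),
                    class = "hologram_frame")
  expect_error(reconstruct(holo, holo, opt), "extract_sideband")
})
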