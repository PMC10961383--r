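test_that("empty scene has identically zero phase", {
  p <- scene_params(field_size_px = c(64, 64), n_cells = 0,
                    membrane_enabled = FALSE)
  sc <- simulate_scene(p)
  expect_true(all(sc$true_phase == 0))
})

test_that("scene simulation is bit-identical for a fixed seed", {
  p <- small_scene_params(seed = 11)
  a <- simulate_scene(p)
  b <- simulate_scene(p)
  expect_identical(a$cells, b$cells)
  expect_identical(a$true_phase, b$true_phase)
})

test_that("per-cell volumes match the analytic spherical-cap closed form", {
  p <- scene_params(field_size_px = c(512, 512), n_cells = 10,
                    cell_radius_um = c(5, 8), cell_height_um = c(2, 4),
                    seed = 3)
  sc <- simulate_scene(p)
  expect_equal(nrow(sc$cells), 10)
  # independent closed form: V = pi h^2 (3R - h) / 3 with R = (r^2+h^2)/(2h)
  r <- sc$cells$radius_um; h <- sc$cells$height_um
  R <- (r^2 + h^2) / (2 * h)
  v_oracle <- pi * h^2 * (3 * R - h) / 3
  expect_equal(sc$true_cell_volumes_um3, v_oracle, tolerance = 1e-12)
  # volume bookkeeping: discretized height integral within 2% of the sum
  hm <- scene_height_map(sc)
  v_int <- sum(hm$values) * hm$sampling_um^2
  expect_lt(abs(v_int / sum(v_oracle) - 1), 0.02)
})

test_that("cells are pairwise non-overlapping and inside the field", {
  for (seed in 1:10) {
    p <- small_scene_params(seed = seed, n_cells = 5, field = 192)
    sc <- simulate_scene(p, compute_phase = FALSE)
    px <- p$object_pixel_um
    r_px <- sc$cells$radius_um / px
    expect_true(all(sc$cells$row_px - r_px >= 1 &
                      sc$cells$row_px + r_px <= p$field_size_px[1]))
    expect_true(all(sc$cells$col_px - r_px >= 1 &
                      sc$cells$col_px + r_px <= p$field_size_px[2]))
    d <- as.matrix(dist(cbind(sc$cells$row_px, sc$cells$col_px))) * px
    sums <- outer(sc$cells$radius_um, sc$cells$radius_um, `+`)
    diag(d) <- Inf
    expect_true(all(d > sums | !is.finite(d)))
  }
})

test_that("overcrowded placement fails with an explicit error", {
  p <- scene_params(field_size_px = c(64, 64), n_cells = 50,
                    cell_radius_um = c(5, 8))
  expect_error(simulate_scene(p), "too crowded")
})

test_that("non-physical refractive contrast is rejected", {
  expect_error(scene_params(cell_refractive_index = 1.3,
                            medium_refractive_index = 1.335),
               "phase-advancing")
  expect_error(scene_params(membrane_enabled = TRUE, pore_diameter_um = 5,
                            pore_pitch_um = 4), "pitch")
})

test_that("membrane pores are the only negative-phase structures", {
  p <- scene_params(field_size_px = c(128, 128), n_cells = 3,
                    cell_radius_um = c(3, 4), cell_height_um = c(2, 3),
                    membrane_enabled = TRUE, pore_diameter_um = 1,
                    pore_pitch_um = 6, pore_depth_phase_rad = 0.5, seed = 2)
  sc <- simulate_scene(p)
  expect_lt(min(sc$true_phase), 0)            # pore wells present
  p$membrane_enabled <- FALSE
  expect_gte(min(simulate_scene(p)$true_phase), 0)
})

test_that("control treatment leaves the scene untouched", {
  sc <- simulate_scene(small_scene_params(seed = 5))
  out <- apply_treatment(sc, treatment_effect("control"), seed = 1)
  expect_identical(out$cells, sc$cells)
  expect_identical(out$true_cell_volumes_um3, sc$true_cell_volumes_um3)
})

test_that("zero-dispersion shrink halves every volume exactly", {
  sc <- simulate_scene(small_scene_params(seed = 6))
  out <- apply_treatment(sc, treatment_effect("DOX-EV", 0.5), seed = 1)
  expect_equal(out$true_cell_volumes_um3, sc$true_cell_volumes_um3 * 0.5,
               tolerance = 1e-9)
  # treated cells remain exact spherical caps
  v_cap <- cap_volume(out$cells$radius_um, out$cells$height_um)
  expect_equal(v_cap, out$true_cell_volumes_um3, tolerance = 1e-7)
})

test_that("cell loss removes exactly the requested number of cells", {
  sc <- simulate_scene(small_scene_params(seed = 7, n_cells = 6),
                       compute_phase = FALSE)
  out <- apply_treatment(sc, treatment_effect("si-EV", 0.1, cell_loss_count = 2),
                         seed = 3, regenerate_phase = FALSE)
  expect_equal(nrow(out$cells), 4)
  expect_error(apply_treatment(sc, treatment_effect("si-EV", 0.1,
                                                    cell_loss_count = 7),
                               seed = 1),
               "exceeds")
})

test_that("mean population shrink converges to the configured fraction", {
  # law of large numbers over replicate treated scenes
  eff <- treatment_effect("fol-DOX-EV", 0.4854, shrink_dispersion = 0.05)
  dec <- vapply(1:200, function(i) {
    sc <- simulate_scene(small_scene_params(seed = i, n_cells = 4, field = 160),
                         compute_phase = FALSE)
    tr <- apply_treatment(sc, eff, seed = i + 5000, regenerate_phase = FALSE)
    1 - sum(tr$true_cell_volumes_um3) / sum(sc$true_cell_volumes_um3)
  }, numeric(1))
  se <- sd(dec) / sqrt(length(dec))
  expect_lt(abs(mean(dec) - 0.4854), 3 * se)
})

test_that("shrink is monotone in the configured fraction at zero dispersion", {
  sc <- simulate_scene(small_scene_params(seed = 8), compute_phase = FALSE)
  tot <- vapply(c(0, 0.2, 0.4, 0.6), function(s) {
    out <- apply_treatment(sc, treatment_effect("DOX-EV", s), seed = 1,
                           regenerate_phase = FALSE)
    sum(out$true_cell_volumes_um3)
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
})

test_that("scene serialization round-trips the truth record", {
  sc <- simulate_scene(small_scene_params(seed = 9, field = 112, n_cells = 2))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_equal(back$cells$radius_um, sc$cells$radius_um, tolerance = 1e-12)
  expect_equal(back$true_cell_volumes_um3, sc$true_cell_volumes_um3,
               tolerance = 1e-12)
  expect_equal(back$true_phase, sc$true_phase, tolerance = 1e-6)
})

test_that("flow events honour degenerate and intermediate fractions", {
  all_neg <- simulate_flow_events(0, 500, seed = 1)
  expect_true(all(all_neg$group == "negative"))
  all_pos <- simulate_flow_events(1, 500, seed = 1)
  expect_true(all(all_pos$group == "positive"))
  half <- simulate_flow_events(0.5, 10000, seed = 2)
  share <- mean(half$group == "positive")
  expect_lt(abs(share - 0.5), 2 * sqrt(0.25 / 10000))
  expect_true(all(is.finite(half$intensity)) && all(half$intensity >= 0))
})

test_that("overlapping mixture components raise the warning flag", {
  mix <- flow_mixture(negative = list(meanlog = 4, sdlog = 0.5),
                      positive = list(meanlog = 4.3, sdlog = 0.5))
  tab <- simulate_flow_events(0.5, 100, mixture = mix, seed = 1)
  expect_true(attr(tab, "overlap_warning"))
  expect_false(attr(simulate_flow_events(0.5, 100, seed = 1), "overlap_warning"))
})

test_that("flow event tables round-trip through CSV", {
  tab <- simulate_flow_events(0.3, 200, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_events(tab, path)
  back <- read_flow_events(path)
  expect_equal(back$intensity, tab$intensity, tolerance = 1e-12)
  expect_equal(back$group, tab$group)
})

test_that("seeding-density helper scales field cell counts", {
  lo <- scene_for_seeding(15000)
  hi <- scene_for_seeding(30000)
  expect_equal(hi$n_cells, 2L * lo$n_cells)
})
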