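test_that("pure-phase fields have unit amplitude and correct constants", {
  opt <- test_optics()
  z0 <- phase_to_field(matrix(0, 16, 16), opt)
  expect_true(all(z0$values == 1 + 0i))
  zpi <- phase_to_field(matrix(pi, 16, 16), opt)
  expect_equal(max(Mod(zpi$values + 1)), 0, tolerance = 1e-12)
  rnd <- phase_to_field(matrix(runif(256, -3, 3), 16, 16), opt)
  expect_equal(range(Mod(rnd$values)), c(1, 1), tolerance = 1e-12)
  expect_equal(z0$sampling_um, 5.2 / 20)
})

test_that("plane waves are eigenfunctions of propagation", {
  f <- complex_field(matrix(1 + 0i, 32, 32), sampling_um = 0.5,
                     wavelength_um = 0.6328)
  expect_identical(propagate_angular_spectrum(f, 0)$values, f$values)
  dz <- 37.5
  out <- propagate_angular_spectrum(f, dz)
  expect_equal(Mod(out$values), matrix(1, 32, 32), tolerance = 1e-12)
  # global phase advance 2 pi dz / lambda (n = 1)
  expected <- (2 * pi * dz / 0.6328) %% (2 * pi)
  got <- Arg(out$values[1, 1]) %% (2 * pi)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("propagation conserves energy and inverts exactly on band-limited fields", {
  w0 <- 10; px <- 0.5; N <- 128
  x <- ((1:N) - N / 2 - 0.5) * px
  U <- complex_field(matrix(complex(real = exp(-outer(x^2, x^2, `+`) / w0^2)),
                            N, N), px)
  Uz <- propagate_angular_spectrum(U, 40)
  expect_equal(sum(Mod(Uz$values)^2), sum(Mod(U$values)^2),
               tolerance = 1e-6)
  back <- propagate_angular_spectrum(Uz, -40)
  expect_lt(sqrt(mean(Mod(back$values - U$values)^2)), 1e-9)
})

test_that("Gaussian beam width follows the closed-form divergence law", {
  w0 <- 20; lam <- 0.6328; z <- 2000; px <- 0.5; N <- 256
  x <- ((1:N) - N / 2 - 0.5) * px
  U <- complex_field(matrix(complex(real = exp(-outer(x^2, x^2, `+`) / w0^2)),
                            N, N), px, wavelength_um = lam)
  Uz <- propagate_angular_spectrum(U, z)
  I <- Mod(Uz$values)^2
  w_meas <- 2 * sqrt(sum(I * outer(x^2, rep(1, N))) / sum(I))
  w_true <- w0 * sqrt(1 + (z * lam / (pi * w0^2))^2)
  expect_lt(abs(w_meas / w_true - 1), 0.02)
})

test_that("two-beam interference spans the detector range", {
  opt <- test_optics(carrier_cycles_per_px = c(0.25, 0), bit_depth = 8,
                     reference_amplitude_ratio = 1)
  flat <- phase_to_field(matrix(0, 64, 64), opt)
  holo <- synthesize_hologram(flat, opt, noise = noise_meta(NULL))
  # I = 2 + 2 cos maps to [0, 255] with the mean at half scale
  expect_lte(min(holo$intensity), 1)
  expect_gte(max(holo$intensity), 254)
  expect_equal(mean(holo$intensity), 127.5, tolerance = 1)
})

test_that("hologram spectrum peaks at the configured carrier bin", {
  opt <- test_optics(carrier_cycles_per_px = c(0.25, 0))
  sc <- simulate_scene(small_scene_params(seed = 2, field = 128))
  holo <- synthesize_hologram(phase_to_field(sc$true_phase, opt), opt,
                              noise = noise_meta(NULL))
  # direct DFT oracle: strongest non-DC coefficient at column offset N/4
  S <- Mod(stats::fft(holo$intensity - mean(holo$intensity)))
  S[1, 1] <- 0
  pk <- arrayInd(which.max(S), dim(S))
  expect_equal(pk[1], 1)               # zero row frequency
  expect_equal(pk[2], 128 / 4 + 1)     # +N/4 column bin
})

test_that("hologram synthesis is deterministic under a fixed noise seed", {
  opt <- test_optics()
  sc <- simulate_scene(small_scene_params(seed = 3, field = 96, n_cells = 2))
  f <- phase_to_field(sc$true_phase, opt)
  a <- synthesize_hologram(f, opt, noise = noise_meta(500, 1, seed = 9))
  b <- synthesize_hologram(f, opt, noise = noise_meta(500, 1, seed = 9))
  expect_identical(a$intensity, b$intensity)
  c <- synthesize_hologram(f, opt, noise = noise_meta(500, 1, seed = 10))
  expect_false(identical(a$intensity, c$intensity))
})

test_that("holograms round-trip through TIFF with sidecar metadata", {
  opt <- test_optics()
  sc <- simulate_scene(small_scene_params(seed = 4, field = 96, n_cells = 2))
  holo <- synthesize_hologram(phase_to_field(sc$true_phase, opt), opt,
                              noise = noise_meta(NULL))
  path <- withr::local_tempfile(fileext = ".tif")
  write_hologram(holo, path)
  back <- read_hologram(path)
  expect_identical(back$intensity, holo$intensity)
  expect_equal(back$optics$carrier_cycles_per_px,
               holo$optics$carrier_cycles_per_px)
})

test_that("sideband extraction is linear in the object field", {
  opt <- test_optics()
  p1 <- small_scene_params(seed = 21, field = 128, n_cells = 1)
  p2 <- small_scene_params(seed = 22, field = 128, n_cells = 1)
  U1 <- phase_to_field(simulate_scene(p1)$true_phase, opt)
  U2 <- phase_to_field(simulate_scene(p2)$true_phase, opt)
  Usum <- complex_field(U1$values + U2$values, U1$sampling_um,
                        wavelength_um = U1$wavelength_um)
  h1 <- synthesize_hologram(U1, opt, noise = noise_meta(NULL))
  h2 <- synthesize_hologram(U2, opt, noise = noise_meta(NULL))
  hs <- synthesize_hologram(Usum, opt, noise = noise_meta(NULL))
  # undo the per-hologram mean-intensity normalization before comparing
  scale_of <- function(U) {
    nr <- nrow(U$values); nc <- ncol(U$values)
    fc <- opt$carrier_cycles_per_px
    xg <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
    yg <- matrix(rep(0:(nr - 1), nc), nr, nc)
    R <- opt$reference_amplitude_ratio * exp(2i * pi * (fc[1] * xg + fc[2] * yg))
    mean(Mod(U$values + R)^2)
  }
  e1 <- extract_sideband(h1, opt)$values * scale_of(U1)
  e2 <- extract_sideband(h2, opt)$values * scale_of(U2)
  es <- extract_sideband(hs, opt)$values * scale_of(Usum)
  err <- sqrt(mean(Mod(es - (e1 + e2))^2)) / sqrt(mean(Mod(es)^2))
  expect_lt(err, 0.05)  # quantization-limited superposition
})
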