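# Shared small fixtures: everything is generated in code at test time.

test_optics <- function(...) optical_config(...)

# a modest scene that reconstructs in well under a second
small_scene_params <- function(seed = 1L, n_cells = 4L, field = 128L, ...) {
  scene_params(field_size_px = c(field, field), n_cells = n_cells,
               cell_radius_um = c(4, 6), cell_height_um = c(2, 4),
               seed = seed, ...)
}

fast_recon_options <- function(...) {
  reconstruct_options(autofocus_range_um = c(-20, 20), autofocus_steps = 9L,
                      ...)
}

# noise-free hologram pair for a scene
holo_pair <- function(scene, optics = test_optics(), noise = noise_meta(NULL),
                      defocus_um = 0) {
  obj <- synthesize_hologram(phase_to_field(scene$true_phase, optics), optics,
                             defocus_um = defocus_um, noise = noise)
  ref <- reference_hologram(optics, scene$params$field_size_px,
                            defocus_um = defocus_um, noise = noise)
  list(object = obj, reference = ref)
}

# smooth random residue-free phase field spanning several 2*pi wraps
smooth_random_phase <- function(n = 64L, seed = 1L, amplitude_rad = 9) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * n), n, n)
    g <- EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = 6))
    g <- g - min(g)
    g / max(g) * amplitude_rad
  })
}

# match measured regions to true cells by nearest centroid
match_regions <- function(regions, cells) {
  vapply(seq_len(nrow(cells)), function(i)
    which.min((regions$centroid_row_px - cells$row_px[i])^2 +
                (regions$centroid_col_px - cells$col_px[i])^2),
    integer(1))
}
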