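# Ground-truth scene generation: spherical-cap cells on an optional porous
# membrane, with treatment effects (volume shrink, cell loss) applied to the
# truth record so the whole hologram -> height -> morphometry chain can be
# validated closed-loop.

#' Parameters of a synthetic cell/membrane scene
#'
#' Cells are spherical caps sitting on the substrate: a cap of base radius
#' `r` and maximum height `h` is the slice of a sphere of radius
#' `R = (r^2 + h^2) / (2h)`, with height profile
#' `z(rho) = sqrt(R^2 - rho^2) - (R - h)` and closed-form volume
#' `V = pi h^2 (3R - h) / 3`. The cap family is used because its volume has a
#' closed form, giving an analytic oracle for every volume measurement
#' downstream. Caps must be sub-hemispherical (`h <= r`) so the dome profile
#' is a single-valued height map. Cell phase is `phi = (2 pi / lambda) * delta_n * z` with
#' `delta_n = cell_refractive_index - medium_refractive_index` (default
#' 1.385 - 1.335 = 0.05, a mid-range literature contrast for adherent cells).
#' The membrane, when enabled, is a square lattice of sub-resolution pores
#' rendered as shallow negative-phase wells.
#'
#' @param field_size_px field size, `c(rows, cols)` pixels
#' @param object_pixel_um object-plane sampling in um/pixel
#' @param n_cells number of cells to place (non-negative)
#' @param cell_radius_um range `c(min, max)` of cap base radii, um
#' @param cell_height_um range `c(min, max)` of cap maximum heights, um
#' @param cell_refractive_index refractive index of the cells
#' @param medium_refractive_index refractive index of the surrounding medium
#' @param membrane_enabled add the porous-membrane background?
#' @param pore_diameter_um pore diameter, um (default 0.4, typical of
#'   commercial transwell insert membranes)
#' @param pore_pitch_um pore lattice pitch, um (must exceed the diameter)
#' @param pore_depth_phase_rad pore well depth expressed in phase radians
#' @param seed integer RNG seed; all scene randomness derives from it
#' @return a `scene_params` object
#' @export
scene_params <- function(field_size_px = c(256L, 256L),
                         object_pixel_um = 0.26,
                         n_cells = 10L,
                         cell_radius_um = c(5, 8),
                         cell_height_um = c(2, 4),
                         cell_refractive_index = 1.385,
                         medium_refractive_index = 1.335,
                         membrane_enabled = FALSE,
                         pore_diameter_um = 0.4,
                         pore_pitch_um = 4,
                         pore_depth_phase_rad = 0.5,
                         seed = 1L) {
  field_size_px <- as.integer(field_size_px)
  if (length(field_size_px) == 1) field_size_px <- rep(field_size_px, 2)
  stopifnot(length(field_size_px) == 2, all(field_size_px > 0))
  if (object_pixel_um <= 0) stop("scene.object_pixel_um must be positive")
  n_cells <- as.integer(n_cells)
  if (n_cells < 0) stop("scene.n_cells must be non-negative")
  cell_radius_um <- sort(as.numeric(cell_radius_um))
  cell_height_um <- sort(as.numeric(cell_height_um))
  if (length(cell_radius_um) == 1) cell_radius_um <- rep(cell_radius_um, 2)
  if (length(cell_height_um) == 1) cell_height_um <- rep(cell_height_um, 2)
  if (cell_radius_um[1] <= 0) stop("scene.cell_radius_um must be positive")
  if (cell_height_um[1] <= 0) stop("scene.cell_height_um must be positive")
  if (cell_height_um[2] > cell_radius_um[1])
    stop("cap height cannot exceed the base radius: the dome profile is ",
         "single-valued only for height <= radius")
  if (cell_refractive_index <= medium_refractive_index)
    stop("cells must be phase-advancing: cell_refractive_index > medium_refractive_index")
  if (membrane_enabled && pore_diameter_um >= pore_pitch_um)
    stop("scene.pore_diameter_um must be smaller than scene.pore_pitch_um")
  if (pore_diameter_um <= 0 || pore_pitch_um <= 0)
    stop("pore geometry must be positive")
  structure(list(field_size_px = field_size_px,
                 object_pixel_um = object_pixel_um,
                 n_cells = n_cells,
                 cell_radius_um = cell_radius_um,
                 cell_height_um = cell_height_um,
                 cell_refractive_index = cell_refractive_index,
                 medium_refractive_index = medium_refractive_index,
                 membrane_enabled = isTRUE(membrane_enabled),
                 pore_diameter_um = pore_diameter_um,
                 pore_pitch_um = pore_pitch_um,
                 pore_depth_phase_rad = pore_depth_phase_rad,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Treatment effect applied to a scene
#'
#' Encodes a population volume-shrink fraction (with per-cell dispersion) and
#' a cell-loss count. `control` must carry zero effect. The four printed
#' effect sizes for the EV formulations are available via
#' [ev_treatment_effects()].
#'
#' @param label one of `"control"`, `"si-EV"`, `"fol-si-EV"`, `"DOX-EV"`,
#'   `"fol-DOX-EV"`
#' @param volume_shrink_fraction mean per-cell volume shrink, in `[0, 1)`
#' @param cell_loss_count number of cells removed by the treatment
#' @param shrink_dispersion standard deviation of the per-cell shrink
#' @return a `treatment_effect` object
#' @export
treatment_effect <- function(label,
                             volume_shrink_fraction = 0,
                             cell_loss_count = 0L,
                             shrink_dispersion = 0) {
  labels <- c("control", "si-EV", "fol-si-EV", "DOX-EV", "fol-DOX-EV")
  label <- match.arg(label, labels)
  if (volume_shrink_fraction < 0 || volume_shrink_fraction >= 1)
    stop("volume_shrink_fraction must lie in [0, 1)")
  cell_loss_count <- as.integer(cell_loss_count)
  if (cell_loss_count < 0) stop("cell_loss_count must be non-negative")
  if (shrink_dispersion < 0) stop("shrink_dispersion must be non-negative")
  if (label == "control" &&
      (volume_shrink_fraction != 0 || cell_loss_count != 0L))
    stop("control effect must have zero shrink and zero cell loss")
  structure(list(label = label,
                 volume_shrink_fraction = volume_shrink_fraction,
                 cell_loss_count = cell_loss_count,
                 shrink_dispersion = shrink_dispersion),
            class = "treatment_effect")
}

#' The four EV-treatment effect sizes plus control
#'
#' Mean percent volume decreases of astrocytes in the insert model:
#' si-EV 7.406, fol-si-EV 14.62, DOX-EV 27.25, fol-DOX-EV 48.54 (percent).
#' Cell-loss counts default to 0 (the reported count changes are
#' sign-ambiguous, so they are configuration-driven rather than preset).
#'
#' @param shrink_dispersion per-cell shrink standard deviation shared by the
#'   non-control effects
#' @return named list of [treatment_effect()] objects
#' @export
ev_treatment_effects <- function(shrink_dispersion = 0.05) {
  fr <- c("control" = 0, "si-EV" = 0.07406, "fol-si-EV" = 0.1462,
          "DOX-EV" = 0.2725, "fol-DOX-EV" = 0.4854)
  out <- lapply(names(fr), function(lb)
    treatment_effect(lb, fr[[lb]],
                     shrink_dispersion = if (lb == "control") 0 else shrink_dispersion))
  names(out) <- names(fr)
  out
}

#' Analytic spherical-cap volume
#'
#' @param radius_um cap base radius, um
#' @param height_um cap maximum height, um
#' @return volume in um^3, `V = pi h (3 r^2 + h^2) / 6`
#' @export
cap_volume <- function(radius_um, height_um) {
  pi * height_um * (3 * radius_um^2 + height_um^2) / 6
}

# location parameter of a [0,1)-truncated normal whose MEAN equals `target`
# (plain truncation would lift the mean when target is within a few sd of 0)
truncnorm_location <- function(target, sd) {
  if (sd == 0) return(target)
  tmean <- function(mu) {
    a <- -mu / sd; b <- (1 - mu) / sd
    Z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
  }
  stats::uniroot(function(m) tmean(m) - target,
                 lower = target - 6 * sd, upper = target + 6 * sd,
                 tol = 1e-12)$root
}

# invert cap_volume in h at fixed base radius (monotone cubic, one real
# positive root of h^3 + 3 r^2 h - 6 V / pi = 0)
cap_height_for_volume <- function(radius_um, volume_um3) {
  vapply(seq_along(volume_um3), function(i) {
    v <- volume_um3[i]; r <- if (length(radius_um) > 1) radius_um[i] else radius_um
    if (v <= 0) return(0)
    stats::uniroot(function(h) cap_volume(r, h) - v,
                   lower = 0, upper = max(1e-6, 2 * v / (pi * r^2) + r),
                   tol = 1e-12)$root
  }, numeric(1))
}

# render the cap height field (um) for a data.frame of cells with columns
# row_px, col_px (continuous, 1-based), radius_um, height_um; overlapping
# caps occlude (pointwise maximum) rather than stack, matching abutting cells
render_cells_height <- function(dims, cells, sampling_um) {
  h <- matrix(0, dims[1], dims[2])
  if (is.null(cells) || nrow(cells) == 0) return(h)
  for (i in seq_len(nrow(cells))) {
    r_um <- cells$radius_um[i]; hmax <- cells$height_um[i]
    R <- (r_um^2 + hmax^2) / (2 * hmax)
    r_px <- r_um / sampling_um
    i0 <- max(1L, floor(cells$row_px[i] - r_px - 1))
    i1 <- min(dims[1], ceiling(cells$row_px[i] + r_px + 1))
    j0 <- max(1L, floor(cells$col_px[i] - r_px - 1))
    j1 <- min(dims[2], ceiling(cells$col_px[i] + r_px + 1))
    rows <- i0:i1; cols <- j0:j1
    dy <- (rows - cells$row_px[i]) * sampling_um
    dx <- (cols - cells$col_px[i]) * sampling_um
    rho2 <- outer(dy^2, dx^2, `+`)
    cap <- pmax(sqrt(pmax(R^2 - rho2, 0)) - (R - hmax), 0)
    cap[rho2 > r_um^2] <- 0
    h[rows, cols] <- pmax(h[rows, cols], cap)
  }
  h
}

# membrane pore lattice as a negative phase field; pores are anti-aliased
# discs (linear edge coverage over one pixel) so sub-pixel pores keep the
# correct integrated area
render_membrane_phase <- function(dims, sampling_um, pore_diameter_um,
                                  pore_pitch_um, depth_rad) {
  phase <- matrix(0, dims[1], dims[2])
  pitch_px <- pore_pitch_um / sampling_um
  r_um <- pore_diameter_um / 2
  centers_r <- seq(pitch_px / 2, dims[1], by = pitch_px)
  centers_c <- seq(pitch_px / 2, dims[2], by = pitch_px)
  half <- ceiling(r_um / sampling_um) + 1
  for (cr in centers_r) for (cc in centers_c) {
    rows <- max(1L, floor(cr - half)):min(dims[1], ceiling(cr + half))
    cols <- max(1L, floor(cc - half)):min(dims[2], ceiling(cc + half))
    dy <- (rows - cr) * sampling_um
    dx <- (cols - cc) * sampling_um
    rho <- sqrt(outer(dy^2, dx^2, `+`))
    cov <- pmin(pmax(0.5 + (r_um - rho) / sampling_um, 0), 1)
    phase[rows, cols] <- phase[rows, cols] - depth_rad * cov
  }
  phase
}

#' Simulate a ground-truth scene
#'
#' Places `n_cells` non-overlapping spherical-cap cells by rejection sampling
#' (radii and heights uniform over their configured ranges, centers uniform
#' over the in-field region), optionally adds a porous-membrane lattice, and
#' records the ground-truth optical phase and analytic per-cell volumes.
#' Deterministic for a fixed seed.
#'
#' @param params a [scene_params()]
#' @param wavelength_um wavelength used to convert height to phase
#' @param compute_phase set `FALSE` to skip rendering `true_phase` (geometry
#'   and volumes only; used by fast statistical calibrations)
#' @param max_retries rejection-sampling budget before giving up
#' @return a `synthetic_scene`: `params`, `cells` (data.frame `row_px`,
#'   `col_px`, `radius_um`, `height_um`), `true_phase` (radians),
#'   `true_cell_volumes_um3`, `wavelength_um`, `delta_n`
#' @export
simulate_scene <- function(params, wavelength_um = 0.6328,
                           compute_phase = TRUE, max_retries = 10000L) {
  stopifnot(inherits(params, "scene_params"))
  dims <- params$field_size_px
  px <- params$object_pixel_um
  cells <- withr::with_seed(params$seed, {
    placed <- data.frame(row_px = numeric(0), col_px = numeric(0),
                         radius_um = numeric(0), height_um = numeric(0))
    tries <- 0L
    while (nrow(placed) < params$n_cells) {
      if (tries >= max_retries)
        stop("field too crowded: could not place ", params$n_cells,
             " non-overlapping cells in ", max_retries, " retries")
      tries <- tries + 1L
      r_um <- runif(1, params$cell_radius_um[1], params$cell_radius_um[2])
      h_um <- runif(1, params$cell_height_um[1], params$cell_height_um[2])
      r_px <- r_um / px
      if (2 * r_px + 4 >= min(dims))
        stop("field too crowded: a single cell does not fit in the field")
      cr <- runif(1, r_px + 2, dims[1] - r_px - 1)
      cc <- runif(1, r_px + 2, dims[2] - r_px - 1)
      ok <- TRUE
      if (nrow(placed) > 0) {
        d_um <- sqrt((placed$row_px - cr)^2 + (placed$col_px - cc)^2) * px
        ok <- all(d_um > placed$radius_um + r_um + px)
      }
      if (ok)
        placed <- rbind(placed, data.frame(row_px = cr, col_px = cc,
                                           radius_um = r_um, height_um = h_um))
    }
    placed
  })
  delta_n <- params$cell_refractive_index - params$medium_refractive_index
  scene <- structure(list(params = params,
                          cells = cells,
                          true_phase = NULL,
                          true_cell_volumes_um3 =
                            cap_volume(cells$radius_um, cells$height_um),
                          wavelength_um = wavelength_um,
                          delta_n = delta_n,
                          treatment = NULL),
                     class = "synthetic_scene")
  if (compute_phase) scene$true_phase <- scene_phase(scene)
  scene
}

# render the ground-truth phase of a scene from its current cell table
scene_phase <- function(scene) {
  p <- scene$params
  h <- render_cells_height(p$field_size_px, scene$cells, p$object_pixel_um)
  phase <- (2 * pi / scene$wavelength_um) * scene$delta_n * h
  if (p$membrane_enabled)
    phase <- phase + render_membrane_phase(p$field_size_px, p$object_pixel_um,
                                           p$pore_diameter_um, p$pore_pitch_um,
                                           p$pore_depth_phase_rad)
  phase
}

#' Ground-truth height map of a scene
#'
#' @param scene a `synthetic_scene`
#' @return a [height_map] of the cell-only thickness field (um)
#' @export
scene_height_map <- function(scene) {
  p <- scene$params
  h <- render_cells_height(p$field_size_px, scene$cells, p$object_pixel_um)
  height_map(h, sampling_um = p$object_pixel_um, delta_n = scene$delta_n)
}

#' Apply a treatment effect to a scene
#'
#' Removes `cell_loss_count` randomly chosen cells, then draws a per-cell
#' shrink `s_i` from a normal with the stated dispersion truncated to
#' `[0, 1)` — the normal's location is adjusted so the truncated mean equals
#' `volume_shrink_fraction` exactly — and rescales each surviving cell so its
#' volume becomes `(1 - s_i) V_i`. The footprint (base radius) is kept fixed and the new cap
#' height is solved from the target volume, so cells stay exact spherical
#' caps and the analytic volume bookkeeping remains valid.
#'
#' @param scene a `synthetic_scene`
#' @param effect a [treatment_effect()]
#' @param seed integer seed for the treatment randomness
#' @param regenerate_phase recompute `true_phase` (set `FALSE` for fast
#'   truth-only calibrations)
#' @return the treated `synthetic_scene`
#' @export
apply_treatment <- function(scene, effect, seed = 1L, regenerate_phase = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(effect, "treatment_effect"))
  n <- nrow(scene$cells)
  if (effect$cell_loss_count > n)
    stop("cell_loss_count (", effect$cell_loss_count,
         ") exceeds the scene's cell count (", n, ")")
  if (effect$label == "control") {
    scene$treatment <- effect
    return(scene)
  }
  scene <- withr::with_seed(as.integer(seed), {
    keep <- seq_len(n)
    if (effect$cell_loss_count > 0)
      keep <- sort(sample(n, n - effect$cell_loss_count))
    cells <- scene$cells[keep, , drop = FALSE]
    vols <- scene$true_cell_volumes_um3[keep]
    m <- length(keep)
    s <- rep(effect$volume_shrink_fraction, m)
    if (effect$shrink_dispersion > 0) {
      mu <- truncnorm_location(effect$volume_shrink_fraction,
                               effect$shrink_dispersion)
      for (i in seq_len(m)) {
        for (try in 1:1000) {
          si <- rnorm(1, mu, effect$shrink_dispersion)
          if (si >= 0 && si < 1) { s[i] <- si; break }
        }
      }
    }
    new_vols <- vols * (1 - s)
    cells$height_um <- cap_height_for_volume(cells$radius_um, new_vols)
    rownames(cells) <- NULL
    scene$cells <- cells
    scene$true_cell_volumes_um3 <- new_vols
    scene$treatment <- effect
    scene$applied_shrink <- s
    scene
  })
  if (regenerate_phase && !is.null(scene$true_phase))
    scene$true_phase <- scene_phase(scene)
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synthetic_scene> %dx%d px (%.3g um/px), %d cells%s\n",
              p$field_size_px[1], p$field_size_px[2], p$object_pixel_um,
              nrow(x$cells),
              if (p$membrane_enabled) ", porous membrane" else ""))
  if (!is.null(x$treatment))
    cat(sprintf("  treatment: %s (shrink %.4g, loss %d)\n",
                x$treatment$label, x$treatment$volume_shrink_fraction,
                x$treatment$cell_loss_count))
  invisible(x)
}

#' Scene parameters for a seeding-density condition
#'
#' Maps a per-insert seeded cell count to the number of cells expected in one
#' 20x field using a fixed representative scale (default: one field cell per
#' 1500 seeded cells, i.e. 10 cells for 15,000 seeded and 20 for 30,000).
#'
#' @param n_seeded cells seeded per insert (e.g. 15000 or 30000)
#' @param base_params a [scene_params()] supplying everything but `n_cells`
#' @param cells_per_seeded field cells per seeded cell
#' @return a `scene_params` with `n_cells` set from the density
#' @export
scene_for_seeding <- function(n_seeded, base_params = scene_params(),
                              cells_per_seeded = 1 / 1500) {
  stopifnot(n_seeded > 0)
  base_params$n_cells <- max(0L, as.integer(round(n_seeded * cells_per_seeded)))
  base_params
}

#' Serialize a scene to disk
#'
#' Writes the truth record as JSON (parameters, cell table, volumes) and the
#' ground-truth phase as a scaled 32-bit float TIFF with a JSON sidecar.
#'
#' @param scene a `synthetic_scene`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(params = unclass(scene$params),
               cells = scene$cells,
               true_cell_volumes_um3 = scene$true_cell_volumes_um3,
               wavelength_um = scene$wavelength_um,
               delta_n = scene$delta_n,
               treatment = if (is.null(scene$treatment)) NULL else unclass(scene$treatment))
  json_path <- file.path(dir, "scene.json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths <- json_path
  if (!is.null(scene$true_phase)) {
    tif <- file.path(dir, "true_phase.tif")
    write_image_tiff(scene$true_phase, tif)
    paths <- c(paths, tif)
  }
  invisible(paths)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir directory containing `scene.json`
#' @return a `synthetic_scene`
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"), simplifyVector = TRUE)
  params <- do.call(scene_params, meta$params)
  cells <- as.data.frame(meta$cells)
  phase <- NULL
  tif <- file.path(dir, "true_phase.tif")
  if (file.exists(tif)) phase <- read_image_tiff(tif)
  structure(list(params = params, cells = cells, true_phase = phase,
                 true_cell_volumes_um3 = meta$true_cell_volumes_um3,
                 wavelength_um = meta$wavelength_um, delta_n = meta$delta_n,
                 treatment = if (length(meta$treatment) == 0) NULL else
                   do.call(treatment_effect, meta$treatment)),
            class = "synthetic_scene")
}
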