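# End-to-end pipeline: simulate -> synthesize holograms -> reconstruct ->
# measure -> compare, with a deterministic artifact tree.

# deterministic per-field seed derivation, kept under 2^31; the arithmetic
# index is scrambled through one RNG round because structured seed sequences
# yield correlated Mersenne-Twister streams
derive_seed <- function(base, condition_index, field_index, stage = 0L) {
  k <- (as.integer(base) * 7919L + condition_index * 1009L +
          field_index * 101L + stage * 13L) %% 2147483587L + 1L
  withr::with_seed(k, sample.int(2147483587L, 1))
}

# simulate one field of one condition: returns pre/post morphometry reports
run_field <- function(cfg, optics, effect, cond_idx, field_idx) {
  p <- do.call(scene_params, c(cfg$scene,
                               list(seed = derive_seed(cfg$seed, cond_idx,
                                                       field_idx, 0L))))
  p$object_pixel_um <- object_pixel_um(optics)
  scene <- simulate_scene(p, wavelength_um = optics$wavelength_um)
  noise <- noise_meta(cfg$noise$photon_scale, cfg$noise$read_noise_sigma,
                      seed = derive_seed(cfg$seed, cond_idx, field_idx, 1L))
  ropts <- do.call(reconstruct_options, cfg$reconstruction)
  mopts <- cfg$morphometry
  measure_scene <- function(sc, stage) {
    nz <- noise
    nz$seed <- derive_seed(cfg$seed, cond_idx, field_idx, stage)
    holo <- synthesize_hologram(phase_to_field(sc$true_phase, optics),
                                optics, noise = nz)
    ref <- reference_hologram(optics, p$field_size_px,
                              noise = {nr <- nz; nr$seed <- nz$seed + 1L; nr})
    rec <- reconstruct(holo, ref, optics, ropts)
    labels <- segment_cells(rec$height, mopts$min_height_um,
                            mopts$min_area_um2, mopts$smooth_sigma_px,
                            mopts$watershed_tolerance_um)
    list(report = measure_cells(labels, rec$height, mopts$dilate_px),
         rec = rec, holo = holo)
  }
  pre <- measure_scene(scene, 2L)
  treated <- apply_treatment(scene, effect,
                             seed = derive_seed(cfg$seed, cond_idx,
                                                field_idx, 3L))
  post <- measure_scene(treated, 4L)
  list(pre = pre, post = post, scene = scene, treated = treated)
}

#' Run the full simulation/reconstruction/statistics pipeline
#'
#' For the control and every configured treatment, simulates `n_fields`
#' replicate fields, renders noisy off-axis holograms of the untreated and
#' treated scenes, reconstructs height maps, measures morphometry, summarizes
#' percent volume decreases, compares every treatment against control
#' (Welch), and runs the flow-cytometry uptake gating for each configured
#' fraction. Writes a deterministic artifact tree (`holograms/`, `phase/`,
#' `height/`, `tables/`, `config.yaml`, `log.txt`) under `out_dir`.
#'
#' @param config a configuration list from [load_config()] /
#'   [default_config()]
#' @param out_dir output directory (default: `config$output_dir`); `NULL`
#'   skips writing artifacts
#' @return invisibly, `list(summaries, comparisons, uptake, qc)`
#' @export
run_pipeline <- function(config = default_config(), out_dir = config$output_dir) {
  validate_config(config)
  t0 <- Sys.time()
  log_lines <- c(sprintf("holoqpi %s | R %s", packageVersion("holoqpi"),
                         getRversion()),
                 sprintf("seed: %d", config$seed))
  optics <- do.call(optical_config, config$optics)
  conditions <- c(list(list(label = "control", volume_shrink_fraction = 0,
                            cell_loss_count = 0L, shrink_dispersion = 0)),
                  config$treatments)
  if (!is.null(out_dir)) {
    for (d in c("", "holograms", "phase", "height", "tables"))
      dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
    save_config(config, file.path(out_dir, "config.yaml"))
  }
  summaries <- list(); qc <- list()
  decreases <- list()
  for (ci in seq_along(conditions)) {
    tr <- do.call(treatment_effect, conditions[[ci]])
    t_stage <- Sys.time()
    pre_reports <- list(); post_reports <- list()
    for (fi in seq_len(config$stats$n_fields)) {
      fld <- run_field(config, optics, tr, ci, fi)
      pre_reports[[fi]] <- fld$pre$report
      post_reports[[fi]] <- fld$post$report
      if (!is.null(out_dir) && fi == 1L) {
        tag <- gsub("[^A-Za-z0-9]+", "_", tr$label)
        write_hologram(fld$pre$holo,
                       file.path(out_dir, "holograms", paste0(tag, "_pre.tif")))
        write_hologram(fld$post$holo,
                       file.path(out_dir, "holograms", paste0(tag, "_post.tif")))
        write_image_tiff(fld$post$rec$phase$values,
                         file.path(out_dir, "phase", paste0(tag, "_post.tif")))
        write_image_tiff(fld$post$rec$height$values,
                         file.path(out_dir, "height", paste0(tag, "_post.tif")))
        qc[[tr$label]] <- fld$post$rec$qc
      }
    }
    summaries[[tr$label]] <- volume_change(pre_reports, post_reports, tr$label)
    decreases[[tr$label]] <- summaries[[tr$label]]$decreases
    log_lines <- c(log_lines, sprintf(
      "condition %-12s: %d fields in %.1f s", tr$label,
      config$stats$n_fields,
      as.numeric(difftime(Sys.time(), t_stage, units = "secs"))))
  }
  comparisons <- do.call(rbind, lapply(names(decreases)[-1], function(lb) {
    cmp <- compare_conditions(decreases[[lb]], decreases[["control"]])
    data.frame(condition = lb, reference = "control",
               mean_difference_pct = cmp$difference, p_value = cmp$p_value)
  }))
  uptake <- do.call(rbind, lapply(names(config$flow$fractions), function(lb) {
    seed_u <- derive_seed(config$seed, match(lb, names(config$flow$fractions)),
                          0L, 9L)
    exp_t <- simulate_flow_experiment(config$flow$fractions[[lb]],
                                      config$flow$n_events,
                                      flow_mixture(config$flow$negative,
                                                   config$flow$positive),
                                      seed = seed_u)
    g <- gate_positive(exp_t$treated, exp_t$control,
                       config$stats$control_quantile)
    data.frame(condition = lb, percent_positive = g$percent_positive,
               percent_positive_corrected = g$percent_positive_corrected,
               gate_threshold = g$gate_threshold,
               control_false_positive_pct = g$control_false_positive_pct)
  }))
  summary_df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(condition = s$label, n_fields = s$n_fields,
               mean_volume_decrease_pct = s$mean_volume_decrease_pct,
               sd_volume_decrease_pct = s$sd_volume_decrease_pct,
               mean_count_change = s$mean_count_change,
               sd_count_change = s$sd_count_change)))
  rownames(summary_df) <- NULL
  if (!is.null(out_dir)) {
    write.csv(summary_df, file.path(out_dir, "tables", "condition_summaries.csv"),
              row.names = FALSE)
    write.csv(comparisons, file.path(out_dir, "tables", "comparisons.csv"),
              row.names = FALSE)
    write.csv(uptake, file.path(out_dir, "tables", "uptake.csv"),
              row.names = FALSE)
    dec_df <- do.call(rbind, lapply(names(decreases), function(lb)
      data.frame(condition = lb, field = seq_along(decreases[[lb]]),
                 volume_decrease_pct = decreases[[lb]])))
    write.csv(dec_df, file.path(out_dir, "tables", "field_decreases.csv"),
              row.names = FALSE)
    jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    log_lines <- c(log_lines, sprintf(
      "total wall time: %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  invisible(list(summaries = summary_df, comparisons = comparisons,
                 uptake = uptake, qc = qc, decreases = decreases))
}
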