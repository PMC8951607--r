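PIPELINE_KEYS <- c("structure", "trajectory", "synthetic", "discard",
                   "hbond", "channel", "windows", "outdir", "seed", "plots")

#' Run the full analysis pipeline
#'
#' Executes geometry, hydrogen-bond, solvent and dynamics analyses on one
#' trajectory and writes tidy TSV tables plus a machine-readable YAML
#' summary of the headline observables into `outdir`. The configuration
#' (plus seed and package version) is serialized alongside, making every
#' output directory self-describing. The trajectory is either read from
#' `structure`/`trajectory` paths (PDB/GRO + multi-model PDB) or generated
#' by the synthetic module when `synthetic` parameters are given.
#'
#' @param config a named list or path to a YAML file. Recognised keys:
#'   `structure`, `trajectory` (input paths), `synthetic` (list with
#'   optional `nanotube`, `motion`, `waters`, `membrane` entries),
#'   `discard` (ps), `hbond` (`d_max`, `angle_max`), `channel`
#'   (`radius_cut`, `mouth_pad`), `windows` (diffusion window lengths,
#'   ps), `outdir`, `seed`, `plots`. Unknown keys are rejected.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  outdir <- config$outdir %||% stop("config must name an outdir")
  discard <- config$discard %||% 0
  seed <- config$seed %||% 1L

  # -- inputs (validated before any output is written)
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    spec <- do.call(nanotube_spec, syn$nanotube %||% list())
    frame <- build_ideal_nanotube(spec)
    if (!is.null(syn$waters)) frame <- place_channel_waters(frame, syn$waters)
    if (!is.null(syn$membrane)) frame <- build_membrane_proxy(frame, syn$membrane)
    motion <- do.call(motion_spec, c(syn$motion %||% list(), list(seed = seed)))
    traj <- simulate_trajectory(frame, motion)
  } else {
    if (is.null(config$trajectory) || !file.exists(config$trajectory))
      stop("trajectory file missing: ", config$trajectory %||% "<unset>")
    traj <- read_trajectory(config$trajectory)
  }

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(outdir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message("stage: geometry")
  deform <- radial_deformation(traj, discard = discard)
  tsv(deform, "ring_deformation")
  com <- com_distance_series(traj, discard = discard)
  tsv(com, "com_distances")
  tilts <- tilt_angles(traj, discard = discard)
  tsv(tilts, "tilt_angles")

  message("stage: hbonds")
  crit <- do.call(hbond_criterion, config$hbond %||% list())
  records <- hbond_series(traj, criterion = crit, discard = discard)
  classes <- c("cp_cp", "cp_cp_backbone", "cp_water", "cp_lipid")
  counts <- purrr::map_dfr(classes, function(cl) {
    cc <- count_hbonds(records, class = cl)
    cc$class <- cl
    cc
  })
  tsv(counts, "hbond_counts")

  message("stage: solvent")
  region <- do.call(channel_region, config$channel %||% list())
  wcount <- purrr::map_dfr(which(traj$time >= discard), function(t) {
    tibble::tibble(frame = t, time = traj$time[t],
                   count = count_channel_waters(get_frame(traj, t), region))
  })
  tsv(wcount, "water_counts")
  pat <- axial_pattern(traj, region = region, discard = discard)
  tsv(pat$slots, "axial_pattern")
  prof <- radius_profile(traj, region = region, discard = discard)
  tsv(prof, "radius_profile")

  message("stage: dynamics")
  # a short or motionless trajectory has no meaningful tilt PCA
  pca <- tryCatch(suppressWarnings(tilt_pca(tilts)), error = function(e) NULL)
  tsv(if (!is.null(pca)) tidy(pca) else
    tibble::tibble(component = integer(), eigenvalue = numeric(),
                   fraction = numeric(), cumulative = numeric()),
    "tilt_pca")
  windows <- config$windows %||% numeric(0)
  com_track <- com_series(traj, discard = discard)
  dfits <- purrr::map_dfr(windows, function(w) {
    fit <- fit_diffusion(lateral_displacements(com_track, window = w))
    glance(fit)
  })
  if (nrow(dfits) > 0) tsv(dfits, "diffusion")

  if (isTRUE(config$plots)) {
    if (!is.null(pca))
      ggplot2::ggsave(file.path(outdir, "tilt_pca.png"), autoplot(pca),
                      width = 5, height = 4)
    ggplot2::ggsave(file.path(outdir, "radius_profile.png"),
                    plot_radius_profile(prof), width = 6, height = 4)
    ggplot2::ggsave(file.path(outdir, "tilt_series.png"),
                    plot_tilt_series(tilts), width = 6, height = 4)
  }

  summary <- list(
    n_frames = n_frames(traj),
    backbone_hbonds_mean = mean(count_hbonds(records, "cp_cp_backbone")$count),
    cp_cp_hbonds_mean = mean(count_hbonds(records, "cp_cp")$count),
    channel_waters_mean = mean(wcount$count),
    water_pattern = pat$label,
    tube_tilt_mean = mean(tilts$tilt[tilts$unit == "tube"]),
    pca_first_fraction = if (!is.null(pca)) pca$fractions[1] else NA,
    diffusion = if (nrow(dfits) > 0)
      lapply(seq_len(nrow(dfits)), function(i) as.list(dfits[i, ])) else NULL)
  yaml::write_yaml(summary, file.path(outdir, "summary.yaml"))
  yaml::write_yaml(c(config, list(package_version = as.character(
    utils::packageVersion("scpntools")))), file.path(outdir, "config.yaml"))
  if (!is.null(traj$ground_truth))
    write_ground_truth(traj$ground_truth, file.path(outdir, "ground_truth.yaml"))
  invisible(summary)
}
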