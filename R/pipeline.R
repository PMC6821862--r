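# End-to-end orchestration of the standard workflow:
# simulate/load -> correct -> track -> calibrate -> dejitter -> sinogram ->
# reconstruct -> FRC, with a single reproducibility seed and per-stage
# outputs written with provenance.

#' Pipeline run configuration
#'
#' All knobs for one reproducible end-to-end run. One global `seed` derives
#' every stage seed deterministically (single-knob reproducibility). The
#' configuration is serializable to a `key: value` manifest via
#' [save_run_config()] and a run is reproducible from its saved config.
#'
#' @param out_dir output directory (created if missing).
#' @param input path to an existing projection stack (TIFF or directory), or
#'   NULL to simulate one.
#' @param geometry an [acquisition_geometry()].
#' @param phantom_size simulated phantom size `c(z, y, x)`.
#' @param bead_z_frac,bead_radius_px,bead_dy_px,bead_dx_px fiducial bead
#'   placement for the simulated phantom: fractional z position, radius, and
#'   (y, x) offsets from the axis in px.
#' @param artifacts an [artifact_spec()]; its jitter/noise seeds are
#'   overridden from `seed`.
#' @param bright_level simulated bright-field level (tOPT), counts.
#' @param filter a [filter_spec()].
#' @param polarity fiducial polarity for tracking.
#' @param rows 0-based rows to reconstruct (NULL = all).
#' @param frc_rows 0-based rows for the split-half FRC (NULL = middle row of
#'   `rows`).
#' @param calibrate run axis calibration (default TRUE).
#' @param dejitter run dynamic offset correction (default TRUE).
#' @param bright path to a bright-field TIFF when `input` is a measured tOPT
#'   stack (required in that case).
#' @param seed global integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       input = NULL,
                       geometry = acquisition_geometry(256, pixel_size_um = 10),
                       phantom_size = c(40, 96, 96),
                       bead_z_frac = 0.85, bead_radius_px = 2,
                       bead_dy_px = 8, bead_dx_px = 20,
                       artifacts = artifact_spec(),
                       bright_level = 1000,
                       filter = filter_spec("ramp"),
                       polarity = "bright",
                       rows = NULL, frc_rows = NULL,
                       calibrate = TRUE, dejitter = TRUE,
                       bright = NULL,
                       seed = 1L) {
  cfg <- structure(list(out_dir = out_dir, input = input, geometry = geometry,
                        phantom_size = phantom_size, bead_z_frac = bead_z_frac,
                        bead_radius_px = bead_radius_px,
                        bead_dy_px = bead_dy_px, bead_dx_px = bead_dx_px,
                        artifacts = artifacts, bright_level = bright_level,
                        filter = filter, polarity = polarity, rows = rows,
                        frc_rows = frc_rows, calibrate = calibrate,
                        dejitter = dejitter, bright = bright,
                        seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!inherits(cfg$geometry, "acquisition_geometry"))
    stop_config("geometry must be an acquisition_geometry")
  if (!inherits(cfg$artifacts, "artifact_spec"))
    stop_config("artifacts must be an artifact_spec")
  if (!inherits(cfg$filter, "filter_spec"))
    stop_config("filter must be a filter_spec")
  if (!is.null(cfg$input) && cfg$geometry$modality == "tOPT" &&
      is.null(cfg$bright))
    stop_config("modality tOPT with a measured input requires a bright-field image")
  invisible(cfg)
}

# Deterministic stage seeds derived from the one global seed.
stage_seed <- function(seed, stage) {
  offsets <- c(jitter = 101L, noise = 211L, misc = 307L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% .Machine$integer.max
}

#' Save / load a run configuration
#'
#' Flat `key: value` manifest round trip: `load_run_config(save_run_config(x))`
#' reproduces the run bit-for-bit (fixed seed).
#'
#' @param cfg a [run_config()].
#' @param path manifest path.
#' @return `path` / a `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  g <- cfg$geometry; a <- cfg$artifacts; f <- cfg$filter
  m <- list(out_dir = cfg$out_dir,
            input = cfg$input %||% "",
            n_projections = g$n_projections,
            angular_range_deg = g$angular_range_deg,
            start_angle_deg = g$start_angle_deg,
            pixel_size_um = g$pixel_size_um,
            min_step_deg = g$min_step_deg,
            modality = g$modality,
            phantom_size = cfg$phantom_size,
            bead_z_frac = cfg$bead_z_frac,
            bead_radius_px = cfg$bead_radius_px,
            bead_dy_px = cfg$bead_dy_px, bead_dx_px = cfg$bead_dx_px,
            axis_offset_px = a$axis_offset_px,
            tilt_inplane_deg = a$tilt_inplane_deg,
            tilt_outplane_deg = a$tilt_outplane_deg,
            jitter_sigma_px = a$jitter_sigma_px,
            noise = a$noise, noise_param = a$noise_param,
            illumination_peak_ratio =
              if (is.null(a$illumination)) 0 else attr(a$illumination, "peak_ratio") %||% 1.5,
            bright_level = cfg$bright_level,
            filter_kind = f$kind, filter_padding = f$padding,
            polarity = cfg$polarity,
            rows = cfg$rows %||% "",
            frc_rows = cfg$frc_rows %||% "",
            calibrate = cfg$calibrate, dejitter = cfg$dejitter,
            bright = cfg$bright %||% "",
            seed = cfg$seed)
  write_manifest(m, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  m <- read_manifest(path)
  blank <- function(v) is.null(v) || !length(v) || is.na(v[1]) || !nzchar(v[1])
  num <- function(k, default = NULL) {
    v <- m[[k]]
    if (blank(v)) default else as.numeric(v)
  }
  chr <- function(k, default = NULL) {
    v <- m[[k]]
    if (blank(v)) default else as.character(v[1])
  }
  ratio <- num("illumination_peak_ratio", 0)
  size <- as.integer(num("phantom_size"))
  il <- if (ratio > 0) {
    fld <- illumination_field(size[1], size[3], ratio)
    attr(fld, "peak_ratio") <- ratio
    fld
  } else NULL
  run_config(
    out_dir = chr("out_dir"),
    input = chr("input"),
    geometry = acquisition_geometry(num("n_projections"),
                                    num("angular_range_deg", 360),
                                    num("start_angle_deg", 0),
                                    num("pixel_size_um", 1),
                                    num("min_step_deg", 360 / 1024),
                                    chr("modality", "tOPT")),
    phantom_size = size,
    bead_z_frac = num("bead_z_frac", 0.85),
    bead_radius_px = num("bead_radius_px", 2),
    bead_dy_px = num("bead_dy_px", 8), bead_dx_px = num("bead_dx_px", 20),
    artifacts = artifact_spec(num("axis_offset_px", 0),
                              num("tilt_inplane_deg", 0),
                              num("tilt_outplane_deg", 0),
                              num("jitter_sigma_px", 0),
                              illumination = il,
                              noise = chr("noise", "none"),
                              noise_param = num("noise_param", 0)),
    bright_level = num("bright_level", 1000),
    filter = filter_spec(chr("filter_kind", "ramp"), num("filter_padding", 2)),
    polarity = chr("polarity", "bright"),
    rows = if (is.null(num("rows"))) NULL else as.integer(num("rows")),
    frc_rows = if (is.null(num("frc_rows"))) NULL else as.integer(num("frc_rows")),
    calibrate = as.logical(chr("calibrate", "TRUE")),
    dejitter = as.logical(chr("dejitter", "TRUE")),
    bright = chr("bright"),
    seed = as.integer(num("seed", 1)))
}

# Disks-plus-fiducial phantom used by the simulated pipeline: the sample
# (cylinders) occupies the lower z range and the bead sits above it, off-axis.
pipeline_phantom <- function(cfg) {
  size <- cfg$phantom_size
  ph <- make_phantom("disks", size)
  sample_top <- floor(size[1] * 0.6)
  ph$voxels[(sample_top + 1):size[1], , ] <- 0
  bead_z <- round(size[1] * cfg$bead_z_frac)
  bead <- phantom_bead(size,
                       center = c(bead_z,
                                  (size[2] - 1) / 2 + cfg$bead_dy_px,
                                  (size[3] - 1) / 2 + cfg$bead_dx_px),
                       radius = cfg$bead_radius_px, value = 2)
  ph$voxels <- ph$voxels + bead
  ph$kind <- "disks+bead"
  ph
}

#' Run the full OPT pipeline
#'
#' Executes the standard workflow in order: simulate (or load) projections,
#' Beer-Lambert/flat-field correction, fiducial tracking, axis calibration,
#' dynamic offset (jitter) correction, sinogram assembly, filtered
#' back-projection, and split-half FRC. Each stage's output is written under
#' `cfg$out_dir`; skipping the calibration or dejitter stage is allowed and
#' recorded in the run log. Any stage failure aborts with the stage name.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage log lines (default FALSE; logs go to
#'   stderr).
#' @return a list: `volume` ([opt_volume()]), `frc` (`frc_result`), `track`,
#'   `model` ([geometry_model()]), `corrections`, `phantom` (simulated runs),
#'   `paths` (named output files).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_run_config(cfg)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(fmt, ...) {
    if (!quiet)
      message(sprintf("[optomo %7.2fs] %s", proc.time()[["elapsed"]] - t0,
                      sprintf(fmt, ...)))
  }
  run_stage <- function(name, expr) {
    log_stage("stage %s", name)
    tryCatch(expr, error = function(e) {
      stop_with("optomo_stage_error", "stage '%s' failed: %s", name,
                conditionMessage(e))
    })
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  phantom <- NULL
  a <- cfg$artifacts
  a$jitter_seed <- stage_seed(cfg$seed, "jitter")
  a$noise_seed <- stage_seed(cfg$seed, "noise")

  if (is.null(cfg$input) || !nzchar(cfg$input %||% "")) {
    sim <- run_stage("simulate", {
      phantom <- pipeline_phantom(cfg)
      fp <- forward_project(phantom, cfg$geometry, a)
      if (cfg$geometry$modality == "tOPT")
        fp$stack <- attenuation_to_intensity(
          fp$stack, cfg$bright_level *
            (a$illumination %||% matrix(1, dim(fp$stack$data)[2],
                                        dim(fp$stack$data)[3])))
      list(fp = fp, phantom = phantom)
    })
    phantom <- sim$phantom
    stack <- sim$fp$stack
    paths$projections <- file.path(cfg$out_dir, "projections.tif")
    write_stack(stack, paths$projections)
    paths$truth <- file.path(cfg$out_dir, "truth.manifest")
    write_manifest(list(axis_offset_px = a$axis_offset_px,
                        tilt_inplane_deg = a$tilt_inplane_deg,
                        tilt_outplane_deg = a$tilt_outplane_deg,
                        jitter_sigma_px = a$jitter_sigma_px,
                        jitter_shifts = sim$fp$jitter_shifts),
                   paths$truth)
    bright_img <- matrix(cfg$bright_level, dim(stack$data)[2], dim(stack$data)[3]) *
      (a$illumination %||% 1)
  } else {
    stack <- run_stage("load", read_stack(cfg$input, cfg$geometry))
    bright_img <- if (!is.null(cfg$bright) && nzchar(cfg$bright))
      read_tiff(cfg$bright)[[1]] else NULL
  }

  stack <- run_stage("correct", {
    if (cfg$geometry$modality == "tOPT")
      beer_lambert_correct(stack, bright_field(bright_img), floor = 1e-3)
    else flatfield_correct(stack)
  })

  track <- run_stage("track", {
    d <- dim(stack$data)
    roi_h <- max(9L, as.integer(6 * cfg$bead_radius_px))
    bead_z <- round(cfg$phantom_size[1] * cfg$bead_z_frac)
    r0 <- max(0, bead_z - roi_h %/% 2)
    track_fiducial(stack, c(r0, 0, min(roi_h, d[2] - r0), d[3]),
                   polarity = cfg$polarity)
  })
  paths$track <- file.path(cfg$out_dir, "track.csv")
  utils::write.csv(as.data.frame(unclass(track)), paths$track, row.names = FALSE)

  model <- if (cfg$calibrate) {
    m <- run_stage("calibrate",
                   estimate_geometry(track, detector_center_col(dim(stack$data)[3])))
    paths$geometry <- file.path(cfg$out_dir, "geometry.manifest")
    write_manifest(list(axis_offset_px = m$axis_offset_px,
                        tilt_inplane_deg = m$tilt_inplane_deg,
                        tilt_outplane_deg = m$tilt_outplane_deg,
                        source = m$source), paths$geometry)
    m
  } else {
    log_stage("stage calibrate skipped")
    NULL
  }

  corrections <- if (cfg$dejitter) {
    co <- run_stage("dejitter", dynamic_offset(track))
    paths$corrections <- file.path(cfg$out_dir, "corrections.csv")
    utils::write.csv(data.frame(angle_deg = track$angle_deg,
                                correction_px = as.numeric(co)),
                     paths$corrections, row.names = FALSE)
    co
  } else {
    log_stage("stage dejitter skipped")
    NULL
  }

  rows <- cfg$rows %||% (seq_len(dim(stack$data)[2]) - 1)
  volume <- run_stage("reconstruct",
                      reconstruct_volume(stack, model, corrections,
                                         cfg$filter, rows))
  paths$volume <- file.path(cfg$out_dir, "volume.tif")
  write_stack(volume, paths$volume)

  frc <- run_stage("frc", {
    fr <- cfg$frc_rows %||% rows[ceiling(length(rows) / 2)]
    frc_resolution_from_halves(stack, model, corrections, cfg$filter, fr)
  })
  paths$frc <- file.path(cfg$out_dir, "frc.csv")
  utils::write.csv(data.frame(freq_cyc_per_px = frc$freq_cyc_per_px,
                              frc = frc$frc, threshold = frc$threshold),
                   paths$frc, row.names = FALSE)
  paths$config <- file.path(cfg$out_dir, "config.manifest")
  save_run_config(cfg, paths$config)
  log_stage("done")
  list(volume = volume, frc = frc, track = track, model = model,
       corrections = corrections, phantom = phantom, paths = paths)
}
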