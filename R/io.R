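#' Read a voxel volume (mask or dose map) from NIfTI
#'
#' Reads a NIfTI file and returns its 3-D grid together with the voxel
#' size and full affine, which downstream functions use to verify that
#' masks and dose maps share the same grid.  Masks are coerced to \{0, 1\}:
#' values within `tol` of 0/1 are snapped with a warning, anything else is
#' an error (resampling is out of scope and silently reinterpreting label
#' values would be worse).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask Validate and coerce to a binary mask.
#' @param tol Snap tolerance for near-binary values.
#' @return A list of class `cv_volume`: `grid` (3-D array), `pixdim` (mm),
#'   `affine` (4x4).
#' @export
read_voxel_volume <- function(path, mask = FALSE, tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  grid <- as.array(img)
  grid <- array(as.numeric(grid), dim(grid))  # plain array, no image attrs
  if (length(dim(grid)) != 3)
    stop("expected a 3-D volume, got ", length(dim(grid)), " dimensions")
  if (mask) {
    near0 <- abs(grid) <= tol
    near1 <- abs(grid - 1) <= tol
    bad <- !(near0 | near1)
    if (any(bad))
      stop(sprintf("mask is not binary: %d voxel(s) outside {0,1}", sum(bad)))
    if (any((near0 & grid != 0) | (near1 & grid != 1)))
      warning("near-binary mask values snapped to {0,1}")
    grid <- array(as.numeric(near1), dim(grid))
  }
  structure(list(grid = grid, pixdim = RNifti::pixdim(img)[1:3],
                 affine = structure(RNifti::xform(img), code = NULL)),
            class = "cv_volume")
}

#' Write a voxel volume to NIfTI
#'
#' @param grid 3-D array (or `cv_volume`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixdim Voxel edge lengths in mm (length 3).
#' @return `path`, invisibly.
#' @export
write_voxel_volume <- function(grid, path, pixdim = c(1, 1, 1)) {
  if (inherits(grid, "cv_volume")) {
    pixdim <- grid$pixdim
    grid <- grid$grid
  }
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two voxel volumes share a grid
#'
#' Dose maps must live on the same grid as the tumour mask; any mismatch
#' in dimensions or affine is an error, never a silent resample.
#'
#' @param a,b `cv_volume` objects from [read_voxel_volume()].
#' @param tol Affine comparison tolerance.
#' @return `TRUE` invisibly, or an error.
#' @export
assert_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(dim(a$grid), collapse = "x"),
                 paste(dim(b$grid), collapse = "x")))
  if (max(abs(a$affine - b$affine)) > tol)
    stop("affine mismatch between volumes sharing a grid")
  invisible(TRUE)
}

#' Write a volume series to CSV
#'
#' One row per timepoint with columns `timepoint`, `hour`, `volume_cm3`
#' (comma-separated, UTF-8, header row).
#'
#' @param series A [volume_series()].
#' @param path Output path.
#' @param hours Optional named hours matching the series names.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(series, path, hours = NULL) {
  df <- data.frame(timepoint = names(series),
                   hour = if (is.null(hours)) NA_real_
                          else as.numeric(hours[names(series)]),
                   volume_cm3 = as.numeric(series))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a volume series from CSV
#'
#' @param path CSV written by [write_volume_series()] (columns `timepoint`,
#'   `volume_cm3`).
#' @return A [volume_series()].
#' @export
read_volume_series <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("timepoint", "volume_cm3") %in% names(df)))
  volume_series(setNames(df$volume_cm3, df$timepoint))
}

#' Write a treatment schedule (with dose maps) to a directory
#'
#' The schedule structure goes to `schedule.yaml`; each BT fraction's
#' total-dose map is written as NIfTI next to it.
#'
#' @param schedule A [treatment_schedule()].
#' @param dir Output directory (created if missing).
#' @param pixdim Voxel size of the dose maps (mm).
#' @return The YAML path, invisibly.
#' @export
write_schedule <- function(schedule, dir, pixdim = c(1, 1, 1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bt <- lapply(seq_along(schedule$bt), function(i) {
    f <- schedule$bt[[i]]
    map_file <- sprintf("bt%d_dose.nii.gz", i)
    write_voxel_volume(f$dose_map, file.path(dir, map_file), pixdim)
    list(hour = f$hour, dose_map = map_file,
         n_pulses = f$train$n_pulses, pulse_dose = f$train$pulse_dose,
         pulse_duration = f$train$pulse_duration,
         interpulse_gap = f$train$interpulse_gap)
  })
  doc <- list(ebrt = lapply(seq_len(nrow(schedule$ebrt)), function(i)
                list(hour = schedule$ebrt$hour[i],
                     dose = schedule$ebrt$dose[i])),
              cisplatin = as.numeric(schedule$cisplatin),
              bt = bt,
              timepoints = as.list(schedule$timepoints),
              t_end = schedule$t_end)
  path <- file.path(dir, "schedule.yaml")
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a treatment schedule written by [write_schedule()]
#'
#' @param dir Directory containing `schedule.yaml` and dose-map NIfTIs.
#' @return A [treatment_schedule()].
#' @export
read_schedule <- function(dir) {
  doc <- yaml::read_yaml(file.path(dir, "schedule.yaml"))
  ebrt <- if (length(doc$ebrt))
    data.frame(hour = vapply(doc$ebrt, `[[`, numeric(1), "hour"),
               dose = vapply(doc$ebrt, `[[`, numeric(1), "dose"))
  else NULL
  bt <- lapply(doc$bt, function(f) {
    vol <- read_voxel_volume(file.path(dir, f$dose_map))
    list(hour = f$hour, dose_map = vol$grid,
         train = pulse_train(f$n_pulses, f$pulse_dose, f$pulse_duration,
                             f$interpulse_gap))
  })
  treatment_schedule(ebrt = ebrt, cisplatin = as.numeric(doc$cisplatin),
                     bt = bt, timepoints = unlist(doc$timepoints),
                     t_end = doc$t_end)
}

#' Machine-readable run manifest
#'
#' Serialises what a run needs to be reproduced: the configuration values,
#' the seed, and package/R versions, plus a content hash of the
#' configuration.
#'
#' @param config Named list of configuration values (paths, grids, flags).
#' @param seed Integer seed of the run.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  manifest <- list(
    config = config,
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))) %%
      .Machine$integer.max,
    package = as.character(utils::packageVersion("cervosim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
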