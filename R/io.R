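#' Write a multi-echo complex volume to NIfTI with a JSON sidecar
#'
#' The complex array is stored as a 5D NIfTI (x, y, z, echo, re/im); echo
#' times, voxel spacing, metadata and a provenance block (package version,
#' configuration hash, seeds) go to `<path>.json`.
#'
#' @param vol A [multi_echo_volume()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "multi_echo_volume"))
  d <- dim(vol$data)
  arr <- array(0, dim = c(d, 2L))
  arr[, , , , 1L] <- Re(vol$data)
  arr[, , , , 2L] <- Im(vol$data)
  img <- RNifti::asNifti(arr, pixdim = c(vol$voxel_size_mm, 1, 1))
  RNifti::writeNifti(img, path)
  sidecar <- list(
    echo_times_s = vol$echo_times_s,
    voxel_size_mm = vol$voxel_size_mm,
    meta = vol$meta,
    provenance = provenance_block(vol$meta, seed = vol$meta$noise_seed)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read a multi-echo volume written by [write_volume()]
#'
#' @param path NIfTI path.
#' @return A [multi_echo_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("volume not found: '%s'", path))
  arr <- as.array(RNifti::readNifti(path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop(sprintf("sidecar not found: '%s'", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  d <- dim(arr)
  data <- array(complex(real = arr[seq_len(prod(d[1:4]))],
                        imaginary = arr[prod(d[1:4]) + seq_len(prod(d[1:4]))]),
                dim = d[1:4])
  multi_echo_volume(data, meta$echo_times_s,
                    voxel_size_mm = meta$voxel_size_mm, meta = meta$meta)
}

#' Write fat-water maps to NIfTI
#'
#' Writes PDFF (%), R2* (1/s), B0 (Hz) and residual maps as
#' `<prefix>_pdff.nii.gz` etc., plus a JSON sidecar with provenance.
#'
#' @param result A `fatwater_result`.
#' @param prefix Output path prefix.
#' @param voxel_size_mm Voxel spacing.
#' @return Named vector of written paths, invisibly.
#' @export
write_maps <- function(result, prefix, voxel_size_mm = c(1.5, 1.5, 1.5)) {
  stopifnot(inherits(result, "fatwater_result"))
  maps <- list(pdff = result$pdff_map, r2star = result$r2star_map,
               b0 = result$f0_map, residual = result$residual_map)
  paths <- vapply(names(maps), function(nm) {
    p <- sprintf("%s_%s.nii.gz", prefix, nm)
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]], pixdim = voxel_size_mm), p)
    p
  }, character(1))
  jsonlite::write_json(
    list(maps = as.list(paths), echo_times_s = result$echo_times_s,
         provenance = provenance_block(result$config)),
    paste0(prefix, "_maps.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a gradient waveform as TSV
#'
#' Columns: `t_s` and one per axis (mT/m); `#` header lines carry raster and
#' provenance.
#'
#' @param wf A [gradient_waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_tsv <- function(wf, path) {
  stopifnot(inherits(wf, "gradient_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gradient waveform, raster_s=%.8g, package freerunfw %s",
                     wf$dt, utils::packageVersion("freerunfw")), con)
  tab <- data.frame(t_s = (seq_len(nrow(wf$G)) - 1) * wf$dt, wf$G,
                    check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gradient waveform TSV written by [write_waveform_tsv()]
#'
#' @param path TSV path.
#' @return A [gradient_waveform()].
#' @export
read_waveform_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("waveform not found: '%s'", path))
  hdr <- readLines(path, n = 1L)
  dt <- as.numeric(sub(".*raster_s=([0-9.eE+-]+).*", "\\1", hdr))
  tab <- read.delim(path, comment.char = "#")
  gradient_waveform(as.matrix(tab[, -1L, drop = FALSE]), dt,
                    axes = colnames(tab)[-1L])
}

#' Write a JSON report with provenance
#'
#' @param report Named list of results.
#' @param path Output path.
#' @param config Configuration to hash into the provenance block.
#' @param seed Seed to record.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, config = list(), seed = NULL) {
  report$provenance <- provenance_block(config, seed)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load an experiment configuration (YAML or JSON)
#'
#' Unknown keys are kept; missing keys fall back to `defaults`.
#'
#' @param path Config path (`.yaml`/`.yml`/`.json`).
#' @param defaults Named list of defaults.
#' @return Named list.
#' @export
load_experiment_config <- function(path, defaults = list()) {
  if (!file.exists(path)) stop(sprintf("config not found: '%s'", path))
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  modifyList(defaults, cfg)
}
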