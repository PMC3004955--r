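# Readers/writers and the pipeline runner: NIfTI volumes/series (with
# TR in the header), k-space / kernel bundles, CSV metric tables and a
# reproducibility manifest.

#' Write a volume or 4D series as NIfTI
#'
#' @param x 2D/3D/4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size (mm), recycled to 3.
#' @param TR repetition time (s) stored in the 4th pixdim slot (4D
#'   only).
#' @return `path`, invisibly.
#' @export
write_nifti_vol <- function(x, path, voxel_mm = 3, TR = NULL) {
  if (length(dim(x)) < 2) stop("x must be at least 2D")
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  vox <- rep(voxel_mm, length.out = 3)
  pd <- if (length(dim(x)) == 4) c(vox, TR %||% 1) else vox
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume or series
#' @param path file path.
#' @return list: `data` (array), `voxel_mm`, `TR` (4D only, else NA).
#' @export
read_nifti_vol <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("malformed NIfTI file: ", path, " (", conditionMessage(e), ")"))
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, voxel_mm = pd[seq_len(min(3, length(pd)))],
       TR = if (length(dim(arr)) == 4 && length(pd) >= 4) pd[4]
            else NA_real_)
}

#' Check that two NIfTI volumes share a grid
#' @param a,b results of [read_nifti_vol()].
#' @return TRUE, or an error describing the mismatch.
#' @export
check_matched_geometry <- function(a, b) {
  if (!identical(dim(a$data)[1:3], dim(b$data)[1:3]))
    stop("volume dimensions do not match")
  if (any(abs(a$voxel_mm - b$voxel_mm) > 1e-6))
    stop("voxel sizes do not match")
  TRUE
}

#' Export a phantom as NIfTI magnitude/phase pairs
#' @param phantom a [make_brain_phantom()].
#' @param prefix output path prefix; writes `<prefix>_mag.nii.gz`,
#'   `<prefix>_phase.nii.gz` and `<prefix>_labels.nii.gz`.
#' @return character vector of paths, invisibly.
#' @export
export_phantom_nifti <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "mux_phantom"))
  N <- phantom$matrix
  ns <- length(phantom$slices)
  mag <- array(0, c(N, N, ns)); phs <- array(0, c(N, N, ns))
  lab <- array(0L, c(N, N, ns))
  for (s in seq_len(ns)) {
    mag[, , s] <- Mod(phantom$slices[[s]])
    phs[, , s] <- Arg(phantom$slices[[s]])
    lab[, , s] <- phantom$labels[[s]]
  }
  paths <- c(paste0(prefix, "_mag.nii.gz"), paste0(prefix, "_phase.nii.gz"),
             paste0(prefix, "_labels.nii.gz"))
  write_nifti_vol(mag, paths[1], phantom$voxel_size_mm)
  write_nifti_vol(phs, paths[2], phantom$voxel_size_mm)
  write_nifti_vol(lab, paths[3], phantom$voxel_size_mm)
  invisible(paths)
}

#' Save / load a k-space or kernel bundle
#'
#' Serialises a `mux_kspace`, `mb_kernel` or calibration list together
#' with its layout metadata to a single binary bundle file.
#' @param x object to save.
#' @param path file path (conventionally `.rds`).
#' @return `save_bundle` returns `path` invisibly; `load_bundle` the
#'   object.
#' @export
save_bundle <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle not found: ", path)
  readRDS(path)
}

#' Run a simulation/reconstruction pipeline from a configuration
#'
#' Executes the requested stages (phantom, simulate, recon, gfactor,
#' timing) and writes every artifact plus a JSON manifest recording
#' parameters, seeds and file checksums, so a run can be reproduced
#' byte-for-byte from config + manifest.
#'
#' @param config named list: `out_dir`; `seed`; `stages` (character
#'   subset of `c("phantom","simulate","recon","gfactor","timing")`);
#'   optional `protocol` (a [protocol_spec()] or path to a key=value
#'   protocol file); optional `n_slices_phantom`, `n_coils`,
#'   `noise_sigma`.
#' @return the manifest, invisibly; artifacts are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("phantom", "simulate", "recon")
  known <- c("phantom", "simulate", "recon", "gfactor", "timing")
  if (length(bad <- setdiff(stages, known)))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  spec <- config$protocol %||% protocol_spec()
  if (is.character(spec)) spec <- read_protocol(spec)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("muxepi")),
                   seed = seed, stages = stages,
                   parameters = list(m = spec$m, n = spec$n,
                                     R_pe = spec$R_pe, TR = spec$TR,
                                     matrix = spec$matrix),
                   files = list(), status = "ok")
  written <- character()
  fail_at <- NULL
  res <- tryCatch({
    phantom <- coils <- mux <- cal <- NULL
    if (any(c("phantom", "simulate", "recon", "gfactor") %in% stages)) {
      fail_at <- "phantom"
      phantom <- make_brain_phantom(
        n_slices = config$n_slices_phantom %||% (spec$m * spec$n),
        matrix = spec$matrix, fov_mm = spec$fov_mm, seed = seed)
      coils <- make_coil_sensitivities(phantom,
                                       n_coils = config$n_coils %||% 16,
                                       seed = seed)
      if ("phantom" %in% stages) {
        p <- export_phantom_nifti(phantom, file.path(out_dir, "phantom"))
        written <- c(written, p)
      }
    }
    if (any(c("simulate", "recon") %in% stages)) {
      fail_at <- "simulate"
      mux <- simulate_mux_acquisition(phantom, coils, spec, seed = seed,
                                      noise_sigma =
                                        config$noise_sigma %||% 0)
      cal <- simulate_singleband_calibration(phantom, coils, spec)
      p <- file.path(out_dir, "kspace.rds")
      save_bundle(mux, p); written <- c(written, p)
    }
    if ("recon" %in% stages) {
      fail_at <- "recon"
      rec <- reconstruct(mux, calibration = cal)
      arr <- simplify2array(rec$slice_images)
      p <- file.path(out_dir, "recon.nii.gz")
      write_nifti_vol(arr, p, phantom$voxel_size_mm)
      written <- c(written, p)
    }
    if ("gfactor" %in% stages) {
      fail_at <- "gfactor"
      g <- analytic_g_factor(coils, mb_group = seq_len(spec$n),
                             R_pe = spec$R_pe)
      p <- file.path(out_dir, "gfactor.csv")
      utils::write.csv(data.frame(slice = g$mb_group,
                                  mean_g = g$mean_g, max_g = g$max_g),
                       p, row.names = FALSE)
      written <- c(written, p)
    }
    if ("timing" %in% stages) {
      fail_at <- "timing"
      p <- file.path(out_dir, "timing.csv")
      utils::write.csv(timing_report(spec), p, row.names = FALSE)
      written <- c(written, p)
    }
    fail_at <- NULL
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) {
    manifest$status <- "failed"
    manifest$failed_stage <- fail_at
    manifest$error <- conditionMessage(res)
  }
  manifest$files <- as.list(tools::md5sum(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (manifest$status == "failed")
    warning("pipeline failed at stage '", fail_at, "': ", manifest$error)
  invisible(manifest)
}
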