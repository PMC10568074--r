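# Volume container and file I/O. Volumes are plain 3-D arrays carrying voxel
# size and acquisition metadata; NIfTI-1 is the on-disk format (RAS
# orientation, affine built from the voxel size).

#' Create an image volume
#'
#' A light container for a 3-D scalar field: the data array plus voxel size
#' (mm) and free-form metadata (sequence label, NEX, seed). Values must be
#' finite.
#'
#' @param data Numeric 3-D array.
#' @param voxel_mm Length-3 voxel size in mm.
#' @param meta Named list of metadata.
#' @param allow_na Permit `NA` values (used by derived maps to flag voxels
#'   outside the mask); acquisition volumes must be finite everywhere.
#' @return An object of class `mwi_volume` (an array with attributes).
#' @export
mwi_volume <- function(data, voxel_mm = c(1.72, 1.72, 5), meta = list(),
                       allow_na = FALSE) {
  if (length(dim(data)) != 3) abort("`data` must be a 3-D array.")
  bad <- if (allow_na) any(is.nan(data) | is.infinite(data)) else any(!is.finite(data))
  if (bad) abort("Volume values must all be finite.")
  if (length(voxel_mm) != 3 || any(voxel_mm <= 0))
    abort("`voxel_mm` must be 3 positive numbers.")
  structure(data, voxel_mm = as.numeric(voxel_mm), meta = meta,
            class = c("mwi_volume", "array"))
}

#' @export
print.mwi_volume <- function(x, ...) {
  v <- attr(x, "voxel_mm")
  cat(sprintf("<mwi_volume> %s voxels of %s mm; range [%.4g, %.4g]\n",
              paste(dim(x), collapse = " x "),
              paste(format(v, digits = 3), collapse = " x "),
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  m <- attr(x, "meta")
  if (length(m)) cat("  meta:", paste(names(m), unlist(lapply(m, format)),
                                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# strip attributes for arithmetic
vol_data <- function(x) {
  a <- as.array(x)
  attributes(a) <- list(dim = dim(x))
  a
}

#' Read and write NIfTI-1 volumes
#'
#' Volumes are written RAS-oriented with the voxel size in the header
#' (diagonal affine); reading recovers the data array and voxel size. Data
#' are stored and returned in the canonical x-fastest axis order used
#' throughout the package.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param vol An [mwi_volume()].
#' @return `read_volume()` returns an [mwi_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) abort(paste0("Not a readable NIfTI file: ", path),
                                            class = "stairmwi_format_error"))
  pix <- RNifti::pixdim(img)
  if (length(pix) < 3 || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0)) {
    warn("Voxel size missing from header; assuming 1 mm isotropic.")
    pix <- c(1, 1, 1)
  }
  mwi_volume(array(as.numeric(img), dim = dim(img)[1:3]),
             voxel_mm = pix[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mwi_volume"))
  img <- RNifti::asNifti(vol_data(vol))
  RNifti::pixdim(img) <- attr(vol, "voxel_mm")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write run configuration
#'
#' The run configuration carries the two protocols, the quantification
#' constants, the AFP pulse definition and the phantom specification as one
#' YAML document. Unknown top-level keys are rejected so that typos do not
#' silently fall back to defaults. [default_config()] returns the shipped
#' defaults (the in-vivo STAIR/PD protocols and calibrated pulse).
#'
#' @param path Path to a YAML file.
#' @param config A named list as returned by [read_config()].
#' @return A named list with elements `protocols`, `constants`, `afp`,
#'   `phantom`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("protocols", "constants", "afp", "phantom")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", "),
                 ". Allowed: ", paste(allowed, collapse = ", "), "."),
          class = "stairmwi_config_error")
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_config
#' @export
default_config <- function() {
  read_config(system.file("extdata", "defaults.yaml", package = "stairmwi",
                          mustWork = TRUE))
}

# build seq_params / quant_constants from config sub-lists
config_protocol <- function(p) {
  seq_params(tr_ms = p$tr_ms, ti_ms = p$ti_ms, te_ms = p$te_ms,
             flip_deg = p$flip_deg %||% 90, nex = p$nex %||% 1L,
             label = p$label %||% "")
}

config_constants <- function(cst) do.call(quant_constants, cst)

#' Write ROI statistics to CSV
#'
#' @param stats A tibble as returned by [extract_roi_stats()] or
#'   [quantify_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_stats <- function(stats, path) {
  readr::write_csv(stats, path)
  invisible(path)
}
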