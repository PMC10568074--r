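# Digital brain phantom: a labeled ellipsoidal "brain" with two-compartment
# voxels (myelin water + long-T1 water), forward-simulated through the STAIR
# and PD signal models with complex Rician noise and NEX averaging. This is
# the validation bed standing in for in-vivo data.

#' Default tissue class table
#'
#' Ground-truth parameters per tissue class. Only the white-matter T1 band
#' and the group aMWF values are anchored to the in-vivo study (NWM 9.9%,
#' NAWM 8.5%, lesion 3.6%); the remaining relaxation and proton-density
#' values are editorial defaults in the physiological range and are exposed
#' here for overriding.
#'
#' @return A tibble with one row per class: `name`, `amwf_true` (fraction),
#'   `t1_long_ms`, `t2s_long_ms`, `t1_mw_ms`, `t2s_mw_ms`, `m0_total`.
#' @export
tissue_classes <- function() {
  tibble(
    name       = c("NWM", "NAWM", "GM", "lesion", "CSF"),
    amwf_true  = c(0.099, 0.085, 0.03, 0.036, 0),
    t1_long_ms = c(850, 900, 1500, 1100, 4000),
    t2s_long_ms = c(60, 60, 60, 60, 500),
    t1_mw_ms   = 220,
    t2s_mw_ms  = 10,
    m0_total   = c(0.7, 0.7, 0.8, 0.7, 1.0)
  )
}

check_classes <- function(classes) {
  stopifnot(is.data.frame(classes))
  need <- c("name", "amwf_true", "t1_long_ms", "t2s_long_ms",
            "t1_mw_ms", "t2s_mw_ms", "m0_total")
  missing <- setdiff(need, names(classes))
  if (length(missing))
    abort(paste0("Class table lacks columns: ", paste(missing, collapse = ", ")))
  if (any(classes$amwf_true < 0 | classes$amwf_true > 0.5))
    abort("`amwf_true` must lie in [0, 0.5].")
  if (any(classes$t1_long_ms < 300 | classes$t1_long_ms > 5000))
    abort("`t1_long_ms` must lie in [300, 5000] ms.")
  invisible(classes)
}

#' Phantom specification
#'
#' Geometry, tissue parameters, noise level and simulation mode for the
#' synthetic brain. The default grid is 64 x 64 x 15 voxels of
#' 1.72 x 1.72 x 5 mm (a desk-scale version of the 128 x 128 x 15 in-vivo
#' matrix).
#'
#' @param shape Grid dimensions (3 integers).
#' @param voxel_mm Voxel size (mm).
#' @param classes Tissue class table; see [tissue_classes()].
#' @param n_lesions Number of lesion spheres placed in white matter
#'   (patients; use 0 for healthy anatomy).
#' @param lesion_radius_vox In-plane lesion radius range (voxels).
#' @param n_rois,roi_radius_vox Number and in-plane radius of the non-lesion
#'   white-matter analysis ROIs.
#' @param noise_sigma Per-channel, per-excitation Gaussian noise SD in
#'   signal units where CSF proton density is 1. The default 0.005 gives a
#'   white-matter SNR of roughly 130 per excitation in the PD image and
#'   roughly 9 in the STAIR image after NEX = 30 complex averaging.
#' @param mode `"model_matched"` (forward model identical to the one the
#'   quantifier inverts; recovery is exact without noise) or `"two_pool"`
#'   (full two-compartment signal including residual long-T1 leakage, the
#'   phantom's model of apparent-MWF bias).
#' @param seed Integer seed; all phantom randomness flows from it.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 15), voxel_mm = c(1.72, 1.72, 5),
                         classes = tissue_classes(), n_lesions = 9L,
                         lesion_radius_vox = c(1.5, 3), n_rois = 8L,
                         roi_radius_vox = 3, noise_sigma = 0.005,
                         mode = c("model_matched", "two_pool"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(shape) != 3 || any(shape < 6)) abort("`shape` must be 3 dims >= 6.")
  check_classes(classes)
  if (n_lesions < 0) abort("`n_lesions` must be >= 0.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  structure(
    list(shape = as.integer(shape), voxel_mm = voxel_mm, classes = classes,
         n_lesions = as.integer(n_lesions),
         lesion_radius_vox = lesion_radius_vox, n_rois = as.integer(n_rois),
         roi_radius_vox = roi_radius_vox, noise_sigma = noise_sigma,
         mode = mode, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# tissue label codes
TISSUE_CODES <- c(background = 0L, WM = 1L, GM = 2L, CSF = 3L, lesion = 4L)

# internal: draw one subject's class table; between-subject variation enters
# only through amwf_true, truncated to the physical range
jitter_classes <- function(classes, jitter_sd) {
  jit <- jitter_sd[classes$name]
  jit[is.na(jit)] <- 0
  classes$amwf_true <- pmin(pmax(
    classes$amwf_true + rnorm(nrow(classes), 0, jit), 0), 0.5)
  classes
}

# internal: logical array of an axis-aligned ellipsoid
ellipsoid_mask <- function(shape, center, semi_axes) {
  x <- (seq_len(shape[1]) - center[1]) / semi_axes[1]
  y <- (seq_len(shape[2]) - center[2]) / semi_axes[2]
  z <- (seq_len(shape[3]) - center[3]) / semi_axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

# internal: place n non-overlapping ellipsoidal blobs fully inside `allowed`
place_blobs <- function(shape, allowed, n, radius_range, z_radius = 1,
                        max_retries = 1000L) {
  ids <- array(0L, dim = shape)
  candidates <- which(allowed)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_retries)
      abort("Could not place non-overlapping blobs in white matter.",
            class = "stairmwi_placement_error")
    ctr <- arrayInd(sample(candidates, 1L), shape)
    r <- stats::runif(1, radius_range[1], radius_range[2])
    blob <- ellipsoid_mask(shape, as.numeric(ctr), c(r, r, z_radius))
    if (!any(blob)) next
    if (all(allowed[blob]) && all(ids[blob] == 0L)) {
      placed <- placed + 1L
      ids[blob] <- placed
    }
  }
  ids
}

#' Build the phantom label maps
#'
#' Deterministic given the spec seed: an ellipsoidal brain with a cortical
#' grey-matter shell, a white-matter core, central CSF, `n_lesions`
#' non-overlapping lesion blobs inside white matter, and `n_rois` analysis
#' ROIs placed in lesion-free white matter (the phantom's stand-in for the
#' eight manually drawn white-matter regions).
#'
#' @param spec A [phantom_spec()].
#' @param group `"control"` (no lesions) or `"patient"`.
#' @param seed Optional override of `spec$seed`.
#' @return An object of class `phantom_labels`: list of [mwi_volume()]s
#'   `tissue` (codes 0 = background, 1 = WM, 2 = GM, 3 = CSF, 4 = lesion),
#'   `roi` (0 or ROI index) and `lesion` (0 or lesion index), plus the
#'   `group` and the white-matter class name (`NWM` for controls, `NAWM`
#'   for patients).
#' @export
build_label_map <- function(spec, group = c("patient", "control"),
                            seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  group <- match.arg(group)
  seed <- seed %||% spec$seed
  set.seed(seed)
  shp <- spec$shape
  ctr <- (shp + 1) / 2
  brain <- ellipsoid_mask(shp, ctr, c(0.44, 0.46, 0.48) * shp)
  inner_semi <- pmax(c(0.44, 0.46, 0.48) * shp - c(3, 3, 1.2), 1)
  inner <- ellipsoid_mask(shp, ctr, inner_semi)
  # central ventricle; capped so small desk-scale grids keep a WM core
  csf <- ellipsoid_mask(shp, ctr, pmin(c(6, 4, 2), 0.55 * inner_semi))
  tissue <- array(TISSUE_CODES[["background"]], dim = shp)
  tissue[brain] <- TISSUE_CODES[["GM"]]
  tissue[inner] <- TISSUE_CODES[["WM"]]
  tissue[csf & inner] <- TISSUE_CODES[["CSF"]]
  wm <- tissue == TISSUE_CODES[["WM"]]

  n_les <- if (group == "patient") spec$n_lesions else 0L
  lesion_ids <- if (n_les > 0)
    place_blobs(shp, wm, n_les, spec$lesion_radius_vox)
  else array(0L, dim = shp)
  tissue[lesion_ids > 0] <- TISSUE_CODES[["lesion"]]
  wm <- tissue == TISSUE_CODES[["WM"]]

  r <- spec$roi_radius_vox
  roi_ids <- place_blobs(shp, wm, spec$n_rois, c(r, r))

  mk <- function(a, what) mwi_volume(a, spec$voxel_mm,
                                     meta = list(content = what, seed = seed))
  structure(
    list(tissue = mk(tissue, "tissue labels"),
         roi = mk(roi_ids, "WM analysis ROIs"),
         lesion = mk(lesion_ids, "lesion ids"),
         group = group,
         wm_class = if (group == "control") "NWM" else "NAWM"),
    class = "phantom_labels"
  )
}

# internal: per-voxel class parameter lookup for a label volume
class_lookup <- function(labels, classes) {
  tiss <- vol_data(labels$tissue)
  name <- rep(NA_character_, length(tiss))
  name[tiss == TISSUE_CODES[["WM"]]] <- labels$wm_class
  name[tiss == TISSUE_CODES[["GM"]]] <- "GM"
  name[tiss == TISSUE_CODES[["CSF"]]] <- "CSF"
  name[tiss == TISSUE_CODES[["lesion"]]] <- "lesion"
  idx <- match(name, classes$name)
  list(idx = idx, in_brain = !is.na(idx))
}

#' Forward-simulate one acquisition of the phantom
#'
#' Computes the noiseless per-voxel signal and applies NEX-averaged complex
#' noise. A sequence with an inversion time is simulated as a STAIR
#' acquisition, one without as the proton-density reference.
#'
#' In `model_matched` mode the forward model is exactly the pair of
#' single-pool equations the quantifier inverts: the STAIR voxel is
#' `m0_total * amwf * mw_signal_scale()` and the PD voxel is
#' `m0_total * exp(-TE / T2*_total)` with the constants' total-water T2*.
#' In `two_pool` mode both acquisitions are the sum of the myelin-water and
#' long-T1 compartments with their own relaxation times and inversion
#' efficiencies, so residual long-T1 leakage through the imperfect null is
#' present, as in tissue.
#'
#' Noise: `nex` independent complex Gaussian samples (SD `noise_sigma` per
#' channel) are averaged in the complex domain, then magnitude is taken.
#' With `noise_sigma = 0` the signed noiseless signal is returned.
#'
#' @param labels A [build_label_map()] result.
#' @param classes Tissue class table (possibly subject-jittered).
#' @param seq A [seq_params()].
#' @param constants A [quant_constants()].
#' @param mode `"model_matched"` or `"two_pool"`.
#' @param noise_sigma Per-channel noise SD; see [phantom_spec()].
#' @param seed Integer seed for the noise draws.
#' @return An [mwi_volume()].
#' @export
simulate_acquisition <- function(labels, classes, seq,
                                 constants = quant_constants(),
                                 mode = c("model_matched", "two_pool"),
                                 noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(labels, "phantom_labels"), inherits(seq, "seq_params"))
  mode <- match.arg(mode)
  check_classes(classes)
  lk <- class_lookup(labels, classes)
  shp <- dim(labels$tissue)
  n <- prod(shp)
  is_stair <- !is.null(seq$ti_ms)

  amwf <- classes$amwf_true[lk$idx]
  m0 <- classes$m0_total[lk$idx]
  sig <- numeric(n)
  if (mode == "model_matched") {
    if (is_stair) {
      sig[lk$in_brain] <- (m0 * amwf)[lk$in_brain] *
        mw_signal_scale(constants, seq)
    } else {
      sig[lk$in_brain] <- m0[lk$in_brain] *
        exp(-seq$te_ms / constants$t2s_total_ms)
    }
  } else {
    t1m <- classes$t1_mw_ms[lk$idx]; t2m <- classes$t2s_mw_ms[lk$idx]
    t1l <- classes$t1_long_ms[lk$idx]; t2l <- classes$t2s_long_ms[lk$idx]
    if (is_stair) {
      mwp <- stair_longitudinal(t1m, seq$tr_ms, seq$ti_ms, constants$q_mw) *
        exp(-seq$te_ms / t2m)
      lng <- stair_longitudinal(t1l, seq$tr_ms, seq$ti_ms, constants$q_long) *
        exp(-seq$te_ms / t2l)
    } else {
      mwp <- exp(-seq$te_ms / t2m)
      lng <- exp(-seq$te_ms / t2l)
    }
    s <- m0 * (amwf * mwp + (1 - amwf) * lng)
    sig[lk$in_brain] <- s[lk$in_brain]
  }

  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    nex <- seq$nex
    re <- sig + rowMeans(matrix(rnorm(n * nex, 0, noise_sigma), n, nex))
    im <- rowMeans(matrix(rnorm(n * nex, 0, noise_sigma), n, nex))
    sig <- sqrt(re^2 + im^2)
  }
  mwi_volume(array(sig, dim = shp), attr(labels$tissue, "voxel_mm"),
             meta = list(label = seq$label, nex = seq$nex, seed = seed,
                         mode = mode, noise_sigma = noise_sigma))
}

#' Simulate a subject cohort
#'
#' Generates healthy-control and patient subjects: per subject the class
#' aMWF values are jittered by a between-subject SD (defaults matching the
#' reported group SDs, 1.3/1.2/1.3 percentage points for NWM/NAWM/lesion),
#' anatomy is built (patients receive lesions), and STAIR and PD volumes are
#' forward-simulated. All randomness derives from `seed`; reruns are
#' identical.
#'
#' @param spec A [phantom_spec()].
#' @param n_controls,n_patients Subjects per group.
#' @param seq_stair,seq_pd Acquisition protocols.
#' @param constants A [quant_constants()].
#' @param jitter_sd Named vector of between-subject SDs of `amwf_true`
#'   (fractions) per class name; classes not named are not jittered.
#' @param seed Master seed.
#' @return An object of class `mwi_cohort`: `subjects` (list with `id`,
#'   `group`, `labels`, `stair`, `pd`, `classes`) and `truth` (tibble of the
#'   per-subject jittered class truths).
#' @export
simulate_cohort <- function(spec, n_controls = 7L, n_patients = 7L,
                            seq_stair = stair_protocol(),
                            seq_pd = pd_protocol(),
                            constants = quant_constants(),
                            jitter_sd = c(NWM = 0.013, NAWM = 0.012,
                                          lesion = 0.013),
                            seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_controls + n_patients < 1) abort("Need at least one subject.")
  set.seed(seed)
  n_tot <- n_controls + n_patients
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  groups <- rep(c("control", "patient"), c(n_controls, n_patients))

  subjects <- vector("list", n_tot)
  truth <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    set.seed(subject_seeds[i])
    cls <- jitter_classes(spec$classes, jitter_sd)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
    labels <- build_label_map(spec, group = groups[i], seed = sub_seeds[1])
    stair <- simulate_acquisition(labels, cls, seq_stair, constants,
                                  mode = spec$mode,
                                  noise_sigma = spec$noise_sigma,
                                  seed = sub_seeds[2])
    pd <- simulate_acquisition(labels, cls, seq_pd, constants,
                               mode = spec$mode,
                               noise_sigma = spec$noise_sigma,
                               seed = sub_seeds[3])
    id <- sprintf("%s%02d", if (groups[i] == "control") "hc" else "ms", i)
    subjects[[i]] <- list(id = id, group = groups[i], labels = labels,
                          stair = stair, pd = pd, classes = cls)
    truth[[i]] <- dplyr::mutate(cls[, c("name", "amwf_true")],
                                subject_id = id, group = groups[i],
                                .before = 1)
  }
  structure(list(subjects = subjects,
                 truth = dplyr::bind_rows(truth),
                 spec = spec, seed = seed),
            class = "mwi_cohort")
}

#' @export
print.mwi_cohort <- function(x, ...) {
  gr <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<mwi_cohort> %d subjects (%s), %s grid, mode = %s, seed = %d\n",
              length(x$subjects),
              paste(names(gr), gr, sep = ": ", collapse = ", "),
              paste(x$spec$shape, collapse = " x "), x$spec$mode, x$seed))
  invisible(x)
}
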