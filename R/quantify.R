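# Voxel-wise apparent myelin water fraction (aMWF) mapping: the STAIR image
# is (after long-T1 suppression) proportional to the myelin-water
# magnetization, the PD image to total water, so aMWF = M0_MW / M0_total is
# recovered by dividing the images and removing the known signal scales.

#' Calibration factor from image ratio to aMWF
#'
#' The ratio of the two per-unit-magnetization signal scales:
#' \deqn{k = \frac{e^{-TE_{PD}/T_{2,total}^*}}
#'   {(1 - Q_{MW} e^{-TR/T_{1,MW}} - (1-Q_{MW}) e^{-TI/T_{1,MW}})
#'    \, e^{-TE_{STAIR}/T_{2,MW}^*}}}
#' so that `aMWF = k * S_STAIR / S_PD`. With the default constants and
#' protocols k is about 7.44.
#'
#' @param constants A [quant_constants()].
#' @param seq_stair,seq_pd The two protocols ([seq_params()]).
#' @return Dimensionless scale factor.
#' @export
#' @examples
#' amwf_scale_factor(quant_constants(), stair_protocol(), pd_protocol())
amwf_scale_factor <- function(constants = quant_constants(),
                              seq_stair = stair_protocol(),
                              seq_pd = pd_protocol()) {
  mw <- mw_signal_scale(constants, seq_stair)
  if (abs(mw) < 1e-12)
    abort("Myelin-water signal scale is zero; constants are pathological.")
  exp(-seq_pd$te_ms / constants$t2s_total_ms) / mw
}

# internal: largest 6-connected component of a logical array (flood fill
# from every unvisited foreground voxel, vectorized frontier expansion)
largest_component <- function(mask) {
  shp <- dim(mask)
  n <- prod(shp)
  strides <- c(1L, shp[1], shp[1] * shp[2])
  coord_ok <- function(idx, axis, dir) {
    pos <- arrayInd(idx, shp)[, axis]
    if (dir > 0) pos < shp[axis] else pos > 1
  }
  labels <- integer(n)
  comp <- 0L
  todo <- which(mask)
  seen <- logical(n)
  best <- integer(0)
  for (start in todo) {
    if (seen[start]) next
    comp <- comp + 1L
    members <- integer(0)
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier)) {
      members <- c(members, frontier)
      nxt <- integer(0)
      for (axis in 1:3) for (dir in c(-1L, 1L)) {
        ok <- coord_ok(frontier, axis, dir)
        cand <- frontier[ok] + dir * strides[axis]
        cand <- cand[mask[cand] & !seen[cand]]
        seen[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
      frontier <- unique(nxt)
    }
    if (length(members) > length(best)) best <- members
  }
  out <- array(FALSE, dim = shp)
  out[best] <- TRUE
  out
}

#' Brain mask from the PD image
#'
#' Voxels whose PD signal exceeds `rel_threshold` times the robust maximum
#' (99th percentile) of the volume; only the largest 6-connected component
#' is kept, discarding isolated noise voxels.
#'
#' @param pd An [mwi_volume()] PD image.
#' @param rel_threshold Fraction of the robust maximum, in (0, 1).
#' @return A logical array of the mask.
#' @export
make_mask <- function(pd, rel_threshold = 0.1) {
  stopifnot(inherits(pd, "mwi_volume"))
  if (rel_threshold <= 0 || rel_threshold >= 1)
    abort("`rel_threshold` must be in (0, 1).")
  x <- vol_data(pd)
  robust_max <- quantile(x, 0.99, names = FALSE)
  mask <- x > rel_threshold * robust_max
  if (!any(mask))
    abort("Empty mask: no voxel exceeds the PD threshold.")
  largest_component(mask)
}

#' Compute the apparent myelin water fraction map
#'
#' Voxel-wise `aMWF = k * S_STAIR / S_PD` inside the mask, with
#' `k = amwf_scale_factor(...)`. Voxels outside the mask are `NA`. Raw
#' values below 0 are clipped to 0 and above 1 to 1; the counts of clipped
#' voxels are recorded (negative ratios arise from noise where the
#' myelin-water signal is small).
#'
#' @param stair,pd Co-registered [mwi_volume()]s of identical shape.
#' @param constants A [quant_constants()].
#' @param seq_stair,seq_pd The acquisition protocols.
#' @param mask Optional logical array; defaults to [make_mask()] on the PD
#'   image intersected with a PD floor that removes unstable ratios.
#' @param pd_rel_threshold Relative PD floor used when `mask` is `NULL`.
#' @return An object of class `amwf_map`: list with `data`
#'   ([mwi_volume()], `NA` outside the mask), `mask`, `k`,
#'   `n_clipped_low`, `n_clipped_high`, `constants`, `seqs`.
#' @export
compute_amwf_map <- function(stair, pd, constants = quant_constants(),
                             seq_stair = stair_protocol(),
                             seq_pd = pd_protocol(), mask = NULL,
                             pd_rel_threshold = 0.1) {
  stopifnot(inherits(stair, "mwi_volume"), inherits(pd, "mwi_volume"))
  if (!identical(dim(stair), dim(pd)))
    abort("STAIR and PD volumes have different shapes.",
          class = "stairmwi_geometry_error")
  if (is.null(mask)) {
    mask <- make_mask(pd, pd_rel_threshold)
  } else {
    if (!identical(dim(mask), dim(pd)))
      abort("Mask shape does not match the volumes.",
            class = "stairmwi_geometry_error")
    mask <- mask & (vol_data(pd) > 0)
  }
  if (!any(mask)) abort("Mask is empty.")
  k <- amwf_scale_factor(constants, seq_stair, seq_pd)
  s <- vol_data(stair); p <- vol_data(pd)
  raw <- array(NA_real_, dim = dim(s))
  raw[mask] <- k * s[mask] / p[mask]
  n_lo <- sum(raw[mask] < 0)
  n_hi <- sum(raw[mask] > 1)
  raw[mask] <- pmin(pmax(raw[mask], 0), 1)
  structure(
    list(data = mwi_volume(raw, attr(pd, "voxel_mm"),
                           meta = list(content = "aMWF", k = k),
                           allow_na = TRUE),
         mask = mask, k = k, n_clipped_low = n_lo, n_clipped_high = n_hi,
         constants = constants, seqs = list(stair = seq_stair, pd = seq_pd)),
    class = "amwf_map"
  )
}

#' @export
print.amwf_map <- function(x, ...) {
  v <- x$data[x$mask]
  cat(sprintf(
    "<amwf_map> %s voxels, %d in mask; median aMWF %.3f; k = %.3f; clipped %d low / %d high\n",
    paste(dim(x$data), collapse = " x "), sum(x$mask), stats::median(v),
    x$k, x$n_clipped_low, x$n_clipped_high))
  invisible(x)
}

#' ROI statistics from an aMWF map
#'
#' Mean and SD of the map over each labeled ROI, restricted to in-mask
#' voxels. ROIs without in-mask voxels are reported with `n_voxels = 0` and
#' missing mean/SD.
#'
#' @param map An [compute_amwf_map()] result.
#' @param roi_labels An integer [mwi_volume()] (0 = no ROI) aligned with the
#'   map.
#' @param roi_names Optional names per ROI index; defaults to
#'   `roi1, roi2, ...`.
#' @param subject_id Identifier copied into the output.
#' @return A tibble: `subject_id`, `roi_name`, `n_voxels`, `mean`, `sd`.
#' @export
extract_roi_stats <- function(map, roi_labels, roi_names = NULL,
                              subject_id = NA_character_) {
  stopifnot(inherits(map, "amwf_map"))
  if (!identical(dim(roi_labels), dim(map$data)))
    abort("ROI labels do not align with the map.",
          class = "stairmwi_geometry_error")
  ids <- sort(unique(as.integer(roi_labels[roi_labels > 0])))
  if (!is.null(roi_names)) {
    if (length(roi_names) < length(ids))
      abort("Fewer `roi_names` than ROI indices present.",
            class = "stairmwi_lookup_error")
  } else {
    roi_names <- paste0("roi", seq_len(max(ids, 0L)))
  }
  purrr::map_dfr(ids, function(i) {
    sel <- (vol_data(roi_labels) == i) & map$mask
    v <- map$data[sel]
    tibble(subject_id = subject_id, roi_name = roi_names[i],
           n_voxels = sum(sel),
           mean = if (sum(sel)) mean(v) else NA_real_,
           sd = if (sum(sel) > 1) sd(v) else NA_real_)
  })
}

#' Quantify a simulated cohort
#'
#' Runs the full quantification over a [simulate_cohort()] result: per
#' subject, compute the aMWF map and extract one observation per
#' white-matter ROI (group `NWM` for controls, `NAWM` for patients) and one
#' per lesion (group `lesion`). This observation table is the input to
#' [summarize_cohort()].
#'
#' @param cohort An `mwi_cohort`.
#' @param constants,seq_stair,seq_pd Quantification assumptions; default to
#'   the cohort's acquisition protocols.
#' @return A tibble: `subject_id`, `group`, `roi_name`, `n_voxels`, `value`
#'   (ROI-mean aMWF, fraction).
#' @export
quantify_cohort <- function(cohort, constants = quant_constants(),
                            seq_stair = stair_protocol(),
                            seq_pd = pd_protocol()) {
  stopifnot(inherits(cohort, "mwi_cohort"))
  quantify_cohort_impl(cohort, constants, seq_stair, seq_pd)
}

quantify_cohort_impl <- function(cohort, constants, seq_stair, seq_pd) {
  purrr::map_dfr(cohort$subjects, function(sub) {
    map <- compute_amwf_map(sub$stair, sub$pd, constants, seq_stair, seq_pd)
    wm <- extract_roi_stats(map, sub$labels$roi, subject_id = sub$id)
    wm <- dplyr::mutate(wm, group = sub$labels$wm_class, .after = "subject_id")
    out <- dplyr::select(wm, "subject_id", "group", "roi_name",
                         "n_voxels", value = "mean")
    if (any(sub$labels$lesion > 0)) {
      les <- extract_roi_stats(
        map, sub$labels$lesion,
        roi_names = paste0("lesion", seq_len(max(sub$labels$lesion))),
        subject_id = sub$id)
      les <- dplyr::mutate(les, group = "lesion", .after = "subject_id")
      out <- dplyr::bind_rows(
        out, dplyr::select(les, "subject_id", "group", "roi_name",
                           "n_voxels", value = "mean"))
    }
    out
  })
}

#' Monte Carlo parameter recovery over replicate cohorts
#'
#' Simulates `n_replicates` independent cohorts (each with its own subjects
#' drawn from the same population), quantifies each, and pools the ROI-mean
#' observations per group. With a single 7+7-subject cohort the pooled group
#' mean still carries a between-subject sampling SD of about 0.5 percentage
#' points (7 subjects, 1.2-1.3 pp jitter); replication averages that
#' Monte Carlo error down without changing the per-cohort design.
#'
#' @param spec A [phantom_spec()].
#' @param n_replicates Number of independent cohorts.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param ... Passed on to [simulate_cohort()] (cohort sizes, protocols,
#'   jitter).
#' @param constants Quantification constants.
#' @return A list: `means` (tibble `group`, `mean_amwf`, `n_obs`) pooled
#'   over all replicates, and `per_replicate` (tibble with per-replicate
#'   group means and the observation tables nested in `obs`).
#' @export
recover_group_means <- function(spec, n_replicates = 1L, seed = spec$seed,
                                constants = quant_constants(), ...) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  all_obs <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cohort <- simulate_cohort(spec, seed = rep_seeds[r], ...)
    obs <- quantify_cohort(cohort, constants = constants)
    dplyr::mutate(obs, replicate = r, .before = 1)
  })
  summarise_groups <- function(d)
    dplyr::summarise(dplyr::group_by(d, .data$group),
                     mean_amwf = mean(.data$value), n_obs = dplyr::n(),
                     .groups = "drop")
  per <- dplyr::group_modify(dplyr::group_by(all_obs, .data$replicate),
                             ~ summarise_groups(.x))
  list(means = summarise_groups(all_obs),
       per_replicate = dplyr::ungroup(per),
       obs = all_obs)
}
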