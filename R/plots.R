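# ggplot2 graphics for each result type.

#' Plot the residual suppression profile
#'
#' Residual long-T1 signal across the suppression band at one or more
#' candidate inversion times.
#'
#' @param spec A [suppression_spec()].
#' @param ti_ms Vector of inversion times (ms) to overlay.
#' @return A ggplot.
#' @export
plot_residual_profile <- function(spec, ti_ms) {
  df <- purrr::map_dfr(ti_ms, function(ti)
    dplyr::mutate(residual_signal_profile(spec, ti),
                  ti = sprintf("TI = %.2f ms", ti)))
  ggplot2::ggplot(df, ggplot2::aes(.data$t1_ms, .data$signal,
                                   colour = .data$ti)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "T1 (ms)", y = "residual signal (fraction of M0)",
                  colour = NULL,
                  title = sprintf("Long-T1 suppression at TR = %g ms",
                                  spec$tr_ms)) +
    ggplot2::theme_minimal()
}

#' Plot inversion efficiency against T2
#'
#' @param profile A tibble from [q_profile()].
#' @return A ggplot.
#' @export
plot_q_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$t2_ms, .data$q)) +
    ggplot2::geom_hline(yintercept = -1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "T2 (ms)", y = "inversion efficiency Q",
                  title = "Adiabatic inversion efficiency vs T2") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a volume
#'
#' @param vol An [mwi_volume()] or the `data` element of an `amwf_map`.
#' @param slice Slice index along the third axis; defaults to the middle.
#' @param limits Optional colour limits.
#' @return A ggplot.
#' @export
plot_slice <- function(vol, slice = NULL, limits = NULL) {
  stopifnot(inherits(vol, "mwi_volume"))
  slice <- slice %||% ceiling(dim(vol)[3] / 2)
  sl <- vol_data(vol)[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, na.value = "black") +
    ggplot2::coord_fixed(ratio = attr(vol, "voxel_mm")[2] /
                           attr(vol, "voxel_mm")[1]) +
    ggplot2::labs(title = sprintf("slice %d", slice), fill = NULL) +
    ggplot2::theme_void()
}

#' @describeIn summarize_cohort Bar plot of the group means with their
#'   confidence intervals, annotated with the Games-Howell adjusted
#'   p-values.
#' @param object An `amwf_comparison`.
#' @export
autoplot.amwf_comparison <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(.data$group, 100 * .data$mean)) +
    ggplot2::geom_col(fill = "grey85", colour = "grey30", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$conf_low, ymax = 100 * .data$conf_high),
      width = 0.15) +
    ggplot2::labs(x = NULL, y = "aMWF (%)",
                  title = "Group comparison of aMWF",
                  subtitle = paste(
                    sprintf("%s vs %s: p = %.2g", object$pairwise$group1,
                            object$pairwise$group2, object$pairwise$p_adj),
                    collapse = "; ")) +
    ggplot2::theme_minimal()
}
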