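# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_step
#'   geom_point geom_histogram geom_smooth geom_vline geom_hline geom_col
#'   facet_wrap labs scale_fill_gradient2 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a voxel-wise correlation map as axial slices
#'
#' @param object A `swa_statmap` (or `swa_perm`, whose significant voxels are
#'   outlined) with grid coordinates.
#' @param ... Unused.
#' @return A ggplot object: x/y tiles filled by r, faceted by z slice.
#' @export
autoplot.swa_statmap <- function(object, ...) {
  df <- object$stats
  assert_that(all(c("x", "y", "z") %in% names(df)),
              "stat map has no voxel coordinates to plot")
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$r)) +
    geom_tile() +
    facet_wrap(~z, labeller = ggplot2::label_both) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1)) +
    labs(x = "x (mm)", y = "y (mm)", fill = "r",
         title = "Voxel-wise partial correlation") +
    theme_minimal()
}

#' @export
autoplot.swa_perm <- function(object, ...) {
  p <- autoplot(object$statmap)
  sig <- object$statmap$stats[object$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    p <- p + geom_tile(data = sig, fill = NA, colour = "black",
                       linewidth = 0.6)
  }
  p + labs(subtitle = sprintf("critical |r| = %.3f (alpha = %g, %d permutations)",
                              object$critical_r, object$alpha, object$n_perm))
}

#' @export
autoplot.swa_map <- function(object, ...) {
  df <- dplyr::mutate(object$grid, value = object$values)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile() +
    facet_wrap(~z, labeller = ggplot2::label_both) +
    labs(x = "x (mm)", y = "y (mm)",
         fill = if (object$log_transformed) "log10 density" else "density",
         title = "SWA current-density map") +
    theme_minimal()
}

#' @export
autoplot.swa_spectra <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$freq, y = .data$psd, group = .data$channel)) +
    geom_line(alpha = 0.4) +
    geom_vline(xintercept = object$band, linetype = "dashed") +
    labs(x = "frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)),
         title = "Stage-gated channel spectra") +
    theme_minimal()
}

#' Plot a hypnogram
#'
#' @param hyp A [hypnogram()] object.
#' @return A ggplot step plot over the night, deep sleep lowest.
#' @export
plot_hypnogram <- function(hyp) {
  lev <- c("N3", "N2", "N1", "REM", "W")
  df <- tibble(
    hours = (seq_along(hyp$stages) - 1) * hyp$epoch_sec / 3600,
    stage = factor(hyp$stages, levels = lev)
  )
  ggplot(df, aes(x = .data$hours, y = as.integer(.data$stage))) +
    geom_step() +
    ggplot2::scale_y_continuous(breaks = seq_along(lev), labels = lev) +
    labs(x = "time since lights off (h)", y = NULL, title = "Hypnogram") +
    theme_minimal()
}

#' Histogram of absolute D-scores with bias-category cutpoints
#'
#' @param abs_d Numeric vector of absolute D-scores (or a behavior tibble
#'   with an `abs_d` column).
#' @param binwidth Histogram bin width.
#' @return A ggplot histogram with dashed lines at 0.20 / 0.49 / 0.74.
#' @export
plot_dscore_histogram <- function(abs_d, binwidth = 0.1) {
  if (is.data.frame(abs_d)) abs_d <- abs_d$abs_d
  ggplot(tibble(abs_d = abs_d), aes(x = .data$abs_d)) +
    geom_histogram(binwidth = binwidth, boundary = 0,
                   fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = c(0.20, 0.49, 0.74), linetype = "dashed") +
    labs(x = "|D|", y = "subjects",
         title = "Distribution of absolute IAT D-scores") +
    theme_minimal()
}

#' Scatterplot of ROI current density against behavior
#'
#' Shows the partial relationship: both axes are residualized on the
#' covariates before plotting, with a least-squares line and its 95%
#' confidence band.
#'
#' @param roi_means Per-subject ROI mean (log relative current density).
#' @param behavior Per-subject absolute D-scores.
#' @param covariates Optional covariates (e.g. total sleep time).
#' @return A ggplot object.
#' @export
plot_roi_scatter <- function(roi_means, behavior, covariates = NULL) {
  n <- length(roi_means)
  X <- covariate_matrix(covariates, n)
  df <- tibble(
    roi = stats::lm.fit(X, roi_means)$residuals,
    behavior = stats::lm.fit(X, behavior)$residuals
  )
  ggplot(df, aes(x = .data$roi, y = .data$behavior)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, colour = "#2166ac") +
    labs(x = "ROI log10 relative SWA current density (residualized)",
         y = "absolute IAT D-score (residualized)",
         title = "ROI brain-behavior association") +
    theme_minimal()
}

#' Per-cycle correlation plot
#'
#' @param per_cycle Tibble from [per_cycle_analysis()].
#' @return A ggplot bar chart of r per sleep cycle.
#' @export
plot_cycle_correlations <- function(per_cycle) {
  ggplot(per_cycle, aes(x = .data$cycle, y = .data$r)) +
    geom_col(fill = "grey70", colour = "grey30") +
    geom_hline(yintercept = 0) +
    labs(x = "sleep cycle", y = "partial r",
         title = "ROI brain-behavior correlation per sleep cycle") +
    theme_minimal()
}
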