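# Minimal figure helpers (ggplot2, Suggests). Publication styling is out of
# scope; these are quick-look plots of the core outputs.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plotting requires the ggplot2 package")
}

#' Heatmap of a wavelet power spectrum
#'
#' Displays the 0--1 normalized power matrix on a log2 period axis; cells
#' with p > 0.05 (if [significance()] was run) are dimmed.
#'
#' @param spectrum a [cwt()] result.
#' @param max_cells downsample the time axis to at most this many columns.
#' @return A ggplot object.
#' @export
plot_wavelet_spectrum <- function(spectrum, max_cells = 2000) {
  need_ggplot()
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  disp <- global_and_normalized(spectrum)$display_power
  nt <- ncol(disp)
  keep <- unique(round(seq(1, nt, length.out = min(nt, max_cells))))
  df <- expand.grid(time = keep, period = spectrum$periods)
  df$power <- as.vector(t(disp[, keep, drop = FALSE]))
  if (!is.null(spectrum$pvalues))
    df$power <- df$power * ifelse(as.vector(t(spectrum$pvalues[, keep])) <= 0.05, 1, 0.35)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$period,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_gradientn(colours = c("#2166ac", "#f7f7f7", "#b2182b")) +
    ggplot2::labs(x = "timestep", y = "period (h)", fill = "power (0-1)")
}

#' Lunar-bin means with confidence ribbons
#'
#' One panel per variable: 12 bin means with 95% CI ribbons, principal
#' phases marked, and the last-quartile window (third quarter to new moon)
#' delimited by dashed lines.
#'
#' @param summary a [phase_means()] result.
#' @return A ggplot object.
#' @export
plot_phase_summary <- function(summary) {
  need_ggplot()
  stopifnot(inherits(summary, "phase_summary"))
  df <- do.call(rbind, lapply(names(summary$bins), function(v)
    cbind(variable = v, summary$bins[[v]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(9.5, 12.5), linetype = "dashed") +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_continuous(breaks = c(1, 3.5, 6.5, 9.5, 12),
                                labels = c("NM", "1Q", "FM", "3Q", "NM")) +
    ggplot2::labs(x = "lunar-cycle interval", y = "mean",
                  title = summary$species)
}
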