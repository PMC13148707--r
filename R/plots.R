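#' Plot the modes of a decomposition
#'
#' Stacked time-series panels: each IMF, the residual and the filtered-out
#' content.
#'
#' @param object an `ebmd_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ebmd_result <- function(object, ...) {
  df <- tidy.ebmd_result(object)
  df$series <- factor(df$series, levels = unique(df$series))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, title = "EBMD modes")
}

#' @export
plot.ebmd_result <- function(x, ...) print(autoplot.ebmd_result(x, ...))

#' Plot the segmented spectrum of a decomposition
#'
#' The spectrum used for pre-segmentation (Blaschke spectrum over orders or
#' Fourier magnitude over bins) with its trend and segment boundaries.
#'
#' @param result an `ebmd_result`.
#' @return a ggplot object.
#' @export
plot_blaschke_spectrum <- function(result) {
  stopifnot(inherits(result, "ebmd_result"))
  spec <- result$diagnostics$spectrum
  trend <- result$diagnostics$trend
  segs <- result$diagnostics$segments
  df <- data.frame(index = seq_along(spec), spectrum = spec,
                   trend = if (!is.null(trend)) trend$values else NA_real_)
  xlab <- if (identical(result$diagnostics$spectrum_axis, "fourier"))
    "frequency bin" else "Blaschke order"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$spectrum), fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "firebrick") +
    ggplot2::labs(x = xlab, y = "mean component energy",
                  title = "Segmented spectrum")
  if (!is.null(segs) && nrow(segs))
    p <- p + ggplot2::geom_vline(xintercept = c(segs$a - 0.5, segs$b + 0.5),
                                 linetype = "dashed", colour = "steelblue")
  p
}

#' Plot envelope spectra of the IMFs
#'
#' One panel per IMF showing the envelope spectrum with the dominant pulse
#' frequency marked; the signature on which fusion decisions are based.
#'
#' @param result an `ebmd_result`.
#' @param fmax optional upper frequency limit in Hz.
#' @return a ggplot object.
#' @export
plot_envelope_spectra <- function(result, fmax = NULL) {
  stopifnot(inherits(result, "ebmd_result"))
  if (!length(result$imfs)) stop("no IMFs to plot")
  dfs <- lapply(seq_along(result$imfs), function(i) {
    sig <- result$imfs[[i]]$signature
    data.frame(imf = paste0("IMF", i),
               freq = (seq_along(sig$env_spectrum) - 1) * sig$bin_hz,
               amp = sig$env_spectrum,
               dom = sig$dominant_freq)
  })
  df <- do.call(rbind, dfs)
  if (!is.null(fmax)) df <- df[df$freq <= fmax, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$amp)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$dom),
                        linetype = "dotted", colour = "firebrick") +
    ggplot2::facet_wrap(~imf, scales = "free_y") +
    ggplot2::labs(x = "envelope frequency [Hz]", y = "amplitude",
                  title = "IMF envelope spectra")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
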