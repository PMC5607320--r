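#' Plot a simulated pulling trace
#'
#' Force versus cantilever displacement, with detected unfolding events
#' marked and annotated by the number of residues unfolded at each drop.
#'
#' @param object A `sim_trace` from [run_pulling()].
#' @param events Optional event table from [detect_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$displacement_A, .data$force)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "cantilever displacement (Å)",
                  y = "spring force (ε/Å)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p +
      ggplot2::geom_point(data = events, colour = "firebrick", size = 1.6) +
      ggplot2::geom_text(data = events,
                         ggplot2::aes(label = .data$n_unfolded),
                         vjust = -0.8, size = 3)
  }
  p
}

#' Plot force-distance curves
#'
#' @param curves Long tibble (curve_id, tss_nm, force_pN).
#' @param alpha Line transparency.
#' @return A ggplot object (curves superposed).
#' @export
plot_fd_curves <- function(curves, alpha = 0.25) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$tss_nm, .data$force_pN,
                                       group = .data$curve_id)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(x = "tip-sample separation (nm)", y = "force (pN)") +
    ggplot2::theme_minimal()
}

#' Plot an F-Lc histogram
#'
#' @param object An `flc_histogram` from [fd_to_flc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flc_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$lc_mid, .data$mass)) +
    ggplot2::geom_col(width = diff(attr(object, "edges"))[1]) +
    ggplot2::labs(x = "contour length Lc (nm)", y = "force mass") +
    ggplot2::theme_minimal()
}

#' Plot a cluster report
#'
#' Peak-group positions with occurrence probabilities, one panel per
#' cluster.
#'
#' @param object A `cluster_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_report <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$lc_mean_nm, .data$occurrence)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lc_mean_nm, yend = 0),
                          linewidth = 1) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lc_mean_nm - .data$lc_sd_nm,
                   xmax = .data$lc_mean_nm + .data$lc_sd_nm,
                   y = .data$occurrence), height = 0.03) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "contour length Lc (nm)",
                  y = "occurrence probability") +
    ggplot2::ylim(0, 1.05) +
    ggplot2::theme_minimal()
}

#' Plot a melting scan
#'
#' Mean folded fraction versus temperature with the interpolated unfolding
#' temperature marked.
#'
#' @param object A `melting_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.melting_scan <- function(object, ...) {
  prof <- attr(object, "profile")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$k_bt, .data$q)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = prof) +
    ggplot2::geom_vline(xintercept = attr(object, "t_unfold"),
                        linetype = 2, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "thermal energy kBT (ε)",
                  y = "native-contact fraction Q") +
    ggplot2::theme_minimal()
}
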