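#' Tidy a cluster report
#'
#' @param x A `cluster_report` from [peak_statistics()].
#' @param ... Unused.
#' @return A plain tibble of per-peak-group statistics.
#' @export
tidy.cluster_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Per-cluster summary of a cluster report
#'
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @return Tibble (cluster, n_members, fraction, n_peaks, last_lc_nm).
#' @export
glance.cluster_report <- function(x, ...) {
  sizes <- attr(x, "cluster_sizes")
  frac <- attr(x, "cluster_fraction")
  tibble::as_tibble(unclass(x)) |>
    dplyr::summarise(n_peaks = dplyr::n(),
                     last_lc_nm = max(.data$lc_mean_nm),
                     .by = "cluster") |>
    dplyr::left_join(sizes, by = "cluster") |>
    dplyr::mutate(fraction = unname(frac[as.character(.data$cluster)])) |>
    dplyr::select("cluster", "n_members", "fraction", "n_peaks",
                  "last_lc_nm") |>
    dplyr::arrange(dplyr::desc(.data$n_members))
}

#' Tidy an fd_analysis result
#'
#' @param x An `fd_analysis` from [analyze_curves()].
#' @param ... Unused.
#' @return The per-peak-group statistics tibble.
#' @export
tidy.fd_analysis <- function(x, ...) tidy(x$report)

#' Dataset-level summary of an fd_analysis result
#'
#' @param x An `fd_analysis`.
#' @param ... Unused.
#' @return One-row tibble (n_input, n_filtered, n_clusters).
#' @export
glance.fd_analysis <- function(x, ...) {
  tibble::tibble(n_input = x$n_input, n_filtered = x$n_filtered,
                 n_clusters = dplyr::n_distinct(x$membership$cluster))
}

#' Tidy a melting scan
#'
#' @param x A `melting_scan`.
#' @param ... Unused.
#' @return Tibble of per-temperature mean folded fractions.
#' @export
tidy.melting_scan <- function(x, ...) attr(x, "profile")

#' Unfolding temperature from a melting scan
#'
#' @param x A `melting_scan`.
#' @param ... Unused.
#' @return One-row tibble (t_unfold, n_temperatures, replicas).
#' @export
glance.melting_scan <- function(x, ...) {
  tibble::tibble(t_unfold = attr(x, "t_unfold"),
                 n_temperatures = dplyr::n_distinct(x$k_bt),
                 replicas = max(x$replicate))
}
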