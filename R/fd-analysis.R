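#' Read force-distance curves from two-column text files
#'
#' Accepts a directory or a vector of file paths; each file holds one curve
#' as two numeric columns (tip-sample separation, force), TSV or CSV, with an
#' optional header. Units are normalised to nm / pN through the dialect.
#' Malformed or empty files are skipped with a warning and the batch
#' continues.
#'
#' @param paths Directory or character vector of files.
#' @param dialect List: `sep` (`"\t"` default, `","` for CSV),
#'   `distance_unit` (`"nm"`, `"um"`), `force_unit` (`"pN"`, `"nN"`).
#' @return Long tibble (curve_id, tss_nm, force_pN).
#' @export
read_fd_curves <- function(paths, dialect = list()) {
  sep <- dialect$sep %||% "\t"
  dunit <- dialect$distance_unit %||% "nm"
  funit <- dialect$force_unit %||% "pN"
  dfac <- switch(dunit, nm = 1, um = 1e3,
                 stop("unknown distance unit ", dunit))
  ffac <- switch(funit, pN = 1, nN = 1e3, stop("unknown force unit ", funit))
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, full.names = TRUE)
  read_one <- function(p) {
    raw <- tryCatch(
      utils::read.table(p, sep = sep, header = FALSE, comment.char = "#",
                        colClasses = "character"),
      error = function(e) NULL)
    if (is.null(raw) || nrow(raw) == 0 || ncol(raw) < 2) {
      warning("skipping ", basename(p), ": not a two-column numeric table")
      return(NULL)
    }
    x <- suppressWarnings(as.numeric(raw[[1]]))
    f <- suppressWarnings(as.numeric(raw[[2]]))
    if (is.na(x[1]) && is.na(f[1])) { x <- x[-1]; f <- f[-1] }  # header row
    ok <- !is.na(x) & !is.na(f)
    if (!all(ok)) warning(sum(!ok), " non-numeric row(s) dropped in ",
                          basename(p))
    if (sum(ok) == 0) {
      warning("skipping ", basename(p), ": no numeric rows")
      return(NULL)
    }
    tibble::tibble(curve_id = sub("\\.[^.]*$", "", basename(p)),
                   tss_nm = x[ok] * dfac, force_pN = f[ok] * ffac)
  }
  out <- purrr::compact(lapply(paths, read_one))
  if (length(out) == 0) return(tibble::tibble(curve_id = character(),
                                              tss_nm = numeric(),
                                              force_pN = numeric()))
  dplyr::bind_rows(out)
}

#' Detect and fit rupture peaks in one force-distance curve
#'
#' The curve is denoised with a Savitzky-Golay filter, sawtooth peaks are
#' located as running maxima terminated by a force drop exceeding both an
#' absolute and a fractional threshold, and the rising edge before each peak
#' is least-squares fitted with the worm-like chain to estimate its contour
#' length. The peak force is the maximum measured force before the drop.
#'
#' @param trace Data frame (tss_nm, force_pN), one curve.
#' @param wlc [wlc_params()].
#' @param min_force Minimum peak force retained, pN.
#' @param smooth_window Savitzky-Golay window length (odd).
#' @param drop_frac,drop_abs Drop thresholds ending a peak (fraction of the
#'   peak height; absolute pN).
#' @param noise_floor Points below this force are excluded from WLC fits, pN.
#' @param merge_tol Detections within the same curve closer than this in `Lc`
#'   (nm) are collapsed to the strongest one.
#' @return Tibble (lc_nm, force_pN, x_peak_nm), one row per retained peak.
#' @export
detect_fd_peaks <- function(trace, wlc = wlc_params(), min_force = 35,
                            smooth_window = 7, drop_frac = 0.3,
                            drop_abs = 20, noise_floor = 10,
                            merge_tol = 5) {
  empty <- tibble::tibble(lc_nm = numeric(), force_pN = numeric(),
                          x_peak_nm = numeric())
  if (nrow(trace) < smooth_window + 2) return(empty)
  ord <- order(trace$tss_nm)
  x <- trace$tss_nm[ord]; f <- trace$force_pN[ord]
  fs <- signal::sgolayfilt(f, p = 3, n = smooth_window)
  idx <- find_force_peaks(fs, drop_frac, drop_abs, min_peak = min_force)
  if (length(idx) == 0) return(empty)
  starts <- c(1L, utils::head(idx, -1) + 1L)
  fit_one <- function(i0, ip) {
    seg <- seq(i0, ip)
    seg <- seg[f[seg] > noise_floor & x[seg] > 0]
    if (length(seg) < 3) return(NULL)
    xp <- x[ip]
    sse <- function(lc) sum((f[seg] - wlc_force(pmin(x[seg], lc * 0.999),
                                                lc, wlc))^2)
    fit <- stats::optimize(sse, c(xp + 1e-3, max(xp * 10, 1000)))
    # rupture force read off the denoised trace at the peak
    tibble::tibble(lc_nm = fit$minimum, force_pN = max(fs[seq(i0, ip)]),
                   x_peak_nm = xp)
  }
  out <- purrr::compact(purrr::map2(starts, idx, fit_one))
  if (length(out) == 0) return(empty)
  res <- dplyr::bind_rows(out)
  res <- res[res$force_pN >= min_force, ]
  # collapse residual double-detections of one rupture
  if (nrow(res) > 1) {
    res <- res[order(res$lc_nm), ]
    grp <- cumsum(c(1, diff(res$lc_nm) > merge_tol))
    res <- res |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::slice_max(.data$force_pN, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-".grp")
  }
  res
}

detect_all_peaks <- function(curves, wlc, ...) {
  curves |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(d, g) detect_fd_peaks(d, wlc = wlc, ...)) |>
    dplyr::ungroup()
}

#' Filter curves on peak force and final contour length
#'
#' Keeps curves whose retained peaks all exceed the force threshold and whose
#' final (detachment) peak falls inside the accepted contour-length window.
#'
#' @param peaks Peak table from [detect_fd_peaks()] with a `curve_id` column.
#' @param min_force Minimum force required of every retained peak, pN.
#' @param last_lc_range Accepted window for the final peak's `Lc`, nm.
#' @param all_peaks If `FALSE`, only the smallest retained peak must clear
#'   the force threshold.
#' @return Character vector of curve ids passing the filter.
#' @export
filter_curves <- function(peaks, min_force = 35, last_lc_range = c(0, 200),
                          all_peaks = TRUE) {
  if (nrow(peaks) == 0) return(character())
  peaks |>
    dplyr::summarise(
      force_ok = if (all_peaks) all(.data$force_pN >= min_force) else
        min(.data$force_pN) >= min_force,
      last_lc = .data$lc_nm[which.max(.data$lc_nm)],
      .by = "curve_id") |>
    dplyr::filter(.data$force_ok,
                  .data$last_lc >= last_lc_range[1],
                  .data$last_lc <= last_lc_range[2]) |>
    dplyr::pull("curve_id")
}

#' Cluster curves by shifted overlap of their F-Lc histograms
#'
#' Pairwise similarity is the maximum overlap (sum of bin-wise minima of the
#' unit-normalised histograms) over integer bin shifts within
#' `max_shift_nm`; curves are grouped by average-linkage hierarchical
#' clustering cut at `1 - sim_threshold`. Each member also receives its best
#' alignment shift against the cluster reference (the member with the
#' highest mean within-cluster similarity), so downstream statistics can
#' compensate unspecific attachment offsets.
#'
#' @param curves Long tibble (curve_id, tss_nm, force_pN).
#' @param wlc [wlc_params()].
#' @param bin_width,lc_range,min_force Histogram construction, see
#'   [fd_to_flc()].
#' @param max_shift_nm Maximum allowed alignment shift, nm.
#' @param sim_threshold Minimum similarity for cluster membership.
#' @return Tibble (curve_id, cluster, shift_nm) with the histogram matrix and
#'   similarity matrix in attributes.
#' @export
cluster_curves <- function(curves, wlc = wlc_params(), bin_width = 3,
                           lc_range = c(0, 320), min_force = 10,
                           max_shift_nm = 5, sim_threshold = 0.4) {
  ids <- unique(curves$curve_id)
  if (length(ids) < 2) stop("need at least two curves to cluster")
  hists <- lapply(ids, function(id)
    fd_to_flc(curves[curves$curve_id == id, ], wlc, bin_width, lc_range,
              min_force)$mass)
  h <- do.call(rbind, hists)
  rownames(h) <- ids
  if (all(rowSums(h) == 0)) stop("all F-Lc histograms are empty")
  max_shift <- max(0L, as.integer(floor(max_shift_nm / bin_width)))
  sim <- cpp_shift_overlap(h, max_shift)
  d <- stats::as.dist(1 - sim)
  cl <- stats::cutree(stats::hclust(d, method = "average"),
                      h = 1 - sim_threshold)
  shift_nm <- numeric(length(ids))
  for (k in unique(cl)) {
    members <- which(cl == k)
    if (length(members) == 1) { shift_nm[members] <- 0; next }
    ref <- members[which.max(rowMeans(sim[members, members, drop = FALSE]))]
    for (m in members) {
      s <- cpp_best_shift(h[ref, ], h[m, ], max_shift)
      # member bin j+s aligns with reference bin j: correct by -s bins
      shift_nm[m] <- -s * bin_width
    }
    # attachment offsets average to zero over a cluster; re-centre so the
    # reference curve's own offset does not bias the aligned positions
    shift_nm[members] <- shift_nm[members] - mean(shift_nm[members])
  }
  structure(tibble::tibble(curve_id = ids, cluster = unname(cl),
                           shift_nm = shift_nm),
            histograms = h, similarity = sim, bin_width = bin_width)
}

# group pooled Lc values by the modes of their histogram: local maxima of a
# lightly smoothed count histogram; adjacent modes are treated as one peak
# group unless they are at least tol apart AND separated by a valley dipping
# below depth_frac of the smaller mode (a lumpy single cloud has shallow
# dips; genuinely distinct peaks have deep ones)
group_peak_positions <- function(lc, tol = 6, bw = NULL, depth_frac = 0.6) {
  if (length(lc) == 1) return(1L)
  if (is.null(bw)) bw <- tol / 3
  breaks <- seq(min(lc) - bw, max(lc) + bw, by = bw)
  breaks <- c(breaks, max(breaks) + bw)
  cnt <- tabulate(findInterval(lc, breaks), nbins = length(breaks) - 1)
  s <- as.numeric(stats::filter(c(0, cnt, 0), rep(1 / 3, 3), sides = 2))
  s <- s[2:(length(cnt) + 1)]
  pad <- c(-1, s, -1)
  modes <- which(diff(sign(diff(pad))) < 0 & s > 0)
  if (length(modes) <= 1) return(rep(1L, length(lc)))
  mids <- function(m) breaks[m] + bw / 2
  repeat {
    if (length(modes) == 1) break
    merged <- FALSE
    for (k in seq_len(length(modes) - 1)) {
      span <- modes[k]:modes[k + 1]
      valley <- min(s[span])
      low <- min(s[modes[k]], s[modes[k + 1]])
      if (mids(modes[k + 1]) - mids(modes[k]) < tol ||
          valley > depth_frac * low) {
        drop <- if (s[modes[k]] <= s[modes[k + 1]]) k else k + 1
        modes <- modes[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  if (length(modes) == 1) return(rep(1L, length(lc)))
  cutpos <- vapply(seq_len(length(modes) - 1), function(k) {
    span <- modes[k]:modes[k + 1]
    breaks[span[which.min(s[span])]] + bw / 2
  }, numeric(1))
  findInterval(lc, cutpos) + 1L
}

#' Per-cluster peak statistics
#'
#' Pools the (alignment-corrected) peak contour lengths of each cluster's
#' members, partitions them into peak groups at the valleys between the modes
#' of their histogram (modes closer than `tol` are merged), and reports per
#' group the mean and SD of `Lc` (nm and residues), the occurrence
#' probability (fraction of member curves showing the peak) and the
#' rupture-force statistics.
#'
#' @param peaks Peak table (curve_id, lc_nm, force_pN).
#' @param membership Tibble from [cluster_curves()].
#' @param wlc [wlc_params()] (for the residue conversion).
#' @param tol Grouping tolerance on `Lc`, nm.
#' @param min_occurrence Peak groups observed in a smaller fraction of the
#'   cluster are dropped as unreproducible.
#' @return A `cluster_report` tibble (cluster, peak, lc_mean_nm, lc_sd_nm,
#'   lc_mean_aa, occurrence, force_mean_pN, force_sd_pN, n_curves) with
#'   cluster sizes and occurrence fractions in attributes.
#' @export
peak_statistics <- function(peaks, membership, wlc = wlc_params(), tol = 6,
                            min_occurrence = 0.1) {
  dat <- dplyr::inner_join(peaks, membership, by = "curve_id")
  dat$lc_aligned <- dat$lc_nm + dat$shift_nm
  sizes <- dplyr::count(membership, .data$cluster, name = "n_members")
  one_cluster <- function(d, size) {
    d <- d[order(d$lc_aligned), ]
    d |>
      dplyr::mutate(peak = group_peak_positions(.data$lc_aligned, tol)) |>
      dplyr::summarise(
        lc_mean_nm = mean(.data$lc_aligned),
        lc_sd_nm = stats::sd(.data$lc_aligned),
        force_mean_pN = mean(.data$force_pN),
        force_sd_pN = stats::sd(.data$force_pN),
        n_curves = dplyr::n_distinct(.data$curve_id),
        .by = "peak") |>
      dplyr::mutate(occurrence = .data$n_curves / size,
                    lc_mean_aa = lc_to_aa(.data$lc_mean_nm, wlc)) |>
      dplyr::filter(.data$occurrence >= min_occurrence) |>
      dplyr::arrange(.data$lc_mean_nm) |>
      dplyr::mutate(peak = dplyr::row_number())
  }
  rep <- dat |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(d, key)
      one_cluster(d, sizes$n_members[sizes$cluster == key$cluster])) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", "peak", "lc_mean_nm", "lc_sd_nm", "lc_mean_aa",
                  "occurrence", "force_mean_pN", "force_sd_pN", "n_curves")
  structure(tibble::new_tibble(rep, class = "cluster_report"),
            cluster_sizes = sizes,
            cluster_fraction = stats::setNames(
              sizes$n_members / sum(sizes$n_members), sizes$cluster))
}

#' Full force-spectroscopy analysis pipeline
#'
#' Chains peak detection, curve filtering, F-Lc histogram construction,
#' shift-tolerant clustering and per-cluster peak statistics.
#'
#' @param curves Long tibble (curve_id, tss_nm, force_pN).
#' @param wlc [wlc_params()].
#' @param bin_width Histogram bin width for reporting, nm.
#' @param cluster_bin_width Bin width used for the clustering similarity;
#'   defaults to `max(bin_width, 3)` (fine reporting bins make histogram
#'   overlap too sparse to cluster on).
#' @param lc_range Histogram range, nm.
#' @param min_peak_force Force threshold for retained peaks, pN.
#' @param last_lc_range Accepted window for the final peak, nm.
#' @param sim_threshold,max_shift_nm Clustering controls
#'   ([cluster_curves()]).
#' @param group_tol Peak-grouping tolerance, nm ([peak_statistics()]).
#' @param ... Further arguments passed to [detect_fd_peaks()].
#' @return An `fd_analysis` list: `report` ([peak_statistics()] result),
#'   `membership`, `peaks`, `n_input`, `n_filtered`.
#' @export
analyze_curves <- function(curves, wlc = wlc_params(), bin_width = 3,
                           cluster_bin_width = NULL,
                           lc_range = c(0, 320), min_peak_force = 35,
                           last_lc_range = c(0, 200), sim_threshold = 0.4,
                           max_shift_nm = 5, group_tol = 6, ...) {
  if (is.null(cluster_bin_width)) cluster_bin_width <- max(bin_width, 3)
  peaks <- detect_all_peaks(curves, wlc, min_force = min_peak_force, ...)
  keep <- filter_curves(peaks, min_peak_force, last_lc_range)
  if (length(keep) < 2)
    stop("fewer than two curves survive filtering")
  filtered <- curves[curves$curve_id %in% keep, ]
  membership <- cluster_curves(filtered, wlc, cluster_bin_width, lc_range,
                               max_shift_nm = max_shift_nm,
                               sim_threshold = sim_threshold)
  report <- peak_statistics(peaks[peaks$curve_id %in% keep, ], membership,
                            wlc, tol = group_tol)
  structure(list(report = report, membership = membership, peaks = peaks,
                 n_input = dplyr::n_distinct(curves$curve_id),
                 n_filtered = length(keep)),
            class = "fd_analysis")
}

#' @export
print.fd_analysis <- function(x, ...) {
  cat("fd_analysis:", x$n_filtered, "of", x$n_input,
      "curves pass filtering;",
      dplyr::n_distinct(x$membership$cluster), "cluster(s)\n")
  print(x$report)
  invisible(x)
}
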