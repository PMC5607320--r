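kbt_pn_nm <- function(temperature_k) 0.0138065 * temperature_k

#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation,
#' `F = (kB T / p) * (1/(4 (1 - x/Lc)^2) - 1/4 + x/Lc)`.
#'
#' @param x Extension, nm (vectorised).
#' @param lc Contour length, nm.
#' @param wlc [wlc_params()].
#' @return Force, pN. Errors when any `x >= lc` (the model diverges).
#' @export
wlc_force <- function(x, lc, wlc = wlc_params()) {
  if (any(x >= lc)) stop("extension must be smaller than the contour length")
  if (any(x < 0)) stop("extension must be non-negative")
  t <- x / lc
  (kbt_pn_nm(wlc$temperature_k) / wlc$p_nm) * (0.25 / (1 - t)^2 - 0.25 + t)
}

#' Invert the worm-like chain point by point
#'
#' For each (extension, force) sample, finds the unique contour length `Lc`
#' at which the Marko-Siggia force at that extension equals the measured
#' force. Solved as the single root in (0, 1) of the cubic in `u = 1 - x/Lc`
#' by vectorised bisection.
#'
#' @param x Extension, nm (vectorised).
#' @param f Force, pN (positive).
#' @param wlc [wlc_params()].
#' @return Contour length, nm (NA where `f <= 0` or `x <= 0`).
#' @export
wlc_contour_length <- function(x, f, wlc = wlc_params()) {
  A <- kbt_pn_nm(wlc$temperature_k) / wlc$p_nm
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(f) & x > 0 & f > 0
  if (!any(ok)) return(out)
  b <- f[ok] / A - 0.75
  g <- function(u) u^3 + b * u^2 - 0.25   # root in (0,1): g(0)<0, g(1)=f/A>0
  lo <- rep(1e-12, sum(ok)); hi <- rep(1 - 1e-12, sum(ok))
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  u <- (lo + hi) / 2
  out[ok] <- x[ok] / (1 - u)
  out
}

#' Convert contour length to residues
#'
#' Divides `Lc` by the per-residue contour length of a stretched peptide
#' chain (0.4 nm by default; 0.36 nm matches the printed rhodopsin
#' conversions).
#'
#' @param lc_nm Contour length, nm.
#' @param wlc [wlc_params()] supplying `residue_nm`.
#' @param round Round to the nearest integer for display.
#' @return Residue count (raw value unless `round = TRUE`).
#' @export
lc_to_aa <- function(lc_nm, wlc = wlc_params(), round = FALSE) {
  stopifnot(all(lc_nm >= 0))
  aa <- lc_nm / wlc$residue_nm
  if (round) round(aa) else aa
}

#' Convert residues to contour length
#'
#' @param aa Residue count.
#' @param wlc [wlc_params()].
#' @return Contour length, nm.
#' @export
aa_to_lc <- function(aa, wlc = wlc_params()) aa * wlc$residue_nm

#' Transform a force-distance curve to a force-weighted contour-length
#' histogram
#'
#' Each sample above the noise floor is inverted through the worm-like chain
#' ([wlc_contour_length()]) and its force deposited in the bin containing the
#' resulting `Lc`.
#'
#' @param trace Data frame with columns `tss_nm`, `force_pN` (one curve).
#' @param wlc [wlc_params()].
#' @param bin_width Bin width, nm.
#' @param lc_range Histogram range, nm.
#' @param min_force Noise floor, pN; points below are skipped.
#' @param normalize Divide the bin masses by their sum.
#' @return A `flc_histogram` tibble (lc_mid, mass) with the bin edges and the
#'   number of skipped points in attributes.
#' @export
fd_to_flc <- function(trace, wlc = wlc_params(), bin_width = 3,
                      lc_range = c(0, 320), min_force = 10,
                      normalize = FALSE) {
  edges <- seq(lc_range[1], lc_range[2], by = bin_width)
  mids <- utils::head(edges, -1) + bin_width / 2
  keep <- trace$force_pN > min_force & trace$tss_nm > 0
  lc <- wlc_contour_length(trace$tss_nm[keep], trace$force_pN[keep], wlc)
  inside <- !is.na(lc) & lc >= lc_range[1] & lc < lc_range[2]
  bin <- findInterval(lc[inside], edges, rightmost.closed = TRUE)
  mass <- as.numeric(tapply(trace$force_pN[keep][inside], factor(bin,
          levels = seq_along(mids)), sum))
  mass[is.na(mass)] <- 0
  if (normalize && sum(mass) > 0) mass <- mass / sum(mass)
  structure(tibble::new_tibble(tibble::tibble(lc_mid = mids, mass = mass),
                               class = "flc_histogram"),
            edges = edges, normalized = normalize,
            n_skipped = sum(!keep) + sum(keep) - sum(inside))
}
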