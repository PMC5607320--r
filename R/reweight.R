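#' Principal axis of a helix
#'
#' First principal direction of the C-alpha point cloud, oriented from the
#' N- to the C-terminal end.
#'
#' @param coords Numeric matrix (>= 4 rows) of C-alpha positions.
#' @return Unit 3-vector.
#' @export
helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("need at least 4 C-alpha positions")
  cc <- scale(coords, scale = FALSE)
  sv <- svd(cc)
  if (sv$d[1] < 1e-9 || sv$d[1] / max(sv$d[2], 1e-12) < 1 + 1e-9)
    stop("degenerate point cloud: no unique principal axis")
  ax <- sv$v[, 1]
  if (sum(ax * (coords[nrow(coords), ] - coords[1, ])) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Angle between two helix axes
#'
#' @param axis1,axis2 Unit 3-vectors.
#' @return Angle in radians, in `[0, pi]`.
#' @export
helix_angle <- function(axis1, axis2) {
  acos(max(-1, min(1, sum(axis1 * axis2))))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places `n_points` quasi-uniform test points (golden-section spiral) on
#' each atom's solvent-expanded sphere (radius + probe) and counts the
#' fraction not buried inside any neighbouring expanded sphere.
#'
#' @param atoms Data frame with columns `x`, `y`, `z` and either `radius` or
#'   `elem` (radii then taken per element: C 1.88, N 1.64, O 1.46, S 1.77).
#' @param probe Probe radius, A.
#' @param n_points Test points per atom.
#' @return The input tibble with an `area` column (A^2 per atom).
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960) {
  atoms <- tibble::as_tibble(atoms)
  if (!"radius" %in% names(atoms)) {
    tab <- c(C = 1.88, N = 1.64, O = 1.46, S = 1.77, SE = 1.77)
    atoms$radius <- unname(tab[atoms$elem])
    if (anyNA(atoms$radius))
      stop("no radius for element(s): ",
           paste(unique(atoms$elem[is.na(atoms$radius)]), collapse = ", "))
  }
  n <- nrow(atoms)
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  sphere <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rexp <- atoms$radius + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * rexp[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij2 <- sum((xyz[i, ] - xyz[j, ])^2)
      if (dij2 >= (rexp[i] + rexp[j])^2) next
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > rexp[j]^2
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * rexp[i]^2 * mean(exposed)
  }
  atoms$area <- area
  atoms
}

#' Split per-residue SASA into hydrophobic and hydrophilic transmembrane
#' contributions
#'
#' @param areas Numeric per-residue accessible areas, A^2.
#' @param hydrophobic,membrane_contact Logical per-residue flags.
#' @return One-row tibble (a_hphob, a_hphil), A^2, summed over
#'   membrane-contact residues only.
#' @export
transmembrane_sasa_split <- function(areas, hydrophobic, membrane_contact) {
  tm <- membrane_contact
  tibble::tibble(a_hphob = sum(areas[tm & hydrophobic]),
                 a_hphil = sum(areas[tm & !hydrophobic]))
}

#' Cholesterol-dependent transfer coefficient model
#'
#' Maps the membrane cholesterol fraction `c` to a transfer free-energy
#' gain per unit of hydrophobic area exposed to the membrane (kB T / A^2).
#' The coefficient must vanish at `c = 0` and increase with `c`; intermediate
#' values are linearly interpolated.
#'
#' @param chol_fraction Cholesterol fractions in `[0, 1]` (must include 0).
#' @param dg_per_A2 Transfer coefficients, kB T per A^2.
#' @return A function-bearing list of class `cholesterol_model` with
#'   `coef(c)`.
#' @export
cholesterol_model <- function(chol_fraction, dg_per_A2) {
  stopifnot(length(chol_fraction) == length(dg_per_A2),
            any(chol_fraction == 0), all(chol_fraction >= 0 &
                                           chol_fraction <= 1))
  o <- order(chol_fraction)
  cf <- chol_fraction[o]; dg <- dg_per_A2[o]
  if (dg[cf == 0] != 0) stop("the coefficient must vanish at c = 0")
  if (any(diff(dg) < 0)) stop("the coefficient must be monotone in c")
  structure(list(table = tibble::tibble(chol_fraction = cf,
                                        dg_per_A2 = dg),
                 coef = function(c) stats::approx(cf, dg, xout = c,
                                                  rule = 2)$y),
            class = "cholesterol_model")
}

#' Illustrative cholesterol model
#'
#' A linear coefficient reaching 0.01 kB T/A^2 at 50% cholesterol. This is a
#' synthetic, order-of-magnitude placeholder for a membrane-partitioning
#' calibration, bundled so the reweighting machinery can be exercised; it is
#' not a literature-derived parameterisation.
#'
#' @return A `cholesterol_model`.
#' @export
illustrative_cholesterol_model <- function() {
  cholesterol_model(chol_fraction = seq(0, 0.5, by = 0.1),
                    dg_per_A2 = 0.002 * seq(0, 5))
}

#' Reweight a conformational ensemble for membrane hydrophobicity
#'
#' A more hydrophobic (cholesterol-rich) membrane favours conformations that
#' expose more hydrophobic surface to the lipids. Each frame is reweighted
#' by `w ~ exp(beta g(c) (A_HPHOB - A_ref))` with `g(c)` the transfer
#' coefficient of the cholesterol model (in kB T/A^2, so `beta = 1`); the
#' exponent is max-shifted before exponentiation and the weights are
#' normalised to unit sum.
#'
#' @param samples Tibble with columns `frame`, `alpha_rad`, `a_hphob`
#'   (`a_hphil` optional).
#' @param model A [cholesterol_model()].
#' @param c Cholesterol fraction in `[0, 1]`.
#' @param a_ref Reference area, A^2 (default: ensemble mean of `a_hphob`).
#' @return The samples with a `weight` column (sums to 1).
#' @export
reweight_ensemble <- function(samples, model = illustrative_cholesterol_model(),
                              c = 0, a_ref = NULL) {
  stopifnot(nrow(samples) > 0)
  if (is.null(a_ref)) a_ref <- mean(samples$a_hphob)
  g <- model$coef(c)
  expo <- g * (samples$a_hphob - a_ref)
  w <- exp(expo - max(expo))
  samples$weight <- w / sum(w)
  samples
}

#' Weighted distribution of the inter-helix angle
#'
#' @param samples Output of [reweight_ensemble()] (or raw samples; uniform
#'   weights assumed).
#' @param breaks Histogram breaks over `[0, pi]` (count or vector).
#' @return Tibble (alpha_mid, density).
#' @export
alpha_distribution <- function(samples, breaks = 60) {
  w <- if ("weight" %in% names(samples)) samples$weight else
    rep(1 / nrow(samples), nrow(samples))
  if (length(breaks) == 1) breaks <- seq(0, pi, length.out = breaks + 1)
  bin <- findInterval(samples$alpha_rad, breaks, rightmost.closed = TRUE)
  mids <- utils::head(breaks, -1) + diff(breaks) / 2
  dens <- as.numeric(tapply(w, factor(bin, levels = seq_along(mids)), sum))
  dens[is.na(dens)] <- 0
  tibble::tibble(alpha_mid = mids, density = dens / diff(breaks))
}

#' Relative population of the active versus inactive conformational state
#'
#' Computes `[P_c(meta)/P_c(rhod)] / [P_0(meta)/P_0(rhod)]`: the
#' metarhodopsin-II-like to rhodopsin-like population ratio under cholesterol
#' fraction `c`, normalised to the cholesterol-free ensemble (so the value at
#' `c = 0` is exactly 1).
#'
#' @param samples Ensemble tibble (frame, alpha_rad, a_hphob).
#' @param model A [cholesterol_model()].
#' @param c Cholesterol fraction (vectorised).
#' @param split List with `meta` and `rhod`, each an `alpha_rad` range
#'   `c(lo, hi)` (disjoint, within `[0, pi]`).
#' @param a_ref Optional reference area passed to [reweight_ensemble()].
#' @return Tibble (chol_fraction, ratio).
#' @export
population_ratio <- function(samples, model = illustrative_cholesterol_model(),
                             c = 0.5, split = list(meta = c(0, 2.4),
                                                   rhod = c(2.4, pi)),
                             a_ref = NULL) {
  in_range <- function(a, r) a >= r[1] & a < r[2]
  mass <- function(w, sel) sum(w[sel])
  sel_m <- in_range(samples$alpha_rad, split$meta)
  sel_r <- in_range(samples$alpha_rad, split$rhod)
  w0 <- rep(1 / nrow(samples), nrow(samples))
  m0 <- mass(w0, sel_m); r0 <- mass(w0, sel_r)
  if (m0 == 0 || r0 == 0)
    stop("both states need nonzero population at c = 0")
  ratio <- vapply(c, function(ci) {
    w <- reweight_ensemble(samples, model, ci, a_ref)$weight
    rr <- mass(w, sel_r)
    if (rr == 0) stop("inactive-state population vanished at c = ", ci)
    (mass(w, sel_m) / rr) / (m0 / r0)
  }, numeric(1))
  tibble::tibble(chol_fraction = c, ratio = ratio)
}

#' Split threshold from the valley of a bimodal angle distribution
#'
#' Locates the minimum of the (optionally weighted) angle histogram between
#' the two largest modes; falls back to an error when the distribution is
#' unimodal, in which case the split must be supplied by the user.
#'
#' @param samples Ensemble tibble.
#' @param breaks Histogram resolution.
#' @return Threshold angle, rad.
#' @export
state_split_threshold <- function(samples, breaks = 60) {
  d <- alpha_distribution(samples, breaks)
  dens <- as.numeric(stats::filter(d$density, rep(1 / 3, 3), sides = 2))
  dens[is.na(dens)] <- 0
  is_mode <- which(diff(sign(diff(c(-Inf, dens, -Inf)))) == -2)
  # substantial modes only: at least 20% of the main mode, separated by a
  # valley dipping below 60% of the smaller of the two
  is_mode <- is_mode[dens[is_mode] > 0.2 * max(dens)]
  if (length(is_mode) >= 2) {
    modes <- sort(is_mode[order(dens[is_mode],
                                decreasing = TRUE)][1:2])
    valley <- modes[1] + which.min(dens[modes[1]:modes[2]]) - 1
    if (dens[valley] < 0.6 * min(dens[modes]))
      return(d$alpha_mid[valley])
  }
  stop("angle distribution is unimodal; supply the state split explicitly")
}

#' Generate a synthetic conformational ensemble
#'
#' Emulates the post-processed output of an atomistic simulation of an
#' inactive G-protein-coupled receptor in a bilayer: the inter-helix angle
#' `alpha` is drawn from a broad truncated Gaussian on `[0, pi]`, the
#' hydrophobic transmembrane SASA is a concave function of `alpha` peaking at
#' the distribution mode (the most likely conformations expose the most
#' hydrophobic area to the membrane), and the hydrophilic SASA is
#' anti-correlated.
#'
#' @param n Number of frames.
#' @param seed Integer seed.
#' @param alpha_mode Mode of the angle distribution, rad.
#' @param alpha_sd SD of the angle distribution, rad.
#' @param a_hphob_max Hydrophobic TM SASA at the mode, A^2.
#' @param curvature Quadratic fall-off of `a_hphob` with `alpha`, A^2/rad^2.
#' @param sasa_noise Frame-to-frame SASA noise SD, A^2.
#' @return Tibble (frame, alpha_rad, a_hphob, a_hphil).
#' @export
generate_ensemble <- function(n = 10000, seed = 1L, alpha_mode = 2.72,
                              alpha_sd = 0.18, a_hphob_max = 4200,
                              curvature = 1200, sasa_noise = 40) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  a <- stats::rnorm(n, alpha_mode, alpha_sd)
  bad <- which(a < 0 | a > pi)
  while (length(bad) > 0) {
    a[bad] <- stats::rnorm(length(bad), alpha_mode, alpha_sd)
    bad <- bad[a[bad] < 0 | a[bad] > pi]
  }
  dev2 <- (a - alpha_mode)^2
  tibble::tibble(
    frame = seq_len(n),
    alpha_rad = a,
    a_hphob = a_hphob_max - curvature * dev2 + stats::rnorm(n, 0, sasa_noise),
    a_hphil = 950 + 0.75 * curvature * dev2 + stats::rnorm(n, 0, sasa_noise))
}
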