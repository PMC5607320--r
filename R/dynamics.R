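resolve_bead <- function(which, n) {
  if (is.character(which)) {
    switch(which, N = 1L, C = as.integer(n),
           stop("bead must be 'N', 'C' or an index"))
  } else {
    as.integer(which)
  }
}

run_md <- function(chain, params, integrator, n_steps, stride,
                   positions = NULL, velocities = NULL, anchor = 0L,
                   pull = NULL, stop_when_detached = FALSE) {
  pos <- chain_positions(chain, positions)
  vel <- if (is.null(velocities)) matrix(0, nrow(pos), 3) else
    as.matrix(velocities)
  cpp_run_md(pos, vel, as_cg_topology(chain), unclass(params),
             unclass(integrator), as.integer(n_steps), as.integer(stride),
             as.integer(anchor), pull, stop_when_detached)
}

#' Advance the Langevin dynamics by a number of steps
#'
#' One or more BBK velocity-Verlet updates of
#' `m r" = -gamma r' + F_c + sqrt(2 gamma kBT) xi` with Gaussian noise `xi`.
#' With `gamma = 0` and `k_bt = 0` this reduces to plain (NVE) velocity
#' Verlet.
#'
#' @param chain An annotated `bead_chain` supplying the topology.
#' @param params [ff_params()].
#' @param integrator [integrator_params()].
#' @param n_steps Number of timesteps.
#' @param positions,velocities Optional starting state (default: native
#'   coordinates at rest).
#' @param anchored Bead held fixed (`0` = none, `"N"`, `"C"` or an index).
#' @return List with `positions`, `velocities` (N x 3 matrices) and `trace`
#'   (kinetic energy, native-contact fraction `q`, energy terms at the start
#'   and end of the run).
#' @export
langevin_step <- function(chain, params = ff_params(),
                          integrator = integrator_params(), n_steps = 1,
                          positions = NULL, velocities = NULL, anchored = 0) {
  anchor <- if (identical(anchored, 0)) 0L else
    resolve_bead(anchored, nrow(chain))
  res <- run_md(chain, params, integrator, n_steps, stride = max(n_steps, 1),
                positions = positions, velocities = velocities,
                anchor = anchor)
  list(positions = res$positions, velocities = res$velocities,
       trace = tibble::as_tibble(res$trace))
}

#' Equilibrate a chain at the working temperature
#'
#' Unrestrained Langevin dynamics from the native configuration. Returns the
#' final state together with the fraction of intact native contacts `q`
#' (a contact counts as intact while `r_ij < 1.5 sigma_ij`); a warning is
#' raised if the chain has lost more than half of its contacts, which
#' indicates an inconsistency between the model and the chosen temperature.
#'
#' @inheritParams langevin_step
#' @param n_steps Equilibration length, steps.
#' @param stride Recording stride for the returned trace.
#' @return List of class `cg_state`: `positions`, `velocities`, `q`, `trace`.
#' @export
equilibrate <- function(chain, params = ff_params(),
                        integrator = integrator_params(), n_steps = 2e5,
                        stride = 1000) {
  res <- run_md(chain, params, integrator, n_steps, stride)
  tr <- tibble::as_tibble(res$trace)
  q <- tr$q[nrow(tr)]
  if (!is.na(q) && q < 0.5)
    warning(sprintf(
      "q = %.2f after equilibration: the chain unfolded at k_bt = %g",
      q, integrator$k_bt))
  structure(list(positions = res$positions, velocities = res$velocities,
                 q = q, trace = tr), class = "cg_state")
}

#' Constant-velocity pulling simulation
#'
#' Attaches a harmonic spring to the pulled bead, holds the anchored bead
#' fixed, moves the outer spring end along +z at `v_pull` and records the
#' spring force, the cantilever displacement, the pulled-bead extension, the
#' native-contact fraction and the number of residues unfolded from the
#' pulled terminus (a residue counts as unfolded when all of its native
#' contacts are broken and it belongs to the contiguous unfolded stretch
#' ending at the pulled terminus). The run stops early once every native
#' contact is broken (full detachment).
#'
#' @inheritParams langevin_step
#' @param protocol [pulling_protocol()].
#' @param state Optional `cg_state` from [equilibrate()]; default starts from
#'   the native configuration at rest.
#' @param n_steps Maximum number of steps; default covers
#'   `max_displacement` (or the fully stretched chain) at `v_pull`.
#' @param stop_when_detached End the run as soon as (almost) all native
#'   contacts are broken.
#' @return A `sim_trace` tibble (step, time_fs, displacement_A, extension_A,
#'   force in eps/A, kinetic, q, n_unfolded, energy terms) with the protocol
#'   echoed in attributes.
#' @export
run_pulling <- function(chain, params = ff_params(),
                        integrator = integrator_params(),
                        protocol = pulling_protocol(), state = NULL,
                        n_steps = NULL, stop_when_detached = TRUE) {
  n <- nrow(chain)
  pulled <- resolve_bead(protocol$pulled, n)
  anchored <- resolve_bead(protocol$anchored, n)
  if (is.null(n_steps)) {
    max_disp <- protocol$max_displacement
    if (is.null(max_disp)) {
      # travel needed to extend the full contour beyond the initial
      # tip-anchor separation, plus spring slack
      pos0 <- if (is.null(state)) chain_positions(chain) else state$positions
      z_gap <- pos0[pulled, 3] - pos0[anchored, 3]
      max_disp <- params$d0 * (n - 1) - z_gap + 30
    }
    n_steps <- ceiling(max_disp /
                         (protocol$v_pull_fs * integrator$dt_fs))
  }
  res <- run_md(chain, params, integrator, n_steps, protocol$stride,
                positions = if (is.null(state)) NULL else state$positions,
                velocities = if (is.null(state)) NULL else state$velocities,
                anchor = anchored,
                pull = list(pulled = pulled, k_pull = protocol$k_pull,
                            v_pull_fs = protocol$v_pull_fs),
                stop_when_detached = stop_when_detached)
  tr <- tibble::as_tibble(res$trace)
  structure(tibble::new_tibble(tr, class = "sim_trace"),
            protocol = protocol, integrator = integrator, params = params,
            detached = res$detached, n_beads = n)
}

# shared sawtooth drop detector: a peak is a running maximum that (i) rises
# by more than the drop threshold above the valley preceding it and (ii) is
# followed by a force drop exceeding the same threshold; tracking the valley
# prevents double-counting of noise wiggles and of the smoothed decay
# shoulder after a rupture
find_force_peaks <- function(f, drop_frac, drop_abs, min_peak = -Inf) {
  peaks <- integer()
  run_max <- f[1]; run_idx <- 1L
  vmin <- f[1]; rise <- 0
  for (i in seq_along(f)) {
    if (f[i] > run_max) {
      run_max <- f[i]; run_idx <- i
      rise <- run_max - vmin
    }
    need <- max(drop_abs, drop_frac * run_max)
    if (run_max - f[i] > need) {
      if (run_max >= min_peak && rise > need) peaks <- c(peaks, run_idx)
      run_max <- f[i]; run_idx <- i
      vmin <- f[i]; rise <- 0
    }
    if (f[i] < vmin && run_idx < i) {
      # valley below the current maximum resets the candidate rise base
      vmin <- f[i]
      run_max <- f[i]; run_idx <- i; rise <- 0
    } else if (f[i] < vmin) {
      vmin <- f[i]
    }
  }
  peaks
}

#' Detect major unfolding events in a simulated pulling trace
#'
#' The recorded spring force is smoothed with a running mean; a force drop
#' larger than all of (i) a multiple of the thermal force noise, (ii) a
#' fraction of the current peak height and (iii) a fraction of the trace-wide
#' maximum terminates a peak. Only peaks reaching `min_force` (by default a
#' fraction of the trace maximum, mirroring how major force peaks are counted
#' in force spectroscopy) are reported, each with the number of residues
#' unfolded up to the drop.
#'
#' @param trace A `sim_trace` from [run_pulling()].
#' @param drop_frac Fractional force drop that ends a peak.
#' @param noise_mult Multiple of the thermal force SD used as an absolute
#'   prominence threshold.
#' @param major_frac Fraction of the trace-wide maximum force a drop must
#'   exceed, and (unless `min_force` is given) the major-peak height floor.
#' @param smooth_window Running-mean window, in recorded samples.
#' @param min_force Minimum peak force (eps/A); default
#'   `major_frac * max(force)`.
#' @return Tibble (step, displacement_A, force, n_unfolded), one row per
#'   event.
#' @export
detect_events <- function(trace, drop_frac = 0.3, noise_mult = 3,
                          major_frac = 0.25, smooth_window = 7,
                          min_force = NULL) {
  if (nrow(trace) == 0)
    return(tibble::tibble(step = numeric(), displacement_A = numeric(),
                          force = numeric(), n_unfolded = numeric()))
  f <- trace$force
  if (nrow(trace) > smooth_window && smooth_window > 1)
    f <- as.numeric(stats::filter(f, rep(1 / smooth_window, smooth_window),
                                  sides = 2))
  ok <- !is.na(f)
  fs <- f[ok]
  noise_sd <- stats::mad(diff(fs)) / sqrt(2) * sqrt(smooth_window)
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- 1e-9
  if (is.null(min_force)) min_force <- major_frac * max(fs)
  idx <- find_force_peaks(fs, drop_frac,
                          max(noise_mult * noise_sd,
                              major_frac * max(fs)),
                          min_peak = min_force)
  idx <- which(ok)[idx]
  tibble::tibble(step = trace$step[idx],
                 displacement_A = trace$displacement_A[idx],
                 force = trace$force[idx],
                 n_unfolded = trace$n_unfolded[idx])
}

#' Temperature scan of the folded fraction and unfolding temperature
#'
#' Runs replicate Langevin simulations on a temperature grid, averages the
#' equilibrium native-contact fraction `q` over the second half of each run,
#' and locates the unfolding temperature as the point where the mean `q`
#' crosses 0.5 (linear interpolation between grid points).
#'
#' @inheritParams langevin_step
#' @param temperatures Grid of thermal energies `k_bt` (eps) spanning the
#'   transition.
#' @param replicas Replicate runs per temperature.
#' @param n_steps Steps per run.
#' @param stride Recording stride.
#' @return A `melting_scan` tibble (k_bt, replicate, q) with the unfolding
#'   temperature in `attr(, "t_unfold")`.
#' @export
melting_scan <- function(chain, params = ff_params(),
                         integrator = integrator_params(),
                         temperatures = seq(0.4, 0.9, by = 0.05),
                         replicas = 2, n_steps = 1e6, stride = 2000) {
  grid <- tidyr::expand_grid(k_bt = temperatures,
                             replicate = seq_len(replicas))
  q <- purrr::pmap_dbl(grid, function(k_bt, replicate) {
    integ <- integrator
    integ$k_bt <- k_bt
    integ$seed <- derive_seed(integrator$seed,
                              paste0("melt-", k_bt, "-", replicate))
    res <- run_md(chain, params, integ, n_steps, stride)
    tr <- res$trace
    mean(tr$q[tr$step > n_steps / 2], na.rm = TRUE)
  })
  out <- dplyr::mutate(grid, q = q)
  prof <- out |>
    dplyr::summarise(q = mean(.data$q), .by = "k_bt") |>
    dplyr::arrange(.data$k_bt)
  below <- which(prof$q < 0.5)
  if (length(below) == 0 || min(below) == 1)
    stop("mean q does not cross 0.5 inside the temperature grid; ",
         "widen the grid")
  hi <- min(below); lo <- hi - 1
  t_unfold <- prof$k_bt[lo] + (0.5 - prof$q[lo]) *
    (prof$k_bt[hi] - prof$k_bt[lo]) / (prof$q[hi] - prof$q[lo])
  structure(tibble::new_tibble(out, class = "melting_scan"),
            t_unfold = t_unfold, profile = prof)
}
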