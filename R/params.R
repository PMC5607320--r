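#' Force-field parameters for the coarse-grained model
#'
#' Parameters of the structure-based (Go-type) potential: a stiff harmonic
#' backbone, native-contact Lennard-Jones attractions, shifted purely repulsive
#' non-native interactions, a chirality restraint, and an implicit membrane
#' slab whose strength `eps_membr` encodes membrane hydrophobicity (a proxy for
#' cholesterol content). Energies are in units of the contact depth `eps`,
#' distances in Angstrom.
#'
#' @param eps Energy unit; the native-contact well depth (fixed scale, 1).
#' @param k_bb Backbone spring constant, eps/A^2.
#' @param d0 Equilibrium consecutive-bead (virtual peptide bond) length, A.
#' @param sigma0 Repulsion core size for non-native pairs, A.
#' @param d_cut Non-native interaction cutoff, A. Should be close to
#'   `2^(1/6) * sigma0` so the shifted potential vanishes continuously.
#' @param k_chir Chirality restraint constant, eps.
#' @param eps_membr Membrane slab strength, eps. Larger values describe a more
#'   hydrophobic (cholesterol-rich) membrane; 0 disables the slab.
#' @param theta_literal If `TRUE` the chirality step function evaluates to -1
#'   (rather than 0) when the instantaneous chirality agrees with the native
#'   sign, i.e. correct-handed states are rewarded instead of ignored. Kept
#'   only for sensitivity checks; the default is the standard Heaviside form.
#' @return A list of class `ff_params`.
#' @export
ff_params <- function(eps = 1, k_bb = 33.34, d0 = 3.8, sigma0 = 5,
                      d_cut = 5.61, k_chir = 1, eps_membr = 0,
                      theta_literal = FALSE) {
  stopifnot(eps > 0, k_bb > 0, d0 > 0, sigma0 > 0, d_cut > 0, k_chir > 0,
            eps_membr >= 0)
  mismatch <- abs(d_cut - 2^(1 / 6) * sigma0)
  if (mismatch > 0.01) {
    message(sprintf(
      "d_cut = %.3f A is %.3f A away from 2^(1/6)*sigma0; the non-native term
  will be discontinuous at the cutoff.", d_cut, mismatch))
  }
  structure(list(eps = eps, k_bb = k_bb, d0 = d0, sigma0 = sigma0,
                 d_cut = d_cut, k_chir = k_chir, eps_membr = eps_membr,
                 theta_literal = isTRUE(theta_literal)),
            class = "ff_params")
}

#' Langevin integrator parameters
#'
#' The equations of motion `m r" = -gamma r' + F + sqrt(2 gamma kBT) xi` are
#' integrated with the BBK velocity-Verlet discretisation. Time-like constants
#' are quoted in femtoseconds; internally they are converted to the reduced
#' time unit tau = sqrt(m A^2 / eps) through `fs_per_tau`, the calibration that
#' makes the femtosecond labels consistent with unit bead mass (the products
#' gamma*dt and v_pull*dt, which carry the physics, are unit-invariant).
#'
#' @param mass Bead mass (reduced units, 1).
#' @param gamma_fs Friction coefficient, 1/fs.
#' @param dt_fs Integration timestep, fs.
#' @param k_bt Thermal energy, eps.
#' @param fs_per_tau Femtoseconds per reduced time unit.
#' @param seed Integer seed for the thermal noise generator.
#' @return A list of class `integrator_params`.
#' @export
integrator_params <- function(mass = 1, gamma_fs = 8.14e-4, dt_fs = 15,
                              k_bt = 0.52, fs_per_tau = 600, seed = 1L) {
  stopifnot(mass > 0, dt_fs > 0, gamma_fs >= 0, k_bt >= 0, fs_per_tau > 0)
  structure(list(mass = mass, gamma_fs = gamma_fs, dt_fs = dt_fs,
                 k_bt = k_bt, fs_per_tau = fs_per_tau,
                 seed = as.integer(seed)),
            class = "integrator_params")
}

#' Constant-velocity pulling protocol
#'
#' A harmonic spring is attached to the pulled (by default C-terminal) bead;
#' its outer end moves along +z at constant velocity while the anchored (by
#' default N-terminal) bead is held fixed. The separation of the moving end
#' from its origin plays the role of the cantilever displacement in a force
#' spectroscopy experiment.
#'
#' @param v_pull_fs Pulling velocity, A/fs.
#' @param k_pull Spring constant of the pulling spring, eps/A^2. Soft enough
#'   to resolve individual rupture events at the default velocity.
#' @param pulled,anchored `"C"`/`"N"` or a 1-based bead index.
#' @param max_displacement Cantilever travel at which the run stops, A
#'   (`NULL`: run until the chain is fully detached or `n_steps` elapse).
#' @param stride Recording stride, steps.
#' @return A list of class `pulling_protocol`.
#' @export
pulling_protocol <- function(v_pull_fs = 2.035e-6, k_pull = 0.2,
                             pulled = "C", anchored = "N",
                             max_displacement = NULL, stride = 1000L) {
  stopifnot(v_pull_fs > 0, k_pull > 0, stride >= 1)
  structure(list(v_pull_fs = v_pull_fs, k_pull = k_pull, pulled = pulled,
                 anchored = anchored, max_displacement = max_displacement,
                 stride = as.integer(stride)),
            class = "pulling_protocol")
}

#' Membrane slab geometry
#'
#' Borders of the implicit membrane along the z axis (the structure is assumed
#' pre-oriented with the membrane normal along z) plus the width of the linear
#' ramp over which the slab potential switches on.
#'
#' @param z_min,z_max Lower/upper border of the membrane, A.
#' @param ramp_width Width of the boundary ramp, A (fixed at 3 in the model).
#' @return A list of class `membrane_slab`.
#' @export
membrane_slab <- function(z_min = -17.034, z_max = 15.896, ramp_width = 3) {
  stopifnot(z_min < z_max, ramp_width > 0)
  structure(list(z_min = z_min, z_max = z_max, ramp_width = ramp_width),
            class = "membrane_slab")
}

#' Worm-like chain parameters
#'
#' @param p_nm Persistence length, nm.
#' @param temperature_k Temperature, K (`kB*T` = 4.114 pN nm at 298 K).
#' @param residue_nm Contour length per amino acid in a stretched chain,
#'   nm/residue. 0.4 is the generic value; 0.36 matches the printed
#'   rhodopsin contour-length-to-residue conversions.
#' @return A list of class `wlc_params`.
#' @export
wlc_params <- function(p_nm = 0.4, temperature_k = 298, residue_nm = 0.4) {
  stopifnot(p_nm > 0, temperature_k > 0, residue_nm > 0)
  structure(list(p_nm = p_nm, temperature_k = temperature_k,
                 residue_nm = residue_nm),
            class = "wlc_params")
}

#' Derive a stage-specific seed from a base seed
#'
#' One global seed fans out to named per-stage generators so that pipeline
#' stages draw from independent, reproducible streams. The derived seed is
#' kept below 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1) + 1)
}
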