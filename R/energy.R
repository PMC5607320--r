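#' Backbone energy
#'
#' Harmonic tethers between consecutive beads,
#' `sum_i k_BB (r_{i,i+1} - d0)^2`.
#'
#' @param chain A `bead_chain` (native positions) or anything accepted by
#'   `positions`.
#' @param params [ff_params()].
#' @param positions Optional N x 3 matrix overriding the chain coordinates.
#' @return Energy in eps.
#' @export
backbone_energy <- function(chain, params = ff_params(), positions = NULL) {
  pos <- chain_positions(chain, positions)
  r <- sqrt(rowSums(diff(pos)^2))
  sum(params$k_bb * (r - params$d0)^2)
}

#' Native-contact energy
#'
#' Lennard-Jones attraction over the native contact pairs with per-pair
#' `sigma_ij` equal to the native C-alpha separation:
#' `sum 4 eps [(sigma/r)^12 - (sigma/r)^6]`.
#'
#' @inheritParams backbone_energy
#' @param contacts Tibble (i, j, sigma); defaults to the chain's contact map.
#' @return Energy in eps.
#' @export
native_energy <- function(chain, params = ff_params(), contacts = NULL,
                          positions = NULL) {
  pos <- chain_positions(chain, positions)
  if (is.null(contacts)) contacts <- attr(chain, "contacts")
  if (is.null(contacts) || nrow(contacts) == 0) return(0)
  r2 <- rowSums((pos[contacts$i, , drop = FALSE] -
                 pos[contacts$j, , drop = FALSE])^2)
  if (any(r2 == 0)) stop("native contact with zero distance")
  s6 <- (contacts$sigma^2 / r2)^3
  sum(4 * params$eps * (s6^2 - s6))
}

#' Non-native repulsion energy
#'
#' Shifted, purely repulsive Lennard-Jones on every non-adjacent, non-native
#' pair: `4 eps [(sigma0/r)^12 - (sigma0/r)^6] + eps` below `d_cut`, zero
#' above.
#'
#' @inheritParams native_energy
#' @return Energy in eps (always non-negative for `d_cut = 2^(1/6) sigma0`).
#' @export
nonnative_energy <- function(chain, params = ff_params(), contacts = NULL,
                             positions = NULL) {
  pos <- chain_positions(chain, positions)
  if (is.null(contacts)) contacts <- attr(chain, "contacts")
  n <- nrow(pos)
  if (n < 3) return(0)
  dmat <- as.matrix(stats::dist(pos))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  excl <- sep <= 1
  if (!is.null(contacts) && nrow(contacts) > 0) {
    excl[cbind(contacts$i, contacts$j)] <- TRUE
    excl[cbind(contacts$j, contacts$i)] <- TRUE
  }
  keep <- upper.tri(dmat) & !excl & dmat < params$d_cut
  r <- dmat[keep]
  if (length(r) == 0) return(0)
  s6 <- (params$sigma0 / r)^6
  sum(4 * params$eps * (s6^2 - s6) + params$eps)
}

#' Chirality energy
#'
#' `sum k_CHIR C_i^2 Theta(-C_i C_i^NAT)`: internal beads pay a quadratic
#' penalty only when the instantaneous chirality sign opposes the native one
#' (Theta is the Heaviside step: 1 for positive argument, 0 otherwise; with
#' `theta_literal = TRUE` the step instead takes value -1 for non-positive
#' arguments).
#'
#' @inheritParams backbone_energy
#' @param chirality_native Numeric vector of native chiralities; defaults to
#'   the chain's annotation.
#' @return Energy in eps.
#' @export
chirality_energy <- function(chain, params = ff_params(),
                             chirality_native = NULL, positions = NULL) {
  pos <- chain_positions(chain, positions)
  if (is.null(chirality_native)) chirality_native <- attr(chain, "chirality")
  if (is.null(chirality_native)) return(0)
  ci <- native_chirality(pos, d0 = params$d0)
  ok <- !is.na(ci) & !is.na(chirality_native)
  opposed <- ok & (ci * chirality_native < 0)
  e <- sum(params$k_chir * ci[opposed]^2)
  if (params$theta_literal) {
    agree <- ok & !(ci * chirality_native < 0)
    e <- e - sum(params$k_chir * ci[agree]^2)
  }
  e
}

#' Membrane slab energy
#'
#' Acts only on residues flagged as in native membrane contact. A hydrophobic
#' contact residue pays 0 inside the slab, a linear ramp over `ramp_width` at
#' each border, and `eps_membr` outside; a hydrophilic contact residue feels
#' the same profile multiplied by -1 (it is pushed out of the membrane).
#'
#' @inheritParams backbone_energy
#' @param hydrophobic,membrane_contact Logical per-residue flags; default to
#'   the chain's annotation.
#' @param slab A [membrane_slab()]; defaults to the chain's annotation.
#' @return Energy in eps.
#' @export
membrane_energy <- function(chain, params = ff_params(), hydrophobic = NULL,
                            membrane_contact = NULL, slab = NULL,
                            positions = NULL) {
  pos <- chain_positions(chain, positions)
  if (is.null(hydrophobic)) hydrophobic <- chain$hydrophobic
  if (is.null(membrane_contact)) membrane_contact <- chain$membrane_contact
  if (is.null(slab)) slab <- attr(chain, "slab")
  if (is.null(slab)) slab <- membrane_slab()
  z <- pos[, 3]
  w <- slab$ramp_width
  ev <- ifelse(z > slab$z_min & z < slab$z_max, 0,
        ifelse(z >= slab$z_min - w & z <= slab$z_min,
               (slab$z_min - z) / w,
        ifelse(z >= slab$z_max & z <= slab$z_max + w,
               (z - slab$z_max) / w, 1)))
  s <- ifelse(hydrophobic, 1, -1)
  sum(params$eps_membr * s[membrane_contact] * ev[membrane_contact])
}

#' Total potential energy with per-term breakdown
#'
#' @inheritParams backbone_energy
#' @param engine `"cpp"` evaluates through the compiled kernel shared with the
#'   dynamics; `"r"` uses the independent vectorised R implementation of each
#'   term.
#' @return One-row tibble (v_bb, v_nat, v_non, v_chir, v_membr, total), eps.
#' @export
total_energy <- function(chain, params = ff_params(), positions = NULL,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  pos <- chain_positions(chain, positions)
  if (engine == "cpp") {
    e <- cpp_energy(pos, as_cg_topology(chain), unclass(params))
    return(tibble::as_tibble(as.list(e)))
  }
  v <- c(v_bb = backbone_energy(chain, params, pos),
         v_nat = native_energy(chain, params, positions = pos),
         v_non = nonnative_energy(chain, params, positions = pos),
         v_chir = chirality_energy(chain, params, positions = pos),
         v_membr = membrane_energy(chain, params, positions = pos))
  tibble::as_tibble(as.list(c(v, total = sum(v))))
}

#' Analytic forces
#'
#' Negative gradient of the total potential. At the non-differentiable corner
#' points of the membrane ramp the one-sided derivative from inside the ramp
#' is used (the potential is continuous, so the impulse error is bounded by
#' the timestep).
#'
#' @inheritParams backbone_energy
#' @return Tibble (residue, fx, fy, fz) in eps/A.
#' @export
forces <- function(chain, params = ff_params(), positions = NULL) {
  pos <- chain_positions(chain, positions)
  f <- cpp_forces(pos, as_cg_topology(chain), unclass(params))
  tibble::tibble(residue = seq_len(nrow(f)),
                 fx = f[, 1], fy = f[, 2], fz = f[, 3])
}
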