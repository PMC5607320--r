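#' Synthetic seven-transmembrane helical bundle
#'
#' Generates an idealised 348-residue GPCR-like fold: seven membrane-spanning
#' alpha-helices (ideal helix geometry, 1.5 A rise, 100 degrees per residue,
#' 2.3 A C-alpha radius) arranged on a circle, connected by circular-arc loops
#' with 3.8 A bead spacing, plus extended N- and C-terminal tails leaving the
#' membrane on opposite sides. The sequence is sampled segment-wise from
#' hydrophobic-rich (helix) and polar-rich (loop/tail) residue pools.
#'
#' This is a synthetic stand-in for an experimental membrane-protein
#' structure: it reproduces the size, topology, helix packing distances and
#' hydrophobicity layout that the coarse-grained model expects, but not the
#' tertiary detail of any real protein. Native contacts are assigned with the
#' C-alpha distance criterion ([contact_map_calpha()]), since an idealised
#' C-alpha trace has no heavy-atom detail for the overlap criterion.
#'
#' @param seed Seed for the sequence draw (geometry is deterministic).
#' @param slab Membrane slab used to centre the helices and assign
#'   membrane-contact flags.
#' @param helix_radius C-alpha helix radius, A.
#' @param bundle_radius Radius of the circle of helix axes, A.
#' @param contact_cutoff C-alpha native-contact cutoff, A.
#' @return An annotated `bead_chain` (348 beads) with a `segments` attribute
#'   describing the helix/loop layout.
#' @export
synthetic_tm_bundle <- function(seed = 20417, slab = membrane_slab(),
                                helix_radius = 2.3, bundle_radius = 11,
                                contact_cutoff = 8.5) {
  segs <- tibble::tibble(
    type = c("tail_n", "H1", "loop", "H2", "loop", "H3", "loop", "H4",
             "loop", "H5", "loop", "H6", "loop", "H7", "tail_c"),
    len = c(34, 30, 7, 29, 6, 33, 11, 23, 26, 26, 21, 31, 8, 24, 39))
  stopifnot(sum(segs$len) == 348)
  rise <- 1.5; turn <- 100 * pi / 180; d0 <- 3.8
  zc <- (slab$z_min + slab$z_max) / 2
  helix_ids <- which(grepl("^H", segs$type))
  n_helix <- length(helix_ids)
  dirs <- rep(c(1, -1), length.out = n_helix)         # H1 up, H2 down, ...
  th <- 2 * pi * (seq_len(n_helix) - 1) / n_helix     # axis positions
  centers <- cbind(bundle_radius * cos(th), bundle_radius * sin(th))

  helix_coords <- function(k) {
    len <- segs$len[helix_ids[k]]
    tt <- seq_len(len) - 1
    span <- rise * (len - 1)
    z0 <- zc - dirs[k] * span / 2
    phi <- th[k] + pi + dirs[k] * turn * tt
    cbind(centers[k, 1] + helix_radius * cos(phi),
          centers[k, 2] + helix_radius * sin(phi),
          z0 + dirs[k] * rise * tt)
  }
  hel <- lapply(seq_len(n_helix), helix_coords)

  # circular arc from P to Q with n interior beads spaced ~3.8 A,
  # bulging along direction b0 (orthogonalised against the chord)
  arc_loop <- function(P, Q, n, b0) {
    d <- sqrt(sum((Q - P)^2))
    L <- (n + 1) * d0
    e1 <- (Q - P) / d
    b <- b0 - sum(b0 * e1) * e1
    b <- b / sqrt(sum(b^2))
    f <- function(theta) theta / (2 * sin(theta / 2)) - L / d
    theta <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-4))$root
    Rr <- L / theta
    M <- (P + Q) / 2
    O <- M - Rr * cos(theta / 2) * b
    phi <- -theta / 2 + theta * seq_len(n) / (n + 1)
    t(vapply(phi, function(p) O + Rr * (cos(p) * b + sin(p) * e1),
             numeric(3)))
  }
  out_dir <- function(P, Q) {
    m <- (P + Q) / 2
    v <- c(m[1], m[2], 0)
    v / sqrt(sum(v^2))
  }

  pieces <- vector("list", nrow(segs))
  for (k in seq_len(n_helix)) pieces[[helix_ids[k]]] <- hel[[k]]
  for (k in seq_len(n_helix - 1)) {
    li <- helix_ids[k] + 1
    P <- hel[[k]][nrow(hel[[k]]), ]
    Q <- hel[[k + 1]][1, ]
    side <- dirs[k]                       # loop sits where helix k ended
    b0 <- c(0, 0, side) + 0.45 * out_dir(P, Q)
    pieces[[li]] <- arc_loop(P, Q, segs$len[li], b0)
  }
  # straight tails, tilted off the membrane normal
  P1 <- hel[[1]][1, ]
  u_n <- c(0.45 * out_dir(P1, P1)[1:2], -1)
  u_n <- u_n / sqrt(sum(u_n^2))
  nN <- segs$len[1]
  pieces[[1]] <- t(vapply(rev(seq_len(nN)), function(k) P1 + k * d0 * u_n,
                          numeric(3)))
  PC <- hel[[n_helix]][nrow(hel[[n_helix]]), ]
  u_c <- c(0.45 * out_dir(PC, PC)[1:2], 1)
  u_c <- u_c / sqrt(sum(u_c^2))
  nC <- segs$len[nrow(segs)]
  pieces[[nrow(segs)]] <- t(vapply(seq_len(nC), function(k) PC + k * d0 * u_c,
                                   numeric(3)))
  pos <- do.call(rbind, pieces)

  # the planar arcs give correct spacing but long loops can fold back onto
  # the bundle; relax loop beads (helices and tails fixed) under backbone
  # springs plus a soft-core repulsion until the path is clash-free
  seg_start <- cumsum(c(1, utils::head(segs$len, -1)))
  loop_rows <- which(segs$type == "loop")
  movable <- unlist(lapply(loop_rows, function(k)
    seq(seg_start[k], seg_start[k] + segs$len[k] - 1)))
  pos <- relax_path(pos, movable, d0 = d0)

  helix_pool <- c(L = .18, I = .13, V = .13, A = .12, F = .09, G = .07,
                  T = .06, S = .06, M = .05, Y = .04, W = .04, C = .03)
  polar_pool <- c(R = .11, K = .11, D = .10, E = .10, S = .10, T = .09,
                  N = .08, Q = .08, G = .08, P = .06, A = .05, H = .04)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  aa <- unlist(lapply(seq_len(nrow(segs)), function(si) {
    pool <- if (grepl("^H", segs$type[si])) helix_pool else polar_pool
    sample(names(pool), segs$len[si], replace = TRUE, prob = pool)
  }))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  chain <- tibble::tibble(residue = seq_len(nrow(pos)), aa = aa,
                          x = pos[, 1], y = pos[, 2], z = pos[, 3])
  chain$hydrophobic <- classify_hydrophobicity(chain$aa)
  chain$membrane_contact <- assign_membrane_contact(chain, slab)
  chain <- new_bead_chain(chain, slab = slab)
  contacts <- contact_map_calpha(chain, cutoff = contact_cutoff)
  chain <- new_bead_chain(chain, contacts = contacts,
                          chirality = native_chirality(chain), slab = slab)
  attr(chain, "segments") <- dplyr::mutate(segs, start = seg_start,
                                           end = seg_start + segs$len - 1)
  chain
}

# deterministic gradient-descent relaxation of a subset of beads: harmonic
# bonds at d0 along the chain plus quadratic soft-core repulsion (range rc)
# between all pairs separated by >= 2 in sequence
relax_path <- function(pos, movable, d0 = 3.8, rc = 6, k_bond = 10,
                       k_rep = 4, step = 5e-3, n_iter = 4000) {
  n <- nrow(pos)
  mov <- sort(unique(movable))
  is_mov <- logical(n); is_mov[mov] <- TRUE
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  pairs <- NULL
  refresh <- function() {
    dmat <- as.matrix(stats::dist(pos))
    hit <- which(dmat < rc + 1.5 & sep >= 2 & upper.tri(dmat),
                 arr.ind = TRUE)
    keep <- is_mov[hit[, 1]] | is_mov[hit[, 2]]
    hit[keep, , drop = FALSE]
  }
  for (it in seq_len(n_iter)) {
    if (it %% 25 == 1) pairs <- refresh()
    grad <- matrix(0, n, 3)
    dv <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
    dr <- sqrt(rowSums(dv^2))
    gvec <- dv * (2 * k_bond * (dr - d0) / pmax(dr, 1e-9))
    grad[-n, ] <- grad[-n, ] - gvec
    grad[-1, ] <- grad[-1, ] + gvec
    if (nrow(pairs) > 0) {
      ii <- pairs[, 1]; jj <- pairs[, 2]
      dvec <- pos[ii, , drop = FALSE] - pos[jj, , drop = FALSE]
      r <- sqrt(rowSums(dvec^2))
      act <- r < rc
      if (any(act)) {
        g <- -2 * k_rep * (rc - r[act]) / pmax(r[act], 1e-9)
        contrib <- dvec[act, , drop = FALSE] * g
        agg <- rowsum(rbind(contrib, -contrib), c(ii[act], jj[act]))
        rows <- as.integer(rownames(agg))
        grad[rows, ] <- grad[rows, ] + agg
      }
    }
    pos[mov, ] <- pos[mov, ] - step * grad[mov, , drop = FALSE]
    if (it %% 500 == 0 && max(abs(grad[mov, ])) < 0.05) break
  }
  pos
}

#' Render a bead chain as C-alpha-only PDB text
#'
#' @param chain A `bead_chain`.
#' @return Character vector of PDB ATOM records (chain A).
#' @export
bead_chain_pdb <- function(chain) {
  aa3 <- bio3d::aa123(chain$aa)
  sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          chain$residue, aa3, chain$residue, chain$x, chain$y, chain$z)
}
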