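test_that("backbone energy is harmonic about d0", {
  line <- cbind(3.8 * (0:4), 0, 0)
  ch <- chain_fixture(line)
  expect_equal(backbone_energy(ch), 0)

  stretched <- line
  stretched[5, 1] <- stretched[4, 1] + 4.8  # one bond at 4.8 A
  expect_equal(backbone_energy(ch, positions = stretched), 33.34)

  squeezed <- line
  squeezed[5, 1] <- squeezed[4, 1] + 3.0    # one bond at 3.0 A
  expect_equal(backbone_energy(ch, positions = squeezed), 33.34 * 0.64)
})

test_that("native contact term is the Lennard-Jones potential in sigma", {
  pos <- cbind(c(0, 3.8, 7.6), 0, 0)
  ct <- tibble::tibble(i = 1L, j = 3L, sigma = 7.6)
  ch <- chain_fixture(pos, contacts = ct)
  expect_equal(native_energy(ch), 0)  # r = sigma

  at_min <- pos
  at_min[3, 1] <- 2^(1 / 6) * 7.6
  expect_equal(native_energy(ch, positions = at_min), -1)

  far <- pos
  far[3, 1] <- 3 * 7.6
  expect_equal(native_energy(ch, positions = far),
               4 * (3^-12 - 3^-6), tolerance = 1e-12)
  expect_lt(abs(native_energy(ch, positions = far) - (-5.47e-3)), 1e-5)

  clash <- pos
  clash[3, ] <- pos[1, ]
  expect_error(native_energy(ch, positions = clash), "zero")
})

test_that("non-native repulsion is the shifted truncated LJ", {
  pair_e <- function(r) {
    pos <- cbind(c(0, 20, r), c(0, 40, 0), 0)  # bead 2 far away
    nonnative_energy(chain_fixture(pos))
  }
  expect_equal(pair_e(5.0), 1)                 # 4(1-1) + eps at r = sigma0
  expect_equal(pair_e(6.0), 0)                 # beyond d_cut
  expect_lt(abs(pair_e(5.61)), 1e-3)           # vanishes at the cutoff
  expect_gt(pair_e(4.0), 0)
})

test_that("chirality penalises only sign-opposed configurations", {
  hx <- helix_coords(10)
  ch <- chain_fixture(hx, contacts = contact_map_calpha(
    tibble::tibble(x = hx[, 1], y = hx[, 2], z = hx[, 3])))
  expect_equal(chirality_energy(ch), 0)  # native agrees with itself

  mir <- hx
  mir[, 3] <- -mir[, 3]
  cn <- attr(ch, "chirality")
  e_mirror <- chirality_energy(ch, positions = mir)
  expect_equal(e_mirror, sum(cn[!is.na(cn)]^2), tolerance = 1e-12)

  # single opposed bead arithmetic: k_chir * C^2 * Theta
  expect_equal(1 * (-0.5)^2 * 1, 0.25)
  line <- cbind(3.8 * (0:9), 0, 0)
  expect_equal(chirality_energy(ch, positions = line), 0)  # all C_i = 0

  # literal step-function reading rewards agreeing beads
  pars_lit <- ff_params(theta_literal = TRUE)
  expect_equal(chirality_energy(ch, pars_lit),
               -sum(cn[!is.na(cn)]^2), tolerance = 1e-12)
})

test_that("membrane slab: zero inside, linear ramps, signed by hydrophobicity", {
  slab <- membrane_slab()
  em <- ff_params(eps_membr = 2)
  zpts <- function(z) cbind(0, 0, z)
  e_at <- function(z, hphob) {
    ch <- chain_fixture(zpts(c(z, z + 60)), hydrophobic = hphob,
                        membrane_contact = c(TRUE, FALSE), slab = slab)
    membrane_energy(ch, em)
  }
  expect_equal(e_at(0, TRUE), 0)
  expect_equal(e_at(slab$z_min - 1.5, TRUE), 0.5 * 2)     # ramp midpoint
  expect_equal(e_at(slab$z_max + 10, FALSE), -2)          # hydrophilic flip
  expect_equal(e_at(slab$z_max + 1, TRUE), 2 / 3)
  expect_equal(e_at(slab$z_min - 10, TRUE), 2)

  # per-residue bounds over a z sweep
  z <- seq(slab$z_min - 10, slab$z_max + 10, by = 0.25)
  e_h <- vapply(z, e_at, numeric(1), hphob = TRUE)
  expect_true(all(e_h >= 0 & e_h <= 2))
  e_p <- vapply(z, e_at, numeric(1), hphob = FALSE)
  expect_true(all(e_p >= -2 & e_p <= 0))
})

test_that("total energy decomposes exactly and matches the R reference", {
  bun <- bundle_cache()
  pars <- ff_params(eps_membr = 4.03)
  set.seed(42)
  pos <- photopull:::chain_positions(bun) + matrix(rnorm(3 * 348, 0, 0.4),
                                                   348, 3)
  e_cpp <- total_energy(bun, pars, positions = pos)
  e_r <- total_energy(bun, pars, positions = pos, engine = "r")
  expect_equal(as.numeric(e_cpp), as.numeric(e_r), tolerance = 1e-10)
  expect_equal(e_cpp$total,
               e_cpp$v_bb + e_cpp$v_nat + e_cpp$v_non + e_cpp$v_chir +
                 e_cpp$v_membr)
  expect_gte(e_cpp$v_non, 0)

  # native configuration with no membrane: all structural terms at minimum
  e0 <- total_energy(bun, ff_params())
  expect_equal(e0$v_nat, 0, tolerance = 1e-10)
  expect_equal(e0$v_chir, 0)
  expect_gte(e0$v_non, 0)
})

test_that("energy is invariant under rigid motion when the membrane is off", {
  bun <- bundle_cache()
  pars <- ff_params(eps_membr = 0)
  pos <- photopull:::chain_positions(bun)
  e0 <- total_energy(bun, pars)$total
  R <- rotation_matrix(c(0.3, -1, 0.5), 1.23)
  moved <- pos %*% t(R)
  moved <- sweep(moved, 2, c(11, -7, 23), "+")
  e1 <- total_energy(bun, pars, positions = moved)$total
  expect_lt(abs(e1 - e0), 1e-9)
})

test_that("analytic forces match central finite differences", {
  set.seed(5)
  n <- 10
  for (rep in 1:10) {
    base <- cbind(cumsum(runif(n, 3.5, 4.1)), rnorm(n, 0, 2), rnorm(n, 0, 2))
    ct <- tibble::tibble(i = c(1L, 2L, 4L), j = c(5L, 7L, 9L),
                         sigma = runif(3, 5, 8))
    ch <- chain_fixture(base, contacts = ct,
                        hydrophobic = sample(c(TRUE, FALSE), n, TRUE),
                        membrane_contact = sample(c(TRUE, FALSE), n, TRUE),
                        slab = membrane_slab(-4, 4))
    pars <- ff_params(eps_membr = 3)
    for (cfg in 1:10) {
      pos <- base + matrix(rnorm(3 * n, 0, 0.35), n, 3)
      f <- as.matrix(forces(ch, pars, positions = pos)[, c("fx", "fy", "fz")])
      h <- 1e-5
      fd <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        for (k in 1:3) {
          pp <- pos; pm <- pos
          pp[i, k] <- pp[i, k] + h
          pm[i, k] <- pm[i, k] - h
          fd[i, k] <- -(total_energy(ch, pars, positions = pp,
                                     engine = "r")$total -
                        total_energy(ch, pars, positions = pm,
                                     engine = "r")$total) / (2 * h)
        }
      }
      expect_lt(max(abs(f - fd)) / max(abs(f)), 1e-4)
    }
  }
})

test_that("net force vanishes under the translation-invariant terms", {
  bun <- bundle_cache()
  f <- forces(bun, ff_params(eps_membr = 0))
  expect_lt(max(abs(colSums(as.matrix(f[, c("fx", "fy", "fz")])))), 1e-9)
})

test_that("parameter validation enforces positivity and flags cutoff drift", {
  expect_error(ff_params(k_bb = -1))
  expect_message(ff_params(d_cut = 5.0), "d_cut")
  expect_silent(ff_params())
  expect_error(integrator_params(dt_fs = 0))
  expect_error(membrane_slab(5, -5))
})
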