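test_that("a free particle stays put; a constant force gives the Verlet kick", {
  # two beads at d0: no net force, nothing moves at T = 0
  ch <- chain_fixture(cbind(c(0, 3.8), 0, 0))
  integ0 <- integrator_params(gamma_fs = 0, k_bt = 0, seed = 1)
  st <- langevin_step(ch, ff_params(), integ0, n_steps = 1)
  expect_equal(st$positions, photopull:::chain_positions(ch))

  # one stretched bond: first half-kick displaces by F dt^2 / (2 m)
  pos0 <- cbind(c(0, 4.3), 0, 0)
  f0 <- forces(ch, ff_params(), positions = pos0)
  st1 <- langevin_step(ch, ff_params(), integ0, n_steps = 1,
                       positions = pos0)
  dt <- integ0$dt_fs / integ0$fs_per_tau
  expect_equal(st1$positions[1, 1] - pos0[1, 1],
               f0$fx[1] * dt^2 / 2, tolerance = 1e-12)
})

test_that("kinetic energy equilibrates to kBT/2 per degree of freedom", {
  bun <- bundle_cache()
  res <- photopull:::run_md(bun, ff_params(),
                            integrator_params(k_bt = 0.52, seed = 3),
                            1e5, 1000)
  tr <- tibble::as_tibble(res$trace)
  ke_dof <- mean(tr$kinetic[tr$step > 2e4]) / (3 * nrow(bun))
  expect_equal(ke_dof, 0.26, tolerance = 0.02 / 0.26)
})

test_that("NVE dynamics conserves energy near the native minimum", {
  ch <- hairpin_chain(50)
  set.seed(11)
  pos <- photopull:::chain_positions(ch) + matrix(rnorm(150, 0, 0.003), 50, 3)
  res <- photopull:::run_md(ch, ff_params(),
                            integrator_params(gamma_fs = 0, k_bt = 0,
                                              seed = 1),
                            1e4, 100, positions = pos)
  tr <- tibble::as_tibble(res$trace)
  etot <- tr$kinetic + tr$v_bb + tr$v_nat + tr$v_non + tr$v_chir + tr$v_membr
  expect_lt(max(etot) - min(etot), 1e-2)
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  ch <- relaxed_helix_chain(30)
  integ <- integrator_params(seed = 77)
  r1 <- photopull:::run_md(ch, ff_params(), integ, 2000, 100)
  r2 <- photopull:::run_md(ch, ff_params(), integ, 2000, 100)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$trace$q, r2$trace$q)
  r3 <- photopull:::run_md(ch, ff_params(),
                           integrator_params(seed = 78), 2000, 100)
  expect_false(identical(r1$positions, r3$positions))
})

test_that("equilibration keeps the fold at the working temperature and loses it
           far above", {
  bun <- bundle_cache()
  st <- equilibrate(bun, ff_params(), integrator_params(seed = 4),
                    n_steps = 3e5)
  expect_gt(st$q, 0.8)

  expect_warning(
    st_hot <- equilibrate(bun, ff_params(),
                          integrator_params(k_bt = 2, seed = 4),
                          n_steps = 1e5),
    "unfolded")
  expect_lt(st_hot$q, 0.5)
})

test_that("a single native contact ruptures as one force peak that relaxes", {
  # bent three-bead chain with both bonds at d0 and the (1,3) contact along
  # the pulling axis, short enough (3.3 A) that the Lennard-Jones tail is
  # negligible before the backbone goes taut
  pos <- rbind(c(0, 0, 0), c(3.42, 0, 1.65), c(0, 0, 3.3))
  ct <- tibble::tibble(i = 1L, j = 3L, sigma = 3.3)
  ch <- chain_fixture(pos, contacts = ct)
  tr <- run_pulling(ch, ff_params(),
                    integrator_params(k_bt = 0.02, seed = 6),
                    pulling_protocol(v_pull_fs = 2.035e-6 * 50,
                                     k_pull = 0.2, pulled = 3, anchored = 1,
                                     max_displacement = 7, stride = 100),
                    stop_when_detached = FALSE)
  peak <- max(tr$force)
  # analytic LJ rupture force (max attractive slope) plus spring/noise slack
  f_lj <- 2.6899 / ct$sigma  # 12*(7/13)^(13/6) - 6*(7/13)^(7/6) in eps/sigma
  expect_equal(peak, f_lj, tolerance = 0.35)
  i_peak <- which.max(tr$force)
  expect_lt(min(tr$force[i_peak:nrow(tr)]), 0.4 * peak)
  ev <- detect_events(tr, min_force = 0.25)
  expect_equal(nrow(ev), 1)
})

test_that("event detection responds to drops, not monotone rises", {
  rising <- tibble::tibble(step = 1:200, displacement_A = 1:200,
                           force = seq(0, 4, length.out = 200),
                           n_unfolded = 0)
  expect_equal(nrow(detect_events(rising, smooth_window = 1)), 0)

  saw <- tibble::tibble(step = 1:300, displacement_A = 1:300,
                        force = rep(c(seq(0.1, 3, length.out = 80),
                                      seq(0.2, 0.05, length.out = 20)), 3),
                        n_unfolded = rep(c(rep(0, 80), rep(10, 20)), 3) +
                          rep(c(0, 10, 20), each = 100))
  ev <- detect_events(saw, smooth_window = 1, min_force = 1)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$n_unfolded, c(0, 10, 20))

  empty <- tibble::tibble(step = numeric(), displacement_A = numeric(),
                          force = numeric(), n_unfolded = numeric())
  expect_equal(nrow(detect_events(empty)), 0)
})

test_that("cantilever displacement advances at the pulling velocity", {
  ch <- relaxed_helix_chain(12)
  pr <- pulling_protocol(v_pull_fs = 2.035e-6, max_displacement = 0.5,
                         stride = 1000)
  tr <- run_pulling(ch, ff_params(), integrator_params(k_bt = 0, seed = 1),
                    protocol = pr)
  # displacement = v * dt * steps exactly
  expect_equal(tr$displacement_A,
               tr$step * 2.035e-6 * 15, tolerance = 1e-12)
})

test_that("melting scan localises the unfolding temperature", {
  ch <- relaxed_helix_chain(40)
  # grid entirely below any transition: q stays high, no crossing
  expect_error(
    melting_scan(ch, ff_params(), integrator_params(seed = 2),
                 temperatures = c(0.05, 0.1), replicas = 1, n_steps = 2e4,
                 stride = 1000),
    "widen")
})
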