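test_that("helix axis is the principal direction, oriented N to C", {
  hx <- helix_coords(180)  # long ideal helix: axis converges onto z
  ax <- helix_axis(hx)
  expect_equal(abs(sum(ax * c(0, 0, 1))), 1, tolerance = 1e-6)
  expect_gt(ax[3], 0)

  R <- rotation_matrix(c(1, 1, 0), 0.8)
  ax_rot <- helix_axis(hx %*% t(R))
  expect_equal(as.numeric(ax_rot), as.numeric(R %*% ax), tolerance = 1e-6)

  set.seed(6)
  hx40 <- helix_coords(40)
  noisy <- hx40 + matrix(rnorm(120, 0, 0.3), 40, 3)
  ang <- acos(abs(sum(helix_axis(noisy) * c(0, 0, 1))))
  expect_lt(ang, 2 * pi / 180)

  expect_error(helix_axis(hx[1:3, ]), "at least 4")
  expect_silent(helix_axis(cbind(1:10, 1:10, 1:10)))  # rank-1 cloud is fine
  expect_error(helix_axis(matrix(1, 5, 3)), "degenerate")
})

test_that("angles between axes cover the full range", {
  expect_equal(helix_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(helix_angle(c(0, 0, 1), c(0, 0, -1)), pi)
  expect_equal(helix_angle(c(1, 0, 0), c(0, 1, 0)), pi / 2)
})

test_that("Shrake-Rupley areas: isolated spheres, additivity, and the
           sampling oracle", {
  one <- sasa(tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7))
  expect_equal(one$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-3)

  two_far <- sasa(tibble::tibble(x = c(0, 100), y = 0, z = 0,
                                 radius = c(1.7, 1.5)))
  expect_equal(two_far$area, 4 * pi * (c(1.7, 1.5) + 1.4)^2,
               tolerance = 1e-3)

  toy <- tibble::tibble(x = c(0, 2.5, 1.2), y = c(0, 0, 2.0),
                        z = c(0, 0, 0.5), radius = c(1.7, 1.5, 1.6))
  sr <- sasa(toy, n_points = 960)
  expect_true(all(sr$area < 4 * pi * (toy$radius + 1.4)^2))
  # independent oracle: uniform random directions on each expanded sphere
  set.seed(1)
  mc <- vapply(1:3, function(i) {
    n <- 50000
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    r <- toy$radius[i] + 1.4
    pts <- sweep(v * r, 2, c(toy$x[i], toy$y[i], toy$z[i]), "+")
    covered <- rep(FALSE, n)
    for (j in setdiff(1:3, i)) {
      rj <- toy$radius[j] + 1.4
      covered <- covered | ((pts[, 1] - toy$x[j])^2 +
                              (pts[, 2] - toy$y[j])^2 +
                              (pts[, 3] - toy$z[j])^2 < rj^2)
    }
    4 * pi * r^2 * mean(!covered)
  }, numeric(1))
  expect_lt(max(abs(sr$area - mc) / mc), 0.02)

  expect_error(sasa(tibble::tibble(x = 0, y = 0, z = 0, elem = "Zz")),
               "radius")
})

test_that("transmembrane SASA split is pure bookkeeping", {
  areas <- c(10, 20, 30, 40, 50)
  hphob <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  tm <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  sp <- transmembrane_sasa_split(areas, hphob, tm)
  expect_equal(sp$a_hphob, 30)
  expect_equal(sp$a_hphil, 40)
  expect_equal(transmembrane_sasa_split(areas, hphob, rep(FALSE, 5)),
               tibble::tibble(a_hphob = 0, a_hphil = 0))
  sp2 <- transmembrane_sasa_split(areas, rep(TRUE, 5), tm)
  expect_equal(sp2$a_hphil, 0)
})

test_that("cholesterol model validates its anchors", {
  expect_error(cholesterol_model(c(0, 0.5), c(0.1, 0.2)), "vanish")
  expect_error(cholesterol_model(c(0, 0.3, 0.5), c(0, 0.2, 0.1)),
               "monotone")
  m <- illustrative_cholesterol_model()
  expect_equal(m$coef(0), 0)
  expect_true(all(diff(m$coef(seq(0, 0.5, 0.1))) > 0))
})

test_that("reweighting conserves probability and follows the Boltzmann form", {
  en <- generate_ensemble(5000, seed = 4)
  m <- illustrative_cholesterol_model()
  rw0 <- reweight_ensemble(en, m, c = 0)
  expect_equal(rw0$weight, rep(1 / 5000, 5000))
  for (cc in c(0.1, 0.3, 0.5)) {
    w <- reweight_ensemble(en, m, c = cc)$weight
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  # two frames differing by dA: weight ratio exp(g(c) dA)
  two <- tibble::tibble(frame = 1:2, alpha_rad = c(2.5, 2.8),
                        a_hphob = c(4000, 4150), a_hphil = c(1000, 950))
  w <- reweight_ensemble(two, m, c = 0.4, a_ref = 4000)$weight
  expect_equal(w[2] / w[1], exp(m$coef(0.4) * 150), tolerance = 1e-10)
})

test_that("population ratio is 1 at zero cholesterol and declines when the
           active state exposes less hydrophobic area", {
  en <- generate_ensemble(8000, seed = 7)
  pr <- population_ratio(en, c = c(0, 0.1, 0.25, 0.5))
  expect_equal(pr$ratio[1], 1)
  expect_true(all(diff(pr$ratio) < 0))
  expect_lt(pr$ratio[4], 0.6)

  # identical hydrophobic-area distributions in both states: ratio stays 1
  sym <- tibble::tibble(frame = 1:1000,
                        alpha_rad = rep(c(2.0, 3.0), 500),
                        a_hphob = rep(c(4000, 4100), each = 500),
                        a_hphil = 1000)
  pr_sym <- population_ratio(sym, c = c(0, 0.3, 0.5),
                             split = list(meta = c(0, 2.4),
                                          rhod = c(2.4, pi)))
  expect_equal(pr_sym$ratio, c(1, 1, 1), tolerance = 1e-10)

  empty_state <- tibble::tibble(frame = 1:10, alpha_rad = rep(3, 10),
                                a_hphob = 4000, a_hphil = 1000)
  expect_error(population_ratio(empty_state), "nonzero")
})

test_that("the synthetic ensemble has the designed statistical structure", {
  en <- generate_ensemble(10000, seed = 4)
  expect_identical(en, generate_ensemble(10000, seed = 4))
  expect_true(all(en$alpha_rad >= 0 & en$alpha_rad <= pi))
  expect_true(all(en$a_hphob >= 0))
  d <- stats::density(en$alpha_rad, bw = 0.05)
  expect_lt(abs(d$x[which.max(d$y)] - 2.72), 0.02)
  expect_gt(stats::cor(en$a_hphob, -en$a_hphil), 0)
  # hydrophobic area peaks at the angle mode
  near <- abs(en$alpha_rad - 2.72) < 0.05
  far <- abs(en$alpha_rad - 2.72) > 0.3
  expect_gt(mean(en$a_hphob[near]), mean(en$a_hphob[far]))
})

test_that("state split locates the valley of a bimodal angle distribution", {
  set.seed(2)
  bi <- tibble::tibble(frame = 1:2000,
                       alpha_rad = c(rnorm(1000, 1.8, 0.12),
                                     rnorm(1000, 2.7, 0.12)),
                       a_hphob = 4000, a_hphil = 1000)
  thr <- state_split_threshold(bi)
  expect_gt(thr, 2.0)
  expect_lt(thr, 2.5)
  uni <- generate_ensemble(3000, seed = 3)
  expect_error(state_split_threshold(uni), "unimodal")
})
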