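test_that("two-column files read with unit normalisation; bad files skipped", {
  d <- withr::local_tempdir()
  write.table(data.frame(x = c(1, 2, 3), f = c(0.01, 0.02, 0.03)),
              file.path(d, "a.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  writeLines(c("tss\tforce", "1\t10", "2\t20", "junk\trow", "3\t30"),
             file.path(d, "b.tsv"))
  writeLines(character(0), file.path(d, "empty.tsv"))
  expect_warning(
    expect_warning(cv <- read_fd_curves(d, dialect = list(force_unit = "nN")),
                   "empty"),
    "non-numeric")
  expect_equal(sort(unique(cv$curve_id)), c("a", "b"))
  expect_equal(cv$force_pN[cv$curve_id == "a"], c(10, 20, 30))
  expect_equal(cv$force_pN[cv$curve_id == "b"], c(1e4, 2e4, 3e4))
  expect_error(read_fd_curves(file.path(d, "a.tsv"),
                              dialect = list(force_unit = "mN")), "unknown")
})

test_that("peak detection and WLC fitting recover a noiseless sawtooth", {
  w <- wlc_params()
  tpl <- curve_template(lc_nm = c(80, 140), prob = c(1, 1),
                        force_mean_pN = 90, force_sd_pN = 0,
                        noise_sd_pN = 0, offset_nm = 0,
                        drift_sd_pN_per_nm = 0, wlc = w)
  set.seed(2)
  g <- generate_curve(tpl)
  pk <- detect_fd_peaks(g$trace, w)
  expect_equal(nrow(pk), 2)
  expect_lt(max(abs(sort(pk$lc_nm) - c(80, 140))), 1)
  expect_equal(pk$force_pN, c(90, 90), tolerance = 0.05)
})

test_that("pure noise produces no peaks above the force threshold", {
  set.seed(8)
  noise <- tibble::tibble(tss_nm = seq(0.5, 150, by = 0.5),
                          force_pN = rnorm(300, 0, 5))
  expect_equal(nrow(detect_fd_peaks(noise, min_force = 35)), 0)
})

test_that("single-peak rupture force matches the trace maximum", {
  w <- wlc_params()
  tpl <- curve_template(lc_nm = 100, prob = 1, force_mean_pN = 80,
                        force_sd_pN = 0, noise_sd_pN = 0, offset_nm = 0,
                        drift_sd_pN_per_nm = 0, wlc = w)
  set.seed(4)
  g <- generate_curve(tpl)
  pk <- detect_fd_peaks(g$trace, w)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$lc_nm, 100, tolerance = 0.02)
  expect_equal(pk$force_pN, max(g$trace$force_pN), tolerance = 2 / 80)
})

test_that("curve filter enforces the force floor and the last-peak window", {
  peaks <- dplyr::bind_rows(
    tibble::tibble(curve_id = "weak", lc_nm = 120, force_pN = 30),
    tibble::tibble(curve_id = "long", lc_nm = c(100, 250),
                   force_pN = c(60, 80)),
    tibble::tibble(curve_id = "good", lc_nm = c(100, 180),
                   force_pN = c(50, 80)))
  expect_equal(filter_curves(peaks, 35, c(0, 200)), "good")
  expect_equal(sort(filter_curves(peaks, 35, c(0, 300))), c("good", "long"))
  expect_equal(sort(filter_curves(peaks, 25, c(0, 200))), c("good", "weak"))
  expect_equal(filter_curves(peaks[0, ]), character())
})

test_that("clustering tolerates 5 nm shifts but separates larger ones", {
  tpl <- smfs_templates()$cng_closed
  ds <- generate_dataset(tpl, n = 15, seed = 31)
  base <- ds$curves
  shifted <- base
  shifted$tss_nm <- shifted$tss_nm + 4
  shifted$curve_id <- paste0(shifted$curve_id, "_s4")
  mem <- cluster_curves(dplyr::bind_rows(base, shifted), bin_width = 1,
                        lc_range = c(0, 320))
  ids <- unique(base$curve_id)
  expect_equal(mem$cluster[match(paste0(ids, "_s4"), mem$curve_id)],
               mem$cluster[match(ids, mem$curve_id)])

  far <- base
  far$tss_nm <- far$tss_nm + 20
  far$curve_id <- paste0(far$curve_id, "_s20")
  mem2 <- cluster_curves(dplyr::bind_rows(base, far), bin_width = 1,
                         lc_range = c(0, 340))
  expect_true(all(mem2$cluster[match(paste0(ids, "_s20"), mem2$curve_id)] !=
                    mem2$cluster[match(ids, mem2$curve_id)]))

  expect_error(cluster_curves(base[base$curve_id == ids[1], ]), "two curves")
  flat <- tibble::tibble(curve_id = rep(c("u", "v"), each = 5),
                         tss_nm = rep(1:5, 2), force_pN = 0)
  expect_error(cluster_curves(flat), "empty")
})

test_that("clustering is invariant to curve order", {
  ds <- generate_dataset(smfs_templates()$cng_closed, n = 12, seed = 5)
  m1 <- cluster_curves(ds$curves)
  perm <- ds$curves[order(rev(ds$curves$curve_id), ds$curves$tss_nm), ]
  m2 <- cluster_curves(perm)
  j <- dplyr::inner_join(m1, m2, by = "curve_id")
  # same partition up to label names
  expect_equal(length(unique(paste(j$cluster.x, j$cluster.y))),
               length(unique(j$cluster.x)))
})

test_that("occurrence probabilities are exact member fractions", {
  set.seed(10)
  n <- 36
  peaks <- dplyr::bind_rows(
    tibble::tibble(curve_id = sprintf("c%02d", 1:34), lc_nm = rnorm(34, 100, 1.5),
                   force_pN = 90),
    tibble::tibble(curve_id = sprintf("c%02d", 1:36), lc_nm = rnorm(36, 150, 1.5),
                   force_pN = 85))
  mem <- tibble::tibble(curve_id = sprintf("c%02d", 1:36), cluster = 1,
                        shift_nm = 0)
  rep <- peak_statistics(peaks, mem)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$occurrence, c(34 / 36, 1))
  expect_true(all(rep$occurrence >= 0 & rep$occurrence <= 1))
  expect_equal(rep$n_curves, c(34L, 36L))
})

test_that("occurrence recovery matches the binomial rate at n = 200", {
  tpl <- curve_template(lc_nm = c(80, 160), prob = c(0.6, 1),
                        force_mean_pN = 100, force_sd_pN = 20,
                        lc_sd_nm = 3, noise_sd_pN = 8)
  ds <- generate_dataset(tpl, n = 200, seed = 99)
  an <- analyze_curves(ds$curves, bin_width = 3, lc_range = c(0, 250),
                       last_lc_range = c(100, 250))
  rep <- tidy(an)
  g <- glance(an$report)
  main <- g$cluster[which.max(g$n_members)]
  mm <- rep[rep$cluster == main, ]
  p80 <- mm$occurrence[which.min(abs(mm$lc_mean_nm - 80))]
  # 3 binomial SEs at p = 0.6, n = 200 is 0.10
  expect_lt(abs(p80 - 0.6), 0.11)
})

test_that("cluster occurrence fractions partition the curves", {
  ds <- generate_dataset(smfs_templates()$cng_closed, n = 30, seed = 12)
  an <- analyze_curves(ds$curves, bin_width = 3, lc_range = c(0, 320),
                       last_lc_range = c(200, 300))
  frac <- attr(an$report, "cluster_fraction")
  expect_lte(sum(frac), 1 + 1e-12)
  expect_equal(sum(attr(an$report, "cluster_sizes")$n_members),
               an$n_filtered)
  expect_s3_class(tidy(an), "tbl_df")
  expect_equal(glance(an)$n_filtered, an$n_filtered)
})
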