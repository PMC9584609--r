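test_that("the radial distribution profile evaluates exactly on a single pair", {
  area <- 25 # um^2 (5 x 5 um ROI)
  g <- tibble::tibble(x = 2500, y = 2500)
  r <- tibble::tibble(x = 2550, y = 2500)
  prof <- rdf(g, r, area_um2 = area)
  hit <- prof$r_min == 40
  expect_equal(prof$g[hit], area * 1e6 / (pi * 1 * 1 * (2 * 40 + 20) * 20))
  expect_true(all(prof$g[!hit] == 0))
  # no red clusters: flat zero with the empty flag
  prof0 <- rdf(g, r[0, ], area_um2 = area)
  expect_true(all(prof0$g == 0))
  expect_true(attr(prof0, "empty"))
})

test_that("independent homogeneous channels give g near 1", {
  set.seed(51)
  side <- 8000
  # green restricted to an interior margin >= r_max so annuli stay inside
  n_g <- 3000; n_r <- 6000
  g <- tibble::tibble(x = runif(n_g, 400, side - 400),
                      y = runif(n_g, 400, side - 400))
  r <- tibble::tibble(x = runif(n_r, 0, side), y = runif(n_r, 0, side))
  prof <- rdf(g, r, area_um2 = side^2 / 1e6)
  # per-bin tolerance from the Poisson error of the expected annulus count
  lam <- n_r / side^2
  expected_counts <- n_g * lam * pi * (2 * prof$r_min + 20) * 20
  expect_true(all(abs(prof$g - 1) < 4 / sqrt(expected_counts)))
  expect_equal(mean(prof$g), 1, tolerance = 0.02)
})

test_that("correlation length is the outer edge of the initial enriched run", {
  prof <- tibble::tibble(r_min = seq(0, 380, 20), r_max = seq(20, 400, 20))
  prof$g <- c(8, 5, 1.0, 0.9, rep(1, 16))
  expect_equal(correlation_length(prof), 40)
  # enrichment out to 100 nm, as on the calibration profiles
  prof$g <- c(6, 4, 2.5, 1.6, 1.2, 0.95, 1.02, rep(1, 13))
  expect_equal(correlation_length(prof), 100)
  prof$g <- rep(1, 20)
  expect_warning(len <- correlation_length(prof))
  expect_true(is.na(len))
  prof$g <- c(3, rep(0.9, 19))
  expect_equal(correlation_length(prof), 20)
})

test_that("colocalization counts use a strict distance threshold", {
  g <- tibble::tibble(x = c(0, 1000), y = c(0, 0))
  r <- tibble::tibble(x = c(0, 1100), y = c(0, 0))
  cc <- colocalize(g, r, d = 100)
  expect_equal(attr(cc, "n_m"), 2L)
  expect_equal(attr(cc, "n_mf"), 1L) # second red at exactly d: not colocalized
  expect_equal(cc$nearest_red, c(0, 100))
  # twin at distance zero for every green
  cc2 <- colocalize(g, g, d = 100)
  expect_equal(attr(cc2, "n_mf"), 2L)
  # monotone in d
  set.seed(9)
  g3 <- tibble::tibble(x = runif(200, 0, 5000), y = runif(200, 0, 5000))
  r3 <- tibble::tibble(x = runif(200, 0, 5000), y = runif(200, 0, 5000))
  counts <- vapply(c(50, 100, 200, 400),
                   function(dd) attr(colocalize(g3, r3, dd), "n_mf"), 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("chance colocalization of independent channels follows the Poisson law", {
  set.seed(61)
  side <- 40000; d <- 100
  lam_r <- 0.8 # per um^2
  n_r <- rpois(1, lam_r * side^2 / 1e6)
  g <- tibble::tibble(x = runif(3000, 500, side - 500),
                      y = runif(3000, 500, side - 500))
  r <- tibble::tibble(x = runif(n_r, 0, side), y = runif(n_r, 0, side))
  frac <- attr(colocalize(g, r, d), "n_mf") / 3000
  expect_equal(frac, p_background(d, lam_r), tolerance = 0.25)
  expect_lt(abs(frac - p_background(d, lam_r)),
            3 * sqrt(p_background(d, lam_r) / 3000))
})

test_that("background probability and corrected ratio evaluate exactly", {
  expect_equal(p_background(0, 5), 0)
  expect_equal(p_background(100, 0), 0)
  expect_equal(p_background(100, 0.8), 1 - exp(-pi * 0.01 * 0.8))
  expect_error(p_background(-1, 1), class = "dcc_domain_error")
  expect_equal(corrected_ratio(100, 26, 0), 0.26)
  expect_equal(corrected_ratio(100, 5, 0.05), 0) # pure background
  p_rb <- 0.0248
  expect_equal(corrected_ratio(1000, 260, p_rb),
               (260 - 1000 * p_rb) / (1000 - 1000 * p_rb))
  expect_equal(round(corrected_ratio(1000, 260, p_rb), 4), 0.2412)
  expect_warning(out <- corrected_ratio(100, 1, 0.05))
  expect_equal(out, 0)
  expect_error(corrected_ratio(10, 10, 1), class = "dcc_domain_error")
})

test_that("per-cell analysis recovers the detection probability from a scene", {
  sc <- quick_scene(seed = 71, oligomer = 2, background_red = 0,
                    field = 20000, density = 1.5)
  res <- colocalization_ratios(sc$green, sc$red, sc$rois)
  expect_equal(res$p_rb, 0) # no background: correction reduces to the raw ratio
  expect_equal(res$pd, res$n_mf / res$n_m)
  # within 3 binomial SE of the forward model value (small conditioning bias
  # from marker-side selection is well below this at p_marker = 0.8)
  e <- pd_modified(2, 0.17, 0.30)
  se <- sqrt(e * (1 - e) / res$n_m)
  expect_lt(abs(res$pd - e), 3 * se + 0.01)
})

test_that("identical scenes give identical per-cell results", {
  r1 <- colocalization_ratios(quick_scene(81)$green, quick_scene(81)$red,
                              quick_scene(81)$rois)
  r2 <- colocalization_ratios(quick_scene(81)$green, quick_scene(81)$red,
                              quick_scene(81)$rois)
  expect_identical(r1, r2)
})
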