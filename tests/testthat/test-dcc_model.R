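test_that("detection probabilities evaluate exactly", {
  expect_equal(pd_simple(1, 0.3), 0.3)
  expect_equal(pd_simple(3, 0), 0)
  expect_equal(pd_simple(4, 0.1), 1 - 0.9^4)
  expect_equal(round(pd_simple(4, 0.1), 4), 0.3439)
  expect_error(pd_simple(0, 0.5), class = "dcc_domain_error")
  # n = 1 reduces to p for any double-loss level
  for (m in c(0, 0.3, 0.8)) expect_equal(pd_modified(1, 0.42, m), 0.42)
  # m = 0 reduces to the simple model
  expect_equal(pd_modified(1:4, 0.17, 0), pd_simple(1:4, 0.17))
  expect_equal(round(pd_modified(2, 0.17, 0.30), 4), 0.2460)
  expect_error(pd_modified(2, 0.2, 1), class = "dcc_domain_error")
})

test_that("the double-loss closed form matches a subunit-level Monte-Carlo oracle", {
  set.seed(91)
  for (case in list(c(2, 0.17, 0.30), c(3, 0.3, 0.6), c(5, 0.1, 0.3))) {
    mc <- mc_pd_modified(case[1], case[2], case[3], draws = 4e5)
    expect_lt(abs(pd_modified(case[1], case[2], case[3]) - mc$est), 4 * mc$se)
  }
})

test_that("detection probability increases with n and with p", {
  for (p in c(0.1, 0.3, 0.6)) {
    for (m in c(0, 0.3, 0.7)) {
      e <- pd_modified(1:6, p, m)
      expect_true(all(diff(e) > 0))
    }
  }
  for (n in 1:4) {
    e <- pd_modified(n, seq(0.05, 0.95, 0.05), 0.3)
    expect_true(all(diff(e) > 0))
  }
})

test_that("grid fitting recovers noise-free parameters exactly", {
  truth <- tibble::tibble(protein = paste0("r", 1:5), n = c(1, 2, 2, 3, 4),
                          pd = pd_modified(c(1, 2, 2, 3, 4), 0.17, 0.30))
  fit <- fit_dcc(truth, model = "modified", use = "means")
  expect_equal(fit$m, 0.30)
  expect_equal(fit$p, 0.17)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # simple model, single monomeric reference
  fit1 <- fit_dcc(tibble::tibble(n = rep(1, 4), pd = rep(0.17, 4)),
                  model = "simple")
  expect_equal(fit1$p, 0.17)
  expect_error(fit_dcc(tibble::tibble(n = 1, pd = 0.2)[0, ]),
               class = "dcc_fit_error")
  expect_error(fit_dcc(tibble::tibble(n = rep(1, 3), pd = 0.2),
                       model = "modified"),
               class = "dcc_fit_error")
})

test_that("tidy, glance and autoplot work on fits", {
  fit <- fit_dcc(reference_ratios(), model = "modified", use = "means")
  td <- tidy(fit)
  expect_equal(td$term, c("m", "p"))
  expect_equal(glance(fit)$nobs, 5)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the mismatch coefficient matches direct arithmetic", {
  expect_equal(mismatch(c(0.2, 0.3), 0.25), 0)
  expect_equal(mismatch(c(0.2, 0.3), 0.35), 1 - 0.005 / 0.025)
  expect_equal(mismatch(c(0.2, 0.3), 50), 1, tolerance = 1e-4)
  expect_equal(mismatch(rep(0.2, 3), 0.2), 0) # both sums zero
  expect_error(mismatch(0.2, 0.2), class = "dcc_domain_error")
  # asymmetry: appending an observation at the sample mean shifts M^2
  # whenever E differs from the mean, and only then
  x <- c(0.2, 0.3)
  expect_false(isTRUE(all.equal(mismatch(c(x, 0.25), 0.35), mismatch(x, 0.35))))
  expect_equal(mismatch(c(x, 0.25), 0.25), mismatch(x, 0.25))
})

test_that("K-S comparison flags separated samples at the corrected level", {
  same <- ks_compare(1:10 / 10, 1:10 / 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$alpha_adj, 0.0125)
  apart <- ks_compare(runif(20, 0, 0.3), runif(20, 0.5, 0.8))
  expect_equal(apart$statistic, 1)
  expect_true(apart$reject)
})

test_that("state separation behaves across the parameter plane", {
  surf <- sensitivity_surface(n_max = 4, p_grid = c(0, 0.3, 0.9),
                              m_grid = c(0, 0.3))
  at <- function(m, p) surf$separation[surf$m == m & surf$p == p]
  # m = 0, p = 0.3: gaps 0.21, 0.147, 0.1029 -> min 0.1029
  expect_equal(at(0, 0.3), 0.1029, tolerance = 1e-9)
  expect_equal(at(0, 0), 0)
  # saturation: higher-state gaps shrink as p grows
  expect_lt(at(0, 0.9), at(0, 0.3))
})

test_that("bootstrap classification identifies synthetic oligomeric states", {
  cal <- simulate_calibration(n_list = c(1, 2, 2, 3, 4),
                              cells_per_protein = 25, seed = 101)
  poi2 <- simulate_calibration(n_list = 2, cells_per_protein = 25, seed = 102)
  cl <- classify_dcc(poi2$pd, cal, B = 2000, seed = 103)
  expect_equal(cl$n_star, 2)
  expect_lt(cl$states$m2_lo[2], 0.05) # CI reaches near-zero mismatch
  expect_true(all(cl$states$m2 >= 0 - 1e-9))
  expect_false(cl$ks$reject[cl$ks$ref_n == 2][1])
  td <- tidy(cl)
  expect_equal(nrow(td), 4)
  expect_s3_class(autoplot(cl), "ggplot")
  # mean ratio near the dimer prediction classifies as a dimer; near the
  # monomer prediction as a monomer (means as reported for the anion
  # exchanger and the vesicular transporter families). Calibration is
  # nearly noise-free so the expected ratios sit at E(n; 0.30, 0.17).
  cal0 <- simulate_calibration(cells_per_protein = 20, mean_n_m = 2e5,
                               cell_sd = 1e-4, seed = 104)
  set.seed(104)
  poi_a3 <- pmin(1, pmax(0, rnorm(26, 0.214, 0.05)))
  expect_equal(classify_dcc(poi_a3, cal0, B = 1000, seed = 105)$n_star, 2)
  poi_vg <- pmin(1, pmax(0, rnorm(23, 0.170, 0.05)))
  expect_equal(classify_dcc(poi_vg, cal0, B = 1000, seed = 106)$n_star, 1)
})

test_that("classification reproducibility under a fixed seed", {
  cal <- simulate_calibration(cells_per_protein = 15, seed = 111)
  poi <- simulate_calibration(n_list = 3, cells_per_protein = 15, seed = 112)
  a <- classify_dcc(poi$pd, cal, B = 1000, seed = 7)
  b <- classify_dcc(poi$pd, cal, B = 1000, seed = 7)
  expect_identical(a$states, b$states)
})
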