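make_track_table <- function(pos_fun, n_frames = 100, beads = 1) {
  rows <- purrr::map_dfr(seq_len(beads), function(b) {
    p <- pos_fun(b, seq_len(n_frames))
    tibble::tibble(frame = seq_len(n_frames), x = p$x, y = p$y)
  })
  loc_table(rows$frame, rows$x, rows$y, channel = "bead", n_frames = n_frames)
}

test_that("bead tracking reproduces stationary and moving beads exactly", {
  tb <- make_track_table(function(b, k) list(x = rep(5000, length(k)),
                                             y = rep(5000, length(k))))
  tr <- track_beads(tb, tibble::tibble(x = 5010, y = 4990))
  expect_true(all(tr$detected))
  expect_equal(tr$x, rep(5000, 100))
  tb2 <- make_track_table(function(b, k) list(x = 5000 + 2 * (k - 1),
                                              y = 5000 - (k - 1)))
  tr2 <- track_beads(tb2, tibble::tibble(x = 5000, y = 5000))
  expect_equal(tr2$x, 5000 + 2 * (0:99))
  expect_equal(tr2$y, 5000 - (0:99))
})

test_that("ambiguous seeds and vanishing beads are rejected", {
  tb <- make_track_table(function(b, k) list(x = rep(5000, length(k)),
                                             y = rep(5000, length(k))))
  expect_error(track_beads(tb, tibble::tibble(x = c(5000, 5100), y = c(5000, 5000))),
               class = "dcc_tracking_error")
  # bead missing in 20% of frames
  tb3 <- tb[tb$frame <= 80, ]
  attr(tb3, "n_frames") <- 100L
  expect_error(track_beads(tb3, tibble::tibble(x = 5000, y = 5000)),
               class = "dcc_tracking_error")
})

test_that("drift estimate is the bead-mean displacement from frame 1", {
  tb <- make_track_table(function(b, k) list(x = 5000 * b + 2 * (k - 1),
                                             y = 3000 * b - (k - 1)), beads = 2)
  tr <- track_beads(tb, tibble::tibble(x = c(5000, 10000), y = c(3000, 6000)))
  dr <- estimate_drift(tr)
  expect_equal(dr$dx, 2 * (0:99))
  expect_equal(dr$dy, -(0:99))
  expect_equal(unlist(dr[1, c("dx", "dy")]), c(dx = 0, dy = 0))
  # beads at different origins with the same motion give the same trajectory
  tr1 <- track_beads(make_track_table(function(b, k)
    list(x = 1000 + 2 * (k - 1), y = 1000 - (k - 1))),
    tibble::tibble(x = 1000, y = 1000))
  expect_equal(estimate_drift(tr1)$dx, dr$dx)
})

test_that("averaging over beads shrinks drift variance as 2 sigma^2 / B", {
  set.seed(11)
  sigma <- 3; B <- 5; reps <- 1500
  # across replicates, the frame-2 drift estimate carries jitter from both
  # the reference frame and the current frame: var = 2 sigma^2 / B
  d2 <- replicate(reps, {
    tracks <- tibble::tibble(bead = rep(seq_len(B), each = 2),
                             frame = rep(1:2, B),
                             x = rnorm(2 * B, 0, sigma),
                             y = rnorm(2 * B, 0, sigma), detected = TRUE)
    estimate_drift(tracks)$dx[2]
  })
  expect_equal(var(d2), 2 * sigma^2 / B, tolerance = 0.15)
})

test_that("drift subtraction restores frame-1 positions and honors the channel offset", {
  drift <- tibble::tibble(frame = 1:50, dx = 3 * (0:49), dy = -(0:49))
  tb <- loc_table(1:50, 1000 + 3 * (0:49), 2000 - (0:49))
  out <- apply_drift(tb, drift)
  expect_equal(out$x, rep(1000, 50))
  expect_equal(out$y, rep(2000, 50))
  # zero trajectory is the identity
  zero <- tibble::tibble(frame = 1:50, dx = 0, dy = 0)
  expect_equal(apply_drift(tb, zero)$x, tb$x)
  # a green final drift of (10, -5) shifts the red table by the extra (-10, 5)
  green_traj <- tibble::tibble(frame = 1:50, dx = seq(0, 10, length.out = 50),
                               dy = seq(0, -5, length.out = 50))
  red <- apply_drift(tb, zero, channel_offset = green_traj)
  expect_equal(red$x, tb$x - 10)
  expect_equal(red$y, tb$y + 5)
  expect_error(apply_drift(loc_table(60L, 1, 1), zero), class = "dcc_index_error")
})

test_that("chained green/red corrections co-register a drift-only bead pair", {
  b <- simulate_beads(n_beads = 9, frames = 50, bead_sigma = 0,
                      drift_sigma = 2, drift_linear = c(0.5, -0.2),
                      lca = NULL, seed = 21)
  tr_g <- track_beads(b$green, b$truth$beads)
  tr_r <- track_beads(b$red, b$truth$beads)
  g <- apply_drift(b$green, estimate_drift(tr_g))
  r <- apply_drift(b$red, estimate_drift(tr_r),
                   channel_offset = estimate_drift(tr_g))
  # all localizations collapse onto the true bead positions
  expect_equal(g$x, b$truth$beads$x[g$bead], tolerance = 1e-9)
  expect_equal(r$x, b$truth$beads$x[r$bead], tolerance = 1e-9)
  expect_equal(r$y, b$truth$beads$y[r$bead], tolerance = 1e-9)
})

test_that("bead pairing forms mutual pairs within the threshold only", {
  g <- tibble::tibble(x = c(1000, 2000, 3000), y = c(1000, 1000, 1000))
  r <- tibble::tibble(x = c(1000, 2050, 3250), y = c(1000, 1000, 1000))
  pr <- pair_beads(g, r, max_pair_dist = 200)
  expect_equal(nrow(pr), 2) # third pair is 250 nm apart
  expect_equal(pr$ax, c(0, 50))
  expect_equal(attr(pr, "n_unpaired"), 2L)
})

test_that("the linear aberration fit inverts an exact linear field", {
  set.seed(3)
  K <- 0.02; x0 <- 1000; y0 <- 2000
  g <- tibble::tibble(x = runif(50, 0, 2e4), y = runif(50, 0, 2e4))
  # forward field defined on red coordinates: r = g + K (r - c)
  r <- tibble::tibble(x = (g$x - K * x0) / (1 - K), y = (g$y - K * y0) / (1 - K))
  fit <- fit_lca_linear(pair_beads(g, r, max_pair_dist = 500))
  expect_equal(fit$K, K, tolerance = 1e-9)
  expect_equal(fit$x0, x0, tolerance = 1e-6)
  expect_equal(fit$y0, y0, tolerance = 1e-6)
  red_tb <- loc_table(rep(1L, 50), r$x, r$y, channel = "red")
  corr <- correct_lca(red_tb, fit)
  expect_equal(corr$x, g$x, tolerance = 1e-6)
  expect_equal(corr$y, g$y, tolerance = 1e-6)
  # zero aberration gives K = 0 and the identity correction
  fit0 <- fit_lca_linear(pair_beads(g, g, max_pair_dist = 500))
  expect_equal(fit0$K, 0, tolerance = 1e-12)
  expect_equal(correct_lca(red_tb, fit0)$x, red_tb$x)
})

test_that("residual shift after the linear fit matches imposed noise", {
  set.seed(5)
  K <- 0.02; x0 <- 9000; y0 <- 11000; sigma <- 9
  g <- tibble::tibble(x = runif(400, 0, 2e4), y = runif(400, 0, 2e4))
  # pairs constructed directly from ground truth: this isolates the fit
  # from the bead-pairing step
  pairs <- tibble::tibble(
    gx = g$x, gy = g$y,
    rx = (g$x - K * x0) / (1 - K) + rnorm(400, 0, sigma),
    ry = (g$y - K * y0) / (1 - K) + rnorm(400, 0, sigma))
  pairs$ax <- pairs$rx - pairs$gx
  pairs$ay <- pairs$ry - pairs$gy
  fit <- fit_lca_linear(pairs)
  shift <- lca_shift(fit, pairs$rx, pairs$ry)
  resid <- c(pairs$ax - shift[, 1], pairs$ay - shift[, 2])
  expect_equal(sd(resid), sigma, tolerance = 0.1)
  expect_equal(fit$sigma_res, sigma, tolerance = 0.1)
})

test_that("the regional model averages per square and fills empty squares", {
  # uniform shift field: every square equals that shift
  g <- tidyr::expand_grid(x = seq(500, 9500, by = 1000),
                          y = seq(500, 9500, by = 1000))
  r <- tibble::tibble(x = g$x + 30, y = g$y - 10)
  pairs <- pair_beads(g, r, max_pair_dist = 200)
  reg <- fit_lca_regional(pairs, grid_edge = 1000, bounds = c(0, 1e4, 0, 1e4))
  expect_true(all(abs(reg$Ax - 30) < 1e-9))
  expect_true(all(abs(reg$Ay + 10) < 1e-9))
  # single populated square propagates everywhere
  one <- pair_beads(tibble::tibble(x = 500, y = 500),
                    tibble::tibble(x = 520, y = 500), max_pair_dist = 200)
  reg1 <- fit_lca_regional(one, grid_edge = 1000, bounds = c(0, 5000, 0, 5000))
  expect_true(all(abs(reg1$Ax - 20) < 1e-9))
  # dense sampling of a linear field: regional ~ linear within discretization
  set.seed(8)
  K <- 0.01; c0 <- 5000
  gd <- tibble::tibble(x = runif(3000, 0, 1e4), y = runif(3000, 0, 1e4))
  pd <- tibble::tibble(gx = gd$x, gy = gd$y,
                       rx = (gd$x - K * c0) / (1 - K),
                       ry = (gd$y - K * c0) / (1 - K))
  pd$ax <- pd$rx - pd$gx
  pd$ay <- pd$ry - pd$gy
  reg2 <- fit_lca_regional(pd, grid_edge = 1000, bounds = c(0, 1e4, 0, 1e4))
  lin <- fit_lca_linear(pd)
  probe <- tibble::tibble(x = runif(200, 1000, 9000), y = runif(200, 1000, 9000))
  d_reg <- lca_shift(reg2, probe$x, probe$y)
  d_lin <- lca_shift(lin, probe$x, probe$y)
  # agreement up to the grid discretization scale (field gradient K per nm
  # over one square edge)
  expect_lt(max(abs(d_reg - d_lin)), 1.5 * K * 1000)
  expect_lt(mean(abs(d_reg - d_lin)), 0.5 * K * 1000)
})

test_that("axial offset is the interpolated distance between focal peaks", {
  z <- seq(-700, 700, by = 100)
  prof <- function(mu) exp(-(z - mu)^2 / (2 * 300^2))
  expect_equal(aca_offset(z, prof(0), prof(0)), 0)
  expect_equal(aca_offset(z, prof(-50), prof(50)), 100, tolerance = 1e-9)
  expect_error(aca_offset(z, rep(1, length(z)), prof(0)),
               class = "dcc_peak_error")
  # noisy profiles (SNR ~ 20 per frame, 10 frames averaged per step, as in
  # the focal-sweep protocol) recover the offset to better than 20 nm
  set.seed(12)
  prof_n <- function(mu) exp(-(z - mu)^2 / (2 * 200^2))
  err <- replicate(300, {
    ig <- prof_n(-50) + rnorm(length(z), 0, 0.05 / sqrt(10))
    ir <- prof_n(50) + rnorm(length(z), 0, 0.05 / sqrt(10))
    aca_offset(z, ig, ir) - 100
  })
  expect_lt(median(abs(err)), 20)
  expect_gte(mean(abs(err) <= 20), 0.9)
})

test_that("axial drift beyond 300 nm is flagged", {
  expect_false(flag_axial_drift(250))
  expect_true(flag_axial_drift(-350))
})
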