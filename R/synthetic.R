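#' Configuration for a synthetic dual-color SMLM scene
#'
#' Defines the ground-truth conditions the generator emulates: membrane
#' protein complexes scattered over a cell region, each subunit tagged with a
#' marker (green/mVenus-like) and an indicator (red/PAmCherry-like)
#' fluorophore; per-subunit double loss of both tags; localization scatter
#' around each visible tag; channel-specific background clusters; per-frame
#' sample drift; a linear lateral chromatic-aberration field on the red
#' channel; and fiducial beads emitting in every frame.
#'
#' @param field Field-of-view edge length in nm (square field).
#' @param cell,background Rectangles `c(xmin, xmax, ymin, ymax)` in nm for the
#'   cell and coverslip-background regions; must be disjoint and are given a
#'   margin inside the field by default.
#' @param complex_density Protein complexes per square micrometer of cell
#'   area.
#' @param oligomer Single integer oligomeric state, or a named numeric vector
#'   of mixture fractions (names = states) summing to 1.
#' @param p_marker Marker (green) recall rate per subunit.
#' @param p Indicator (red) recall rate per subunit.
#' @param m Double-loss probability per subunit.
#' @param sigma_loc Localization scatter (nm, sd per axis) around a tag.
#' @param mean_locs Named vector: mean localization count per visible tag for
#'   `green`, `red`, `background` sources (min-truncated geometric). The
#'   truncation points `min_locs` sit a few counts above the channel DBSCAN
#'   `min_samples` presets so that genuine tags survive clustering despite
#'   localization scatter, while background clusters stay small.
#' @param min_locs Named vector of truncation minima.
#' @param background_density Named vector (per square micrometer) of spurious
#'   cluster densities for the `green` and `red` channels; green background
#'   is negligible on the real instrument.
#' @param frames Frames recorded per channel.
#' @param drift_sigma Random-walk drift step sd (nm/frame, per axis).
#' @param drift_linear Linear drift component (nm/frame, per axis).
#' @param lca List with `K`, `x0`, `y0`: linear chromatic-aberration field
#'   applied to the red channel (defined on observed red coordinates).
#' @param n_beads Number of fiducial beads.
#' @param bead_sigma Localization scatter for beads (nm).
#' @param aggregate_fraction Fraction of complexes rendered as oversized
#'   aggregate clusters (exercises the 500 nm diameter filter).
#' @param aggregate_radius Disk radius (nm) over which an aggregate's
#'   localizations spread uniformly; the resulting cluster radius is about
#'   1.14 times this value, so the default comfortably exceeds the filter.
#' @param aggregate_locs Mean localization count per aggregate (dense enough
#'   to stay above the DBSCAN core threshold across the disk).
#' @param seed Optional integer seed; all scene randomness flows from it.
#'
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(field = 20480,
                         cell = c(500, 0.55 * field, 500, field - 500),
                         background = c(0.62 * field, field - 500, 500, field - 500),
                         complex_density = 1.5,
                         oligomer = 2,
                         p_marker = 0.8, p = 0.17, m = 0.30,
                         sigma_loc = 15,
                         mean_locs = c(green = 20, red = 14, background = 8),
                         min_locs = c(green = 14, red = 10, background = 6),
                         background_density = c(green = 0, red = 0.8),
                         frames = 2000,
                         drift_sigma = 2, drift_linear = c(0.05, 0.05),
                         lca = list(K = 0.01, x0 = field / 2, y0 = field / 2),
                         n_beads = 12, bead_sigma = 10,
                         aggregate_fraction = 0, aggregate_radius = 300,
                         aggregate_locs = 700, seed = NULL) {
  mix <- if (length(oligomer) == 1 && is.null(names(oligomer))) {
    setNames(1, as.character(oligomer))
  } else {
    if (abs(sum(oligomer) - 1) > 1e-8)
      abort("mixture fractions must sum to 1.", class = "dcc_config_error")
    oligomer
  }
  for (pr in c(p_marker, p, m, aggregate_fraction))
    if (pr < 0 || pr > 1)
      abort("probabilities must be in [0, 1].", class = "dcc_config_error")
  cfg <- list(field = field, cell = cell, background = background,
              complex_density = complex_density, oligomer = mix,
              p_marker = p_marker, p = p, m = m, sigma_loc = sigma_loc,
              mean_locs = mean_locs, min_locs = min_locs,
              background_density = background_density, frames = frames,
              drift_sigma = drift_sigma, drift_linear = drift_linear,
              lca = lca, n_beads = n_beads, bead_sigma = bead_sigma,
              aggregate_fraction = aggregate_fraction,
              aggregate_radius = aggregate_radius,
              aggregate_locs = aggregate_locs, seed = seed)
  structure(cfg, class = "scene_config")
}

rect_area_um2 <- function(r) (r[2] - r[1]) * (r[4] - r[3]) / 1e6

# geometric localization count truncated from below: min + Geom(mean extra)
rtrunc_geom <- function(n, min_count, mean_count) {
  extra <- max(mean_count - min_count, 0.01)
  min_count + rgeom(n, prob = 1 / (extra + 1))
}

# beads evenly distributed over the field: jittered grid, guaranteeing
# mutual separation well above the tracking capture radius
bead_positions <- function(n_beads, field, margin = 400) {
  if (!n_beads) return(tibble::tibble(bead = integer(), x = double(), y = double()))
  ncol_g <- ceiling(sqrt(n_beads))
  nrow_g <- ceiling(n_beads / ncol_g)
  gx <- seq(margin, field - margin, length.out = ncol_g + 1)
  gy <- seq(margin, field - margin, length.out = nrow_g + 1)
  spacing <- min(diff(gx)[1], diff(gy)[1])
  centers <- tidyr::expand_grid(cy = head(gy, nrow_g) + diff(gy)[1] / 2,
                                cx = head(gx, ncol_g) + diff(gx)[1] / 2)
  centers <- centers[seq_len(n_beads), ]
  jit <- max(0, spacing / 2 - 250)
  tibble::tibble(bead = seq_len(n_beads),
                 x = centers$cx + runif(n_beads, -jit, jit),
                 y = centers$cy + runif(n_beads, -jit, jit))
}

# random-walk + linear drift; zero on frame 1
sim_drift <- function(frames, sigma, linear) {
  tibble::tibble(
    frame = seq_len(frames),
    dx = c(0, cumsum(rnorm(frames - 1, 0, sigma))) + linear[1] * (seq_len(frames) - 1),
    dy = c(0, cumsum(rnorm(frames - 1, 0, sigma))) + linear[2] * (seq_len(frames) - 1))
}

# forward LCA displacement on red coordinates: measured = true + K (measured - c)
apply_lca_forward <- function(x, y, lca) {
  if (is.null(lca) || lca$K == 0) return(list(x = x, y = y))
  list(x = (x - lca$K * lca$x0) / (1 - lca$K),
       y = (y - lca$K * lca$y0) / (1 - lca$K))
}

# emit localization clouds: one row per localization around each source
emit_locs <- function(sx, sy, sigma, n_locs, frames) {
  sigma <- rep_len(sigma, length(sx))
  idx <- rep.int(seq_along(sx), n_locs)
  total <- length(idx)
  list(source = idx,
       x = sx[idx] + rnorm(total, 0, rep.int(sigma, n_locs)),
       y = sy[idx] + rnorm(total, 0, rep.int(sigma, n_locs)),
       frame = sample.int(frames, total, replace = TRUE))
}

#' Simulate a dual-color SMLM scene with ground truth
#'
#' Places protein complexes uniformly in the cell region, assigns every
#' subunit its double-loss / marker-visible / indicator-visible state,
#' renders a localization cloud for each visible tag, adds channel-specific
#' background clusters over cell and background regions, adds fiducial
#' beads, and finally applies the true drift (both channels; the red channel
#' carries over the drift accumulated during the green recording) and the
#' chromatic-aberration field (red channel).
#'
#' @param config A [scene_config()].
#' @return A list of class `"dcc_scene"`: localization tables `green` and
#'   `red`, bead tables `beads_green` and `beads_red`, the `rois`, and
#'   `truth` (complex table, subunit flags, drift trajectories, LCA
#'   parameters, bead positions, config).
#' @export
simulate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cellr <- config$cell; bgr <- config$background
  cell_area <- rect_area_um2(cellr)
  n_complex <- rpois(1, config$complex_density * cell_area)
  if (n_complex == 0)
    abort("cell region too small for the requested density.",
          class = "dcc_config_error")

  states <- as.integer(names(config$oligomer))
  n_i <- states[sample.int(length(states), n_complex, replace = TRUE,
                           prob = config$oligomer)]
  complexes <- tibble::tibble(
    complex = seq_len(n_complex),
    x = runif(n_complex, cellr[1], cellr[2]),
    y = runif(n_complex, cellr[3], cellr[4]),
    n = n_i,
    aggregate = runif(n_complex) < config$aggregate_fraction)

  subunits <- tibble::tibble(
    complex = rep.int(complexes$complex, complexes$n))
  ns <- nrow(subunits)
  subunits$lost <- runif(ns) < config$m
  subunits$marker_visible <- !subunits$lost & runif(ns) < config$p_marker
  subunits$indicator_visible <- !subunits$lost & runif(ns) < config$p

  drift_g <- sim_drift(config$frames, config$drift_sigma, config$drift_linear)
  drift_r <- sim_drift(config$frames, config$drift_sigma, config$drift_linear)
  offset <- unlist(drift_g[nrow(drift_g), c("dx", "dy")])

  make_channel <- function(which_visible, chan) {
    src <- which(subunits[[which_visible]])
    cpx <- subunits$complex[src]
    n_tags <- length(src)
    bg_rate <- config$background_density[[chan]]
    parts <- list()
    if (n_tags) {
      agg <- complexes$aggregate[cpx]
      # aggregates (protein clumps) render as one dense, uniformly filled
      # disk of localizations; ordinary tags as a Gaussian cloud
      n_locs <- ifelse(agg,
                       rpois(n_tags, config$aggregate_locs),
                       rtrunc_geom(n_tags, config$min_locs[[chan]],
                                   config$mean_locs[[chan]]))
      parts$complex <- emit_locs(complexes$x[cpx], complexes$y[cpx],
                                 config$sigma_loc, n_locs, config$frames)
      agg_loc <- rep.int(agg, n_locs)
      if (any(agg_loc)) {
        na <- sum(agg_loc)
        idx <- parts$complex$source[agg_loc]
        rr <- config$aggregate_radius * sqrt(runif(na))
        th <- runif(na, 0, 2 * pi)
        parts$complex$x[agg_loc] <- complexes$x[cpx][idx] + rr * cos(th)
        parts$complex$y[agg_loc] <- complexes$y[cpx][idx] + rr * sin(th)
      }
      parts$complex$origin <- cpx[parts$complex$source]
    }
    n_bg <- if (bg_rate > 0)
      rpois(1, bg_rate * (cell_area + rect_area_um2(bgr))) else 0L
    if (n_bg > 0) {
      # background clusters land anywhere on the coverslip: split between the
      # two regions proportionally to area
      in_cell <- runif(n_bg) < cell_area / (cell_area + rect_area_um2(bgr))
      bx <- ifelse(in_cell, runif(n_bg, cellr[1], cellr[2]),
                   runif(n_bg, bgr[1], bgr[2]))
      by <- ifelse(in_cell, runif(n_bg, cellr[3], cellr[4]),
                   runif(n_bg, bgr[3], bgr[4]))
      n_locs_bg <- rtrunc_geom(n_bg, config$min_locs[["background"]],
                               config$mean_locs[["background"]])
      parts$background <- emit_locs(bx, by, config$sigma_loc, n_locs_bg,
                                    config$frames)
      parts$background$origin <- rep(NA_integer_, length(parts$background$x))
    }
    if (!length(parts)) {
      return(loc_table(integer(), double(), double(), channel = chan,
                       n_frames = config$frames))
    }
    x <- unlist(lapply(parts, `[[`, "x"), use.names = FALSE)
    y <- unlist(lapply(parts, `[[`, "y"), use.names = FALSE)
    frame <- unlist(lapply(parts, `[[`, "frame"), use.names = FALSE)
    origin <- unlist(lapply(parts, `[[`, "origin"), use.names = FALSE)
    source <- rep(names(parts), vapply(parts, function(p) length(p$x), 1L))
    if (chan == "red") {
      ab <- apply_lca_forward(x, y, config$lca)
      x <- ab$x; y <- ab$y
    }
    dr <- if (chan == "green") drift_g else drift_r
    x <- x + dr$dx[frame] + if (chan == "red") offset[1] else 0
    y <- y + dr$dy[frame] + if (chan == "red") offset[2] else 0
    loc_table(frame, x, y, channel = chan, n_frames = config$frames,
              source = source, origin = origin)
  }

  green <- make_channel("marker_visible", "green")
  red <- make_channel("indicator_visible", "red")

  beads <- bead_positions(config$n_beads, config$field)
  make_beads <- function(chan) {
    if (!config$n_beads) {
      return(loc_table(integer(), double(), double(), channel = "bead",
                       n_frames = config$frames))
    }
    frame <- rep(seq_len(config$frames), times = config$n_beads)
    bead <- rep(beads$bead, each = config$frames)
    x <- beads$x[bead] + rnorm(length(bead), 0, config$bead_sigma)
    y <- beads$y[bead] + rnorm(length(bead), 0, config$bead_sigma)
    if (chan == "red") {
      ab <- apply_lca_forward(x, y, config$lca)
      x <- ab$x; y <- ab$y
    }
    dr <- if (chan == "green") drift_g else drift_r
    x <- x + dr$dx[frame] + if (chan == "red") offset[1] else 0
    y <- y + dr$dy[frame] + if (chan == "red") offset[2] else 0
    loc_table(frame, x, y, channel = "bead", n_frames = config$frames,
              bead = bead)
  }

  rois <- roi_set(
    roi_rect(cellr[1], cellr[2], cellr[3], cellr[4], type = "cell", id = "cell_1"),
    roi_rect(bgr[1], bgr[2], bgr[3], bgr[4], type = "background", id = "bg_1"))

  structure(list(
    green = green, red = red,
    beads_green = make_beads("green"), beads_red = make_beads("red"),
    rois = rois,
    truth = list(complexes = complexes, subunits = subunits,
                 drift_green = drift_g, drift_red = drift_r,
                 channel_offset = offset, lca = config$lca, beads = beads,
                 config = config)),
    class = "dcc_scene")
}

#' Simulate bead-only recordings for registration
#'
#' Beads emit one localization per frame per channel; drift and a linear
#' chromatic-aberration field are imposed with known ground truth. Suitable
#' for exercising drift estimation and LCA fitting in isolation. Defaults
#' follow the calibration protocol: short (50-frame) recordings of well
#' separated beads.
#'
#' @param n_beads Number of beads.
#' @param frames Frames per channel.
#' @param field Field edge (nm).
#' @param bead_sigma Localization scatter (nm); 0 gives noiseless tables.
#' @param drift_sigma,drift_linear Drift model (see [scene_config()]).
#' @param lca List `(K, x0, y0)` or `NULL` for no aberration.
#' @param seed Optional seed.
#' @return A list with tables `green`, `red` and the ground `truth`.
#' @export
simulate_beads <- function(n_beads = 20, frames = 50, field = 20480,
                           bead_sigma = 0, drift_sigma = 0,
                           drift_linear = c(0, 0),
                           lca = list(K = 0.01, x0 = field / 2, y0 = field / 2),
                           seed = NULL) {
  stopifnot(n_beads >= 1)
  if (!is.null(seed)) set.seed(seed)
  cfg <- scene_config(field = field, frames = frames, n_beads = n_beads,
                      bead_sigma = bead_sigma, drift_sigma = drift_sigma,
                      drift_linear = drift_linear, lca = lca,
                      complex_density = 1.5)
  beads <- bead_positions(n_beads, field)
  drift_g <- sim_drift(frames, drift_sigma, drift_linear)
  drift_r <- sim_drift(frames, drift_sigma, drift_linear)
  offset <- unlist(drift_g[nrow(drift_g), c("dx", "dy")])
  emit <- function(chan) {
    frame <- rep(seq_len(frames), times = n_beads)
    bead <- rep(beads$bead, each = frames)
    x <- beads$x[bead]; y <- beads$y[bead]
    if (bead_sigma > 0) {
      x <- x + rnorm(length(x), 0, bead_sigma)
      y <- y + rnorm(length(y), 0, bead_sigma)
    }
    if (chan == "red") {
      ab <- apply_lca_forward(x, y, lca)
      x <- ab$x; y <- ab$y
    }
    dr <- if (chan == "green") drift_g else drift_r
    x <- x + dr$dx[frame] + if (chan == "red") offset[1] else 0
    y <- y + dr$dy[frame] + if (chan == "red") offset[2] else 0
    loc_table(frame, x, y, channel = "bead", n_frames = frames, bead = bead)
  }
  list(green = emit("green"), red = emit("red"),
       truth = list(beads = beads, drift_green = drift_g, drift_red = drift_r,
                    channel_offset = offset, lca = lca, config = cfg))
}

#' Simulate per-cell calibration data for reference proteins
#'
#' Generates per-cell colocalization ratios for a panel of reference
#' proteins with known oligomeric states, at the generator's detection
#' parameters. Two levels of realism:
#'
#' * `"counts"` (fast): each cell contributes `N_M ~ Poisson(mean_n_m)`
#'   marker clusters; its expected ratio is the model value `E(n)` perturbed
#'   by a cell-level Gaussian (sd `cell_sd`, truncated to `(0, 1)`)
#'   capturing between-cell variability; `N_MF ~ Binomial(N_M, E_cell)`.
#' * `"scene"`: every cell is a full [simulate_scene()] run pushed through
#'   clustering and [colocalization_ratios()] (drift disabled, registered
#'   coordinates), so the ratio carries all pipeline noise.
#'
#' @param n_list Oligomeric states of the reference panel (repeats allowed,
#'   e.g. two distinct dimeric references).
#' @param cells_per_protein Cells measured per reference protein.
#' @param p,m Generator detection parameters.
#' @param level `"counts"` or `"scene"`.
#' @param mean_n_m Mean marker-cluster count per cell (counts level).
#' @param cell_sd Between-cell sd of the true ratio (counts level). The
#'   default 0.04 is calibrated so that bootstrap confidence intervals of
#'   `(m, p)` on a reference-panel design reproduce the scale of intervals
#'   observed in calibration experiments (p about +/- 0.015, m about
#'   +/- 0.10 at ~110 cells).
#' @param scene_template A [scene_config()] used at scene level (its
#'   `oligomer`, `p` and `m` are overridden per protein).
#' @param seed Optional seed.
#' @return A tibble with columns `protein`, `n`, `cell`, `n_m`, `n_mf`, `pd`.
#' @export
simulate_calibration <- function(n_list = c(1, 2, 2, 3, 4),
                                 cells_per_protein = 25,
                                 p = 0.17, m = 0.30,
                                 level = c("counts", "scene"),
                                 mean_n_m = 300, cell_sd = 0.04,
                                 scene_template = NULL, seed = NULL) {
  level <- match.arg(level)
  if (cells_per_protein < 1)
    abort("`cells_per_protein` must be at least 1.", class = "dcc_config_error")
  if (!is.null(seed)) set.seed(seed)
  proteins <- paste0("ref", seq_along(n_list), "_n", n_list)
  purrr::map2_dfr(proteins, n_list, function(prot, n) {
    if (level == "counts") {
      e <- dcc_expected(n, p, m)
      n_m <- rpois(cells_per_protein, mean_n_m)
      n_m <- pmax(n_m, 1L)
      e_cell <- pmin(1 - 1e-9, pmax(1e-9, rnorm(cells_per_protein, e, cell_sd)))
      n_mf <- rbinom(cells_per_protein, n_m, e_cell)
      tibble::tibble(protein = prot, n = n, cell = seq_len(cells_per_protein),
                     n_m = n_m, n_mf = n_mf, pd = n_mf / n_m)
    } else {
      cfg0 <- scene_template %||%
        scene_config(field = 12000,
                     cell = c(500, 8500, 500, 11500),
                     background = c(9000, 11500, 500, 11500),
                     frames = 200, drift_sigma = 0, drift_linear = c(0, 0),
                     lca = list(K = 0, x0 = 0, y0 = 0), n_beads = 0)
      purrr::map_dfr(seq_len(cells_per_protein), function(ci) {
        cfg <- cfg0
        cfg$oligomer <- setNames(1, as.character(n))
        cfg$p <- p; cfg$m <- m; cfg$seed <- NULL
        sc <- simulate_scene(cfg)
        res <- colocalization_ratios(sc$green, sc$red, sc$rois)
        tibble::tibble(protein = prot, n = n, cell = ci,
                       n_m = res$n_m[1], n_mf = res$n_mf[1], pd = res$pd[1])
      })
    }
  })
}
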