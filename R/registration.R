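#' Track fiducial beads across frames
#'
#' Starting from user- or generator-supplied seed positions, each bead is
#' followed frame by frame: the localization nearest to the bead's running
#' position within `capture_radius` is taken as its position in that frame.
#' Frames without a detection are flagged and linearly interpolated from
#' flanking frames before drift estimation.
#'
#' @param table A localization table containing bead signals.
#' @param seeds Data frame with columns `x`, `y` (nm): approximate bead
#'   positions (e.g. picked from a reconstruction).
#' @param capture_radius Maximum distance (nm) from the running position for a
#'   localization to be assigned to the bead. Seeds closer together than this
#'   are ambiguous and rejected.
#' @param max_missing Maximum tolerated fraction of frames without a
#'   detection per bead.
#'
#' @return A tibble with columns `bead`, `frame`, `x`, `y`, `detected`
#'   (logical; interpolated positions are `detected = FALSE`).
#' @export
track_beads <- function(table, seeds, capture_radius = 200, max_missing = 0.1) {
  n_frames <- attr(table, "n_frames") %||% max(table$frame)
  if (nrow(seeds) > 1) {
    dmin <- min(stats::dist(seeds[, c("x", "y")]))
    if (dmin < capture_radius)
      abort(sprintf("bead seeds %.0f nm apart: closer than the capture radius (%g nm), assignment would be ambiguous.",
                    dmin, capture_radius),
            class = "dcc_tracking_error")
  }
  by_frame <- split(seq_len(nrow(table)), table$frame)
  out <- vector("list", nrow(seeds))
  for (b in seq_len(nrow(seeds))) {
    px <- rep(NA_real_, n_frames); py <- rep(NA_real_, n_frames)
    det <- rep(FALSE, n_frames)
    cx <- seeds$x[b]; cy <- seeds$y[b]
    for (k in seq_len(n_frames)) {
      idx <- by_frame[[as.character(k)]]
      if (!is.null(idx)) {
        d2 <- (table$x[idx] - cx)^2 + (table$y[idx] - cy)^2
        j <- which.min(d2)
        if (length(j) && d2[j] <= capture_radius^2) {
          cx <- table$x[idx[j]]; cy <- table$y[idx[j]]
          px[k] <- cx; py[k] <- cy; det[k] <- TRUE
        }
      }
    }
    if (mean(!det) > max_missing)
      abort(sprintf("bead %d undetected in %.0f%% of frames (> %.0f%% allowed).",
                    b, 100 * mean(!det), 100 * max_missing),
            class = "dcc_tracking_error")
    if (anyNA(px)) {
      f <- which(det)
      px <- approx(f, px[f], xout = seq_len(n_frames), rule = 2)$y
      py <- approx(f, py[f], xout = seq_len(n_frames), rule = 2)$y
    }
    out[[b]] <- tibble::tibble(bead = b, frame = seq_len(n_frames),
                               x = px, y = py, detected = det)
  }
  dplyr::bind_rows(out)
}

#' Estimate the drift trajectory from bead tracks
#'
#' The drift on frame k is the mean displacement of all beads relative to
#' their frame-1 positions, so the trajectory is zero on the first frame by
#' construction.
#'
#' @param tracks Output of [track_beads()].
#' @param n_frames Number of frames; defaults to the maximum frame in
#'   `tracks`.
#'
#' @return A tibble with columns `frame`, `dx`, `dy` (nm). The offset on the
#'   final frame (needed to register a subsequently recorded channel) is
#'   `dplyr::slice_tail(trajectory, n = 1)`.
#' @export
estimate_drift <- function(tracks, n_frames = max(tracks$frame)) {
  first <- tracks[tracks$frame == 1L, ]
  if (!nrow(first) || anyNA(first$x))
    abort("no bead track covers frame 1; drift is defined relative to it.",
          class = "dcc_reference_error")
  ref <- first[match(tracks$bead, first$bead), ]
  traj <- tracks |>
    dplyr::mutate(rx = .data$x - ref$x, ry = .data$y - ref$y) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(dx = mean(.data$rx), dy = mean(.data$ry), .groups = "drop")
  if (nrow(traj) < n_frames)
    abort("tracks do not cover all frames.", class = "dcc_reference_error")
  traj
}

#' Subtract the drift trajectory from a localization table
#'
#' Each localization is shifted by minus the drift of its frame. For the
#' second recorded channel (red, recorded after green), the accumulated drift
#' at the end of the first channel is additionally subtracted so both
#' channels share the green frame-1 reference.
#'
#' @param table A localization table.
#' @param trajectory Drift trajectory from [estimate_drift()] for this
#'   channel.
#' @param channel_offset Either `NULL` (first channel) or a numeric
#'   `c(dx, dy)` / the trajectory of the previously recorded channel, whose
#'   final-frame drift is then subtracted in addition.
#'
#' @return The corrected localization table.
#' @export
apply_drift <- function(table, trajectory, channel_offset = NULL) {
  if (nrow(table) && max(table$frame) > nrow(trajectory))
    abort("localization frame outside the drift trajectory range.",
          class = "dcc_index_error")
  off <- c(0, 0)
  if (!is.null(channel_offset)) {
    off <- if (is.data.frame(channel_offset)) {
      unlist(channel_offset[nrow(channel_offset), c("dx", "dy")])
    } else channel_offset
  }
  table$x <- table$x - trajectory$dx[table$frame] - off[1]
  table$y <- table$y - trajectory$dy[table$frame] - off[2]
  table
}

#' Flag excessive axial drift
#'
#' Recordings whose measured axial focus displacement exceeds the limit are
#' flagged for exclusion (the caller decides whether to drop them).
#'
#' @param axial_drift_nm Measured axial drift (nm).
#' @param limit Threshold in nm.
#' @return Logical: `TRUE` when the recording should be discarded.
#' @export
flag_axial_drift <- function(axial_drift_nm, limit = 300) {
  abs(axial_drift_nm) > limit
}

#' Pair bead clusters across color channels
#'
#' Mutual nearest-neighbour green/red cluster pairs closer than
#' `max_pair_dist` are considered the same bead; the per-bead chromatic shift
#' is red minus green.
#'
#' @param green,red Cluster summaries (see [summarize_clusters()]) with
#'   columns `x`, `y`.
#' @param max_pair_dist Pairing threshold in nm.
#' @return A tibble with the green (`gx`, `gy`) and red (`rx`, `ry`) centers
#'   and the shift (`ax`, `ay`) per paired bead; the number of unpaired
#'   clusters is in attribute `n_unpaired`.
#' @export
pair_beads <- function(green, red, max_pair_dist = 200) {
  if (!nrow(green) || !nrow(red)) {
    out <- tibble::tibble(gx = double(), gy = double(), rx = double(),
                          ry = double(), ax = double(), ay = double())
    attr(out, "n_unpaired") <- nrow(green) + nrow(red)
    return(out)
  }
  d2 <- outer(green$x, red$x, "-")^2 + outer(green$y, red$y, "-")^2
  nn_g <- apply(d2, 1, which.min)       # nearest red for each green
  nn_r <- apply(d2, 2, which.min)       # nearest green for each red
  mutual <- which(nn_r[nn_g] == seq_len(nrow(green)))
  keep <- mutual[d2[cbind(mutual, nn_g[mutual])] <= max_pair_dist^2]
  out <- tibble::tibble(
    gx = green$x[keep], gy = green$y[keep],
    rx = red$x[nn_g[keep]], ry = red$y[nn_g[keep]])
  out$ax <- out$rx - out$gx
  out$ay <- out$ry - out$gy
  attr(out, "n_unpaired") <- nrow(green) + nrow(red) - 2L * nrow(out)
  out
}

#' Fit the global linear lateral chromatic aberration model
#'
#' The lateral chromatic shift between channels grows linearly with distance
#' from a center point `(x0, y0)`: `A_x = K (x - x0)`, `A_y = K (y - y0)`,
#' with a single dimensionless slope `K` shared by both axes. Both axes are
#' stacked into one least-squares problem (`ax ~ K x - K x0`,
#' `ay ~ K y - K y0`), solved in the observed red-channel coordinates.
#'
#' @param pairs Bead pairs from [pair_beads()].
#' @return An object of class `"lca_linear"`: list with `K`, `x0`, `y0` and
#'   the residual standard deviation `sigma_res`.
#' @export
fit_lca_linear <- function(pairs) {
  if (nrow(pairs) < 3)
    abort("need at least 3 bead pairs for the linear aberration fit.",
          class = "dcc_fit_error")
  # A = K * pos + c_axis, shared K, per-axis intercept
  X <- rbind(cbind(pairs$rx, 1, 0), cbind(pairs$ry, 0, 1))
  yv <- c(pairs$ax, pairs$ay)
  qrX <- qr(X)
  if (qrX$rank < 3)
    abort("degenerate bead geometry: linear aberration fit is undetermined.",
          class = "dcc_fit_error")
  beta <- qr.coef(qrX, yv)
  K <- beta[1]
  if (abs(K) >= 1)
    abort("unphysical aberration slope |K| >= 1.", class = "dcc_fit_error")
  x0 <- -beta[2] / K; y0 <- -beta[3] / K
  if (abs(K) < 1e-12) { x0 <- 0; y0 <- 0 }
  res <- yv - X %*% beta
  structure(list(K = unname(K), x0 = unname(x0), y0 = unname(y0),
                 sigma_res = sd(res), n_pairs = nrow(pairs)),
            class = "lca_linear")
}

#' Fit the regional (grid-average) lateral chromatic aberration model
#'
#' The field of view is tiled with squares; within each square the mean bead
#' shift is used as the local correction. Squares without beads are filled by
#' iterated 8-neighbourhood averaging of the populated squares.
#'
#' @param pairs Bead pairs from [pair_beads()].
#' @param grid_edge Square edge length in nm.
#' @param bounds `c(xmin, xmax, ymin, ymax)` of the field of view in nm;
#'   defaults to the tight bounds of the paired beads.
#' @return An object of class `"lca_regional"`: grids `Ax`, `Ay` (rows = y),
#'   the bounds and edge length, and a logical grid `measured`.
#' @export
fit_lca_regional <- function(pairs, grid_edge = 2000, bounds = NULL) {
  if (!nrow(pairs))
    abort("need at least one bead pair.", class = "dcc_fit_error")
  if (is.null(bounds))
    bounds <- c(min(pairs$rx), max(pairs$rx), min(pairs$ry), max(pairs$ry))
  nx <- max(1L, ceiling((bounds[2] - bounds[1]) / grid_edge))
  ny <- max(1L, ceiling((bounds[4] - bounds[3]) / grid_edge))
  ix <- pmin(nx, pmax(1L, floor((pairs$rx - bounds[1]) / grid_edge) + 1L))
  iy <- pmin(ny, pmax(1L, floor((pairs$ry - bounds[3]) / grid_edge) + 1L))
  Ax <- matrix(NA_real_, ny, nx); Ay <- matrix(NA_real_, ny, nx)
  cnt <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(pairs))) {
    r <- iy[i]; c <- ix[i]
    if (cnt[r, c] == 0L) { Ax[r, c] <- 0; Ay[r, c] <- 0 }
    cnt[r, c] <- cnt[r, c] + 1L
    Ax[r, c] <- Ax[r, c] + (pairs$ax[i] - Ax[r, c]) / cnt[r, c]
    Ay[r, c] <- Ay[r, c] + (pairs$ay[i] - Ay[r, c]) / cnt[r, c]
  }
  measured <- cnt > 0L
  fill <- function(M) {
    while (anyNA(M)) {
      M2 <- M
      for (r in seq_len(ny)) for (c in seq_len(nx)) {
        if (is.na(M[r, c])) {
          nb <- M[max(1, r - 1):min(ny, r + 1), max(1, c - 1):min(nx, c + 1)]
          if (!all(is.na(nb))) M2[r, c] <- mean(nb, na.rm = TRUE)
        }
      }
      M <- M2
    }
    M
  }
  structure(list(Ax = fill(Ax), Ay = fill(Ay), measured = measured,
                 bounds = bounds, grid_edge = grid_edge,
                 n_pairs = nrow(pairs)),
            class = "lca_regional")
}

#' Evaluate a lateral chromatic aberration model at positions
#'
#' @param model An `"lca_linear"` or `"lca_regional"` model.
#' @param x,y Red-channel coordinates (nm).
#' @return A two-column matrix of shifts `(ax, ay)` in nm. Positions outside
#'   the regional grid are clamped to the nearest square; the linear model
#'   extrapolates.
#' @export
lca_shift <- function(model, x, y) {
  if (inherits(model, "lca_linear")) {
    cbind(ax = model$K * (x - model$x0), ay = model$K * (y - model$y0))
  } else if (inherits(model, "lca_regional")) {
    nx <- ncol(model$Ax); ny <- nrow(model$Ax)
    ix <- pmin(nx, pmax(1L, floor((x - model$bounds[1]) / model$grid_edge) + 1L))
    iy <- pmin(ny, pmax(1L, floor((y - model$bounds[3]) / model$grid_edge) + 1L))
    cbind(ax = model$Ax[cbind(iy, ix)], ay = model$Ay[cbind(iy, ix)])
  } else {
    abort("unknown LCA model.", class = "dcc_fit_error")
  }
}

#' Correct lateral chromatic aberration in the red channel
#'
#' Subtracts the modelled chromatic shift from every localization, registering
#' the red channel onto the green one.
#'
#' @param table Red-channel localization table (drift-corrected).
#' @param model An LCA model from [fit_lca_linear()] or [fit_lca_regional()].
#' @return The corrected localization table.
#' @export
correct_lca <- function(table, model) {
  if (!nrow(table)) return(table)
  A <- lca_shift(model, table$x, table$y)
  table$x <- table$x - A[, 1]
  table$y <- table$y - A[, 2]
  table
}

#' Axial chromatic aberration from a focal sweep
#'
#' The stage is stepped through focus while bead intensities are recorded in
#' both channels; the axial chromatic aberration is the offset between the
#' two intensity peaks, located to sub-step precision by parabolic
#' interpolation around each maximum.
#'
#' @param z Stage positions (nm), ascending.
#' @param i_green,i_red Mean bead intensities per step in each channel.
#' @return Axial offset in nm (red peak minus green peak). Reported as a
#'   quality-control number; it is never applied as a coordinate correction
#'   in this two-dimensional pipeline.
#' @export
aca_offset <- function(z, i_green, i_red) {
  peak <- function(I) {
    if (diff(range(I)) == 0)
      abort("flat intensity profile: no focal peak.", class = "dcc_peak_error")
    k <- which.max(I)
    if (k == 1 || k == length(I)) return(z[k])
    # parabola through the three samples around the maximum
    dz <- z[k + 1] - z[k]
    denom <- I[k - 1] - 2 * I[k] + I[k + 1]
    if (denom == 0) return(z[k])
    z[k] + 0.5 * dz * (I[k - 1] - I[k + 1]) / denom
  }
  peak(i_red) - peak(i_green)
}

#' Serialize a registration model to JSON
#'
#' Stores the drift trajectory, channel offset and LCA parameters so a
#' correction can be re-applied and audited.
#'
#' @param path Output path.
#' @param drift_green,drift_red Drift trajectories.
#' @param lca LCA model.
#' @return `path`, invisibly.
#' @export
write_registration <- function(path, drift_green = NULL, drift_red = NULL,
                               lca = NULL) {
  obj <- list()
  if (!is.null(drift_green)) obj$drift_green <- drift_green
  if (!is.null(drift_red)) obj$drift_red <- drift_red
  if (!is.null(lca)) {
    obj$lca <- unclass(lca)
    obj$lca_type <- class(lca)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
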