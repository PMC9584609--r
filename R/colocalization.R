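#' Radial distribution of red clusters around green clusters
#'
#' Pair-correlation profile g(r): the density of indicator (red) clusters in
#' annuli around each marker (green) cluster, normalized so that spatially
#' independent channels give g = 1. For bin inner radius r and width dr,
#'
#'   g(r) = a / (pi * N_M * N_F) * sum_i dN_i(r) / ((2 r + dr) * dr)
#'
#' where a is the ROI area, N_M and N_F the green and red cluster counts in
#' the ROI and dN_i(r) the number of red clusters in the annulus
#' `[r, r + dr)` around green cluster i. No edge correction is applied; draw
#' ROIs with at least `r_max` margin.
#'
#' @param green,red Cluster summaries (columns `x`, `y`, nm).
#' @param area_um2 ROI area in square micrometers.
#' @param dr Bin width in nm.
#' @param r_max Maximum distance in nm.
#' @return A tibble with `r_min`, `r_max`, `count` (summed red clusters per
#'   annulus) and `g`. Empty input in either channel yields a zero-count
#'   profile with attribute `empty = TRUE`.
#' @export
rdf <- function(green, red, area_um2, dr = 20, r_max = 400) {
  stopifnot(area_um2 > 0, dr > 0, r_max > dr)
  edges <- seq(0, r_max, by = dr)
  out <- tibble::tibble(r_min = edges[-length(edges)], r_max = edges[-1])
  if (!nrow(green) || !nrow(red)) {
    out$count <- 0L
    out$g <- 0
    attr(out, "empty") <- TRUE
    return(out)
  }
  d2 <- outer(green$x, red$x, "-")^2 + outer(green$y, red$y, "-")^2
  d <- sqrt(d2[d2 < r_max^2])
  cnt <- tabulate(pmin(floor(d / dr) + 1L, length(edges) - 1L),
                  nbins = length(edges) - 1L)
  a_nm2 <- area_um2 * 1e6
  out$count <- cnt
  out$g <- a_nm2 / (pi * nrow(green) * nrow(red)) *
    cnt / ((2 * out$r_min + dr) * dr)
  attr(out, "empty") <- FALSE
  out
}

#' Correlation length of an RDF profile
#'
#' The distance out to which the two channels are enriched above
#' independence: the outer edge of the last bin of the initial contiguous run
#' with g above `baseline`. This distance is used as the maximum
#' colocalization distance (100 nm on the calibration data).
#'
#' @param profile Output of [rdf()].
#' @param baseline Independence level (1 for a normalized RDF).
#' @return Length in nm, or `NA` (with a warning) when g never exceeds the
#'   baseline.
#' @export
correlation_length <- function(profile, baseline = 1) {
  above <- profile$g > baseline
  if (!length(above) || !above[1]) {
    if (!any(above)) {
      warn("RDF never exceeds the baseline; correlation length undefined.")
      return(NA_real_)
    }
    warn("RDF not enriched in the innermost bin; correlation length undefined.")
    return(NA_real_)
  }
  run_end <- if (all(above)) length(above) else which(!above)[1] - 1L
  profile$r_max[run_end]
}

#' Register colocalization between green and red clusters
#'
#' A green (marker) cluster is colocalized when at least one red (indicator)
#' cluster lies strictly closer than the threshold distance `d`.
#'
#' @param green,red Cluster summaries (columns `x`, `y`).
#' @param d Maximum colocalization distance in nm.
#' @param exactly_one If `TRUE`, require exactly one red cluster within `d`
#'   instead of at least one.
#' @return `green` with columns `nearest_red` (nm; `Inf` when there are no
#'   red clusters), `n_red_within` and logical `colocalized`. Summary counts:
#'   `attr(, "n_m")` and `attr(, "n_mf")`.
#' @export
colocalize <- function(green, red, d = 100, exactly_one = FALSE) {
  if (!nrow(green)) {
    green$nearest_red <- double()
    green$n_red_within <- integer()
    green$colocalized <- logical()
  } else if (!nrow(red)) {
    green$nearest_red <- Inf
    green$n_red_within <- 0L
    green$colocalized <- FALSE
  } else {
    d2 <- outer(green$x, red$x, "-")^2 + outer(green$y, red$y, "-")^2
    green$nearest_red <- sqrt(apply(d2, 1, min))
    green$n_red_within <- as.integer(rowSums(d2 < d^2))
    green$colocalized <- if (exactly_one) green$n_red_within == 1L
                         else green$n_red_within >= 1L
  }
  attr(green, "n_m") <- nrow(green)
  attr(green, "n_mf") <- sum(green$colocalized)
  green
}

#' Chance-colocalization probability from background density
#'
#' The number of spurious red background clusters within distance d of a
#' given green cluster is Poisson with mean `pi d^2 D_rb`, so the probability
#' of at least one is `1 - exp(-pi d^2 D_rb)`.
#'
#' @param d Colocalization distance in nm.
#' @param density_um2 Red background cluster density in clusters per square
#'   micrometer.
#' @return Probability of chance colocalization.
#' @examples
#' p_background(100, 0.8) # 0.0248
#' @export
p_background <- function(d, density_um2) {
  if (any(d < 0) || any(density_um2 < 0))
    abort("`d` and `density_um2` must be non-negative.",
          class = "dcc_domain_error")
  1 - exp(-pi * (d / 1000)^2 * density_um2)
}

#' Background-corrected colocalization ratio
#'
#' Removes the expected contribution of chance colocalizations with red
#' background clusters:
#'
#'   P_d = (N_MF - N_M * P_rb) / (N_M - N_M * P_rb)
#'
#' @param n_m Number of green clusters in the cell ROI.
#' @param n_mf Number of colocalized green clusters.
#' @param p_rb Chance-colocalization probability from [p_background()].
#' @return Corrected ratio in `[0, 1]`; values slightly outside from sampling
#'   noise are clamped with a warning.
#' @export
corrected_ratio <- function(n_m, n_mf, p_rb) {
  stopifnot(n_mf <= n_m)
  denom <- n_m - n_m * p_rb
  if (denom <= 0)
    abort("degenerate background: N_M * (1 - P_rb) <= 0.",
          class = "dcc_domain_error")
  pd <- (n_mf - n_m * p_rb) / denom
  if (pd < 0 || pd > 1) {
    warn(sprintf("corrected ratio %.4f outside [0, 1]; clamped.", pd))
    pd <- min(1, max(0, pd))
  }
  pd
}

#' Per-cell colocalization analysis
#'
#' Composes clustering, aggregate filtering, background-density estimation
#' and background-corrected colocalization for every cell ROI of a recording.
#' Input tables must already be drift- and chromatic-aberration corrected.
#'
#' @param green_table,red_table Registered localization tables.
#' @param rois ROI tibble with at least one `"cell"` and one `"background"`
#'   region.
#' @param eps DBSCAN radius (nm).
#' @param min_samples_green,min_samples_red DBSCAN density thresholds.
#' @param max_diameter Aggregate-filter diameter cutoff (nm).
#' @param d Colocalization distance (nm).
#' @param exactly_one Passed to [colocalize()].
#' @return A tibble with one row per cell ROI: `cell_id`, `n_m`, `n_mf`,
#'   `d_rb` (red background density, 1/um^2), `p_rb`, `pd` and the green
#'   cluster density `density_m` (1/um^2). Cluster-retention bookkeeping is
#'   in attribute `retention`.
#' @export
colocalization_ratios <- function(green_table, red_table, rois,
                                  eps = 40, min_samples_green = 10,
                                  min_samples_red = 6, max_diameter = 500,
                                  d = 100, exactly_one = FALSE) {
  gcl <- summarize_clusters(cluster_localizations(green_table, eps, min_samples_green))
  rcl <- summarize_clusters(cluster_localizations(red_table, eps, min_samples_red))
  gcl <- filter_clusters(gcl, max_diameter)
  n_rem_g <- attr(gcl, "n_removed")
  rcl <- filter_clusters(rcl, max_diameter)
  n_rem_r <- attr(rcl, "n_removed")

  bg <- rois[rois$type == "background", ]
  if (!nrow(bg))
    abort("no background ROI: cannot estimate the background density.",
          class = "dcc_roi_error")
  rcl$roi_bg <- locate_in_rois(rcl$x, rcl$y, bg)
  d_rb <- background_density(sum(!is.na(rcl$roi_bg)), sum(bg$area_um2))
  p_rb <- p_background(d, d_rb)

  cells <- rois[rois$type == "cell", ]
  if (!nrow(cells))
    abort("no cell ROI.", class = "dcc_roi_error")
  gcl$roi_cell <- locate_in_rois(gcl$x, gcl$y, cells)
  res <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    id <- cells$roi_id[i]
    g_in <- gcl[!is.na(gcl$roi_cell) & gcl$roi_cell == id, ]
    cc <- colocalize(g_in, rcl, d = d, exactly_one = exactly_one)
    n_m <- attr(cc, "n_m"); n_mf <- attr(cc, "n_mf")
    pd <- if (n_m > 0) corrected_ratio(n_m, n_mf, p_rb) else NA_real_
    tibble::tibble(cell_id = id, n_m = n_m, n_mf = n_mf,
                   d_rb = d_rb, p_rb = p_rb, pd = pd,
                   density_m = n_m / cells$area_um2[i])
  })
  attr(res, "retention") <- tibble::tibble(
    channel = c("green", "red"),
    n_clusters = c(nrow(gcl), nrow(rcl)),
    n_removed = c(n_rem_g, n_rem_r))
  res
}
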