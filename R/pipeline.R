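#' Run the full DCC-SMLM analysis on one recording
#'
#' Composes registration (fiducial drift correction and chromatic-aberration
#' correction), clustering, aggregate filtering, background estimation and
#' colocalization into one deterministic pass, with quality-control
#' summaries. Optionally fits the detection model and classifies a protein
#' of interest when calibration data are supplied.
#'
#' @param scene A `"dcc_scene"` from [simulate_scene()], or `NULL` when the
#'   individual tables are given.
#' @param green,red Localization tables (ignored when `scene` is given).
#' @param rois ROI tibble.
#' @param beads_green,beads_red Bead localization tables for registration, or
#'   `NULL` to skip drift/LCA correction.
#' @param correct_drift,correct_ca Toggle the registration stages.
#' @param lca_method `"linear"` or `"regional"`.
#' @param grid_edge Square edge (nm) for the regional LCA model.
#' @param eps,min_samples_green,min_samples_red,max_diameter,d,exactly_one
#'   Clustering and colocalization parameters (see
#'   [colocalization_ratios()]).
#' @param compute_rdf Also compute the radial distribution profile of the
#'   first cell ROI.
#' @param axial_drift_nm Optional measured axial drift; recordings over
#'   300 nm are flagged in the QC block.
#'
#' @return An object of class `"dcc_run"`: `cells` (per-cell results),
#'   `registration` (trajectories, LCA model, residual bead offsets),
#'   `qc` (cluster retention, colocalization-vs-density correlation, RDF,
#'   axial-drift flag).
#' @export
run_dcc <- function(scene = NULL, green = NULL, red = NULL, rois = NULL,
                    beads_green = NULL, beads_red = NULL,
                    correct_drift = TRUE, correct_ca = TRUE,
                    lca_method = c("linear", "regional"), grid_edge = 2000,
                    eps = 40, min_samples_green = 10, min_samples_red = 6,
                    max_diameter = 500, d = 100, exactly_one = FALSE,
                    compute_rdf = TRUE, axial_drift_nm = NULL) {
  lca_method <- match.arg(lca_method)
  if (!is.null(scene)) {
    stopifnot(inherits(scene, "dcc_scene"))
    green <- scene$green; red <- scene$red; rois <- scene$rois
    beads_green <- beads_green %||% scene$beads_green
    beads_red <- beads_red %||% scene$beads_red
  }
  if (is.null(green) || is.null(red) || is.null(rois))
    abort("need `green`, `red` and `rois` (or a `scene`).",
          class = "dcc_config_error")
  has_beads <- !is.null(beads_green) && !is.null(beads_red) &&
    nrow(beads_green) > 0 && nrow(beads_red) > 0
  if ((correct_drift || correct_ca) && !has_beads)
    abort("registration requested but no bead tables supplied.",
          class = "dcc_config_error")

  # bead clusters are extremely dense (one localization per frame); estimating
  # seed positions and centers from a regular stride subsample keeps DBSCAN
  # cheap without biasing the center (sub-nm SE at a few hundred points)
  thin <- function(tb, max_rows = 4000) {
    if (nrow(tb) <= max_rows) return(tb)
    tb[unique(round(seq(1, nrow(tb), length.out = max_rows))), ]
  }

  registration <- list()
  if (correct_drift) {
    bead_ms <- cluster_defaults("bead")$min_samples
    seed_g <- summarize_clusters(cluster_localizations(thin(beads_green), eps = 200,
                                                       min_samples = bead_ms))
    seed_r <- summarize_clusters(cluster_localizations(thin(beads_red), eps = 200,
                                                       min_samples = bead_ms))
    tr_g <- track_beads(beads_green, seed_g)
    tr_r <- track_beads(beads_red, seed_r)
    drift_g <- estimate_drift(tr_g, attr(beads_green, "n_frames") %||% max(beads_green$frame))
    drift_r <- estimate_drift(tr_r, attr(beads_red, "n_frames") %||% max(beads_red$frame))
    green <- apply_drift(green, drift_g)
    red <- apply_drift(red, drift_r, channel_offset = drift_g)
    beads_green <- apply_drift(beads_green, drift_g)
    beads_red <- apply_drift(beads_red, drift_r, channel_offset = drift_g)
    registration$drift_green <- drift_g
    registration$drift_red <- drift_r
  }
  if (correct_ca) {
    bead_ms <- cluster_defaults("bead")$min_samples
    cl_g <- summarize_clusters(cluster_localizations(thin(beads_green), eps = 40,
                                                     min_samples = bead_ms))
    cl_r <- summarize_clusters(cluster_localizations(thin(beads_red), eps = 40,
                                                     min_samples = bead_ms))
    pairs <- pair_beads(cl_g, cl_r)
    lca <- if (lca_method == "linear") fit_lca_linear(pairs)
           else fit_lca_regional(pairs, grid_edge = grid_edge)
    red <- correct_lca(red, lca)
    beads_red_c <- correct_lca(beads_red, lca)
    cl_r2 <- summarize_clusters(cluster_localizations(thin(beads_red_c), eps = 40,
                                                      min_samples = bead_ms))
    resid <- pair_beads(cl_g, cl_r2)
    registration$lca <- lca
    registration$residual_lca_nm <- if (nrow(resid))
      mean(sqrt(resid$ax^2 + resid$ay^2)) else NA_real_
  }

  cells <- colocalization_ratios(green, red, rois, eps = eps,
                                 min_samples_green = min_samples_green,
                                 min_samples_red = min_samples_red,
                                 max_diameter = max_diameter, d = d,
                                 exactly_one = exactly_one)

  qc <- list(retention = attr(cells, "retention"),
             axial_drift_flag = if (is.null(axial_drift_nm)) NA
                                else flag_axial_drift(axial_drift_nm))
  ok <- !is.na(cells$pd)
  qc$density_correlation <- if (sum(ok) >= 3) {
    ct <- cor.test(cells$pd[ok], cells$density_m[ok])
    tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value)
  } else NULL
  if (compute_rdf) {
    cell1 <- rois[rois$type == "cell", ][1, ]
    gcl <- filter_clusters(summarize_clusters(
      cluster_localizations(green, eps, min_samples_green)), max_diameter)
    rcl <- filter_clusters(summarize_clusters(
      cluster_localizations(red, eps, min_samples_red)), max_diameter)
    v <- cell1$vertices[[1]]
    gin <- gcl[point_in_polygon(gcl$x, gcl$y, v[, 1], v[, 2]), ]
    rin <- rcl[point_in_polygon(rcl$x, rcl$y, v[, 1], v[, 2]), ]
    qc$rdf <- if (nrow(gin) && nrow(rin))
      rdf(gin, rin, cell1$area_um2) else NULL
  }

  structure(list(cells = cells, registration = registration, qc = qc),
            class = "dcc_run")
}

#' @export
print.dcc_run <- function(x, ...) {
  cat("DCC-SMLM run:", nrow(x$cells), "cell ROI(s)\n")
  df <- as.data.frame(x$cells)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, 4)
  print(df, row.names = FALSE)
  if (!is.null(x$registration$residual_lca_nm))
    cat(sprintf("residual chromatic offset: %.1f nm (bead mean)\n",
                x$registration$residual_lca_nm))
  if (!is.null(x$qc$density_correlation))
    cat(sprintf("colocalization vs cluster density: r = %.3f (p = %.3f)\n",
                x$qc$density_correlation$r, x$qc$density_correlation$p_value))
  invisible(x)
}
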