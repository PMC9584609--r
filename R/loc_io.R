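#' Column-mapping dialect for localization tables
#'
#' Localization software (SNSMIL, SMAP, ThunderSTORM, ...) emits delimited
#' tables with differing column names and units. A dialect maps the columns of
#' such a table onto the fields used throughout this package and declares the
#' coordinate unit.
#'
#' @param frame,x,y Column names holding the frame index and planar
#'   coordinates.
#' @param unit Unit of the `x`/`y` columns: `"nm"` or `"px"`. Pixel
#'   coordinates are converted to nm on read using the pixel size.
#' @param aux Named character vector mapping additional columns to keep
#'   (e.g. `c(intensity = "I")`), or `NULL`.
#'
#' @return A list of class `"loc_dialect"`.
#' @examples
#' loc_dialect(frame = "Frame", x = "X_px", y = "Y_px", unit = "px")
#' @export
loc_dialect <- function(frame = "frame", x = "x", y = "y",
                        unit = c("nm", "px"), aux = NULL) {
  unit <- match.arg(unit)
  structure(list(frame = frame, x = x, y = y, unit = unit, aux = aux),
            class = "loc_dialect")
}

#' Construct a localization table
#'
#' The raw currency of the pipeline: one row per localization with a 1-based
#' frame index and planar coordinates in nm (image convention: origin at the
#' field-of-view top-left, y increasing downward).
#'
#' @param frame Integer frame indices (first frame = 1).
#' @param x,y Coordinates in nm.
#' @param channel Channel label, typically `"green"`, `"red"` or `"bead"`.
#' @param pixel_size Camera pixel size in nm/pixel (metadata; default 80).
#' @param n_frames Total number of frames in the recording; defaults to
#'   `max(frame)`.
#' @param ... Additional auxiliary columns (intensity, quality score, ...).
#'
#' @return A tibble with columns `frame`, `x`, `y`, `channel` plus any
#'   auxiliary columns, and attributes `pixel_size` and `n_frames`.
#' @export
loc_table <- function(frame, x, y, channel = "green", pixel_size = 80,
                      n_frames = NULL, ...) {
  frame <- as.integer(frame)
  if (length(frame) && (anyNA(frame) || any(frame < 1L)))
    abort("`frame` must contain integers >= 1.", class = "dcc_format_error")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    abort("coordinates must be finite and non-missing.", class = "dcc_format_error")
  out <- tibble::tibble(frame = frame, x = as.double(x), y = as.double(y),
                        channel = channel, ...)
  attr(out, "pixel_size") <- pixel_size
  attr(out, "n_frames") <- if (is.null(n_frames)) {
    if (nrow(out)) max(out$frame) else 0L
  } else as.integer(n_frames)
  out
}

#' Read a localization table from delimited text
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect A [loc_dialect()] describing column names and unit.
#' @param channel Channel label to attach.
#' @param pixel_size Pixel size in nm/pixel, used to convert `"px"` dialects.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` read as tab, otherwise comma).
#'
#' @return A localization table (see [loc_table()]) in nm.
#' @export
read_localizations <- function(path, dialect = loc_dialect(), channel = "green",
                               pixel_size = 80, delim = NULL) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "dcc_io_error")
  if (is.null(delim))
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  needed <- c(dialect$frame, dialect$x, dialect$y)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dcc_format_error")
  coords <- lapply(needed, function(cl) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad))
        abort(paste0("non-numeric value in column '", cl, "' at row ", bad[1]),
              class = "dcc_parse_error")
      v <- v2
    }
    v
  })
  scale <- if (dialect$unit == "px") pixel_size else 1
  aux <- list()
  if (!is.null(dialect$aux)) {
    aux <- lapply(unname(dialect$aux), function(cl) raw[[cl]])
    names(aux) <- names(dialect$aux)
  }
  do.call(loc_table, c(list(frame = coords[[1]], x = coords[[2]] * scale,
                            y = coords[[3]] * scale, channel = channel,
                            pixel_size = pixel_size), aux))
}

#' Write a localization table to delimited text
#'
#' Coordinates are written in nm with enough digits for lossless round-trip.
#'
#' @param table A localization table.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(table, path, delim = delim)
  invisible(path)
}

#' Render a binary reconstruction image
#'
#' Bins localizations onto a raster; any bin containing at least one
#' localization is set. Used for quick visual reconstructions, not for
#' quantification.
#'
#' @param table A localization table.
#' @param render_px Bin edge length in nm.
#' @param bounds Numeric vector `c(xmin, xmax, ymin, ymax)` in nm; defaults to
#'   the tight bounds of the data (origin at 0 when the table is empty).
#' @param file Optional path to write the raster as an 8-bit PNG (requires the
#'   `png` package).
#'
#' @return An integer matrix (rows = y bins, columns = x bins) of 0/1.
#' @export
render_binary_image <- function(table, render_px = 80, bounds = NULL,
                                file = NULL) {
  stopifnot(render_px > 0)
  if (is.null(bounds)) {
    bounds <- if (nrow(table)) c(0, max(table$x), 0, max(table$y)) else c(0, render_px, 0, render_px)
  }
  nx <- max(1L, ceiling((bounds[2] - bounds[1]) / render_px))
  ny <- max(1L, ceiling((bounds[4] - bounds[3]) / render_px))
  img <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(table)) {
    ix <- pmin(nx, pmax(1L, floor((table$x - bounds[1]) / render_px) + 1L))
    iy <- pmin(ny, pmax(1L, floor((table$y - bounds[3]) / render_px) + 1L))
    img[cbind(iy, ix)] <- 1L
  }
  if (!is.null(file)) {
    if (!requireNamespace("png", quietly = TRUE))
      abort("writing PNG requires the 'png' package.", class = "dcc_io_error")
    png::writePNG(img, target = file)
  }
  img
}

# ---- regions of interest ----------------------------------------------------

shoelace_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  abs(sum(px[j] * py - px * py[j])) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(px, py) {
  n <- length(px)
  if (n < 4) return(FALSE)
  v <- cbind(px, py)
  nxt <- c(seq(2, n), 1)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next # shares the closing vertex
      if (segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}

point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

polygons_overlap <- function(ax, ay, bx, by) {
  if (max(ax) < min(bx) || max(bx) < min(ax) ||
      max(ay) < min(by) || max(by) < min(ay)) return(FALSE)
  if (any(point_in_polygon(ax, ay, bx, by))) return(TRUE)
  if (any(point_in_polygon(bx, by, ax, ay))) return(TRUE)
  na <- length(ax); nb <- length(bx)
  an <- c(seq(2, na), 1); bn <- c(seq(2, nb), 1)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (segments_intersect(c(ax[i], ay[i]), c(ax[an[i]], ay[an[i]]),
                           c(bx[j], by[j]), c(bx[bn[j]], by[bn[j]]))) return(TRUE)
  }
  FALSE
}

#' Rectangular region of interest
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in nm.
#' @param type Region type: `"cell"` or `"background"`.
#' @param id Region identifier.
#' @return A one-row ROI tibble; combine rows with [roi_set()].
#' @export
roi_rect <- function(xmin, xmax, ymin, ymax, type = c("cell", "background"),
                     id = NULL) {
  type <- match.arg(type)
  stopifnot(xmax > xmin, ymax > ymin)
  roi_polygon(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax),
              type = type, id = id)
}

#' Polygonal region of interest
#'
#' @param x,y Polygon vertex coordinates in nm (implicitly closed).
#' @inheritParams roi_rect
#' @return A one-row ROI tibble.
#' @export
roi_polygon <- function(x, y, type = c("cell", "background"), id = NULL) {
  type <- match.arg(type)
  stopifnot(length(x) == length(y), length(x) >= 3)
  x <- as.double(x)
  y <- as.double(y)
  if (polygon_self_intersects(x, y))
    abort("self-intersecting ROI polygon.", class = "dcc_roi_error")
  area <- shoelace_area(x, y)
  if (area <= 0) abort("ROI area must be > 0.", class = "dcc_roi_error")
  tibble::tibble(roi_id = id %||% NA_character_, type = type,
                 vertices = list(cbind(x = x, y = y)),
                 area_um2 = area / 1e6)
}

#' Assemble and validate a set of regions of interest
#'
#' Cell regions delimit the analysed membrane area; background regions lie on
#' the coverslip outside any cell and are used to estimate the density of
#' spurious red-channel clusters. Cell and background regions must not
#' overlap.
#'
#' @param ... One-row ROI tibbles from [roi_rect()] / [roi_polygon()], or data
#'   frames of such rows.
#' @return An ROI tibble with columns `roi_id`, `type`, `vertices` (list of
#'   vertex matrices) and `area_um2`.
#' @export
roi_set <- function(...) {
  rois <- dplyr::bind_rows(...)
  if (any(is.na(rois$roi_id)))
    rois$roi_id[is.na(rois$roi_id)] <-
      paste0(rois$type[is.na(rois$roi_id)], "_",
             seq_len(sum(is.na(rois$roi_id))))
  if (anyDuplicated(rois$roi_id))
    abort("duplicate ROI ids.", class = "dcc_roi_error")
  cells <- which(rois$type == "cell")
  bgs <- which(rois$type == "background")
  for (i in cells) for (j in bgs) {
    vi <- rois$vertices[[i]]; vj <- rois$vertices[[j]]
    if (polygons_overlap(vi[, 1], vi[, 2], vj[, 1], vj[, 2]))
      abort(paste0("cell ROI '", rois$roi_id[i],
                   "' overlaps background ROI '", rois$roi_id[j], "'."),
            class = "dcc_roi_error")
  }
  rois
}

#' Read regions of interest from JSON
#'
#' Expects a JSON array of objects with fields `id`, `type`
#' (`"cell"`/`"background"`) and either `xmin/xmax/ymin/ymax` (rectangle) or
#' `x`/`y` vertex arrays (polygon), all in nm.
#'
#' @param path Path to a JSON file.
#' @return An ROI tibble (see [roi_set()]).
#' @export
read_rois <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "dcc_io_error")
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rows <- lapply(spec, function(r) {
    if (!is.null(r$x)) {
      roi_polygon(unlist(r$x), unlist(r$y), type = r$type, id = r$id)
    } else {
      roi_rect(r$xmin, r$xmax, r$ymin, r$ymax, type = r$type, id = r$id)
    }
  })
  do.call(roi_set, rows)
}

#' Write regions of interest to JSON
#'
#' @param rois An ROI tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  spec <- purrr::pmap(rois, function(roi_id, type, vertices, area_um2) {
    list(id = roi_id, type = type,
         x = unname(vertices[, 1]), y = unname(vertices[, 2]))
  })
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Which region contains each point?
#'
#' @param x,y Coordinates in nm.
#' @param rois An ROI tibble.
#' @param type Optional filter on region type.
#' @return Character vector of `roi_id` (NA when in no region; first matching
#'   region wins).
#' @export
locate_in_rois <- function(x, y, rois, type = NULL) {
  if (!is.null(type)) rois <- rois[rois$type == type, ]
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(rois))) {
    v <- rois$vertices[[i]]
    hit <- is.na(out) & point_in_polygon(x, y, v[, 1], v[, 2])
    out[hit] <- rois$roi_id[i]
  }
  out
}
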