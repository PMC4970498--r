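# CrystFEL geometry parsing, lab-frame assembly and per-pixel q / resolution.

GEOM_PANEL_KEYS <- c("fs", "ss", "corner_x", "corner_y",
                     "min_fs", "max_fs", "min_ss", "max_ss",
                     "res", "coffset")

parse_axis_vector <- function(value, panel, key) {
  m <- gregexpr("([+-]?[0-9]*\\.?[0-9]+|[+-])?\\s*([xyz])", value)[[1]]
  if (m[1] == -1L)
    stop_fmt("panel '%s': cannot parse %s vector '%s'", panel, key, value)
  pieces <- regmatches(value, m)[[1]]
  v <- c(x = 0, y = 0, z = 0)
  for (p in pieces) {
    ax <- substr(p, nchar(p), nchar(p))
    num <- trimws(substr(p, 1L, nchar(p) - 1L))
    coef <- if (num == "" || num == "+") 1 else if (num == "-") -1 else as.numeric(num)
    v[ax] <- v[ax] + coef
  }
  if (v["z"] != 0)
    stop_fmt("panel '%s': z components in %s are not supported", panel, key)
  if (all(v[c("x", "y")] == 0))
    stop_fmt("panel '%s': %s vector is zero", panel, key)
  v[c("x", "y")]
}

#' Parse a CrystFEL detector geometry description
#'
#' Reads the plain-text `key = value` panel blocks of a CrystFEL geometry file
#' and precomputes, for every raw-layout pixel covered by a panel, its
#' lab-frame coordinates (metres) and its target cell in the assembled image.
#'
#' Supported panel keys: `fs`, `ss` (direction vectors such as `+1.0x -0.5y`),
#' `corner_x`, `corner_y` (lab position of the panel's first pixel, in pixel
#' units), `min_fs`/`max_fs`/`min_ss`/`max_ss` (inclusive 0-based raw-layout
#' slab bounds), `res` (pixels per metre; the pixel size is its reciprocal)
#' and the optional `coffset` (extra camera length in metres). Keys given
#' without a panel prefix act as defaults for all panels. Unknown keys are
#' ignored with a warning. Comments start with `;`.
#'
#' @param text path to a geometry file, or its content as a single string or
#'   a character vector of lines.
#' @return An object of class `geometry_map` with elements `panels`,
#'   `raw_shape`, `lab_shape`, `x_map`/`y_map` (metres, `NA` off-panel),
#'   `coffset_map`, `target_lin` (linear index into the assembled image) and
#'   `collisions` (number of raw pixels whose rounded lab cell is shared).
#' @examples
#' g <- parse_geometry(c(
#'   "p0/min_fs = 0", "p0/max_fs = 63", "p0/min_ss = 0", "p0/max_ss = 63",
#'   "p0/fs = +1.0x", "p0/ss = +1.0y",
#'   "p0/corner_x = 0", "p0/corner_y = 0", "p0/res = 5000"))
#' g$lab_shape
#' @export
parse_geometry <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub(";.*$", "", lines))
  entries <- which(nzchar(lines) & grepl("=", lines, fixed = TRUE))

  globals <- list()
  panels <- list()
  unknown <- character(0)
  for (i in entries) {
    eq <- regexpr("=", lines[i], fixed = TRUE)
    lhs <- trimws(substr(lines[i], 1L, eq - 1L))
    rhs <- trimws(substr(lines[i], eq + 1L, nchar(lines[i])))
    if (grepl("/", lhs, fixed = TRUE)) {
      parts <- strsplit(lhs, "/", fixed = TRUE)[[1]]
      pname <- parts[1]
      key <- parts[2]
      if (!key %in% GEOM_PANEL_KEYS) {
        unknown <- c(unknown, lhs)
        next
      }
      if (is.null(panels[[pname]])) panels[[pname]] <- list(name = pname)
      panels[[pname]][[key]] <- rhs
    } else {
      if (!lhs %in% GEOM_PANEL_KEYS) {
        unknown <- c(unknown, lhs)
        next
      }
      globals[[lhs]] <- rhs
    }
  }
  if (length(unknown))
    warning(sprintf("ignoring unknown geometry keys: %s",
                    paste(unique(unknown), collapse = ", ")), call. = FALSE)
  if (!length(panels)) stop_fmt("no panel blocks found in geometry text")

  num_keys <- c("corner_x", "corner_y", "min_fs", "max_fs", "min_ss", "max_ss",
                "res", "coffset")
  required <- c("fs", "ss", "corner_x", "corner_y",
                "min_fs", "max_fs", "min_ss", "max_ss", "res")
  for (pname in names(panels)) {
    p <- panels[[pname]]
    for (k in GEOM_PANEL_KEYS)
      if (is.null(p[[k]]) && !is.null(globals[[k]])) p[[k]] <- globals[[k]]
    missing <- setdiff(required, names(p))
    if (length(missing))
      stop_fmt("panel '%s': missing required key(s): %s",
               pname, paste(missing, collapse = ", "))
    for (k in intersect(num_keys, names(p))) {
      val <- suppressWarnings(as.numeric(p[[k]]))
      if (is.na(val)) stop_fmt("panel '%s': key '%s' is not numeric ('%s')",
                               pname, k, p[[k]])
      p[[k]] <- val
    }
    p$fs_vec <- parse_axis_vector(p$fs, pname, "fs")
    p$ss_vec <- parse_axis_vector(p$ss, pname, "ss")
    cross <- p$fs_vec[1] * p$ss_vec[2] - p$fs_vec[2] * p$ss_vec[1]
    if (abs(cross) < 1e-12)
      stop_fmt("panel '%s': fs and ss vectors are parallel", pname)
    if (p$max_fs < p$min_fs || p$max_ss < p$min_ss)
      stop_fmt("panel '%s': max_fs/max_ss below min_fs/min_ss", pname)
    if (p$res <= 0) stop_fmt("panel '%s': res must be positive", pname)
    p$pixel_size <- 1 / p$res
    p$coffset <- p$coffset %||% 0
    panels[[pname]] <- p
  }

  raw_nrow <- max(vapply(panels, function(p) p$max_ss, 0)) + 1L
  raw_ncol <- max(vapply(panels, function(p) p$max_fs, 0)) + 1L
  x_map <- matrix(NA_real_, raw_nrow, raw_ncol)
  y_map <- matrix(NA_real_, raw_nrow, raw_ncol)
  x_px <- matrix(NA_real_, raw_nrow, raw_ncol)
  y_px <- matrix(NA_real_, raw_nrow, raw_ncol)
  coffset_map <- matrix(NA_real_, raw_nrow, raw_ncol)
  covered_by <- matrix("", raw_nrow, raw_ncol)

  for (p in panels) {
    rows <- (p$min_ss:p$max_ss) + 1L
    cols <- (p$min_fs:p$max_fs) + 1L
    clash <- covered_by[rows, cols] != ""
    if (any(clash))
      stop_fmt("raw-layout slab of panel '%s' overlaps panel '%s'",
               p$name, covered_by[rows, cols][clash][1])
    covered_by[rows, cols] <- p$name
    rel_ss <- matrix(rep(0:(length(rows) - 1L), length(cols)), length(rows))
    rel_fs <- matrix(rep(0:(length(cols) - 1L), each = length(rows)), length(rows))
    px <- p$corner_x + rel_fs * p$fs_vec[1] + rel_ss * p$ss_vec[1]
    py <- p$corner_y + rel_fs * p$fs_vec[2] + rel_ss * p$ss_vec[2]
    x_px[rows, cols] <- px
    y_px[rows, cols] <- py
    x_map[rows, cols] <- px * p$pixel_size
    y_map[rows, cols] <- py * p$pixel_size
    coffset_map[rows, cols] <- p$coffset
  }

  covered <- covered_by != ""
  # nearest-cell placement; half-way coordinates round up so that panels on a
  # half-integer grid (pixel-centre beam conventions) never self-collide
  gc_col <- floor(x_px + 0.5)
  gc_row <- floor(y_px + 0.5)
  cmin <- min(gc_col[covered]); rmin <- min(gc_row[covered])
  lab_shape <- c(max(gc_row[covered]) - rmin + 1L, max(gc_col[covered]) - cmin + 1L)
  target_lin <- matrix(NA_real_, raw_nrow, raw_ncol)
  target_lin[covered] <- (gc_col[covered] - cmin) * lab_shape[1] +
    (gc_row[covered] - rmin) + 1
  collisions <- sum(duplicated(target_lin[covered]))

  structure(list(panels = panels,
                 raw_shape = c(raw_nrow, raw_ncol),
                 lab_shape = as.integer(lab_shape),
                 x_map = x_map, y_map = y_map,
                 coffset_map = coffset_map,
                 covered = covered,
                 target_lin = target_lin,
                 collisions = collisions),
            class = "geometry_map")
}

#' @export
print.geometry_map <- function(x, ...) {
  cat(sprintf("<geometry_map> %d panel(s), raw %dx%d -> lab %dx%d, %d collision(s)\n",
              length(x$panels), x$raw_shape[1], x$raw_shape[2],
              x$lab_shape[1], x$lab_shape[2], x$collisions))
  invisible(x)
}

#' Assemble a raw-layout frame into the lab frame
#'
#' Places every panel-covered raw pixel into the lab-frame cell nearest its
#' lab coordinate (nearest-cell rounding, no sub-pixel interpolation). Cells
#' not covered by any panel carry `fill`. When two raw pixels round to the
#' same cell their values are summed, so the total intensity over mapped
#' cells always equals the total over raw pixels; a warning reports such
#' collisions (valid geometries have none).
#'
#' @param frame numeric matrix in the raw data layout.
#' @param geom a [parse_geometry()] result.
#' @param fill value for unmapped lab-frame cells (default `NA`).
#' @return numeric matrix of dimension `geom$lab_shape`.
#' @export
assemble <- function(frame, geom, fill = NA_real_) {
  stopifnot(inherits(geom, "geometry_map"))
  if (!identical(dim(frame), as.integer(geom$raw_shape)) &&
      !all(dim(frame) == geom$raw_shape))
    stop_fmt("frame is %dx%d but geometry expects raw layout %dx%d",
             nrow(frame), ncol(frame), geom$raw_shape[1], geom$raw_shape[2])
  if (geom$collisions > 0)
    warning(sprintf("%d raw pixel(s) collide in the lab grid; values summed",
                    geom$collisions), call. = FALSE)
  out <- matrix(fill, geom$lab_shape[1], geom$lab_shape[2])
  idx <- which(geom$covered)
  sums <- rowsum(frame[idx], group = geom$target_lin[idx])
  out[as.numeric(rownames(sums))] <- sums
  out
}

#' Beam geometry (wavelength and camera length)
#'
#' @param wavelength photon wavelength in angstrom.
#' @param detector_distance sample-detector distance in metres. The direct
#'   beam defines the lab-frame origin (0, 0).
#' @return object of class `beam_geometry`.
#' @export
beam_geometry <- function(wavelength, detector_distance) {
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop_fmt("wavelength must be positive (angstrom)")
  if (!is.numeric(detector_distance) || detector_distance <= 0)
    stop_fmt("detector_distance must be positive (metres)")
  structure(list(wavelength = wavelength,
                 detector_distance = detector_distance),
            class = "beam_geometry")
}

#' Momentum transfer for a detector radius
#'
#' Elastic-scattering momentum transfer `q = (4*pi/lambda) * sin(theta)` with
#' `theta = arctan(r / d) / 2`, where `lambda` is the photon wavelength in
#' angstrom, `r` the distance of the pixel from the direct beam and `d` the
#' detector distance (both metres). Monotonically increasing in `r`, with
#' `q(0) = 0`.
#'
#' @param radius distance(s) from the direct beam, metres; must be `>= 0`.
#' @param beam a [beam_geometry()].
#' @param coffset extra camera length (metres) added to the detector
#'   distance, e.g. a panel's `coffset`.
#' @return q in inverse angstrom, same shape as `radius`.
#' @export
q_of <- function(radius, beam, coffset = 0) {
  stopifnot(inherits(beam, "beam_geometry"))
  if (any(radius < 0, na.rm = TRUE)) stop_fmt("radius must be >= 0")
  d <- beam$detector_distance + coffset
  if (any(d <= 0)) stop_fmt("detector distance (incl. coffset) must be positive")
  (4 * pi / beam$wavelength) * sin(0.5 * atan(radius / d))
}

#' Diffraction resolution (Bragg d-spacing) for a detector radius
#'
#' `d-spacing = lambda / (2 sin(theta)) = 2*pi / q_of(radius)`. Strictly
#' decreasing in radius; a radius of 0 yields `Inf` (unbounded resolution),
#' not an error.
#'
#' @inheritParams q_of
#' @return d-spacing in angstrom.
#' @export
resolution_of <- function(radius, beam, coffset = 0) {
  q <- q_of(radius, beam, coffset)
  ifelse(q == 0, Inf, 2 * pi / q)
}

#' Per-pixel maps of radius, q and resolution
#'
#' Radius is evaluated at pixel centres from the lab-frame coordinate maps;
#' q and resolution use the panel-local detector distance (global distance
#' plus the panel's `coffset`). Off-panel pixels are `NA`.
#'
#' @param geom a [parse_geometry()] result.
#' @param beam a [beam_geometry()].
#' @return numeric matrix in the raw data layout.
#' @export
radius_map <- function(geom) {
  stopifnot(inherits(geom, "geometry_map"))
  sqrt(geom$x_map^2 + geom$y_map^2)
}

#' @rdname radius_map
#' @export
q_map <- function(geom, beam) {
  r <- radius_map(geom)
  d <- beam$detector_distance + geom$coffset_map
  (4 * pi / beam$wavelength) * sin(0.5 * atan(r / d))
}

#' @rdname radius_map
#' @export
resolution_map <- function(geom, beam) {
  q <- q_map(geom, beam)
  ifelse(q == 0, Inf, 2 * pi / q)
}
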