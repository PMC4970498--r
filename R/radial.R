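# Geometry-aware radial q-profiles and single-particle diagnostics.

#' Geometry-aware radial average in q
#'
#' Every unmasked, panel-covered, finite pixel contributes its value as a
#' weight to the histogram bin of its momentum transfer q; each bin is then
#' normalised by its entry count. Because pixels enter through their true
#' lab-frame q, detector tile gaps and masked regions reduce only the bin
#' counts and never bias the averaged values, unlike a naive projection of
#' the assembled image. Bins are uniform and half-open `[lo, hi)` (the top
#' edge closed); empty bins are `NA`, never zero-filled.
#'
#' @param frame corrected frame in the raw data layout.
#' @param geom a [parse_geometry()] result.
#' @param beam a [beam_geometry()].
#' @param mask optional 0/1 bad-pixel map.
#' @param nbins number of q bins.
#' @param q_range `c(lo, hi)` in inverse angstrom; defaults to the detector's
#'   q extent.
#' @return object of class `radial_profile` with `q_edges`, `q_mid`,
#'   `values`, `counts`.
#' @export
radial_average <- function(frame, geom, beam, mask = NULL, nbins = 100L,
                           q_range = NULL) {
  stopifnot(inherits(geom, "geometry_map"), inherits(beam, "beam_geometry"))
  if (!all(dim(frame) == geom$raw_shape))
    stop_fmt("frame shape does not match geometry raw layout")
  qm <- q_map(geom, beam)
  use <- geom$covered & is.finite(frame)
  if (!is.null(mask)) use <- use & (mask == 0)
  if (is.null(q_range)) {
    if (!any(use)) q_range <- c(0, 1) else q_range <- range(qm[use])
  }
  if (q_range[2] <= q_range[1]) stop_fmt("invalid q_range")
  edges <- seq(q_range[1], q_range[2], length.out = nbins + 1L)
  values <- rep(NA_real_, nbins)
  counts <- integer(nbins)
  if (any(use)) {
    qv <- qm[use]
    wv <- frame[use]
    bin <- findInterval(qv, edges, rightmost.closed = TRUE)
    inb <- bin >= 1L & bin <= nbins
    if (any(inb)) {
      counts <- tabulate(bin[inb], nbins)
      s <- rowsum(wv[inb], group = bin[inb])
      values[as.integer(rownames(s))] <- s / counts[as.integer(rownames(s))]
    }
  } else {
    warning("all pixels masked; radial profile is empty", call. = FALSE)
  }
  structure(list(q_edges = edges,
                 q_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 values = values, counts = counts),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d bins, q in [%.4g, %.4g] 1/A, %d populated\n",
              length(x$values), x$q_edges[1], x$q_edges[length(x$q_edges)],
              sum(x$counts > 0)))
  invisible(x)
}

#' Locate nodes (strict local minima) of a 1D trace
#'
#' A node is a strict local minimum: `x[i] < x[i-1]` and `x[i] < x[i+1]`.
#' `NA` entries never qualify and break comparisons. Optional smoothing
#' applies a centred moving average of window 3 before the search (off by
#' default).
#'
#' @param trace numeric vector (e.g. `radial_profile$values`).
#' @param search_range optional inclusive index interval `c(lo, hi)`.
#' @param smooth apply window-3 moving average first.
#' @return ascending integer indices of the minima (possibly none).
#' @export
find_nodes <- function(trace, search_range = NULL, smooth = FALSE) {
  if (inherits(trace, "radial_profile")) trace <- trace$values
  n <- length(trace)
  if (n < 3L) return(integer(0))
  if (smooth) {
    sm <- stats::filter(trace, rep(1 / 3, 3), sides = 2)
    trace <- as.numeric(sm)
  }
  i <- 2:(n - 1L)
  ok <- !is.na(trace[i]) & !is.na(trace[i - 1L]) & !is.na(trace[i + 1L]) &
    trace[i] < trace[i - 1L] & trace[i] < trace[i + 1L]
  nodes <- i[ok]
  if (!is.null(search_range))
    nodes <- nodes[nodes >= search_range[1] & nodes <= search_range[2]]
  nodes
}

#' Distance between the first two nodes of a trace
#'
#' For oscillatory single-particle profiles (sphere form factor) the spacing
#' of the first two minima is inversely proportional to the particle size, so
#' histogramming this distance monitors sample-size uniformity. Returns `NA`
#' when fewer than two nodes exist.
#'
#' @param trace numeric vector or a `radial_profile`.
#' @param units `"bins"` (index difference) or `"q"` (difference of bin-centre
#'   q, requires a `radial_profile`).
#' @inheritParams find_nodes
#' @return numeric distance or `NA`.
#' @export
node_distance <- function(trace, units = c("bins", "q"), search_range = NULL,
                          smooth = FALSE) {
  units <- match.arg(units)
  prof <- NULL
  if (inherits(trace, "radial_profile")) {
    prof <- trace
    trace <- prof$values
  }
  nodes <- find_nodes(trace, search_range, smooth)
  if (length(nodes) < 2L) return(NA_real_)
  if (units == "q") {
    if (is.null(prof)) stop_fmt("q units need a radial_profile input")
    return(prof$q_mid[nodes[2]] - prof$q_mid[nodes[1]])
  }
  as.numeric(nodes[2] - nodes[1])
}

#' Circular autocorrelation of an image (Cartesian coordinates)
#'
#' Computed by transform-multiply-inverse (periodic boundaries). The
#' zero-shift cell `[1, 1]` equals the sum of squared pixel values, and the
#' result is symmetric under point inversion modulo the image size.
#'
#' @param image numeric matrix.
#' @return matrix of the same size; entry `[i, j]` is the correlation at
#'   shift `(i-1, j-1)`.
#' @export
autocorrelate_cartesian <- function(image) {
  F <- fft(image)
  Re(fft(F * Conj(F), inverse = TRUE)) / length(image)
}

#' Angular autocorrelation in polar coordinates
#'
#' Resamples the image onto a polar grid by bilinear interpolation (samples
#' outside the image count as 0), then computes, at every radius, the
#' circular autocorrelation over the angle. A circularly symmetric image is
#' flat in angular lag at every radius; n-fold symmetric features produce
#' peaks at lags of 2*pi/n.
#'
#' @param image numeric matrix.
#' @param center `c(row, col)` of the beam axis; image centre by default.
#' @param nradii,nangles polar grid size.
#' @param rmax maximum sampled radius (pixels); default reaches the nearest
#'   image edge.
#' @return `nradii x nangles` matrix: radius x angular lag.
#' @export
autocorrelate_polar <- function(image, center = NULL, nradii = 64L,
                                nangles = 180L, rmax = NULL) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  if (is.null(rmax))
    rmax <- min(center[1] - 1, nr - center[1], center[2] - 1, nc - center[2])
  radii <- seq(0, rmax, length.out = nradii)
  angles <- seq(0, 2 * pi, length.out = nangles + 1L)[seq_len(nangles)]
  P <- matrix(0, nradii, nangles)
  for (j in seq_len(nangles)) {
    rr <- center[1] + radii * sin(angles[j])
    cc <- center[2] + radii * cos(angles[j])
    P[, j] <- bilinear_sample(image, rr, cc)
  }
  out <- matrix(0, nradii, nangles)
  for (i in seq_len(nradii)) {
    a <- P[i, ]
    A <- fft(a)
    out[i, ] <- Re(fft(A * Conj(A), inverse = TRUE)) / nangles
  }
  out
}

bilinear_sample <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- image[cbind(ri[ok], ci[ok])]
    v
  }
  val(r0, c0) * (1 - fr) * (1 - fc) +
    val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc +
    val(r0 + 1, c0 + 1) * fr * fc
}

#' Power spectrum of an image
#'
#' Squared modulus of the 2D discrete Fourier transform with the zero
#' frequency shifted to the centre. Satisfies Parseval's identity
#' `sum(P) / N = sum(x^2)` and is invariant under circular translations of
#' the input.
#'
#' @param image numeric matrix.
#' @return matrix of the same size, zero frequency centred.
#' @export
power_spectrum <- function(image) {
  p <- Mod(fft(image))^2
  fftshift2(p)
}

fftshift2 <- function(m) {
  sh <- function(n) {
    k <- ceiling(n / 2)
    if (k >= n) seq_len(n) else c((k + 1L):n, 1:k)
  }
  m[sh(nrow(m)), sh(ncol(m)), drop = FALSE]
}
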