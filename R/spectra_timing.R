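# Worked analysis chains: X-ray fluorescence spectrum extraction and
# timing-tool delay extraction.

#' Extract a fluorescence spectrum from a dispersive detector area
#'
#' Implements the two-step live chain: (a) keep only pixels whose ADU values
#' lie in the single-photon acceptance window `[adu_low, adu_high]` (all
#' other pixels are zeroed); (b) project the region of interest onto the
#' column (x) axis with a per-column normalisation. The default
#' normalisation `"survivors"` divides each column's sum by the number of
#' accepted pixels in that column (columns without survivors are 0);
#' `"roi"` divides by the fixed number of ROI pixels per column, which makes
#' the spectrum proportional to the per-column photon rate. The per-column
#' survivor counts are always recorded.
#'
#' @param frame offset/gain-corrected frame.
#' @param adu_range `c(low, high)` acceptance window in ADU (default 18-50,
#'   a typical single-photon window).
#' @param roi `list(rows =, cols =)` index vectors of the dispersive area;
#'   whole frame by default.
#' @param normalize `"survivors"` or `"roi"`.
#' @return object of class `fluorescence_spectrum` with `values`, `counts`,
#'   `columns`.
#' @export
fluorescence_spectrum <- function(frame, adu_range = c(18, 50), roi = NULL,
                                  normalize = c("survivors", "roi")) {
  normalize <- match.arg(normalize)
  if (adu_range[1] >= adu_range[2]) stop_fmt("adu_range must satisfy low < high")
  rows <- roi$rows %||% seq_len(nrow(frame))
  cols <- roi$cols %||% seq_len(ncol(frame))
  if (min(rows) < 1 || max(rows) > nrow(frame) ||
      min(cols) < 1 || max(cols) > ncol(frame))
    stop_fmt("roi lies outside the frame (%dx%d)", nrow(frame), ncol(frame))
  sub <- frame[rows, cols, drop = FALSE]
  inr <- sub >= adu_range[1] & sub <= adu_range[2]
  counts <- colSums(inr)
  sums <- colSums(sub * inr)
  values <- switch(normalize,
                   survivors = ifelse(counts > 0, sums / counts, 0),
                   roi = sums / nrow(sub))
  structure(list(values = as.numeric(values), counts = as.numeric(counts),
                 columns = cols, adu_range = adu_range, normalize = normalize),
            class = "fluorescence_spectrum")
}

#' Accumulate an average fluorescence spectrum
#'
#' Running mean over spectra of accepted hit events (condition on
#' [is_hit()] upstream). Both the spectrum values and the per-column counts
#' are averaged.
#'
#' @param state accumulator from a previous call or `NULL`.
#' @param spectrum a [fluorescence_spectrum()] result.
#' @return list with `values`, `counts` (running means) and `n`.
#' @export
accumulate_spectrum <- function(state, spectrum) {
  stopifnot(inherits(spectrum, "fluorescence_spectrum"))
  if (is.null(state))
    return(list(values = spectrum$values, counts = spectrum$counts, n = 1L))
  n <- state$n + 1L
  list(values = state$values + (spectrum$values - state$values) / n,
       counts = state$counts + (spectrum$counts - state$counts) / n,
       n = n)
}

#' Timing-tool chain parameters
#'
#' @param signal_rows row indices containing the spectrally encoded streak.
#' @param background_rows equally wide, disjoint row interval close to the
#'   signal, projected and subtracted as local background.
#' @param reference stored projection (same chain, FEL off) used for
#'   normalisation; must be as long as the image is wide and non-zero
#'   everywhere it divides.
#' @param kernel 1D digital filter convolved with the normalised trace.
#' @return list of class `timing_params`.
#' @export
timing_params <- function(signal_rows, background_rows, reference, kernel) {
  if (length(intersect(signal_rows, background_rows)))
    stop_fmt("signal and background row intervals must be disjoint")
  if (length(signal_rows) != length(background_rows))
    stop_fmt("signal and background row intervals must have equal width")
  structure(list(signal_rows = signal_rows, background_rows = background_rows,
                 reference = reference, kernel = kernel),
            class = "timing_params")
}

# same-length convolution with zero padding: out[i] = sum_j k[j] x[i - j + ctr]
conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  ctr <- (m + 1L) %/% 2L
  xp <- c(numeric(m), x, numeric(m))
  vapply(seq_len(n), function(i) sum(k * xp[m + i + ctr - seq_len(m)]),
         numeric(1))
}

#' Locate the spectral-encoding edge in a timing-tool image
#'
#' Implements the per-shot chain: (a) project the signal rows onto the column
#' axis and subtract the projection of the nearby background rows; (b)
#' subtract the stored FEL-off reference and divide by it; (c) convolve the
#' normalised trace with the digital filter kernel (same-length, zero
#' padded); (d) return the position of the highest point of the convolved
#' signal (first index on ties), which marks the column where the
#' white-light spectrum drops.
#'
#' @param image timing-tool camera frame.
#' @param params a [timing_params()] list.
#' @return list with `edge_pixel` (integer column), `trace` (normalised
#'   signal) and `conv` (convolved trace).
#' @export
timing_edge <- function(image, params) {
  stopifnot(inherits(params, "timing_params"))
  if (length(params$reference) != ncol(image))
    stop_fmt("reference length %d != image width %d",
             length(params$reference), ncol(image))
  if (max(params$signal_rows) > nrow(image) ||
      max(params$background_rows) > nrow(image))
    stop_fmt("row intervals lie outside the image")
  zero <- which(params$reference == 0)
  if (length(zero))
    stop_fmt("reference is zero at column(s) %s",
             paste(head(zero, 5), collapse = ", "))
  s <- colSums(image[params$signal_rows, , drop = FALSE]) -
    colSums(image[params$background_rows, , drop = FALSE])
  tr <- (s - params$reference) / params$reference
  cv <- conv_same(tr, params$kernel)
  list(edge_pixel = which.max(cv), trace = tr, conv = cv)
}

#' Convert an edge position to a corrected pump-probe delay
#'
#' Linear pixel-to-time mapping: `delay = nominal_delay +
#' fs_per_pixel * (edge_pixel - reference_pixel)`. The slope is a beamline
#' calibration supplied as input, never fitted here.
#'
#' @param edge_pixel edge position from [timing_edge()].
#' @param fs_per_pixel calibration slope (femtoseconds per pixel).
#' @param nominal_delay set delay of the shot (fs).
#' @param reference_pixel edge position corresponding to the nominal delay.
#' @return corrected delay in femtoseconds.
#' @export
delay_correct <- function(edge_pixel, fs_per_pixel, nominal_delay,
                          reference_pixel = 0) {
  nominal_delay + fs_per_pixel * (edge_pixel - reference_pixel)
}
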