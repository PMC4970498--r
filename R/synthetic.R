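# Synthetic fixture generators with known ground truth. Every generator is a
# pure function of (parameters, seed): all randomness runs under
# withr::with_seed, leaving the caller's RNG state untouched. Fixtures that
# need several independent draws derive sub-seeds as base_seed + k for
# documented small offsets k chosen by the caller.

#' Simulated dark run with per-pixel pedestal, noise and cosmic-like spikes
#'
#' Per-pixel means mu ~ U(mu_range) and noise sigma ~ U(sigma_range) are
#' drawn once; every frame is mu + Gaussian noise. A fraction
#' `outlier_fraction` of pixel-events is replaced by large spikes
#' (mu + U(outlier_amp)), emulating cosmic rays in dark frames.
#'
#' @param shape `c(nrow, ncol)`.
#' @param mu_range,sigma_range uniform ranges of the per-pixel pedestal and
#'   noise (ADU).
#' @param n_frames number of dark frames.
#' @param outlier_fraction fraction of pixel-events spiked.
#' @param outlier_amp uniform range of spike amplitudes above the pedestal.
#' @param seed integer seed.
#' @return list with `frames` (3D array), and `truth` (mu and sigma maps,
#'   spike index matrix, parameters, seed).
#' @export
gen_dark_run <- function(shape = c(64, 64), mu_range = c(50, 150),
                         sigma_range = c(1, 5), n_frames = 200L,
                         outlier_fraction = 0.001,
                         outlier_amp = c(1000, 5000), seed = 1L) {
  withr::with_seed(seed, {
    npix <- prod(shape)
    mu <- runif(npix, mu_range[1], mu_range[2])
    sigma <- runif(npix, sigma_range[1], sigma_range[2])
    X <- mu + matrix(rnorm(npix * n_frames), npix, n_frames) * sigma
    n_spikes <- round(outlier_fraction * npix * n_frames)
    spikes <- integer(0)
    if (n_spikes > 0) {
      spikes <- sample.int(npix * n_frames, n_spikes)
      X[spikes] <- rep(mu, n_frames)[spikes] +
        runif(n_spikes, outlier_amp[1], outlier_amp[2])
    }
    list(frames = array(X, dim = c(shape, n_frames)),
         truth = list(mu = matrix(mu, shape[1], shape[2]),
                      sigma = matrix(sigma, shape[1], shape[2]),
                      spikes = spikes, n_frames = n_frames, seed = seed))
  })
}

#' Synthetic Bragg frame: Gaussian spots on Gaussian noise
#'
#' Places `n_peaks` 2D Gaussian spots at random non-overlapping positions
#' (pairwise separation at least `min_sep`, margin `margin` from the frame
#' edge so analysis boxes stay inside) on a zero-mean Gaussian background.
#'
#' @param shape `c(nrow, ncol)`.
#' @param n_peaks number of injected spots.
#' @param amplitude_range,width_range uniform ranges of spot amplitude (ADU)
#'   and Gaussian sigma (pixels).
#' @param background_sigma background noise sigma (ADU).
#' @param min_sep minimum centre-to-centre separation (pixels).
#' @param margin minimum distance of centres from the frame edge.
#' @param seed integer seed.
#' @return list with `frame` and `truth` (data frame of centres, amplitudes,
#'   widths).
#' @export
gen_bragg_frame <- function(shape = c(48, 48), n_peaks = 5L,
                            amplitude_range = c(30, 300),
                            width_range = c(0.8, 1.5), background_sigma = 3,
                            min_sep = 11, margin = 7, seed = 1L) {
  withr::with_seed(seed, {
    frame <- matrix(rnorm(prod(shape), 0, background_sigma), shape[1], shape[2])
    centres <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centres) < n_peaks) {
      cand <- c(runif(1, margin + 1, shape[1] - margin),
                runif(1, margin + 1, shape[2] - margin))
      if (!nrow(centres) ||
          all(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2)
              >= min_sep)) {
        centres <- rbind(centres, cand)
      }
      tries <- tries + 1L
      if (tries > 5000L)
        stop_fmt("cannot place %d peaks with min_sep %g on a %dx%d frame",
                 n_peaks, min_sep, shape[1], shape[2])
    }
    amp <- if (n_peaks) runif(n_peaks, amplitude_range[1], amplitude_range[2]) else numeric(0)
    wid <- if (n_peaks) runif(n_peaks, width_range[1], width_range[2]) else numeric(0)
    for (k in seq_len(n_peaks)) {
      half <- ceiling(4 * wid[k])
      rr <- max(1, floor(centres[k, 1] - half)):min(shape[1], ceiling(centres[k, 1] + half))
      cc <- max(1, floor(centres[k, 2] - half)):min(shape[2], ceiling(centres[k, 2] + half))
      g <- outer(rr, cc, function(r, c)
        exp(-((r - centres[k, 1])^2 + (c - centres[k, 2])^2) / (2 * wid[k]^2)))
      frame[rr, cc] <- frame[rr, cc] + amp[k] * g
    }
    truth <- data.frame(row = centres[, 1][seq_len(n_peaks)],
                        col = centres[, 2][seq_len(n_peaks)],
                        amplitude = amp, width = wid)
    list(frame = frame, truth = truth)
  })
}

#' Isotropic scattering ring at a known q
#'
#' Pixels whose momentum transfer lies within `q0 +/- width` are set to
#' `value`; everything else is 0, plus optional Gaussian noise.
#'
#' @param geom,beam detector and beam geometry.
#' @param q0,width ring centre and half-width (1/angstrom).
#' @param value ring intensity (ADU).
#' @param noise_sigma Gaussian noise sigma (0 = noiseless).
#' @param seed integer seed (used only when noise_sigma > 0).
#' @return frame in the raw data layout (off-panel pixels 0).
#' @export
gen_ring_frame <- function(geom, beam, q0, width, value = 100,
                           noise_sigma = 0, seed = 1L) {
  qm <- q_map(geom, beam)
  frame <- matrix(0, geom$raw_shape[1], geom$raw_shape[2])
  inring <- !is.na(qm) & abs(qm - q0) <= width
  frame[inring] <- value
  if (noise_sigma > 0)
    frame <- frame + withr::with_seed(seed,
      matrix(rnorm(length(frame), 0, noise_sigma), nrow(frame)))
  frame
}

#' Diffraction of a uniform sphere (form-factor intensity)
#'
#' Intensity per pixel `I(q) = intensity * [3 (sin(qR) - qR cos(qR)) /
#' (qR)^3]^2` with `R = diameter / 2`. The first minimum sits at
#' `qR ~ 4.4934` (first positive root of `tan x = x`), and all minima scale
#' as 1/R, so the node spacing of the radial profile is inversely
#' proportional to the particle size.
#'
#' @param geom,beam detector and beam geometry.
#' @param diameter sphere diameter in angstrom.
#' @param intensity forward-scattering intensity (value at q -> 0).
#' @param noise_sigma Gaussian noise sigma (0 = noiseless).
#' @param seed integer seed (used only when noise_sigma > 0).
#' @return frame in the raw data layout (off-panel pixels 0).
#' @export
gen_sphere_frame <- function(geom, beam, diameter, intensity = 1000,
                             noise_sigma = 0, seed = 1L) {
  qm <- q_map(geom, beam)
  R <- diameter / 2
  x <- qm * R
  f <- ifelse(is.na(x) | x == 0, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  frame <- intensity * f^2
  frame[is.na(qm)] <- 0
  if (noise_sigma > 0)
    frame <- frame + withr::with_seed(seed,
      matrix(rnorm(length(frame), 0, noise_sigma), nrow(frame)))
  frame
}

#' Synthetic timing-tool image with a known spectral edge
#'
#' The FEL-off reference is a smooth positive white-light spectrum; the
#' signal rows carry that spectrum multiplied by a smooth downward step of
#' relative `depth` centred at `edge_col` (width `edge_width` pixels,
#' emulating the finite sharpness of the spectral encoding). Background rows
#' carry only the baseline. The returned kernel is an antisymmetric
#' derivative-of-Gaussian filter whose convolution with the normalised trace
#' peaks at the edge.
#'
#' @param shape `c(nrow, ncol)` of the camera image.
#' @param edge_col true edge position (column).
#' @param depth relative drop of the spectrum after the edge (0-1).
#' @param noise_sigma per-pixel Gaussian noise sigma (ADU).
#' @param edge_width Gaussian width of the step (pixels).
#' @param signal_rows,background_rows row intervals used by the chain.
#' @param kernel_sigma,kernel_half_width filter shape.
#' @param baseline additive per-pixel baseline (ADU).
#' @param seed integer seed.
#' @return list with `image`, `reference`, `kernel`, a ready
#'   [timing_params()] object `params`, and `truth`.
#' @export
gen_timing_image <- function(shape = c(100, 1024), edge_col = 512L,
                             depth = 0.3, noise_sigma = 0, edge_width = 1.5,
                             signal_rows = 21:40, background_rows = 61:80,
                             kernel_sigma = 3, kernel_half_width = 10L,
                             baseline = 20, seed = 1L) {
  nc <- shape[2]
  khw <- kernel_half_width
  if (edge_col <= khw + 1L || edge_col >= nc - khw)
    stop_fmt("edge_col %d too close to the image border for kernel half-width %d",
             edge_col, khw)
  cols <- seq_len(nc)
  ref_row <- 500 * exp(-(cols - nc / 2)^2 / (2 * (nc / 3)^2)) + 100
  step <- 1 - depth * pnorm((cols - edge_col) / edge_width)
  nsig <- length(signal_rows)
  img <- withr::with_seed(seed, {
    m <- matrix(baseline, shape[1], nc)
    for (r in signal_rows) m[r, ] <- m[r, ] + (ref_row / nsig) * step
    if (noise_sigma > 0) m <- m + matrix(rnorm(length(m), 0, noise_sigma), shape[1])
    m
  })
  u <- (-khw):khw
  kernel <- u * exp(-u^2 / (2 * kernel_sigma^2))
  reference <- ref_row  # column projection of signal minus background, FEL off
  list(image = img, reference = reference, kernel = kernel,
       params = timing_params(signal_rows, background_rows, reference, kernel),
       truth = list(edge_col = edge_col, depth = depth,
                    edge_width = edge_width, seed = seed))
}

#' Single-photon fluorescence frame with a known rate profile
#'
#' Per-pixel Poisson photon counts at the given rate, converted to ADU with
#' `adu_per_photon`, plus Gaussian readout noise.
#'
#' @param shape `c(nrow, ncol)`.
#' @param rate per-pixel Poisson rate: a scalar, a per-column vector of
#'   length `ncol` (recycled down rows), or a full matrix.
#' @param adu_per_photon detector gain (ADU per photon).
#' @param noise_sigma readout noise sigma (ADU).
#' @param seed integer seed.
#' @return list with `frame` and `truth` (rate map and photon-count matrix).
#' @export
gen_fluorescence_frame <- function(shape = c(64, 128), rate = 0.05,
                                   adu_per_photon = 30, noise_sigma = 3,
                                   seed = 1L) {
  rate_map <- if (is.matrix(rate)) rate
  else if (length(rate) == shape[2]) matrix(rate, shape[1], shape[2], byrow = TRUE)
  else matrix(rate, shape[1], shape[2])
  if (!all(dim(rate_map) == shape)) stop_fmt("rate has the wrong shape")
  withr::with_seed(seed, {
    photons <- matrix(rpois(prod(shape), as.numeric(rate_map)),
                      shape[1], shape[2])
    frame <- photons * adu_per_photon +
      matrix(rnorm(prod(shape), 0, noise_sigma), shape[1], shape[2])
    list(frame = frame, truth = list(rate = rate_map, photons = photons,
                                     adu_per_photon = adu_per_photon,
                                     seed = seed))
  })
}
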