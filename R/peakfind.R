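# SNR-based Bragg-peak finding, hit classification, saturation statistics,
# virtual powder patterns and hit-rate bookkeeping.

#' Peak-finder parameters
#'
#' @param pixel_threshold seed threshold in ADU: only pixels above it can
#'   start a peak search.
#' @param box_half_width half-width `h` of the local `(2h+1) x (2h+1)`
#'   analysis box around a seed.
#' @param snr_background SNR above which box pixels are stripped from the
#'   background distribution during iterative background estimation.
#' @param snr_peak SNR above which box pixels may join the peak.
#' @param min_npix minimum connected member pixels for an accepted peak.
#' @param hit_range inclusive `c(lower, upper)` peak-count interval that
#'   classifies an event as a crystal hit.
#' @param saturation_threshold ADU above which a peak's highest pixel counts
#'   as saturated.
#' @param eps floor applied to the background standard deviation.
#' @return list of class `peak_params`.
#' @export
peak_params <- function(pixel_threshold = 20, box_half_width = 4,
                        snr_background = 3, snr_peak = 3, min_npix = 3,
                        hit_range = c(5, Inf), saturation_threshold = 15000,
                        eps = 1e-6) {
  stopifnot(box_half_width >= 1, min_npix >= 1,
            hit_range[1] <= hit_range[2])
  structure(list(pixel_threshold = pixel_threshold,
                 box_half_width = as.integer(box_half_width),
                 snr_background = snr_background, snr_peak = snr_peak,
                 min_npix = as.integer(min_npix), hit_range = hit_range,
                 saturation_threshold = saturation_threshold, eps = eps),
            class = "peak_params")
}

empty_peak_table <- function() {
  structure(data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                       center_index = integer(0), seed_row = integer(0),
                       seed_col = integer(0), max_value = numeric(0),
                       integrated = numeric(0), npix = integer(0)),
            class = c("peak_table", "data.frame"))
}

# 8-connected flood fill from the box centre over `ok` cells
flood8 <- function(ok, r0, c0) {
  mem <- matrix(FALSE, nrow(ok), ncol(ok))
  if (!ok[r0, c0]) return(mem)
  stack <- list(c(r0, c0))
  mem[r0, c0] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      rr <- p[1] + dr; cc <- p[2] + dc
      if (rr < 1 || cc < 1 || rr > nrow(ok) || cc > ncol(ok)) next
      if (ok[rr, cc] && !mem[rr, cc]) {
        mem[rr, cc] <- TRUE
        stack[[length(stack) + 1L]] <- c(rr, cc)
      }
    }
  }
  mem
}

#' Find Bragg-peak candidates by local SNR analysis
#'
#' Scans the frame in row-major order for unmasked pixels above
#' `pixel_threshold`. A candidate seeds a peak only if it is the first
#' row-major maximum of its local box (boxes crossing the frame edge are
#' skipped). The box's background mean and standard deviation are then
#' estimated iteratively: pixels whose SNR `(x - mean)/stdv` exceeds
#' `snr_background` are stripped and the statistics recomputed until none
#' exceed it. Pixels in the box with SNR above `snr_peak` that are
#' 8-connected to the seed become peak members; if at least `min_npix`
#' survive, a table row is emitted with the intensity-weighted centroid
#' (weights are background-subtracted values), the seed's position and linear
#' index (`center_index`, R column-major 1-based), the highest member value,
#' the integrated background-subtracted intensity and the member count.
#' Member pixels of accepted peaks are not reused as seeds. Masked and
#' non-finite pixels never seed and never join peaks, and are excluded from
#' box statistics.
#'
#' @param frame corrected frame (matrix).
#' @param params a [peak_params()] list.
#' @param mask optional 0/1 bad-pixel map.
#' @return a `peak_table` data frame (possibly 0 rows).
#' @export
find_peaks <- function(frame, params = peak_params(), mask = NULL) {
  stopifnot(inherits(params, "peak_params"), is.matrix(frame))
  nr <- nrow(frame); nc <- ncol(frame)
  masked <- if (is.null(mask)) matrix(FALSE, nr, nc) else mask != 0
  masked <- masked | !is.finite(frame)
  h <- params$box_half_width
  w <- 2L * h + 1L
  seed_rm <- h * w + h + 1L  # row-major position of the box centre

  cand <- which(frame > params$pixel_threshold & !masked)
  if (!length(cand)) return(empty_peak_table())
  rs <- ((cand - 1L) %% nr) + 1L
  cs <- ((cand - 1L) %/% nr) + 1L
  ord <- order(rs, cs)

  used <- matrix(FALSE, nr, nc)
  rows <- list()
  for (k in ord) {
    r <- rs[k]; cc <- cs[k]
    if (used[r, cc]) next
    if (r - h < 1L || r + h > nr || cc - h < 1L || cc + h > nc) next
    box <- frame[(r - h):(r + h), (cc - h):(cc + h)]
    bmask <- masked[(r - h):(r + h), (cc - h):(cc + h)]
    vals <- box
    vals[bmask] <- -Inf
    mx <- max(vals)
    if (frame[r, cc] < mx) next
    first_rm <- which(as.vector(t(vals)) == mx)[1]
    if (first_rm != seed_rm) next

    bv <- box[!bmask]
    keep <- rep(TRUE, length(bv))
    m <- mean(bv); s <- max(sd_pop(bv), params$eps)
    for (it in 1:20) {
      rej <- keep & ((bv - m) / s > params$snr_background)
      if (!any(rej)) break
      keep <- keep & !rej
      m <- mean(bv[keep]); s <- max(sd_pop(bv[keep]), params$eps)
    }

    ok <- ((box - m) / s > params$snr_peak) & !bmask
    mem <- flood8(ok, h + 1L, h + 1L)
    npix <- sum(mem)
    if (npix < params$min_npix) next

    co <- which(mem, arr.ind = TRUE)
    absr <- co[, 1] + r - h - 1L
    absc <- co[, 2] + cc - h - 1L
    wts <- frame[cbind(absr, absc)] - m
    integrated <- sum(wts)
    rows[[length(rows) + 1L]] <- data.frame(
      centroid_row = sum(wts * absr) / integrated,
      centroid_col = sum(wts * absc) / integrated,
      center_index = (cc - 1L) * nr + r,
      seed_row = r, seed_col = cc,
      max_value = frame[r, cc],
      integrated = integrated, npix = npix)
    used[cbind(absr, absc)] <- TRUE
  }
  if (!length(rows)) return(empty_peak_table())
  out <- do.call(rbind, rows)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Number of Bragg-peak candidates in a table
#' @param table a `peak_table`.
#' @return row count.
#' @export
count_peaks <- function(table) nrow(table)

#' Classify an event as a crystal hit
#'
#' @param n_peaks number of Bragg-peak candidates found in the frame.
#' @param hit_range inclusive `c(lower, upper)` interval.
#' @return `TRUE` iff `lower <= n_peaks <= upper`.
#' @export
is_hit <- function(n_peaks, hit_range) {
  n_peaks >= hit_range[1] & n_peaks <= hit_range[2]
}

#' Saturated-reflection statistics
#'
#' A peak is saturated when its highest pixel value exceeds
#' `saturation_threshold`. On an empty table the ratio is `NA` (undefined),
#' never 0.
#'
#' @param table a `peak_table`.
#' @param saturation_threshold ADU threshold.
#' @return list with `n_saturated`, `n_total`, `ratio`.
#' @export
saturation_ratio <- function(table, saturation_threshold) {
  n_total <- nrow(table)
  n_sat <- sum(table$max_value > saturation_threshold)
  list(n_saturated = n_sat, n_total = n_total,
       ratio = if (n_total == 0) NA_real_ else n_sat / n_total)
}

#' Running-average accumulators (virtual powder pattern, spectra)
#'
#' `running_mean_update(NULL, x)` starts an accumulator; each further call
#' folds one result into the running mean (all contributions weigh equally).
#' `powder_accumulate` is the same operation applied to accepted hit frames:
#' the accumulated mean image is the virtual powder pattern.
#'
#' @param state accumulator from a previous call, or `NULL` to start.
#' @param x numeric result (scalar, vector or matrix; shape must not change).
#' @return list with `mean` (running mean) and `n` (contributions).
#' @export
running_mean_update <- function(state, x) {
  if (is.null(state)) return(list(mean = x, n = 1L))
  if (length(state$mean) != length(x))
    stop_fmt("accumulator shape changed (%d vs %d values)",
             length(state$mean), length(x))
  n <- state$n + 1L
  list(mean = state$mean + (x - state$mean) / n, n = n)
}

#' @rdname running_mean_update
#' @param frame an accepted hit frame.
#' @export
powder_accumulate <- function(state, frame) running_mean_update(state, frame)

#' Hit rate over a trailing window of events
#'
#' Fraction of hit flags among the most recent `window` events (fewer events
#' than `window` -> fraction over what is available), the live feedback
#' quantity displayed during data collection.
#'
#' @param flags logical vector of per-event hit flags, oldest first.
#' @param window number of most recent events considered (default 2400 FEL
#'   shots).
#' @return fraction in `[0, 1]`; `NA` when no events.
#' @export
hit_rate <- function(flags, window = 2400L) {
  if (!length(flags)) return(NA_real_)
  mean(tail(flags, window))
}
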