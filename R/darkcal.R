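# Dark-run calibration: pixel-wise offset/noise maps with iterative outlier
# rejection, bad-pixel detection, corrections and calibration files.

new_calibration_set <- function(offset, noise, counts, mask,
                                mode = "training", train_size = NA_integer_,
                                n_outlier = NA_real_) {
  stopifnot(all(dim(offset) == dim(noise)),
            all(dim(offset) == dim(counts)),
            all(dim(offset) == dim(mask)))
  structure(list(offset = offset, noise = noise, counts = counts, mask = mask,
                 mode = mode, train_size = train_size, n_outlier = n_outlier),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %dx%d, mode '%s', train_size %s, %d bad pixel(s)\n",
              nrow(x$offset), ncol(x$offset), x$mode,
              as.character(x$train_size), sum(x$mask)))
  invisible(x)
}

# One pass of vectorised per-pixel masked statistics over an npix x n matrix.
masked_stats <- function(X, K) {
  cnt <- rowSums(K)
  m <- rowSums(X * K) / cnt
  v <- rowSums((X - m)^2 * K) / cnt
  list(count = cnt, mean = m, sd = sqrt(pmax(v, 0)))
}

#' Train a dark calibration from a stack of dark frames
#'
#' Computes, per pixel, the mean (offset) and population standard deviation
#' (noise) of the stored values, iteratively discarding values with
#' `|x - mean| > n_outlier * max(noise, eps)` and recomputing until no value
#' is discarded (or `max_iter` passes). The number of surviving values per
#' pixel is recorded in `counts`. The noise floor `eps` only enters the
#' rejection test, never the stored noise map, and prevents perfectly
#' constant pixels from rejecting everything.
#'
#' @param frames list of identically shaped matrices or a 3D array
#'   (`nrow x ncol x n_frames`); at least 2 frames.
#' @param n_outlier outlier-rejection multiplier (default 4).
#' @param eps noise floor in ADU used in the rejection test.
#' @param max_iter cap on rejection passes.
#' @return a `calibration_set` with all-good mask; run
#'   [detect_bad_pixels()] to flag bad pixels.
#' @export
darkcal_train <- function(frames, n_outlier = 4, eps = 1e-6, max_iter = 20L) {
  fl <- as_frame_list(frames)
  if (length(fl) < 2L) stop_fmt("training needs at least 2 frames, got %d", length(fl))
  dims <- dim(fl[[1]])
  ok <- vapply(fl, function(f) all(dim(f) == dims), logical(1))
  if (!all(ok)) stop_fmt("frame %d has a different shape", which(!ok)[1])
  if (n_outlier <= 0) stop_fmt("n_outlier must be positive")

  X <- vapply(fl, as.numeric, numeric(prod(dims)))   # npix x n
  if (is.null(dim(X))) X <- matrix(X, nrow = prod(dims))  # single-pixel frames
  K <- matrix(TRUE, nrow(X), ncol(X))
  st <- masked_stats(X, K)
  for (it in seq_len(max_iter)) {
    rej <- K & (abs(X - st$mean) > n_outlier * pmax(st$sd, eps))
    if (!any(rej)) break
    K <- K & !rej
    st <- masked_stats(X, K)
  }
  new_calibration_set(
    offset = matrix(st$mean, dims[1], dims[2]),
    noise  = matrix(st$sd, dims[1], dims[2]),
    counts = matrix(st$count, dims[1], dims[2]),
    mask   = matrix(0, dims[1], dims[2]),
    mode = "training", train_size = length(fl), n_outlier = n_outlier)
}

#' Add a frame to an existing calibration
#'
#' Per pixel, the new value is skipped when `|x - offset| >
#' n_outlier * max(noise, eps)`. Otherwise, in `cumulative` mode all frames
#' weigh equally (running mean and population variance with count increment);
#' in `exponential` mode recent frames weigh more:
#' `offset <- (1 - alpha) * offset + alpha * x` and
#' `variance <- (1 - alpha) * (variance + alpha * (x - offset_old)^2)`,
#' which tracks slow drifts such as temperature-induced pedestal shifts.
#'
#' @param cal a trained `calibration_set`.
#' @param frame raw frame matching the calibration shape.
#' @param scheme `"cumulative"` or `"exponential"`.
#' @param alpha exponential weight in (0, 1].
#' @param n_outlier rejection multiplier; defaults to the training value.
#' @param eps noise floor for the rejection test.
#' @return updated `calibration_set`.
#' @export
darkcal_update <- function(cal, frame, scheme = c("cumulative", "exponential"),
                           alpha = 0.01, n_outlier = NULL, eps = 1e-6) {
  stopifnot(inherits(cal, "calibration_set"))
  scheme <- match.arg(scheme)
  if (!all(dim(frame) == dim(cal$offset)))
    stop_fmt("frame shape does not match calibration maps")
  n_outlier <- n_outlier %||% cal$n_outlier
  if (scheme == "exponential" && (alpha <= 0 || alpha > 1))
    stop_fmt("alpha must be in (0, 1] for the exponential scheme")

  x <- frame
  ok <- abs(x - cal$offset) <= n_outlier * pmax(cal$noise, eps)
  if (scheme == "cumulative") {
    n0 <- cal$counts
    n1 <- n0 + ok
    delta <- x - cal$offset
    mean_new <- cal$offset + ifelse(ok, delta / pmax(n1, 1), 0)
    M2 <- cal$noise^2 * n0
    M2 <- M2 + ifelse(ok, delta * (x - mean_new), 0)
    cal$offset <- mean_new
    cal$noise <- sqrt(pmax(M2, 0) / pmax(n1, 1))
    cal$counts <- n1
  } else {
    off_old <- cal$offset
    cal$offset <- ifelse(ok, (1 - alpha) * off_old + alpha * x, off_old)
    v <- cal$noise^2
    cal$noise <- sqrt(ifelse(ok, (1 - alpha) * (v + alpha * (x - off_old)^2), v))
    cal$counts <- cal$counts + ok
  }
  cal$mode <- scheme
  cal
}

# iterative outlier-rejected mean/sd of a plain vector (same rejection rule
# as training, applied to a whole map when deriving automatic boundaries)
robust_mean_sd <- function(x, n_outlier, eps = 1e-6, max_iter = 20L) {
  keep <- rep(TRUE, length(x))
  m <- mean(x); s <- sd_pop(x)
  for (it in seq_len(max_iter)) {
    rej <- keep & (abs(x - m) > n_outlier * max(s, eps))
    if (!any(rej)) break
    keep <- keep & !rej
    m <- mean(x[keep]); s <- sd_pop(x[keep])
  }
  c(mean = m, sd = s)
}

#' Flag bad pixels from offset and noise boundaries
#'
#' A pixel is bad (mask = 1) when its offset or its noise lies outside its
#' acceptance interval. With `bounds = "auto"` the intervals are
#' `mean +/- n * stdv` of the offset map and of the noise map, each computed
#' with the same iterative outlier rejection as training so that the bad
#' pixels themselves do not widen the boundaries. Explicit intervals may be
#' given instead as `list(offset = c(lo, hi), noise = c(lo, hi))` (either
#' component may be omitted). Degenerate maps (all pixels identical) yield an
#' all-good mask.
#'
#' @param cal a trained `calibration_set`.
#' @param bounds `"auto"` or an explicit list of intervals.
#' @param n auto-boundary multiplier (default 4).
#' @return the `calibration_set` with an updated 0/1 mask.
#' @export
detect_bad_pixels <- function(cal, bounds = "auto", n = 4) {
  stopifnot(inherits(cal, "calibration_set"))
  if (identical(bounds, "auto")) {
    so <- robust_mean_sd(as.numeric(cal$offset), n)
    sn <- robust_mean_sd(as.numeric(cal$noise), n)
    b_off <- c(so["mean"] - n * so["sd"], so["mean"] + n * so["sd"])
    b_noi <- c(sn["mean"] - n * sn["sd"], sn["mean"] + n * sn["sd"])
  } else {
    b_off <- bounds$offset %||% c(-Inf, Inf)
    b_noi <- bounds$noise %||% c(-Inf, Inf)
  }
  bad <- cal$offset < b_off[1] | cal$offset > b_off[2] |
    cal$noise < b_noi[1] | cal$noise > b_noi[2]
  cal$mask <- bad * 1
  cal
}

#' Apply a dark calibration to a raw frame
#'
#' Two downstream dialects are provided: `"crystfel"` subtracts the offset map
#' and sets masked pixels to `masked_value` (default 0), producing
#' dark-calibrated frames; `"nxds"` leaves pixel values untouched and only
#' sets masked pixels to `masked_value` (default -1, a negative sentinel),
#' since nXDS applies its own corrections to raw data.
#'
#' @param frame raw frame.
#' @param cal a `calibration_set` (offset and mask are used).
#' @param dialect `"crystfel"` or `"nxds"`.
#' @param masked_value substitute for masked pixels; dialect default if `NULL`.
#' @return corrected frame.
#' @export
apply_correction <- function(frame, cal, dialect = c("crystfel", "nxds"),
                             masked_value = NULL) {
  stopifnot(inherits(cal, "calibration_set"))
  dialect <- match.arg(dialect)
  if (!all(dim(frame) == dim(cal$offset)))
    stop_fmt("frame shape does not match calibration maps")
  out <- if (dialect == "crystfel") frame - cal$offset else frame
  masked_value <- masked_value %||% if (dialect == "crystfel") 0 else -1
  out[cal$mask == 1] <- masked_value
  out
}

#' Stack calibration maps into one 2D result and split them back
#'
#' The offset, noise, counts and mask maps are stacked vertically (in that
#' fixed order, top to bottom) into a single matrix of 4x the map height;
#' `split_maps()` inverts the stacking exactly.
#'
#' @param cal a `calibration_set`.
#' @return `stack_maps`: a matrix; `split_maps`: a `calibration_set`.
#' @export
stack_maps <- function(cal) {
  stopifnot(inherits(cal, "calibration_set"))
  rbind(cal$offset, cal$noise, cal$counts, cal$mask)
}

#' @rdname stack_maps
#' @param stacked a matrix produced by `stack_maps()`.
#' @param mode,train_size,n_outlier metadata to attach to the rebuilt set
#'   (not stored in the stacked result).
#' @export
split_maps <- function(stacked, mode = "restacked", train_size = NA_integer_,
                       n_outlier = NA_real_) {
  if (nrow(stacked) %% 4L != 0L)
    stop_fmt("stacked height %d is not 4x a map height", nrow(stacked))
  h <- nrow(stacked) %/% 4L
  new_calibration_set(offset = stacked[1:h, , drop = FALSE],
                      noise = stacked[h + 1:h, , drop = FALSE],
                      counts = stacked[2 * h + 1:h, , drop = FALSE],
                      mask = stacked[3 * h + 1:h, , drop = FALSE],
                      mode = mode, train_size = train_size,
                      n_outlier = n_outlier)
}

#' Write / read a calibration file (HDF5)
#'
#' The file holds datasets `/offset`, `/noise`, `/counts` and `/mask` plus
#' root attributes `mode`, `train_size`, `n_outlier` and `timestamp`. When
#' `path` is `NULL` a name is derived from `base_name` and the current time
#' (`<base>_<YYYYmmdd_HHMMSS>.h5`) and a `<base>_latest.h5` alias pointing at
#' the newest file is refreshed (symlink, or copy where symlinks are
#' unavailable).
#'
#' @param cal a `calibration_set`.
#' @param path output file, or `NULL` for automatic timestamped naming.
#' @param base_name,dir base name and directory for automatic naming.
#' @return the path written, invisibly.
#' @export
save_calibration <- function(cal, path = NULL, base_name = "darkcal", dir = ".") {
  stopifnot(inherits(cal, "calibration_set"))
  auto <- is.null(path)
  if (auto) {
    stamp <- format(Sys.time(), "%Y%m%d_%H%M%S")
    path <- file.path(dir, sprintf("%s_%s.h5", base_name, stamp))
    k <- 1L
    while (file.exists(path)) {
      path <- file.path(dir, sprintf("%s_%s_%d.h5", base_name, stamp, k))
      k <- k + 1L
    }
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cal$offset, path, "offset")
  rhdf5::h5write(cal$noise, path, "noise")
  rhdf5::h5write(cal$counts, path, "counts")
  rhdf5::h5write(cal$mask, path, "mask")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(cal$mode, fid, "mode")
  rhdf5::h5writeAttribute(as.integer(cal$train_size), fid, "train_size")
  rhdf5::h5writeAttribute(as.numeric(cal$n_outlier), fid, "n_outlier")
  rhdf5::h5writeAttribute(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), fid, "timestamp")
  rhdf5::H5Fclose(fid)
  if (auto) {
    latest <- file.path(dirname(path), sprintf("%s_latest.h5", base_name))
    suppressWarnings(file.remove(latest))
    ok <- suppressWarnings(file.symlink(basename(path), latest))
    if (!isTRUE(ok)) file.copy(path, latest, overwrite = TRUE)
  }
  invisible(path)
}

#' @rdname save_calibration
#' @param train_size fallback contribution count when the file carries no
#'   `/counts` dataset and no `train_size` attribute: counts are then set to
#'   this value everywhere.
#' @param mask_n auto-boundary multiplier used to regenerate the mask when
#'   the file carries none.
#' @export
load_calibration <- function(path, train_size = NULL, mask_n = 4) {
  if (!file.exists(path)) stop_fmt("no such calibration file: %s", path)
  ls <- rhdf5::h5ls(path)
  have <- ls$name[ls$group == "/"]
  if (!all(c("offset", "noise") %in% have))
    stop_fmt("calibration file lacks offset/noise; found: %s",
             paste(have, collapse = ", "))
  offset <- rhdf5::h5read(path, "offset")
  noise <- rhdf5::h5read(path, "noise")
  attrs <- rhdf5::h5readAttributes(path, "/")
  ts <- attrs$train_size %||% train_size
  mode <- attrs$mode %||% "loaded"
  n_outlier <- attrs$n_outlier %||% NA_real_
  if ("counts" %in% have) {
    counts <- rhdf5::h5read(path, "counts")
  } else {
    if (is.null(ts))
      stop_fmt("file has no counts; supply train_size to substitute them")
    counts <- matrix(as.numeric(ts), nrow(offset), ncol(offset))
  }
  cal <- new_calibration_set(offset = offset, noise = noise, counts = counts,
                             mask = matrix(0, nrow(offset), ncol(offset)),
                             mode = as.character(mode),
                             train_size = as.integer(ts %||% NA),
                             n_outlier = as.numeric(n_outlier))
  if ("mask" %in% have) {
    cal$mask <- rhdf5::h5read(path, "mask")
  } else {
    cal <- detect_bad_pixels(cal, "auto", n = mask_n)
  }
  cal
}

#' Common-mode correction (convenience utility)
#'
#' Subtracts, from every row, the median of that row's unmasked pixels. A
#' simple generic scheme for correlated per-readout-row baseline shifts,
#' provided as a convenience; detector-specific common-mode models are out of
#' scope.
#'
#' @param frame dark-corrected frame.
#' @param mask optional 0/1 bad-pixel map; masked pixels are excluded from
#'   the medians but still shifted.
#' @return corrected frame.
#' @export
common_mode_correct <- function(frame, mask = NULL) {
  if (is.null(mask)) mask <- matrix(0, nrow(frame), ncol(frame))
  med <- vapply(seq_len(nrow(frame)), function(r) {
    v <- frame[r, mask[r, ] == 0]
    if (length(v)) median(v) else 0
  }, numeric(1))
  frame - med
}
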