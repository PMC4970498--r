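# Independent brute-force oracles, deliberately written as plain loops and
# kept separate from the package's vectorised implementations.

# Iterative one/two-sided outlier rejection on a plain vector, as used by
# dark-run training (two-sided) -- returns final stats and the survivor mask.
oracle_reject <- function(values, n_outlier, eps = 1e-6, max_iter = 20) {
  keep <- rep(TRUE, length(values))
  for (it in seq_len(max_iter)) {
    v <- values[keep]
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / length(v))
    out <- abs(values - m) > n_outlier * max(s, eps) & keep
    if (!any(out)) break
    keep[out] <- FALSE
  }
  v <- values[keep]
  m <- sum(v) / length(v)
  list(mean = m, sd = sqrt(sum((v - m)^2) / length(v)), keep = keep)
}

# Direct per-pixel placement: loop over every raw pixel, recompute its lab
# position from the panel entries and drop it into the rounded grid cell.
oracle_assemble <- function(frame, geom, fill = NA_real_) {
  xs <- c(); ys <- c(); vs <- c()
  for (p in geom$panels) {
    for (iss in p$min_ss:p$max_ss) for (ifs in p$min_fs:p$max_fs) {
      x <- p$corner_x + (ifs - p$min_fs) * p$fs_vec[1] + (iss - p$min_ss) * p$ss_vec[1]
      y <- p$corner_y + (ifs - p$min_fs) * p$fs_vec[2] + (iss - p$min_ss) * p$ss_vec[2]
      xs <- c(xs, floor(x + 0.5)); ys <- c(ys, floor(y + 0.5))
      vs <- c(vs, frame[iss + 1, ifs + 1])
    }
  }
  out <- matrix(fill, max(ys) - min(ys) + 1, max(xs) - min(xs) + 1)
  for (k in seq_along(vs)) {
    r <- ys[k] - min(ys) + 1; c <- xs[k] - min(xs) + 1
    out[r, c] <- if (is.na(out[r, c])) vs[k] else out[r, c] + vs[k]
  }
  out
}

# O(N^4) direct-sum circular autocorrelation.
oracle_autocorr <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (dr in 0:(nr - 1)) for (dc in 0:(nc - 1)) {
    s <- 0
    for (r in 1:nr) for (c in 1:nc) {
      r2 <- ((r - 1 + dr) %% nr) + 1
      c2 <- ((c - 1 + dc) %% nc) + 1
      s <- s + img[r, c] * img[r2, c2]
    }
    out[dr + 1, dc + 1] <- s
  }
  out
}

# Brute-force peak finder: same specification as find_peaks(), independently
# coded with scalar loops and label-propagation connectivity.
oracle_find_peaks <- function(frame, params, mask = NULL) {
  nr <- nrow(frame); nc <- ncol(frame)
  msk <- if (is.null(mask)) matrix(FALSE, nr, nc) else mask != 0
  msk <- msk | !is.finite(frame)
  h <- params$box_half_width
  thr <- params$pixel_threshold
  used <- matrix(FALSE, nr, nc)
  out <- NULL
  for (r in 1:nr) for (cc in 1:nc) {
    if (msk[r, cc] || used[r, cc] || frame[r, cc] <= thr) next
    if (r - h < 1 || r + h > nr || cc - h < 1 || cc + h > nc) next
    # first row-major maximum of the unmasked box
    best <- -Inf; best_r <- NA; best_c <- NA
    for (br in (r - h):(r + h)) for (bc in (cc - h):(cc + h)) {
      if (msk[br, bc]) next
      if (frame[br, bc] > best) { best <- frame[br, bc]; best_r <- br; best_c <- bc }
    }
    if (!(best_r == r && best_c == cc)) next
    # iterative background stripping (one-sided)
    bg <- c()
    for (br in (r - h):(r + h)) for (bc in (cc - h):(cc + h))
      if (!msk[br, bc]) bg <- c(bg, frame[br, bc])
    repeat {
      m <- sum(bg) / length(bg)
      s <- max(sqrt(sum((bg - m)^2) / length(bg)), params$eps)
      drop <- (bg - m) / s > params$snr_background
      if (!any(drop)) break
      bg <- bg[!drop]
    }
    # membership by label propagation from the seed
    mem <- matrix(FALSE, nr, nc)
    okm <- matrix(FALSE, nr, nc)
    for (br in (r - h):(r + h)) for (bc in (cc - h):(cc + h))
      okm[br, bc] <- !msk[br, bc] && (frame[br, bc] - m) / s > params$snr_peak
    if (okm[r, cc]) {
      mem[r, cc] <- TRUE
      changed <- TRUE
      while (changed) {
        changed <- FALSE
        for (br in (r - h):(r + h)) for (bc in (cc - h):(cc + h)) {
          if (mem[br, bc] || !okm[br, bc]) next
          nb <- FALSE
          for (dr in -1:1) for (dc in -1:1) {
            rr <- br + dr; c2 <- bc + dc
            if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc && mem[rr, c2]) nb <- TRUE
          }
          if (nb) { mem[br, bc] <- TRUE; changed <- TRUE }
        }
      }
    }
    npix <- sum(mem)
    if (npix < params$min_npix) next
    wsum <- 0; rsum <- 0; csum <- 0; mx <- -Inf
    for (br in 1:nr) for (bc in 1:nc) if (mem[br, bc]) {
      w <- frame[br, bc] - m
      wsum <- wsum + w; rsum <- rsum + w * br; csum <- csum + w * bc
      if (frame[br, bc] > mx) mx <- frame[br, bc]
      used[br, bc] <- TRUE
    }
    out <- rbind(out, data.frame(
      centroid_row = rsum / wsum, centroid_col = csum / wsum,
      center_index = (cc - 1) * nr + r, seed_row = r, seed_col = cc,
      max_value = frame[r, cc], integrated = wsum, npix = npix))
  }
  if (is.null(out)) out <- felreduce::find_peaks(matrix(0, 3, 3),
                                                 felreduce::peak_params())[0, ]
  out
}

# Hand-decoder for the byte-offset stream, reading escapes byte by byte.
oracle_decode_cbf <- function(bytes) {
  vals <- c(); cur <- 0; p <- 1
  int_from <- function(b) {
    u <- sum(as.numeric(b) * 256^(seq_along(b) - 1))
    if (u >= 2^(8 * length(b) - 1)) u - 2^(8 * length(b)) else u
  }
  while (p <= length(bytes)) {
    d <- int_from(bytes[p]); p <- p + 1
    if (d == -128) {
      d <- int_from(bytes[p:(p + 1)]); p <- p + 2
      if (d == -32768) {
        d <- int_from(bytes[p:(p + 3)]); p <- p + 4
        if (d == -2^31) { d <- int_from(bytes[p:(p + 7)]); p <- p + 8 }
      }
    }
    cur <- cur + d
    vals <- c(vals, cur)
  }
  vals
}
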