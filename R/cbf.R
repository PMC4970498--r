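# CBF output/input with x-CBF_BYTE_OFFSET compression.
#
# Byte-offset encoding: the first element is stored as a delta from 0;
# each subsequent element as a delta from its predecessor. A delta in
# [-127, 127] occupies one signed byte; otherwise the escape byte 0x80 is
# written, followed by the delta as little-endian int16 when it fits in
# [-32767, 32767]; otherwise the further escape 0x8000 and an int32; beyond
# that the escape 0x80000000 and an int64. Decoding inverts this exactly.

CBF_MARKER <- as.raw(c(0x0C, 0x1A, 0x04, 0xD5))

# little-endian two's-complement bytes of x (double holding an integer)
le_bytes <- function(x, nbytes) {
  u <- ifelse(x < 0, x + 2^(8 * nbytes), x)
  vapply(seq_len(nbytes), function(k) as.raw((u %/% 256^(k - 1)) %% 256),
         raw(length(x)))
}

#' Encode / decode an integer stream with the CBF byte-offset scheme
#'
#' @param values numeric vector of integral values (each within int64).
#' @return `encode_byte_offset`: a raw vector; `decode_byte_offset`: a
#'   numeric vector of `n` values.
#' @export
encode_byte_offset <- function(values) {
  d <- diff(c(0, as.numeric(values)))
  n <- length(d)
  if (n == 0L) return(raw(0))
  cls <- ifelse(abs(d) <= 127, 1L,
                ifelse(abs(d) <= 32767, 2L,
                       ifelse(abs(d) <= 2^31 - 1, 3L, 4L)))
  sizes <- c(1L, 3L, 7L, 15L)[cls]
  total <- sum(sizes)
  out <- raw(total)
  pos <- cumsum(c(0L, sizes[-n]))  # 0-based start offset per element

  i1 <- which(cls == 1L)
  if (length(i1)) out[pos[i1] + 1L] <- le_bytes(d[i1], 1L)
  i2 <- which(cls == 2L)
  if (length(i2)) {
    out[pos[i2] + 1L] <- as.raw(0x80)
    b <- le_bytes(d[i2], 2L)
    if (length(i2) == 1L) b <- matrix(b, 1L)
    out[pos[i2] + 2L] <- b[, 1]
    out[pos[i2] + 3L] <- b[, 2]
  }
  i3 <- which(cls == 3L)
  if (length(i3)) {
    out[pos[i3] + 1L] <- as.raw(0x80)
    out[pos[i3] + 2L] <- as.raw(0x00)
    out[pos[i3] + 3L] <- as.raw(0x80)
    b <- le_bytes(d[i3], 4L)
    if (length(i3) == 1L) b <- matrix(b, 1L)
    for (k in 1:4) out[pos[i3] + 3L + k] <- b[, k]
  }
  i4 <- which(cls == 4L)
  if (length(i4)) {
    out[pos[i4] + 1L] <- as.raw(0x80)
    out[pos[i4] + 2L] <- as.raw(0x00)
    out[pos[i4] + 3L] <- as.raw(0x80)
    # int32 escape 0x80000000, little endian: 00 00 00 80
    out[pos[i4] + 4L] <- as.raw(0x00)
    out[pos[i4] + 5L] <- as.raw(0x00)
    out[pos[i4] + 6L] <- as.raw(0x00)
    out[pos[i4] + 7L] <- as.raw(0x80)
    b <- le_bytes(d[i4], 8L)
    if (length(i4) == 1L) b <- matrix(b, 1L)
    for (k in 1:8) out[pos[i4] + 7L + k] <- b[, k]
  }
  out
}

#' @rdname encode_byte_offset
#' @param bytes raw vector produced by the encoder.
#' @param n number of values to decode.
#' @export
decode_byte_offset <- function(bytes, n) {
  out <- numeric(n)
  cur <- 0
  p <- 1L
  need <- function(k, p) {
    if (p + k - 1L > length(bytes))
      stop_fmt("truncated byte-offset stream at byte %d (need %d more)",
               p, p + k - 1L - length(bytes))
  }
  rd <- function(p, k) {  # little-endian signed integer of k bytes
    u <- sum(as.numeric(bytes[p:(p + k - 1L)]) * 256^(0:(k - 1L)))
    if (u >= 2^(8 * k - 1)) u - 2^(8 * k) else u
  }
  for (i in seq_len(n)) {
    need(1L, p)
    d <- rd(p, 1L)
    p <- p + 1L
    if (d == -128) {           # 0x80 escape
      need(2L, p)
      d <- rd(p, 2L)
      p <- p + 2L
      if (d == -32768) {       # 0x8000 escape
        need(4L, p)
        d <- rd(p, 4L)
        p <- p + 4L
        if (d == -2^31) {      # 0x80000000 escape
          need(8L, p)
          d <- rd(p, 8L)
          p <- p + 8L
        }
      }
    }
    cur <- cur + d
    out[i] <- cur
  }
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

cbf_header <- function(nrow, ncol, payload_size) {
  paste0(
    "###CBF: VERSION 1.5\r\n",
    "# Detector frame written with x-CBF_BYTE_OFFSET compression\r\n",
    "\r\n",
    "data_image\r\n",
    "\r\n",
    "_array_data.data\r\n",
    ";\r\n",
    "--CIF-BINARY-FORMAT-SECTION--\r\n",
    "Content-Type: application/octet-stream;\r\n",
    "     conversions=\"x-CBF_BYTE_OFFSET\"\r\n",
    "Content-Transfer-Encoding: BINARY\r\n",
    sprintf("X-Binary-Size: %d\r\n", payload_size),
    "X-Binary-ID: 1\r\n",
    "X-Binary-Element-Type: \"signed 32-bit integer\"\r\n",
    "X-Binary-Element-Byte-Order: LITTLE_ENDIAN\r\n",
    sprintf("X-Binary-Number-of-Elements: %d\r\n", nrow * ncol),
    sprintf("X-Binary-Size-Fastest-Dimension: %d\r\n", ncol),
    sprintf("X-Binary-Size-Second-Dimension: %d\r\n", nrow),
    "\r\n")
}

#' Write / read a 2D result as a CBF file
#'
#' Values are rounded to the nearest integer (ties away from zero) and must
#' fit a signed 32-bit integer, checked before anything is written. The
#' binary section uses the x-CBF_BYTE_OFFSET compression with the fast
#' dimension along matrix columns; the miniCBF-style header carries only the
#' binary-section essentials (element type, byte order, element count,
#' dimensions) and no experiment metadata. Reading inverts the encoding
#' exactly; a truncated stream reports the failing byte position.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @return `write_cbf`: `path` invisibly; `read_cbf`: an integer-valued
#'   numeric matrix.
#' @export
write_cbf <- function(image, path) {
  stopifnot(is.matrix(image))
  v <- round_half_away(as.numeric(image))
  if (any(!is.finite(v)) || any(abs(v) > 2^31 - 1))
    stop_fmt("image contains values outside the signed 32-bit range")
  v_rm <- as.vector(t(matrix(v, nrow(image), ncol(image))))  # row-major
  payload <- encode_byte_offset(v_rm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(cbf_header(nrow(image), ncol(image), length(payload))), con)
  writeBin(CBF_MARKER, con)
  writeBin(payload, con)
  writeBin(charToRaw("\r\n--CIF-BINARY-FORMAT-SECTION----\r\n;\r\n"), con)
  invisible(path)
}

#' @rdname write_cbf
#' @export
read_cbf <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  # locate the binary start marker
  hits <- which(raw_all == CBF_MARKER[1])
  start <- NA_integer_
  for (h in hits) {
    if (h + 3L <= length(raw_all) &&
        all(raw_all[h:(h + 3L)] == CBF_MARKER)) { start <- h; break }
  }
  if (is.na(start)) stop_fmt("no CBF binary-section marker found in %s", path)
  header <- rawToChar(raw_all[1:(start - 1L)])
  get_num <- function(key) {
    m <- regmatches(header, regexpr(paste0(key, ":\\s*[0-9]+"), header))
    if (!length(m)) stop_fmt("header lacks %s", key)
    as.numeric(sub(".*:\\s*", "", m))
  }
  if (!grepl("x-CBF_BYTE_OFFSET", header, fixed = TRUE))
    stop_fmt("unsupported CBF conversions (expected x-CBF_BYTE_OFFSET)")
  nelem <- get_num("X-Binary-Number-of-Elements")
  ncol_ <- get_num("X-Binary-Size-Fastest-Dimension")
  nrow_ <- get_num("X-Binary-Size-Second-Dimension")
  payload <- raw_all[(start + 4L):length(raw_all)]
  v <- decode_byte_offset(payload, nelem)
  matrix(v, nrow_, ncol_, byrow = TRUE)
}

#' Export the dark offset map as a separate CBF file
#'
#' Rounds the trained offset map to int32 and writes it as a plain CBF,
#' suitable as a `DARK_CURRENT_IMAGE` for downstream processing. No
#' experiment metadata (photon energy, distance, pixel size) is added.
#'
#' @param cal a trained `calibration_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
export_dark_cbf <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_set"))
  if (!any(cal$counts > 0))
    stop_fmt("calibration is untrained (no contributing images)")
  write_cbf(cal$offset, path)
}
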