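# HDF5 event output: user-defined group layout, multi-event files,
# sub-directory batching, zlib compression.

#' Describe one result to be written to an HDF5 file
#'
#' @param source_name name of the producing operation / result.
#' @param dataset_name name of the dataset in the file; the source name is
#'   used when none is given.
#' @param group_path slash-separated target group (`"/"` for the root).
#' @return list of class `output_item`.
#' @export
output_item <- function(source_name, dataset_name = NULL, group_path = "/") {
  if (!is.character(group_path) || grepl("//", group_path, fixed = TRUE))
    stop_fmt("invalid group path '%s'", group_path)
  structure(list(source_name = source_name,
                 dataset_name = dataset_name %||% source_name,
                 group_path = group_path),
            class = "output_item")
}

normalize_items <- function(items, results) {
  if (is.null(items))
    items <- lapply(names(results), output_item)
  items <- lapply(items, function(it) {
    if (inherits(it, "output_item")) it
    else do.call(output_item, as.list(it))
  })
  targets <- vapply(items, function(it) {
    gp <- sub("/+$", "", it$group_path)
    paste0(if (nzchar(gp)) gp else "", "/", it$dataset_name)
  }, character(1))
  dup <- duplicated(targets)
  if (any(dup))
    stop_fmt("duplicate target path(s): %s",
             paste(unique(targets[dup]), collapse = ", "))
  missing <- setdiff(vapply(items, `[[`, "", "source_name"), names(results))
  if (length(missing))
    stop_fmt("no result named: %s", paste(missing, collapse = ", "))
  list(items = items, targets = targets)
}

h5_ensure_group <- function(path, group) {
  group <- sub("^/", "", sub("/+$", "", group))
  if (!nzchar(group)) return(invisible())
  parts <- strsplit(group, "/", fixed = TRUE)[[1]]
  ex <- rhdf5::h5ls(path)
  have <- paste(sub("/$", "", ex$group), ex$name, sep = "/")
  cur <- ""
  for (p in parts) {
    cur <- paste0(cur, "/", p)
    if (!cur %in% have) rhdf5::h5createGroup(path, cur)
    have <- c(have, cur)
  }
}

h5_write_one <- function(x, path, target, compress) {
  if (is.matrix(x) || (is.numeric(x) && length(x) > 1) || is.array(x)) {
    dims <- dim(x) %||% length(x)
    rhdf5::h5createDataset(path, target, dims = dims,
                           storage.mode = storage.mode(x),
                           chunk = dims, level = if (compress) 6L else 0L)
    rhdf5::h5write(x, path, target)
  } else {
    rhdf5::h5write(x, path, target)
  }
}

#' Write one event's results to an HDF5 file
#'
#' Each item is stored at `<group_path>/<dataset_name>`; scalars become
#' length-1 datasets, vectors and matrices keep their shape. Duplicate target
#' paths raise an error before anything is written. With `compress = TRUE`
#' datasets are zlib-deflated (level 6).
#'
#' @param results named list of 0D/1D/2D results.
#' @param path output file (overwritten).
#' @param items list of [output_item()]s; by default every result is written
#'   under the root group with its own name.
#' @param compress apply zlib compression.
#' @return `path`, invisibly.
#' @export
write_event_h5 <- function(results, path, items = NULL, compress = FALSE) {
  ni <- normalize_items(items, results)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (i in seq_along(ni$items)) {
    it <- ni$items[[i]]
    h5_ensure_group(path, it$group_path)
    h5_write_one(results[[it$source_name]], path, ni$targets[i], compress)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Write a stream of events to a multi-event HDF5 file
#'
#' For every item the per-event results are stacked along an event axis (the
#' leading, i.e. slowest-varying, axis of the stored dataset) and an
#' `/event_id` dataset records the event identifiers. All events must agree
#' in shape per dataset; a mismatch names the offending event.
#'
#' @param events list of named result lists, one per event.
#' @param path output file (overwritten).
#' @param items list of [output_item()]s; defaults to all results of the
#'   first event.
#' @param compress apply zlib compression.
#' @param event_ids event identifiers (default `0:(n-1)`).
#' @return `path`, invisibly.
#' @export
write_multi_event_h5 <- function(events, path, items = NULL, compress = FALSE,
                                 event_ids = NULL) {
  if (!length(events)) stop_fmt("no events to write")
  n <- length(events)
  ni <- normalize_items(items, events[[1]])
  event_ids <- event_ids %||% (seq_len(n) - 1L)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (i in seq_along(ni$items)) {
    it <- ni$items[[i]]
    first <- events[[1]][[it$source_name]]
    d0 <- dim(first) %||% length(first)
    stacked <- array(NA_real_, dim = c(prod(d0), n))
    for (e in seq_len(n)) {
      x <- events[[e]][[it$source_name]]
      if (is.null(x) || !all((dim(x) %||% length(x)) == d0))
        stop_fmt("event %d: shape of '%s' changed", e, it$source_name)
      stacked[, e] <- as.numeric(x)
    }
    # R arrays are written by rhdf5 with dimensions reversed, so putting the
    # event index last here makes it the leading (slowest) axis in the file
    dim(stacked) <- c(d0, n)
    h5_ensure_group(path, it$group_path)
    h5_write_one(stacked, path, ni$targets[i], compress)
  }
  h5_write_one(as.integer(event_ids), path, "/event_id", compress)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a multi-event dataset back as a list of per-event results
#'
#' @param path HDF5 file written by [write_multi_event_h5()].
#' @param name dataset path within the file.
#' @return list of per-event arrays (event axis removed).
#' @export
read_multi_event_h5 <- function(path, name) {
  x <- rhdf5::h5read(path, name)
  d <- dim(x) %||% length(x)
  n <- d[length(d)]
  if (length(d) == 1L) return(as.list(as.numeric(x)))
  lapply(seq_len(n), function(e) {
    idx <- c(lapply(d[-length(d)], seq_len), list(e))
    y <- do.call(`[`, c(list(x), idx))
    if (length(d) == 3L) matrix(y, d[1], d[2]) else as.numeric(y)
  })
}

#' Convenience frame-stack HDF5 layout
#'
#' Stores a stack of raw frames as `/frames` (events on the leading file
#' axis) plus `/event_id`; the layout the pipeline and CLI read.
#'
#' @param frames list of matrices or 3D array.
#' @param path file path.
#' @param event_ids optional identifiers.
#' @param compress apply zlib compression.
#' @export
write_frames_h5 <- function(frames, path, event_ids = NULL, compress = FALSE) {
  fl <- as_frame_list(frames)
  events <- lapply(fl, function(f) list(frames = f))
  write_multi_event_h5(events, path, items = list(output_item("frames")),
                       compress = compress, event_ids = event_ids)
}

#' @rdname write_frames_h5
#' @export
read_frames_h5 <- function(path) {
  frames <- read_multi_event_h5(path, "frames")
  ids <- as.integer(rhdf5::h5read(path, "event_id"))
  list(frames = frames, event_ids = ids)
}

#' Sub-directory batching for per-event files
#'
#' Maps an event index to a sub-directory holding at most `files_per_dir`
#' files, keeping directory listings fast when millions of single-event
#' files are written.
#'
#' @param base_dir output root.
#' @param event_index 0-based event index.
#' @param files_per_dir maximum files per sub-directory.
#' @return directory path `base_dir/<batch>` (not created).
#' @export
batched_path <- function(base_dir, event_index, files_per_dir) {
  stopifnot(files_per_dir >= 1)
  file.path(base_dir, sprintf("%05d", event_index %/% files_per_dir))
}
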