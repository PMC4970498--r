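# INI-driven chaining of operations into per-event processing graphs with
# conditional execution, accumulators and deferred file output.

# --- operation registry -----------------------------------------------------
#
# Each op is fun(inputs, params, state, context) -> list(value =, state =).
# type "event": per-event value; "accumulate": one running result updated once
# per event; "output": collects per-event values, writes at finalisation.

.op_registry <- new.env(parent = emptyenv())

register_op <- function(name, fun, type = "event") {
  assign(name, list(fun = fun, type = type), envir = .op_registry)
}

#' Names of the operations available to chain configurations
#' @return character vector.
#' @export
chain_ops <- function() sort(ls(.op_registry))

num_par <- function(params, key, default = NULL) {
  v <- params[[key]] %||% default
  if (is.null(v)) stop_fmt("missing required parameter '%s'", key)
  as.numeric(v)
}

range_par <- function(params, key, default) {
  v <- params[[key]]
  if (is.null(v)) return(default)
  as.numeric(strsplit(as.character(v), ":", fixed = TRUE)[[1]])
}

# lazily loaded per-stage resources (calibration file, geometry file)
stage_cal <- function(params, state, context) {
  if (!is.null(state$cal)) return(state$cal)
  if (!is.null(params$cal)) load_calibration(params$cal)
  else context$cal %||% stop_fmt("stage needs a calibration ('cal' parameter or context)")
}

stage_geom <- function(params, state, context) {
  if (!is.null(state$geom)) return(state$geom)
  if (!is.null(params$geometry)) parse_geometry(params$geometry)
  else context$geom %||% stop_fmt("stage needs a geometry ('geometry' parameter or context)")
}

local({
  register_op("constant", function(inputs, params, state, context)
    list(value = num_par(params, "value"), state = state))

  register_op("identity", function(inputs, params, state, context)
    list(value = inputs[[1]], state = state))

  register_op("darkcal_apply", function(inputs, params, state, context) {
    state$cal <- stage_cal(params, state, context)
    mv <- if (!is.null(params$masked_value)) as.numeric(params$masked_value) else NULL
    list(value = apply_correction(inputs[[1]], state$cal,
                                  dialect = params$dialect %||% "crystfel",
                                  masked_value = mv),
         state = state)
  })

  register_op("find_peaks", function(inputs, params, state, context) {
    if (is.null(state$pp))
      state$pp <- peak_params(
        pixel_threshold = num_par(params, "threshold", 20),
        box_half_width = num_par(params, "box", 4),
        snr_background = num_par(params, "snr_bg", 3),
        snr_peak = num_par(params, "snr_peak", 3),
        min_npix = num_par(params, "min_pix", 3))
    mask <- context$mask
    if (!is.null(params$cal)) {
      state$cal <- stage_cal(params, state, context)
      mask <- state$cal$mask
    }
    list(value = find_peaks(inputs[[1]], state$pp, mask = mask), state = state)
  })

  register_op("count_peaks", function(inputs, params, state, context)
    list(value = count_peaks(inputs[[1]]), state = state))

  register_op("in_range", function(inputs, params, state, context) {
    rg <- range_par(params, "range", c(num_par(params, "lo", -Inf),
                                       num_par(params, "hi", Inf)))
    list(value = inputs[[1]] >= rg[1] && inputs[[1]] <= rg[2], state = state)
  })

  register_op("saturation_ratio", function(inputs, params, state, context)
    list(value = saturation_ratio(inputs[[1]],
                                  num_par(params, "threshold"))$ratio,
         state = state))

  register_op("radial_average", function(inputs, params, state, context) {
    state$geom <- stage_geom(params, state, context)
    if (is.null(state$beam))
      state$beam <- context$beam %||%
        beam_geometry(num_par(params, "wavelength"),
                      num_par(params, "distance"))
    qr <- range_par(params, "q_range", NULL)
    prof <- radial_average(inputs[[1]], state$geom, state$beam,
                           mask = context$mask,
                           nbins = num_par(params, "nbins", 100),
                           q_range = qr)
    list(value = prof$values, state = state)
  })

  register_op("fluorescence_spectrum", function(inputs, params, state, context) {
    sp <- fluorescence_spectrum(
      inputs[[1]],
      adu_range = range_par(params, "adu_range", c(18, 50)),
      normalize = params$normalize %||% "survivors")
    list(value = sp$values, state = state)
  })

  register_op("average", function(inputs, params, state, context)
    list(value = NULL, state = running_mean_update(state, inputs[[1]])),
    type = "accumulate")

  register_op("powder_average", function(inputs, params, state, context)
    list(value = NULL, state = powder_accumulate(state, inputs[[1]])),
    type = "accumulate")

  register_op("hit_rate", function(inputs, params, state, context) {
    if (is.null(state)) state <- list(flags = logical(0),
                                      window = num_par(params, "window", 2400))
    state$flags <- c(state$flags, isTRUE(as.logical(inputs[[1]])))
    list(value = NULL, state = state)
  }, type = "accumulate")

  register_op("counter", function(inputs, params, state, context) {
    if (is.null(state)) state <- list(n = 0L)
    state$n <- state$n + 1L
    list(value = NULL, state = state)
  }, type = "accumulate")

  register_op("hdf5_out", function(inputs, params, state, context) {
    if (is.null(state)) state <- list(events = list())
    state$events[[length(state$events) + 1L]] <-
      stats::setNames(inputs, names(inputs))
    list(value = NULL, state = state)
  }, type = "output")
})

finalize_accumulator <- function(name, stage, state) {
  op <- get(stage$op, envir = .op_registry)
  if (stage$op == "hit_rate") return(hit_rate(state$flags, state$window))
  if (stage$op == "counter") return(state$n)
  if (stage$op %in% c("average", "powder_average"))
    return(list(mean = state$mean, n = state$n))
  state
}

# --- configuration ----------------------------------------------------------

RESERVED_KEYS <- c("op", "input", "condition", "record")

#' Load an INI chain configuration
#'
#' Each INI section defines one stage: `op` names the operation (see
#' [chain_ops()]), `input` is a comma-separated list of result names (earlier
#' stage names, or the implicit per-event results `frame` and `event_id`),
#' the optional `condition` names a 0D result that gates the stage, and all
#' other keys are operation parameters. Stages are topologically ordered by
#' their input dependencies before execution, so the section order in the
#' file does not matter; cycles and references to results that nothing
#' produces are errors.
#'
#' @param path INI file path.
#' @return object of class `chain_config` (stages in execution order).
#' @export
load_chain_config <- function(path) {
  raw <- ini::read.ini(path)
  if (!length(raw)) stop_fmt("empty chain configuration: %s", path)
  stages <- lapply(names(raw), function(nm) {
    sec <- raw[[nm]]
    op <- sec$op
    if (is.null(op)) stop_fmt("stage '%s' has no 'op' key", nm)
    if (!exists(op, envir = .op_registry))
      stop_fmt("stage '%s': unknown operation '%s'; available: %s",
               nm, op, paste(chain_ops(), collapse = ", "))
    inputs <- if (is.null(sec$input)) character(0)
    else trimws(strsplit(sec$input, ",", fixed = TRUE)[[1]])
    params <- sec[setdiff(names(sec), RESERVED_KEYS)]
    params <- lapply(params, function(v) type.convert(v, as.is = TRUE))
    list(name = nm, op = op, type = get(op, envir = .op_registry)$type,
         inputs = inputs, condition = sec$condition,
         record = isTRUE(as.logical(sec$record %||% FALSE)),
         params = params)
  })
  names(stages) <- names(raw)

  implicit <- c("frame", "event_id")
  produced <- c(implicit, names(stages))
  for (st in stages) {
    bad <- setdiff(c(st$inputs, st$condition), produced)
    if (length(bad))
      stop_fmt("stage '%s': no stage produces input '%s'", st$name, bad[1])
  }
  # Kahn topological sort over stage dependencies
  deps <- lapply(stages, function(st)
    setdiff(c(st$inputs, st$condition), implicit))
  order <- character(0)
  remaining <- names(stages)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm)
      all(deps[[nm]] %in% order), logical(1))]
    if (!length(ready))
      stop_fmt("cyclic dependency among stages: %s",
               paste(remaining, collapse = ", "))
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(stages = stages[order]), class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("<chain_config> %d stage(s): %s\n", length(x$stages),
              paste(names(x$stages), collapse = " -> ")))
  invisible(x)
}

# --- execution --------------------------------------------------------------

#' Run a processing chain over a frame stream
#'
#' For each event the stages execute in dependency order; a stage with a
#' `condition` runs only when that 0D result is true for the current event.
#' Accumulating stages update exactly once per processed event; event
#' (per-event) results never leak between events. A failing stage skips the
#' remainder of that event with a logged reason and processing continues.
#' Output stages collect their inputs and write multi-event HDF5 files when
#' the stream ends.
#'
#' @param config a [load_chain_config()] result.
#' @param frames list of matrices or 3D array; one raw frame per event.
#' @param context named list of shared resources (`cal`, `geom`, `beam`,
#'   `mask`, `event_ids`) that stages may use instead of file parameters.
#' @param verbose log per-event progress to stderr.
#' @return list with `events` (per-event records of recorded and 0D results),
#'   `accumulators` (finalised accumulating results), `outputs` (paths
#'   written), `log` (skip reasons) and `n_events`.
#' @export
run_chain <- function(config, frames, context = list(), verbose = FALSE) {
  stopifnot(inherits(config, "chain_config"))
  fl <- as_frame_list(frames)
  ids <- context$event_ids %||% (seq_along(fl) - 1L)
  states <- stats::setNames(vector("list", length(config$stages)),
                            names(config$stages))
  log <- character(0)
  events <- vector("list", length(fl))

  for (e in seq_along(fl)) {
    results <- list(frame = fl[[e]], event_id = ids[e])
    ok <- TRUE
    for (st in config$stages) {
      if (!is.null(st$condition)) {
        flag <- results[[st$condition]]
        run_it <- !is.null(flag) && isTRUE(as.logical(flag))
        if (!run_it) next
      }
      op <- get(st$op, envir = .op_registry)
      inp <- results[st$inputs]
      names(inp) <- st$inputs
      res <- tryCatch(op$fun(inp, st$params, states[[st$name]], context),
                      error = function(err) err)
      if (inherits(res, "error")) {
        msg <- sprintf("event %s: stage '%s' failed (%s); event skipped",
                       ids[e], st$name, conditionMessage(res))
        log <- c(log, msg)
        if (verbose) message(msg)
        ok <- FALSE
        break
      }
      states[[st$name]] <- res$state
      if (!is.null(res$value)) results[[st$name]] <- res$value
    }
    if (ok) {
      rec <- Filter(function(x) is.atomic(x) && length(x) == 1L,
                    results[setdiff(names(results), c("frame"))])
      for (st in config$stages)
        if (st$record && !is.null(results[[st$name]]))
          rec[[st$name]] <- results[[st$name]]
      events[[e]] <- rec
      if (verbose) message(sprintf("event %s: ok", ids[e]))
    }
  }

  accumulators <- list()
  outputs <- character(0)
  for (st in config$stages) {
    if (st$type == "accumulate" && !is.null(states[[st$name]]))
      accumulators[[st$name]] <- finalize_accumulator(st$name, st,
                                                      states[[st$name]])
    if (st$type == "output" && !is.null(states[[st$name]])) {
      path <- st$params$path %||% stop_fmt("output stage '%s' needs a path",
                                           st$name)
      write_multi_event_h5(states[[st$name]]$events, path,
                           compress = isTRUE(as.logical(st$params$compress %||% FALSE)))
      outputs <- c(outputs, path)
    }
  }
  list(events = events, accumulators = accumulators, outputs = outputs,
       log = log, n_events = length(fl))
}
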