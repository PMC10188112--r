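#' Light schedule on the Zeitgeber clock
#'
#' Describes the light:dark cycle of the tracking room. Zeitgeber time (ZT) is
#' measured in hours since lights-ON: the day spans ZT0 to ZT`day_hours` and
#' the night the remainder of the 24 h cycle. The default is the 14 h:10 h
#' cycle standard for larval zebrafish tracking.
#'
#' @param day_hours Hours of lights-on per cycle (default 14).
#' @param night_hours Hours of lights-off per cycle (default 10). Must satisfy
#'   `day_hours + night_hours == 24`.
#' @param zt0_clock Optional wall-clock time of lights-ON (any string; carried
#'   as metadata only).
#' @return An object of class `light_schedule`.
#' @export
#' @examples
#' light_schedule()
light_schedule <- function(day_hours = 14, night_hours = 10, zt0_clock = NULL) {
  if (!is.numeric(day_hours) || !is.numeric(night_hours) ||
      day_hours <= 0 || night_hours <= 0) {
    abort("`day_hours` and `night_hours` must be positive numbers.")
  }
  if (abs(day_hours + night_hours - 24) > 1e-9) {
    abort("`day_hours` + `night_hours` must equal 24.")
  }
  structure(
    list(day_hours = day_hours, night_hours = night_hours,
         zt0_clock = zt0_clock),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %g h day : %g h night", x$day_hours,
              x$night_hours))
  if (!is.null(x$zt0_clock)) cat(" (ZT0 =", x$zt0_clock, ")")
  cat("\n")
  invisible(x)
}

#' @rdname light_schedule
#' @param path Path to a YAML file with keys `day_hours`, `night_hours` and
#'   optionally `zt0_clock`.
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  light_schedule(day_hours = y$day_hours %||% 14,
                 night_hours = y$night_hours %||% 10,
                 zt0_clock = y$zt0_clock)
}

#' @rdname light_schedule
#' @param schedule A `light_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "light_schedule"))
  yaml::write_yaml(
    list(day_hours = schedule$day_hours, night_hours = schedule$night_hours,
         zt0_clock = schedule$zt0_clock),
    path
  )
  invisible(path)
}

#' Construct a tracking dataset of delta-pixel traces
#'
#' A tracking dataset bundles the per-well delta-pixel activity traces of one
#' plate with the well-to-group assignment and the light schedule. A
#' delta-pixel value is the number of camera pixels whose grey value changed
#' beyond the acquisition sensitivity threshold at one frame transition; the
#' thresholding happens at acquisition, so values here are simply required to
#' be non-negative, with 0 meaning no detected movement.
#'
#' @param values Numeric matrix, frames x wells, with well ids as column
#'   names. All values must be finite and non-negative.
#' @param groups Named character vector or data frame with columns `well_id`
#'   and `group`, mapping every well to its experimental group.
#' @param schedule A [light_schedule()].
#' @param fps Acquisition rate, frames per second.
#' @param start_zt Zeitgeber time (hours since lights-ON) of the first frame.
#' @return An object of class `tracking_data`.
#' @export
tracking_data <- function(values, groups, schedule = light_schedule(),
                          fps = 1, start_zt = 0) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (frames x wells).")
  }
  if (is.null(colnames(values))) {
    abort("`values` must have well ids as column names.")
  }
  if (nrow(values) < 1) abort("Traces must contain at least one frame.")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Invalid delta-pixel value at frame %d, well '%s' (%s).",
      bad[1, 1], colnames(values)[bad[1, 2]],
      format(values[bad[1, 1], bad[1, 2]])
    ))
  }
  if (is.data.frame(groups)) {
    if (!all(c("well_id", "group") %in% names(groups))) {
      abort("`groups` data frame needs columns `well_id` and `group`.")
    }
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$well_id))
  }
  missing_wells <- setdiff(colnames(values), names(groups))
  if (length(missing_wells) > 0) {
    abort(paste0("Wells without a group label: ",
                 paste(missing_wells, collapse = ", ")))
  }
  if (!is.numeric(fps) || fps <= 0) abort("`fps` must be positive.")
  stopifnot(inherits(schedule, "light_schedule"))
  structure(
    list(values = values, groups = groups[colnames(values)],
         schedule = schedule, fps = fps, start_zt = start_zt),
    class = "tracking_data"
  )
}

#' @export
print.tracking_data <- function(x, ...) {
  hrs <- nrow(x$values) / x$fps / 3600
  cat(sprintf(
    "<tracking_data> %d wells x %d frames (%.1f h at %g fps), start ZT%g\n",
    ncol(x$values), nrow(x$values), hrs, x$fps, x$start_zt
  ))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tracking_data <- function(x) dim(x$values)

#' Read and write tracking data
#'
#' The native on-disk format is open and diff-able: a wide UTF-8 CSV of traces
#' (header row of well ids, one row per frame transition) plus a metadata CSV
#' with columns `well_id,group`. `read_tracking()` validates that every value
#' is non-negative, that columns are not ragged, and that every well has a
#' group label, and reports the offending frame/well on failure.
#'
#' @param trace_path Path to the wide trace CSV.
#' @param metadata_path Path to the `well_id,group` metadata CSV.
#' @param schedule A [light_schedule()].
#' @param fps Frames per second of the recording.
#' @param start_zt Zeitgeber time of the first frame, hours.
#' @return `read_tracking()` returns a [tracking_data()] object;
#'   `write_tracking()` invisibly returns its paths.
#' @export
read_tracking <- function(trace_path, metadata_path,
                          schedule = light_schedule(), fps = 1,
                          start_zt = 0) {
  traces <- readr::read_csv(trace_path, col_types = readr::cols(
    .default = readr::col_double()
  ), progress = FALSE)
  prob <- readr::problems(traces)
  if (nrow(prob) > 0) {
    abort(sprintf("Malformed trace CSV at row %d, column %d: %s",
                  prob$row[1], prob$col[1], prob$expected[1]))
  }
  values <- as.matrix(traces)
  na_cell <- which(is.na(values), arr.ind = TRUE)
  if (nrow(na_cell) > 0) {
    abort(sprintf("Missing/ragged value at frame %d, well '%s'.",
                  na_cell[1, 1], colnames(values)[na_cell[1, 2]]))
  }
  meta <- readr::read_csv(metadata_path, col_types = readr::cols(
    well_id = readr::col_character(), group = readr::col_character()
  ), progress = FALSE)
  unknown <- setdiff(meta$well_id, colnames(values))
  if (length(unknown) > 0) {
    abort(paste0("Metadata names wells absent from the traces: ",
                 paste(unknown, collapse = ", ")))
  }
  tracking_data(values, meta, schedule = schedule, fps = fps,
                start_zt = start_zt)
}

#' @rdname read_tracking
#' @param x A `tracking_data` object.
#' @export
write_tracking <- function(x, trace_path, metadata_path) {
  stopifnot(inherits(x, "tracking_data"))
  readr::write_csv(as_tibble(x$values), trace_path, progress = FALSE)
  readr::write_csv(
    tibble(well_id = names(x$groups), group = unname(x$groups)),
    metadata_path, progress = FALSE
  )
  invisible(c(trace_path, metadata_path))
}

#' Segment a recording into day and night epochs
#'
#' Tiles the recording with day/night epochs on the Zeitgeber clock implied by
#' the dataset's light schedule and start ZT. Epoch boundaries land at frame
#' index `round((boundary_zt - start_zt) * 3600 * fps)` (half-up) and frame
#' ranges are half-open `[start_frame, end_frame)`, 0-based, so a boundary
#' frame belongs to the later epoch.
#'
#' @param x A [tracking_data()] object.
#' @param use `"full_epochs_only"` (default) drops epochs truncated by the
#'   start or end of the recording; `"all"` keeps the truncated parts, in
#'   which case the epochs tile the whole recording.
#' @return A tibble with columns `label` ("day"/"night"), `ordinal` (1st day,
#'   1st night, ... among returned epochs of that label), `start_frame`,
#'   `end_frame`.
#' @export
#' @examples
#' plate <- simulate_plate(plate_sim_config(n_wells_per_group = 2,
#'                                          duration_h = 24, seed = 1))
#' segment_epochs(plate)
segment_epochs <- function(x, use = c("full_epochs_only", "all")) {
  use <- match.arg(use)
  stopifnot(inherits(x, "tracking_data"))
  n_frames <- nrow(x$values)
  fps <- x$fps
  start_zt <- x$start_zt
  end_zt <- start_zt + n_frames / (3600 * fps)
  day_h <- x$schedule$day_hours

  # enumerate cycle boundaries generously around the recording
  k <- seq(floor(start_zt / 24) - 1, ceiling(end_zt / 24) + 1)
  zt_start <- sort(c(24 * k, 24 * k + day_h))
  grid <- tibble(
    label = rep_len(c("day", "night"), length(zt_start)),
    zt_start = zt_start,
    zt_end = c(zt_start[-1], max(zt_start) + day_h)
  )
  eps <- 1e-9
  grid <- filter(grid, .data$zt_end > start_zt + eps,
                 .data$zt_start < end_zt - eps)
  if (nrow(grid) == 0) return(empty_epochs())

  grid <- mutate(
    grid,
    complete = .data$zt_start >= start_zt - eps & .data$zt_end <= end_zt + eps,
    start_frame = pmax(0, pmin(
      n_frames, round_half_up((.data$zt_start - start_zt) * 3600 * fps))),
    end_frame = pmax(0, pmin(
      n_frames, round_half_up((.data$zt_end - start_zt) * 3600 * fps)))
  )
  if (use == "full_epochs_only") grid <- filter(grid, .data$complete)
  grid <- filter(grid, .data$end_frame > .data$start_frame)
  if (nrow(grid) == 0) return(empty_epochs())
  grid %>%
    group_by(.data$label) %>%
    mutate(ordinal = row_number()) %>%
    ungroup() %>%
    select("label", "ordinal", "start_frame", "end_frame")
}

empty_epochs <- function() {
  tibble(label = character(), ordinal = integer(),
         start_frame = numeric(), end_frame = numeric())
}
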