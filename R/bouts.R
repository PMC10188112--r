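#' Segment a delta-pixel trace into active and inactive bouts
#'
#' A frame is active iff its delta-pixel value is strictly greater than
#' `activity_floor` (default 0: any detected movement counts, the acquisition
#' sensitivity threshold having been applied upstream). Bouts are the maximal
#' runs of consecutive active or inactive frames; states strictly alternate
#' and the bouts tile the requested frame range exactly.
#'
#' @param values Numeric vector of non-negative delta-pixel values (one well).
#' @param start_frame,end_frame Half-open 0-based frame range to segment;
#'   defaults to the whole trace.
#' @param activity_floor Activity threshold; a frame is active iff
#'   `value > activity_floor`.
#' @return A tibble with columns `state` ("active"/"inactive"),
#'   `start_frame`, `end_frame` (half-open, 0-based).
#' @export
#' @examples
#' segment_bouts(c(0, 3, 5, 0, 0, 2))
segment_bouts <- function(values, start_frame = 0,
                          end_frame = length(values), activity_floor = 0) {
  if (end_frame <= start_frame) abort("Empty frame range.")
  if (start_frame < 0 || end_frame > length(values)) {
    abort("Frame range outside the trace.")
  }
  v <- values[(start_frame + 1):end_frame]
  r <- rle(v > activity_floor)
  ends <- start_frame + cumsum(r$lengths)
  tibble(
    state = ifelse(r$values, "active", "inactive"),
    start_frame = c(start_frame, ends[-length(ends)]),
    end_frame = ends
  )
}

# per-bout statistics of one active bout's delta-pixel values
active_bout_stats <- function(v, fps) {
  m <- mean(v)
  c(
    length_s = length(v) / fps,
    mean = m,
    std = sqrt(mean((v - m)^2)), # population denominator: 1-frame bouts -> 0
    total = sum(v),
    min = min(v),
    max = max(v)
  )
}

#' Nine behavioral parameters of one epoch
#'
#' Computes the nine locomotor parameters (see [bout_measures()]) for one
#' epoch of one trace. Per-bout statistics are averaged, unweighted, across
#' the bouts of the epoch; `n_active_bouts` counts active bouts and
#' `time_active_pct` is `100 * active frames / epoch frames`. Epochs with no
#' active bout report `n_active_bouts = 0`, `time_active_pct = 0` and `NA`
#' (missing, never zero-filled) for the six active-bout statistics; likewise
#' an epoch with no inactive bout reports `inactive_bout_length_s = NA`.
#' Bouts truncated by the epoch boundaries are included as-is.
#'
#' @inheritParams segment_bouts
#' @param fps Frames per second; converts bout lengths to seconds.
#' @return A one-row tibble with the nine [bout_measures()] columns.
#' @export
#' @examples
#' epoch_parameters(c(0, 3, 5, 0, 0, 2), fps = 25)
epoch_parameters <- function(values, fps, start_frame = 0,
                             end_frame = length(values),
                             activity_floor = 0) {
  bouts <- segment_bouts(values, start_frame, end_frame, activity_floor)
  n_frames <- end_frame - start_frame
  act <- filter(bouts, .data$state == "active")
  ina <- filter(bouts, .data$state == "inactive")
  n_act <- nrow(act)
  active_frames <- sum(act$end_frame - act$start_frame)

  if (n_act > 0) {
    per_bout <- vapply(
      seq_len(n_act),
      function(i) active_bout_stats(
        values[(act$start_frame[i] + 1):act$end_frame[i]], fps),
      numeric(6)
    )
    act_stats <- rowMeans(per_bout)
  } else {
    act_stats <- rep(NA_real_, 6)
    names(act_stats) <- c("length_s", "mean", "std", "total", "min", "max")
  }
  inactive_len <- if (nrow(ina) > 0) {
    mean((ina$end_frame - ina$start_frame) / fps)
  } else {
    NA_real_
  }
  tibble(
    active_bout_length_s = act_stats[["length_s"]],
    active_bout_mean = act_stats[["mean"]],
    active_bout_std = act_stats[["std"]],
    active_bout_total = act_stats[["total"]],
    active_bout_min = act_stats[["min"]],
    active_bout_max = act_stats[["max"]],
    n_active_bouts = n_act,
    time_active_pct = 100 * active_frames / n_frames,
    inactive_bout_length_s = inactive_len
  )
}

#' Per-larva behavioral parameters, averaged over days and nights
#'
#' Runs the bout decomposition of every well over every day and night epoch,
#' then averages each of the nine parameters across the day epochs (missing
#' epoch values skipped) to obtain the day value, and likewise for the night:
#' an 18-measure vector per larva in the canonical [fp_measures()] order.
#'
#' @param x A [tracking_data()] object.
#' @param epochs Optional epoch tibble; by default all complete epochs from
#'   [segment_epochs()] with `use = "full_epochs_only"`.
#' @param activity_floor Passed to [segment_bouts()].
#' @return A tibble with columns `larva_id`, `group` and the 18
#'   [fp_measures()] columns. Larvae with no valid epoch of one type carry
#'   `NA` for that half.
#' @export
larva_parameters <- function(x, epochs = NULL, activity_floor = 0) {
  stopifnot(inherits(x, "tracking_data"))
  epochs <- epochs %||% segment_epochs(x, use = "full_epochs_only")
  if (!any(epochs$label == "day") || !any(epochs$label == "night")) {
    warn("Recording lacks a complete day or night epoch; that half is NA.")
  }
  wells <- colnames(x$values)
  rows <- map(wells, function(w) {
    v <- x$values[, w]
    per_epoch <- map(seq_len(nrow(epochs)), function(i) {
      epoch_parameters(v, fps = x$fps,
                       start_frame = epochs$start_frame[i],
                       end_frame = epochs$end_frame[i],
                       activity_floor = activity_floor)
    }) %>% list_rbind()
    per_epoch$label <- epochs$label
    halves <- map(c("day", "night"), function(lab) {
      sub <- filter(per_epoch, .data$label == lab)
      out <- if (nrow(sub) == 0) {
        stats::setNames(rep(NA_real_, 9), bout_measures())
      } else {
        vapply(bout_measures(), function(m) {
          vals <- sub[[m]]
          if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
        }, numeric(1))
      }
      stats::setNames(out, paste0(bout_measures(), "_", lab))
    })
    as_tibble_row(c(list(larva_id = w, group = unname(x$groups[w])),
                    as.list(c(halves[[1]], halves[[2]]))))
  })
  list_rbind(rows)
}
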