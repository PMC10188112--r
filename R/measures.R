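#' Canonical behavioral measure names
#'
#' The locomotor fingerprint is built from nine parameters of the bout
#' decomposition of a delta-pixel trace, each computed once for the day and
#' once for the night:
#'
#' 1. `active_bout_length_s` -- duration of each active bout, in seconds;
#' 2. `active_bout_mean` -- mean of the delta-pixel values composing each
#'    active bout;
#' 3. `active_bout_std` -- standard deviation of the delta-pixel values
#'    composing each active bout (population denominator);
#' 4. `active_bout_total` -- sum of the delta-pixel values of each active bout;
#' 5. `active_bout_min` -- smallest delta-pixel value of each active bout;
#' 6. `active_bout_max` -- largest delta-pixel value of each active bout;
#' 7. `n_active_bouts` -- number of active bouts in the epoch;
#' 8. `time_active_pct` -- percentage of epoch frames that are active;
#' 9. `inactive_bout_length_s` -- duration of each pause between active bouts,
#'    in seconds.
#'
#' Per-bout statistics (all but 7 and 8) are averaged across the bouts of an
#' epoch. `bout_measures()` returns the nine per-epoch names;
#' `fp_measures()` returns the canonical 18-measure fingerprint schema: the
#' nine parameters suffixed `_day`, then the same nine suffixed `_night`.
#'
#' @return A character vector of measure names.
#' @export
#' @examples
#' fp_measures()
bout_measures <- function() {
  c(
    "active_bout_length_s", "active_bout_mean", "active_bout_std",
    "active_bout_total", "active_bout_min", "active_bout_max",
    "n_active_bouts", "time_active_pct", "inactive_bout_length_s"
  )
}

#' @rdname bout_measures
#' @export
fp_measures <- function() {
  c(paste0(bout_measures(), "_day"), paste0(bout_measures(), "_night"))
}

# columns of `x` that belong to a declared measure schema, in schema order
measure_cols <- function(x, measures = NULL) {
  measures <- measures %||% fp_measures()
  measures[measures %in% names(x)]
}
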