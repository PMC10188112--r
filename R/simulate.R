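#' Group effect multipliers for plate simulation
#'
#' Multiplicative effects applied to one simulated group, relative to the
#' baseline bout process: amplitude factors scale the delta-pixel intensity of
#' active frames, bout-rate factors scale the rate of bout initiation (i.e.
#' divide the mean inactive-bout duration), separately for day and night.
#'
#' @param day_amplitude,night_amplitude,day_bout_rate,night_bout_rate
#'   Positive multipliers; 1 means no effect.
#' @return A named list of factors.
#' @export
group_effect <- function(day_amplitude = 1, night_amplitude = 1,
                         day_bout_rate = 1, night_bout_rate = 1) {
  eff <- list(day_amplitude = day_amplitude,
              night_amplitude = night_amplitude,
              day_bout_rate = day_bout_rate,
              night_bout_rate = night_bout_rate)
  if (any(unlist(eff) <= 0)) abort("All group-effect factors must be > 0.")
  eff
}

#' Configuration of a simulated tracking plate
#'
#' The simulator emulates the statistical structure of a larval tracking
#' experiment with an alternating-renewal bout process: each well alternates
#' inactive bouts (delta pixels exactly 0) and active bouts (per-frame delta
#' pixels drawn from a gamma distribution), with exponentially distributed
#' bout durations whose means depend on the epoch type (day/night) and the
#' well's group. It reproduces the bout statistics the pipeline measures; it
#' does not model video, pixel geometry, startle responses or a circadian
#' oscillator free-running without light cues.
#'
#' Baseline defaults describe a realistic larva on a 14:10 cycle: brief
#' frequent swim bouts by day (mean active 2 s, mean inactive 4 s), sparser
#' activity at night (mean active 1.5 s, mean inactive 20 s), gamma amplitude
#' with shape 2 and scale `amplitude_scale = 10` delta-pixel units.
#'
#' @param n_wells_per_group Wells simulated per group.
#' @param group_effects Named list of [group_effect()]s, one per group. The
#'   default plants a daytime-only hyperactivity effect in group `"mut"`
#'   (amplitude x1.5, bout rate x1.3) against a neutral `"wt"`.
#' @param fps Frames per second (default 1; the acquisition rate of real
#'   rigs, 25 fps, is supported but keeps every bout statistic in seconds
#'   either way).
#' @param duration_h Recording length in hours; must cover at least the first
#'   full epoch, and at least 24 h for day+night fingerprinting.
#' @param schedule A [light_schedule()]; the recording starts at ZT0.
#' @param baseline List with `mean_inactive_bout` and `mean_active_bout`
#'   (named `c(day=, night=)`, seconds) and `amplitude_scale` (delta-pixel
#'   units).
#' @param seed Integer seed; the same seed reproduces the plate bit-exactly.
#' @return An object of class `plate_sim_config`.
#' @export
plate_sim_config <- function(
    n_wells_per_group = 48,
    group_effects = list(wt = group_effect(),
                         mut = group_effect(day_amplitude = 1.5,
                                            day_bout_rate = 1.3)),
    fps = 1,
    duration_h = 48,
    schedule = light_schedule(),
    baseline = list(mean_inactive_bout = c(day = 4, night = 20),
                    mean_active_bout = c(day = 2, night = 1.5),
                    amplitude_scale = 10),
    seed = 1) {
  if (n_wells_per_group < 1) abort("Need at least one well per group.")
  if (is.null(names(group_effects)) || any(names(group_effects) == "")) {
    abort("`group_effects` must be a named list (one entry per group).")
  }
  if (fps <= 0) abort("`fps` must be positive.")
  if (duration_h < schedule$day_hours) {
    abort("`duration_h` is shorter than the first full epoch.")
  }
  b <- baseline
  if (any(c(b$mean_inactive_bout, b$mean_active_bout,
            b$amplitude_scale) <= 0)) {
    abort("Baseline bout means and amplitude scale must be positive.")
  }
  structure(
    list(n_wells_per_group = n_wells_per_group,
         group_effects = lapply(group_effects, function(e)
           do.call(group_effect, e)),
         fps = fps, duration_h = duration_h, schedule = schedule,
         baseline = baseline, seed = as.integer(seed)),
    class = "plate_sim_config"
  )
}

# amplitude gamma shape; mean active-frame delta pixels = shape * scale
PLATE_GAMMA_SHAPE <- 2

# one epoch's worth of frames for one well: alternating exponential bouts
simulate_epoch_values <- function(n_frames, fps, mean_inactive_s,
                                  mean_active_s, amp_scale) {
  est <- ceiling(n_frames / fps / (mean_inactive_s + mean_active_s))
  state <- integer(0)
  total <- 0
  while (total < n_frames) {
    k <- max(16, ceiling(est * 1.5))
    li <- pmax(1, round_half_up(rexp(k, 1 / mean_inactive_s) * fps))
    la <- pmax(1, round_half_up(rexp(k, 1 / mean_active_s) * fps))
    lens <- as.vector(rbind(li, la)) # inactive first, then alternate
    state <- c(state, rep(rep_len(c(0L, 1L), 2 * k), times = lens))
    total <- length(state)
  }
  state <- state[seq_len(n_frames)]
  v <- numeric(n_frames)
  n_act <- sum(state)
  if (n_act > 0) {
    v[state == 1L] <- rgamma(n_act, shape = PLATE_GAMMA_SHAPE,
                             scale = amp_scale)
  }
  v
}

#' Simulate a tracking plate with known group effects
#'
#' Generates one delta-pixel trace per well under the alternating-renewal
#' bout model of [plate_sim_config()]. Every frame of an inactive bout is
#' exactly 0 and every frame of an active bout is strictly positive, so the
#' bout structure is recoverable from the trace. The planted group effects,
#' baseline and seed are attached as attribute `sim_truth`.
#'
#' @param config A [plate_sim_config()].
#' @return A [tracking_data()] object with `round(fps * duration_h * 3600)`
#'   frames per trace.
#' @export
#' @examples
#' plate <- simulate_plate(plate_sim_config(n_wells_per_group = 2,
#'                                          duration_h = 24, seed = 7))
#' plate
simulate_plate <- function(config) {
  stopifnot(inherits(config, "plate_sim_config"))
  n_frames <- round_half_up(config$fps * config$duration_h * 3600)
  groups_vec <- rep(names(config$group_effects),
                    each = config$n_wells_per_group)
  wells <- sprintf("w%03d", seq_along(groups_vec))
  names(groups_vec) <- wells

  # epoch layout from ZT0 (mode "all": partial final epoch still simulated)
  skel <- tracking_data(
    matrix(0, nrow = n_frames, ncol = 1, dimnames = list(NULL, "w000")),
    c(w000 = "x"), schedule = config$schedule, fps = config$fps, start_zt = 0
  )
  epochs <- segment_epochs(skel, use = "all")
  b <- config$baseline

  values <- withr::with_seed(config$seed, {
    vapply(wells, function(w) {
      eff <- config$group_effects[[groups_vec[[w]]]]
      v <- numeric(n_frames)
      for (i in seq_len(nrow(epochs))) {
        lab <- epochs$label[i]
        rate_f <- if (lab == "day") eff$day_bout_rate else eff$night_bout_rate
        amp_f <- if (lab == "day") eff$day_amplitude else eff$night_amplitude
        nf <- epochs$end_frame[i] - epochs$start_frame[i]
        v[(epochs$start_frame[i] + 1):epochs$end_frame[i]] <-
          simulate_epoch_values(
            nf, config$fps,
            mean_inactive_s = b$mean_inactive_bout[[lab]] / rate_f,
            mean_active_s = b$mean_active_bout[[lab]],
            amp_scale = b$amplitude_scale * amp_f
          )
      }
      v
    }, numeric(n_frames))
  })

  out <- tracking_data(values, groups_vec, schedule = config$schedule,
                       fps = config$fps, start_zt = 0)
  attr(out, "sim_truth") <- list(group_effects = config$group_effects,
                                 baseline = config$baseline,
                                 seed = config$seed)
  out
}

#' Simulate a fingerprint library with an optional planted mimic
#'
#' Generates a library of standard-normal Z-score fingerprints — a stand-in
#' for a large pharmaco-behavioral reference set. If `mimic_of` is given, one
#' designated condition is planted as `mimic_of + N(0, mimic_noise)` per
#' measure, so the expected Pearson correlation between mimic and query is
#' controlled in closed form: `E[r] ~ sd(q) / sqrt(sd(q)^2 + mimic_noise^2)`
#' for a query with per-measure spread `sd(q)`.
#'
#' @param n_conditions Number of library conditions.
#' @param measures Measure schema (default [fp_measures()]).
#' @param mimic_of Optional query fingerprint (named vector or one-row
#'   tibble) whose measure set must equal `measures`.
#' @param mimic_noise Standard deviation of the Gaussian noise added to the
#'   planted mimic.
#' @param seed Integer seed.
#' @param mimic_name Condition name of the planted row.
#' @return A tibble `condition` x measures; the planted condition name is in
#'   attribute `mimic_condition` (`NULL` when nothing was planted).
#' @export
simulate_library <- function(n_conditions, measures = fp_measures(),
                             mimic_of = NULL, mimic_noise = 0, seed = 1,
                             mimic_name = "mimic") {
  if (length(measures) == 0) abort("`measures` must be non-empty.")
  if (mimic_noise < 0) abort("`mimic_noise` must be >= 0.")
  if (!is.null(mimic_of)) {
    q <- as_fp_vector(mimic_of)
    if (!setequal(names(q), measures)) {
      abort("`mimic_of` measure set does not match `measures`.")
    }
    q <- q[measures]
  }
  withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(n_conditions * length(measures)),
                nrow = n_conditions,
                dimnames = list(NULL, measures))
    mimic_row <- NULL
    if (!is.null(mimic_of)) {
      mimic_row <- sample.int(n_conditions, 1)
      z[mimic_row, ] <- q + rnorm(length(measures), sd = mimic_noise)
    }
    cond <- sprintf("agent_%03d", seq_len(n_conditions))
    if (!is.null(mimic_row)) cond[mimic_row] <- mimic_name
    out <- bind_cols(tibble(condition = cond), as_tibble(z))
    attr(out, "mimic_condition") <- if (is.null(mimic_row)) NULL else
      cond[mimic_row]
    out
  })
}

#' Configuration of a simulated two-condition peak intensity matrix
#'
#' Emulates per-peak accessibility intensities of cells from two conditions
#' within one cell cluster. Intensities are negative-binomial counts
#' (`mu = mean_intensity`, `size = dispersion`); a planted fraction of peaks
#' has its condition-B mean multiplied by `effect_size`. A plain NB (not
#' zero-inflated) is sufficient here because the downstream rank and ECDF
#' tests are distribution-free.
#'
#' @param n_peaks Number of peaks.
#' @param n_cells Named vector of cells per condition, exactly two
#'   conditions, each with at least 2 cells.
#' @param fraction_differential Fraction of peaks planted as differential,
#'   in `[0, 1]`.
#' @param effect_size Multiplicative shift of the condition-B mean at
#'   planted peaks.
#' @param dispersion NB `size` parameter.
#' @param mean_intensity Baseline NB mean.
#' @param seed Integer seed.
#' @return An object of class `peak_sim_config`.
#' @export
peak_sim_config <- function(n_peaks, n_cells = c(A = 50, B = 50),
                            fraction_differential = 0.1, effect_size = 4,
                            dispersion = 2, mean_intensity = 10, seed = 1) {
  if (length(n_cells) != 2 || is.null(names(n_cells))) {
    abort("`n_cells` must name exactly two conditions.")
  }
  if (any(n_cells < 2)) abort("Each condition needs at least 2 cells.")
  if (fraction_differential < 0 || fraction_differential > 1) {
    abort("`fraction_differential` must be in [0, 1].")
  }
  if (effect_size <= 0 || dispersion <= 0 || mean_intensity <= 0) {
    abort("`effect_size`, `dispersion`, `mean_intensity` must be > 0.")
  }
  structure(
    list(n_peaks = as.integer(n_peaks), n_cells = n_cells,
         fraction_differential = fraction_differential,
         effect_size = effect_size, dispersion = dispersion,
         mean_intensity = mean_intensity, seed = as.integer(seed)),
    class = "peak_sim_config"
  )
}

#' Simulate a peak intensity matrix with planted differential peaks
#'
#' @param config A [peak_sim_config()].
#' @return A [peak_matrix()] whose `planted` component records the indices of
#'   the planted differential peaks (empty when
#'   `fraction_differential = 0`); `sim_truth(x)` returns them together with
#'   the config.
#' @export
simulate_peak_matrix <- function(config) {
  stopifnot(inherits(config, "peak_sim_config"))
  conds <- names(config$n_cells)
  n_cells_total <- sum(config$n_cells)
  condition <- rep(conds, times = config$n_cells)
  cell_ids <- paste0(condition, "_",
                     unlist(lapply(config$n_cells, seq_len)))
  n_planted <- round_half_up(config$fraction_differential * config$n_peaks)

  withr::with_seed(config$seed, {
    planted <- sort(sample.int(config$n_peaks, n_planted))
    mu <- matrix(config$mean_intensity, nrow = config$n_peaks,
                 ncol = n_cells_total)
    mu[planted, condition == conds[2]] <-
      config$mean_intensity * config$effect_size
    intensity <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = config$dispersion),
      nrow = config$n_peaks,
      dimnames = list(sprintf("peak_%05d", seq_len(config$n_peaks)),
                      cell_ids)
    )
    out <- peak_matrix(intensity, stats::setNames(condition, cell_ids),
                       planted = planted)
    attr(out, "sim_truth") <- list(planted = planted, config = config)
    out
  })
}

#' Ground truth of a simulated object
#'
#' @param x An object produced by [simulate_plate()] or
#'   [simulate_peak_matrix()].
#' @return The recorded ground truth (planted effects/indices, seed), or
#'   `NULL` for non-simulated objects.
#' @export
sim_truth <- function(x) attr(x, "sim_truth")

#' @rdname sim_truth
#' @param path JSON path for the ground-truth sidecar.
#' @export
write_sim_truth <- function(x, path) {
  truth <- sim_truth(x)
  if (is.null(truth)) abort("Object carries no simulation ground truth.")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
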