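#' Sibling-referenced Z-score fingerprints
#'
#' Converts per-larva parameter vectors into behavioral fingerprints: for
#' every measure, `z = (x - mean_ref) / sd_ref`, where the reference mean and
#' sample standard deviation (denominator `n - 1`) are taken over the larvae
#' of `reference_group` — typically the wild-type siblings on the same plate.
#' Fingerprints are produced for every larva, reference larvae included, so
#' the reference group has per-measure mean 0 and sample sd 1 by construction
#' and its mean fingerprint sits at the origin of the phenotype space.
#'
#' Measures whose reference standard deviation is zero, or with fewer than two
#' non-missing reference larvae, are marked missing (`NA`) for all larvae,
#' with a warning. Missing parameter values stay missing; they are never
#' imputed as zero.
#'
#' @param params Parameter tibble from [larva_parameters()] (columns
#'   `larva_id`, `group`, measures).
#' @param reference_group Name of the reference (wild-type sibling) group.
#' @param measures Measure columns to use; defaults to the [fp_measures()]
#'   columns present in `params`.
#' @return A tibble with `larva_id`, `group`, `reference_group` and one
#'   Z-score column per measure.
#' @export
zscore_fingerprints <- function(params, reference_group, measures = NULL) {
  measures <- measure_cols(params, measures)
  if (length(measures) == 0) abort("No measure columns found in `params`.")
  ref <- filter(params, .data$group == reference_group)
  if (nrow(ref) < 2) {
    abort(sprintf("Reference group '%s' needs at least 2 larvae.",
                  reference_group))
  }
  out <- tibble(larva_id = params$larva_id, group = params$group,
                reference_group = reference_group)
  degenerate <- character()
  for (m in measures) {
    rv <- ref[[m]][!is.na(ref[[m]])]
    if (length(rv) < 2 || sd(rv) == 0) {
      degenerate <- c(degenerate, m)
      out[[m]] <- NA_real_
    } else {
      out[[m]] <- (params[[m]] - mean(rv)) / sd(rv)
    }
  }
  if (length(degenerate) > 0) {
    warn(paste0("Reference group is degenerate (sd 0 or n < 2) for: ",
                paste(degenerate, collapse = ", "),
                "; these measures are reported missing."))
  }
  out
}

#' Summarize a group's fingerprint as mean and SEM per measure
#'
#' @param fps Fingerprint tibble from [zscore_fingerprints()].
#' @param group Group to summarize.
#' @param measures Measure columns; defaults to those present.
#' @return A tibble with one row per measure: `group`, `measure` (in
#'   canonical order), `mean_z`, `sem_z` (`sd / sqrt(n)` over non-missing
#'   members; `NA` when `n = 1`), `n`.
#' @export
group_fingerprint <- function(fps, group, measures = NULL) {
  measures <- measure_cols(fps, measures)
  sub <- filter(fps, .data$group == !!group)
  if (nrow(sub) == 0) abort(sprintf("Group '%s' has no members.", group))
  rows <- map(measures, function(m) {
    v <- sub[[m]][!is.na(sub[[m]])]
    n <- length(v)
    tibble(
      group = group, measure = m,
      mean_z = if (n > 0) mean(v) else NA_real_,
      sem_z = if (n > 1) sd(v) / sqrt(n) else NA_real_,
      n = n
    )
  })
  out <- list_rbind(rows)
  out$measure <- factor(out$measure, levels = measures)
  out
}

#' Euclidean phenotype distance
#'
#' The magnitude of a larva's deviation from its wild-type sibling cohort:
#' the root-sum-of-squares of its fingerprint Z-scores, i.e. the Euclidean
#' distance to the reference mean fingerprint, which the Z-normalization
#' places at the origin. Missing measures are excluded (not zero-filled); the
#' number of measures actually used is reported so distances computed over
#' differing subsets stay auditable.
#'
#' @inheritParams group_fingerprint
#' @return A tibble `larva_id`, `group`, `n_measures`, `distance`.
#' @export
fp_distance <- function(fps, measures = NULL) {
  measures <- measure_cols(fps, measures)
  z <- as.matrix(fps[, measures, drop = FALSE])
  n_measures <- rowSums(!is.na(z))
  if (any(n_measures == 0)) {
    abort(sprintf("All measures missing for larva '%s'.",
                  fps$larva_id[which(n_measures == 0)[1]]))
  }
  tibble(
    larva_id = fps$larva_id, group = fps$group,
    n_measures = n_measures,
    distance = sqrt(rowSums(z^2, na.rm = TRUE))
  )
}

# coerce a fingerprint-like thing to a named numeric vector of measures
as_fp_vector <- function(x, measures = NULL) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    if (all(c("measure", "mean_z") %in% names(x))) { # group_fingerprint form
      return(stats::setNames(x$mean_z, as.character(x$measure)))
    }
    if (nrow(x) != 1) {
      abort("Expected a single fingerprint (one row) or a named vector.")
    }
    m <- measure_cols(x, measures)
    return(stats::setNames(as.numeric(x[1, m]), m))
  }
  abort("Cannot interpret this object as a fingerprint.")
}

#' Pearson correlation between two fingerprints
#'
#' Fingerprints are aligned by measure name and correlated over their shared
#' non-missing measures (pairwise-complete). If fewer than `min_overlap`
#' measures are shared the comparison is refused; if either side has zero
#' variance on the shared measures the correlation is undefined and reported
#' as `NA` with a warning.
#'
#' @param a,b Fingerprints: named numeric vectors, one-row fingerprint
#'   tibbles, or [group_fingerprint()] summaries (whose `mean_z` is used).
#' @param min_overlap Minimum number of shared non-missing measures.
#' @return A single correlation value in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' fp_correlate(c(a = 1, b = 2, c = 3), c(a = 2, b = 4, c = 6),
#'              min_overlap = 3)
fp_correlate <- function(a, b, min_overlap = 5) {
  va <- as_fp_vector(a)
  vb <- as_fp_vector(b)
  shared <- intersect(names(va)[!is.na(va)], names(vb)[!is.na(vb)])
  if (length(shared) < min_overlap) {
    abort(sprintf("Only %d shared non-missing measures (min_overlap = %d).",
                  length(shared), min_overlap))
  }
  x <- va[shared]; y <- vb[shared]
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero variance on one side; correlation undefined (NA).")
    return(NA_real_)
  }
  cor(x, y)
}
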