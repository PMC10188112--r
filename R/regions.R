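#' Classify bulk differential-accessibility regions
#'
#' Applies the bulk region classification rule to a table of per-region
#' differential statistics (accessibility ratio mutant/WT and FDR, as
#' produced by a standard count-model fit, which this function consumes but
#' does not compute):
#'
#' * `up`: `fdr < sig_fdr` and `ratio > 1`;
#' * `down`: `fdr < sig_fdr` and `ratio < 1`;
#' * `unaffected`: `fdr > unaffected_fdr` and
#'   `ratio_window[1] < ratio < ratio_window[2]` — the control set for
#'   downstream plotting and motif enrichment;
#' * `none`: everything else.
#'
#' The classes are disjoint by construction. Rows with a non-positive ratio
#' are invalid and dropped with a warning naming them.
#'
#' @param stats Data frame with columns `region`, `ratio` (> 0) and `fdr`
#'   (in `[0, 1]`).
#' @param sig_fdr FDR cutoff for up/down calls (default 0.01).
#' @param unaffected_fdr Lower FDR bound for the unaffected class (default
#'   0.95).
#' @param ratio_window Open ratio interval for the unaffected class
#'   (default `c(0.995, 1.005)`).
#' @return The input tibble with an added factor column `class` with levels
#'   `up`, `down`, `unaffected`, `none`.
#' @export
#' @examples
#' classify_regions(data.frame(region = c("r1", "r2", "r3"),
#'                             ratio = c(1.5, 0.5, 1.0),
#'                             fdr = c(0.005, 0.005, 0.97)))
classify_regions <- function(stats, sig_fdr = 0.01, unaffected_fdr = 0.95,
                             ratio_window = c(0.995, 1.005)) {
  if (!all(c("region", "ratio", "fdr") %in% names(stats))) {
    abort("`stats` needs columns region, ratio, fdr.")
  }
  bad <- which(!is.finite(stats$ratio) | stats$ratio <= 0)
  if (length(bad) > 0) {
    warn(paste0("Dropping rows with non-positive ratio: ",
                paste(stats$region[head(bad, 5)], collapse = ", "),
                if (length(bad) > 5) ", ..." else ""))
    stats <- stats[-bad, , drop = FALSE]
  }
  out <- as_tibble(stats)
  out$class <- factor(
    dplyr::case_when(
      out$fdr < sig_fdr & out$ratio > 1 ~ "up",
      out$fdr < sig_fdr & out$ratio < 1 ~ "down",
      out$fdr > unaffected_fdr &
        out$ratio > ratio_window[1] & out$ratio < ratio_window[2] ~
        "unaffected",
      TRUE ~ "none"
    ),
    levels = c("up", "down", "unaffected", "none")
  )
  out
}
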