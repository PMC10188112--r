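#' Tidy a permutation null
#'
#' @param x A [permutation_null()] result.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per shuffle (`shuffle`,
#'   `n_significant`). `glance()`: a one-row summary with the observed count,
#'   the empirical p-value and the thresholds used.
#' @export
tidy.perm_null <- function(x, ...) {
  tibble(shuffle = seq_len(x$n_shuffles), n_significant = x$null_counts)
}

#' @rdname tidy.perm_null
#' @export
glance.perm_null <- function(x, ...) {
  tibble(
    n_shuffles = x$n_shuffles,
    observed = x$observed,
    null_mean = mean(x$null_counts),
    null_max = max(x$null_counts),
    p_empirical = x$p_empirical,
    wilcoxon_p = x$thresholds[["wilcoxon_p"]],
    ks_p = x$thresholds[["ks_p"]],
    rule = x$rule
  )
}

#' Summarize a peak significance table
#'
#' @param x A [peak_significance()] result.
#' @param ... Unused.
#' @return A one-row tibble: number of peaks, significant calls per
#'   direction, deduplicated significant peak count, thresholds and rule.
#' @export
glance.peak_sig <- function(x, ...) {
  th <- attr(x, "thresholds")
  per_dir <- x %>%
    group_by(.data$direction) %>%
    summarise(n_sig = sum(.data$significant), .groups = "drop")
  tibble(
    n_peaks = length(unique(x$peak)),
    n_sig_total = x %>%
      group_by(.data$peak) %>%
      summarise(s = any(.data$significant), .groups = "drop") %>%
      pull("s") %>% sum(),
    !!paste0("n_sig_", per_dir$direction[1]) := per_dir$n_sig[1],
    !!paste0("n_sig_", per_dir$direction[2]) := per_dir$n_sig[2],
    wilcoxon_p = th[["wilcoxon_p"]],
    ks_p = th[["ks_p"]],
    rule = attr(x, "rule")
  )
}
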