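#' One-tailed Wilcoxon rank-sum p-value
#'
#' Tail probability of the Mann-Whitney statistic of `x` versus `y`.
#' For tie-free samples with `length(x) + length(y) <= exact_cutoff` the
#' exact null distribution is used; otherwise the normal approximation with
#' tie correction and a 0.5 continuity correction. `alternative = "greater"`
#' tests whether `x` is stochastically greater than `y`.
#'
#' This is the per-peak filtering statistic of the differential-accessibility
#' analysis: raw p-values, no multiplicity correction at this step.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative `"greater"` or `"less"` (direction of `x` vs `y`).
#' @param exact_cutoff Maximum combined sample size for the exact branch.
#' @return A single p-value in `(0, 1]`.
#' @export
#' @examples
#' wilcoxon_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater") # 1/20
wilcoxon_one_tailed <- function(x, y, alternative = c("greater", "less"),
                                exact_cutoff = 12) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) abort("Samples must be non-empty.")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && N <= exact_cutoff) {
    p <- if (alternative == "greater") {
      pwilcox(U - 1, m, n, lower.tail = FALSE) # P(U >= u)
    } else {
      pwilcox(U, m, n)                         # P(U <= u)
    }
  } else {
    tie_term <- sum(tabulate(match(c(x, y), unique(c(x, y))))^3) -
      sum(tabulate(match(c(x, y), unique(c(x, y)))))
    sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term / (N * (N - 1))))
    if (sigma == 0) return(1)
    mu <- m * n / 2
    p <- if (alternative == "greater") {
      pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    } else {
      pnorm((U - mu + 0.5) / sigma)
    }
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' One-tailed Kolmogorov-Smirnov statistic and p-value
#'
#' `D` is the supremum of the signed ECDF difference in the stated direction
#' (`"greater"`: `sup_t F_y(t) - F_x(t)`, large when `x` is stochastically
#' greater than `y`), and the p-value is the one-sided asymptotic bound
#' `exp(-2 D^2 n_e)` with effective size `n_e = m n / (m + n)`, clamped to
#' `(0, 1]`. Exact small-sample KS tail probabilities are not implemented.
#'
#' @inheritParams wilcoxon_one_tailed
#' @return A list with elements `statistic` (D, in `[0, 1]`) and `p.value`.
#' @export
#' @examples
#' ks_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater") # D = 1
ks_one_tailed <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) abort("Samples must be non-empty.")
  m <- length(x); n <- length(y)
  t_eval <- sort(unique(c(x, y)))
  Fx <- findInterval(t_eval, sort(x)) / m
  Fy <- findInterval(t_eval, sort(y)) / n
  D <- if (alternative == "greater") max(Fy - Fx) else max(Fx - Fy)
  D <- max(D, 0)
  p <- exp(-2 * D^2 * m * n / (m + n))
  list(statistic = D, p.value = min(max(p, .Machine$double.xmin), 1))
}

# ---- vectorized per-peak machinery -----------------------------------------
# Everything that depends only on the intensity values (ranks, sort orders,
# tie masks, tie-corrected variances) is precomputed once; a label assignment
# then yields all four p-value vectors in O(peaks x cells) vector operations,
# which is what makes the 1000-shuffle permutation null affordable.

pm_precompute <- function(pm, exact_cutoff = 12) {
  X <- pm$intensity
  np <- nrow(X); N <- ncol(X)
  condA <- pm$conditions[1]
  nA <- sum(pm$condition == condA); nB <- N - nA
  R <- t(apply(X, 1, rank))
  tie_term <- apply(X, 1, function(v) {
    l <- rle(sort(v))$lengths
    sum(l^3 - l)
  })
  has_ties <- tie_term > 0
  ordT <- apply(X, 1, order)                       # N x np, column-major
  flat <- sweep(ordT, 2, (seq_len(np) - 1) * N, `+`)
  sortedT <- matrix(t(X)[as.vector(flat)], nrow = N)
  lastT <- rbind(sortedT[-1, , drop = FALSE] != sortedT[-N, , drop = FALSE],
                 TRUE)
  sigma <- sqrt(nA * nB / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  list(
    np = np, N = N, nA = nA, nB = nB, condA = condA,
    R = R, sigma = sigma, has_ties = has_ties,
    ordT = ordT, last_vec = as.vector(lastT),
    col_end = seq_len(np) * N,
    pos = rep(seq_len(N), np),
    exact = !has_ties & (N <= exact_cutoff)
  )
}

# p-values for all peaks under one label assignment (isA: logical over cells)
pm_pvalues <- function(pre, isA) {
  nA <- pre$nA; nB <- pre$nB; N <- pre$N; np <- pre$np
  U <- rowSums(pre$R[, isA, drop = FALSE]) - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  ok <- pre$sigma > 0
  pW_A <- pW_B <- rep(1, np)
  pW_A[ok] <- pnorm((U[ok] - mu - 0.5) / pre$sigma[ok], lower.tail = FALSE)
  pW_B[ok] <- pnorm((U[ok] - mu + 0.5) / pre$sigma[ok])
  if (any(pre$exact)) {
    pW_A[pre$exact] <- pwilcox(U[pre$exact] - 1, nA, nB, lower.tail = FALSE)
    pW_B[pre$exact] <- pwilcox(U[pre$exact], nA, nB)
  }

  zA <- as.numeric(isA)[as.vector(pre$ordT)]       # A-membership, sorted order
  cs <- cumsum(zA)
  offs <- c(0, cs[pre$col_end[-np]])
  cntA <- cs - rep(offs, each = N)
  FA <- cntA / nA
  FB <- (pre$pos - cntA) / nB
  diffs <- FB - FA
  diffs[!pre$last_vec] <- NA_real_                 # evaluate ECDFs at run ends
  dm <- matrix(diffs, nrow = N)
  D_A <- pmax(apply_colmax(dm), 0)
  D_B <- pmax(apply_colmax(-dm), 0)
  ne2 <- 2 * nA * nB / N
  list(
    pW_A = clamp_p(pW_A), pW_B = clamp_p(pW_B),
    pKS_A = clamp_p(exp(-ne2 * D_A^2)), pKS_B = clamp_p(exp(-ne2 * D_B^2)),
    D_A = D_A, D_B = D_B
  )
}

clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

# column maxima ignoring NAs, via max.col on the transpose (C-level fast path)
apply_colmax <- function(m) {
  tm <- t(m)
  tm[is.na(tm)] <- -Inf
  tm[cbind(seq_len(nrow(tm)), max.col(tm, ties.method = "first"))]
}

sig_calls <- function(p, wilcoxon_p, ks_p, rule) {
  if (rule == "both") {
    list(A = p$pW_A < wilcoxon_p & p$pKS_A < ks_p,
         B = p$pW_B < wilcoxon_p & p$pKS_B < ks_p)
  } else {
    list(A = p$pW_A < wilcoxon_p | p$pKS_A < ks_p,
         B = p$pW_B < wilcoxon_p | p$pKS_B < ks_p)
  }
}

#' Condition-specific peak significance calls
#'
#' Tests every peak in both directions — "greater in A" (the intensity
#' distribution in condition A stochastically exceeds B) and "greater in B" —
#' with the one-tailed Wilcoxon rank-sum and one-tailed KS tests, and calls a
#' peak significant in a direction when the raw p-values pass the thresholds
#' under the combination rule. The defaults are the screening thresholds
#' 0.001 (Wilcoxon) and 0.01 (KS), combined conservatively with `"both"`
#' (both tests must pass); no multiple-testing correction is applied at this
#' filtering step by design — the permutation null of [permutation_null()]
#' is the calibration instrument instead.
#'
#' @param pm A [peak_matrix()].
#' @param wilcoxon_p,ks_p Raw p-value thresholds.
#' @param rule `"both"` (default) or `"either"`.
#' @param exact_cutoff Passed to the Wilcoxon exact branch (see
#'   [wilcoxon_one_tailed()]).
#' @return A tibble with two rows per peak: `peak`, `direction` (the
#'   condition whose distribution is tested as greater), `p_wilcoxon`,
#'   `p_ks`, `ks_D`, `significant`. Thresholds and rule are attached as
#'   attributes and via [glance()].
#' @export
peak_significance <- function(pm, wilcoxon_p = 0.001, ks_p = 0.01,
                              rule = c("both", "either"),
                              exact_cutoff = 12) {
  rule <- match.arg(rule)
  stopifnot(inherits(pm, "peak_matrix"))
  pre <- pm_precompute(pm, exact_cutoff)
  p <- pm_pvalues(pre, pm$condition == pre$condA)
  sig <- sig_calls(p, wilcoxon_p, ks_p, rule)
  peaks <- rownames(pm$intensity)
  out <- bind_rows(
    tibble(peak = peaks, direction = pm$conditions[1],
           p_wilcoxon = p$pW_A, p_ks = p$pKS_A, ks_D = p$D_A,
           significant = sig$A),
    tibble(peak = peaks, direction = pm$conditions[2],
           p_wilcoxon = p$pW_B, p_ks = p$pKS_B, ks_D = p$D_B,
           significant = sig$B)
  ) %>%
    arrange(match(.data$peak, peaks), match(.data$direction, pm$conditions))
  attr(out, "thresholds") <- c(wilcoxon_p = wilcoxon_p, ks_p = ks_p)
  attr(out, "rule") <- rule
  class(out) <- c("peak_sig", class(out))
  out
}

count_significant <- function(pre, isA, wilcoxon_p, ks_p, rule) {
  sig <- sig_calls(pm_pvalues(pre, isA), wilcoxon_p, ks_p, rule)
  sum(sig$A | sig$B) # a peak significant in both directions counts once
}

#' Label-shuffling permutation null for the significant-peak count
#'
#' How many significant peaks would the screening thresholds produce if the
#' condition labels carried no information? Each shuffle permutes the
#' condition labels across cells — preserving both group sizes and, per peak,
#' the multiset of intensities — and recounts the significant peaks (both
#' directions, deduplicated per peak). The empirical p-value of the observed
#' count uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_shuffles)`, so it can never be
#' smaller than `1/(n_shuffles + 1)`.
#'
#' @inheritParams peak_significance
#' @param n_shuffles Number of label shuffles (default 1000).
#' @param seed Optional integer seed for the shuffles.
#' @return An object of class `perm_null`: list with `n_shuffles`,
#'   `null_counts`, `observed`, `p_empirical`, `thresholds`, `rule`.
#'   [tidy()] returns the null counts, [glance()] the one-row summary.
#' @export
permutation_null <- function(pm, n_shuffles = 1000, seed = NULL,
                             wilcoxon_p = 0.001, ks_p = 0.01,
                             rule = c("both", "either"),
                             exact_cutoff = 12) {
  rule <- match.arg(rule)
  stopifnot(inherits(pm, "peak_matrix"))
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1.")
  pre <- pm_precompute(pm, exact_cutoff)
  isA_obs <- pm$condition == pre$condA
  observed <- count_significant(pre, isA_obs, wilcoxon_p, ks_p, rule)

  run <- function() {
    vapply(seq_len(n_shuffles), function(s) {
      isA <- logical(pre$N)
      isA[sample.int(pre$N, pre$nA)] <- TRUE
      stopifnot(sum(isA) == pre$nA) # group sizes preserved by construction
      count_significant(pre, isA, wilcoxon_p, ks_p, rule)
    }, numeric(1))
  }
  null_counts <- if (is.null(seed)) run() else
    withr::with_seed(as.integer(seed), run())

  structure(
    list(n_shuffles = n_shuffles, null_counts = null_counts,
         observed = observed,
         p_empirical = (1 + sum(null_counts >= observed)) / (1 + n_shuffles),
         thresholds = c(wilcoxon_p = wilcoxon_p, ks_p = ks_p), rule = rule),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null> observed %d significant peaks; null over %d shuffles: %g-%g (median %g)\n  empirical p = %.4g\n",
    x$observed, x$n_shuffles, min(x$null_counts), max(x$null_counts),
    stats::median(x$null_counts), x$p_empirical
  ))
  invisible(x)
}
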