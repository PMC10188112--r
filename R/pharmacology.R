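#' Read and write fingerprint libraries
#'
#' A fingerprint library stores one behavioral fingerprint per condition
#' (e.g. one psychoactive compound at one dose; compound-by-dose entries are
#' distinct conditions, never aggregated). On disk it is a CSV whose first
#' column is `condition`, an optional `annotation` column carries free-text
#' target classes, and the remaining columns are measure names from the
#' declared schema.
#'
#' @param path CSV path.
#' @return A tibble: `condition`, optional `annotation`, measure columns.
#' @export
read_library <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  spec <- readr::cols(condition = readr::col_character(),
                      .default = readr::col_double())
  if ("annotation" %in% header) {
    spec$cols$annotation <- readr::col_character()
  }
  lib <- readr::read_csv(path, col_types = spec, progress = FALSE)
  if (anyDuplicated(lib$condition)) abort("Duplicate condition names.")
  lib
}

#' @rdname read_library
#' @param lib Library tibble.
#' @export
write_library <- function(lib, path) {
  readr::write_csv(lib, path, progress = FALSE)
  invisible(path)
}

#' Rank a library against a query fingerprint
#'
#' Computes the Pearson correlation between the query fingerprint and every
#' library condition over their shared non-missing measures, and returns the
#' conditions ranked by decreasing correlation — the drug-matching step of a
#' pharmaco-behavioral screen: the top-ranked compounds are the candidate
#' phenocopies of the query phenotype.
#'
#' Conditions sharing fewer than `min_overlap` measures with the query, or
#' with an undefined (zero-variance) correlation, are dropped from the
#' ranking. Ties in correlation are broken by condition name.
#'
#' @param query A fingerprint (named vector, one-row fingerprint tibble, or
#'   [group_fingerprint()] summary).
#' @param lib Library tibble (see [read_library()]).
#' @param min_overlap Minimum shared measures per condition.
#' @return A tibble `condition`, `r`, `n_overlap` (plus `annotation` if the
#'   library carries one), sorted by `r` descending.
#' @export
rank_library <- function(query, lib, min_overlap = 5) {
  q <- as_fp_vector(query)
  q <- q[!is.na(q)]
  measures <- intersect(names(q), names(lib))
  rows <- map(seq_len(nrow(lib)), function(i) {
    v <- stats::setNames(as.numeric(lib[i, measures]), measures)
    shared <- measures[!is.na(v)]
    r <- if (length(shared) < min_overlap ||
             sd(q[shared]) == 0 || sd(v[shared]) == 0) {
      NA_real_
    } else {
      cor(q[shared], v[shared])
    }
    tibble(condition = lib$condition[i], r = r,
           n_overlap = length(shared))
  })
  out <- list_rbind(rows) %>%
    filter(!is.na(.data$r), .data$n_overlap >= min_overlap) %>%
    arrange(desc(.data$r), .data$condition)
  if (nrow(out) == 0) warn("No library condition meets `min_overlap`.")
  if ("annotation" %in% names(lib)) {
    out <- left_join(out, select(lib, "condition", "annotation"),
                     by = "condition")
  }
  out
}

#' Hierarchical clustergram of fingerprints
#'
#' Agglomerative average-linkage (UPGMA) clustering of fingerprint rows under
#' correlation distance `d = 1 - r` (Pearson, pairwise-complete). This is the
#' clustergram used to place a mutant fingerprint among library compounds:
#' rows that phenocopy each other merge low in the tree.
#'
#' Ties in the merge order are broken deterministically in favor of the pair
#' whose clusters contain the lowest original row indices, so the tree
#' (topology and merge heights) is invariant to permuting the input rows. Any
#' pair of rows sharing fewer than `min_overlap` measures, or with an
#' undefined correlation, aborts with the pair named — a clustergram over an
#' incomplete dissimilarity is not meaningful.
#'
#' @param x A tibble with a `condition` (or `larva_id`) id column plus
#'   measure columns, or a numeric matrix with row names.
#' @param min_overlap Minimum shared non-missing measures per pair.
#' @return An object of class `hclust` (standard `merge`, `height`, `order`,
#'   `labels` components; `plot()` and `stats::as.dendrogram()` work).
#' @export
cluster_fingerprints <- function(x, min_overlap = 5) {
  if (is.data.frame(x)) {
    id_col <- intersect(c("condition", "larva_id", "id"), names(x))[1]
    if (is.na(id_col)) abort("Need an id column (condition/larva_id/id).")
    labels <- as.character(x[[id_col]])
    m <- as.matrix(x[, setdiff(names(x), c(id_col, "annotation",
                                           "group", "reference_group")),
                     drop = FALSE])
  } else {
    m <- as.matrix(x)
    labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  }
  n <- nrow(m)
  if (n < 2) abort("Need at least 2 rows to cluster.")
  if (anyDuplicated(labels)) abort("Row labels must be unique.")

  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (sum(ok) < min_overlap) {
        abort(sprintf("Rows '%s' and '%s' share only %d measures.",
                      labels[i], labels[j], sum(ok)))
      }
      if (sd(m[i, ok]) == 0 || sd(m[j, ok]) == 0) {
        abort(sprintf("Correlation undefined for rows '%s' and '%s'.",
                      labels[i], labels[j]))
      }
      d[i, j] <- d[j, i] <- 1 - cor(m[i, ok], m[j, ok])
    }
  }
  upgma(d, labels)
}

# UPGMA agglomeration with Lance-Williams updates and lowest-original-index
# tie-breaking; returns a stats::hclust-compatible object.
upgma <- function(d, labels) {
  n <- nrow(d)
  active <- seq_len(n)
  code <- -seq_len(n)         # hclust merge codes
  size <- rep(1L, n)
  rep_idx <- seq_len(n)       # lowest original row index in each cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  diag(d) <- Inf

  for (step in seq_len(n - 1)) {
    sub <- d[active, active, drop = FALSE]
    h <- min(sub)
    cand <- which(sub <= h + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: lowest pair of original-row representatives
    ri <- rep_idx[active[cand[, 1]]]
    rj <- rep_idx[active[cand[, 2]]]
    lo <- pmin(ri, rj); hi <- pmax(ri, rj)
    pick <- order(lo, hi)[1]
    a <- active[cand[pick, 1]]
    b <- active[cand[pick, 2]]

    merge[step, ] <- sort_merge_codes(code[a], code[b])
    height[step] <- h
    others <- setdiff(active, c(a, b))
    if (length(others) > 0) {
      d[a, others] <- d[others, a] <-
        (size[a] * d[a, others] + size[b] * d[b, others]) /
        (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    rep_idx[a] <- min(rep_idx[a], rep_idx[b])
    code[a] <- step
    active <- setdiff(active, b)
  }
  structure(
    list(merge = merge, height = height, order = hclust_leaf_order(merge),
         labels = labels, method = "average",
         dist.method = "1 - pearson", call = match.call()),
    class = "hclust"
  )
}

# hclust convention: singletons (negative codes) before clusters, else by code
sort_merge_codes <- function(a, b) {
  if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) ||
      (a > 0 && b < 0)) c(b, a) else c(a, b)
}

hclust_leaf_order <- function(merge) {
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  }
  leaves(nrow(merge))
}
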