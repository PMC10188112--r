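# Independent brute-force oracles. These deliberately avoid the vectorized
# code paths of the package: frame-by-frame scans, full enumeration, O(n*m)
# loops, so that agreement is evidence and not tautology.

# run-length bout decomposition by a literal frame scan (preallocated)
oracle_bouts <- function(values, start_frame = 0,
                         end_frame = length(values), activity_floor = 0) {
  n <- end_frame - start_frame
  states <- character(n)
  starts <- numeric(n)
  ends <- numeric(n)
  k <- 0L
  cur_state <- NA_character_
  for (f in start_frame:(end_frame - 1)) {
    st <- if (values[f + 1] > activity_floor) "active" else "inactive"
    if (!identical(st, cur_state)) {
      k <- k + 1L
      states[k] <- st
      starts[k] <- f
      ends[k] <- f + 1
      cur_state <- st
    } else {
      ends[k] <- f + 1
    }
  }
  tibble::tibble(state = states[seq_len(k)], start_frame = starts[seq_len(k)],
                 end_frame = ends[seq_len(k)])
}

# naive UPGMA: recompute the mean pairwise original distance between every
# pair of clusters at every step (no Lance-Williams update); same
# lowest-original-index tie-break as documented.
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        key <- c(h, min(min(clusters[[i]]), min(clusters[[j]])),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) ||
            key[1] < best$key[1] - 1e-12 ||
            (abs(key[1] - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    members <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- list(members = members,
                                         height = best$key[1])
    clusters[[best$i]] <- members
    clusters[[best$j]] <- NULL
  }
  merges
}

# member sets (original row indices) and heights per merge of an hclust
hclust_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    mem <- unlist(lapply(hc$merge[k, ], function(code) {
      if (code < 0) -code else sets[[code]]$members
    }))
    sets[[k]] <- list(members = sort(mem), height = hc$height[k])
  }
  sets
}

# exact one-tailed rank-sum p by enumerating all C(N, m) group assignments
oracle_wilcox_enum <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  m <- length(x)
  w_obs <- sum(rank(pooled)[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  r <- rank(pooled)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  if (alternative == "greater") mean(ws >= w_obs) else mean(ws <= w_obs)
}

# one-sided KS statistic by sweeping every observed threshold
oracle_ks_D <- function(x, y, alternative = "greater") {
  ts <- sort(unique(c(x, y)))
  d <- vapply(ts, function(t) {
    if (alternative == "greater") mean(y <= t) - mean(x <= t)
    else mean(x <= t) - mean(y <= t)
  }, numeric(1))
  max(c(d, 0))
}

# O(n*m) interval overlap (>= 1 shared base, half-open)
oracle_overlaps <- function(a, b) {
  out <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      out[i, j] <- a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]
    }
  }
  out
}

# small random tie-free samples for exact-test comparisons
random_tiefree <- function(m, n) {
  v <- sample(seq_len(200), m + n)
  list(x = v[seq_len(m)], y = v[(m + 1):(m + n)])
}
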