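test_that("exact one-tailed Wilcoxon matches the textbook case", {
  expect_equal(wilcoxon_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05)
  expect_equal(wilcoxon_one_tailed(c(1, 2, 3), c(4, 5, 6), "less"), 0.05)
})

test_that("identical samples carry no evidence", {
  x <- c(1, 5, 9)
  expect_gte(wilcoxon_one_tailed(x, x, "greater"), 0.5)
  expect_gte(wilcoxon_one_tailed(rep(2, 10), rep(2, 10), "greater"), 0.5)
  ks <- ks_one_tailed(x, x, "greater")
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p.value, 1)
})

test_that("exact Wilcoxon equals full enumeration for sizes up to (4,4)", {
  withr::with_seed(31, {
    for (m in 1:4) {
      for (n in 1:4) {
        for (rep in 1:3) {
          s <- random_tiefree(m, n)
          for (alt in c("greater", "less")) {
            expect_equal(wilcoxon_one_tailed(s$x, s$y, alt),
                         oracle_wilcox_enum(s$x, s$y, alt),
                         tolerance = 1e-12)
          }
        }
      }
    }
  })
})

test_that("complementary exact tails overlap at the boundary atom", {
  withr::with_seed(32, {
    for (i in 1:10) {
      s <- random_tiefree(sample(2:4, 1), sample(2:4, 1))
      expect_gte(wilcoxon_one_tailed(s$x, s$y, "greater") +
                   wilcoxon_one_tailed(s$y, s$x, "greater"), 1)
    }
  })
})

test_that("the normal branch approximates the exact branch", {
  withr::with_seed(33, {
    s <- random_tiefree(6, 6)
    p_exact <- wilcoxon_one_tailed(s$x, s$y, "greater")
    p_approx <- wilcoxon_one_tailed(s$x, s$y, "greater", exact_cutoff = 0)
    expect_equal(p_approx, p_exact, tolerance = 0.15)
  })
  expect_error(wilcoxon_one_tailed(numeric(0), 1), "non-empty")
})

test_that("one-sided KS statistic on disjoint supports is 1", {
  ks <- ks_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(ks$statistic, 1)
  expect_equal(ks$p.value, exp(-2 * 1 * 9 / 6))
  # wrong direction: no mass above
  expect_equal(ks_one_tailed(c(4, 5, 6), c(1, 2, 3), "less")$statistic, 0)
})

test_that("KS D equals the ECDF sweep oracle, ties included", {
  withr::with_seed(34, {
    for (i in 1:50) {
      x <- sample(0:8, sample(3:20, 1), replace = TRUE)
      y <- sample(0:8, sample(3:20, 1), replace = TRUE)
      for (alt in c("greater", "less")) {
        expect_equal(ks_one_tailed(x, y, alt)$statistic,
                     oracle_ks_D(x, y, alt), tolerance = 1e-12)
      }
    }
  })
})

test_that("peak_significance agrees with the scalar tests peak by peak", {
  withr::with_seed(35, {
    pmx <- simulate_peak_matrix(peak_sim_config(
      n_peaks = 30, n_cells = c(A = 8, B = 10), fraction_differential = 0.2,
      effect_size = 6, seed = 40))
    ps <- peak_significance(pmx)
    isA <- pmx$condition == pmx$conditions[1]
    for (i in seq_len(30)) {
      x <- pmx$intensity[i, isA]
      y <- pmx$intensity[i, !isA]
      rowA <- ps[ps$peak == rownames(pmx$intensity)[i] &
                   ps$direction == pmx$conditions[1], ]
      expect_equal(rowA$p_wilcoxon, wilcoxon_one_tailed(x, y, "greater"),
                   tolerance = 1e-12)
      expect_equal(rowA$p_ks, ks_one_tailed(x, y, "greater")$p.value,
                   tolerance = 1e-12)
      rowB <- ps[ps$peak == rownames(pmx$intensity)[i] &
                   ps$direction == pmx$conditions[2], ]
      expect_equal(rowB$p_wilcoxon, wilcoxon_one_tailed(x, y, "less"),
                   tolerance = 1e-12)
      expect_equal(rowB$p_ks, ks_one_tailed(y, x, "greater")$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("constant peaks are never significant in either direction", {
  m <- matrix(5, nrow = 3, ncol = 10)
  pmx <- peak_matrix(m, rep(c("A", "B"), each = 5))
  ps <- peak_significance(pmx)
  expect_false(any(ps$significant))
  expect_true(all(ps$p_wilcoxon == 1))
})

test_that("planted differential peaks are detected, nulls rarely called", {
  pmx <- simulate_peak_matrix(peak_sim_config(
    n_peaks = 300, fraction_differential = 0.1, effect_size = 4, seed = 41))
  ps <- peak_significance(pmx)
  planted_ids <- rownames(pmx$intensity)[pmx$planted]
  by_peak <- tapply(ps$significant, ps$peak, any)
  expect_gte(mean(by_peak[planted_ids]), 0.8)
  null_ids <- setdiff(rownames(pmx$intensity), planted_ids)
  expect_lte(mean(by_peak[null_ids]), 0.02)
  # planted direction is condition B (the scaled condition)
  sigB <- ps$significant[ps$direction == pmx$conditions[2]]
  sigA <- ps$significant[ps$direction == pmx$conditions[1]]
  expect_gt(sum(sigB), sum(sigA))
})

test_that("the either rule is at least as permissive as both", {
  pmx <- simulate_peak_matrix(peak_sim_config(
    n_peaks = 100, fraction_differential = 0.2, effect_size = 2, seed = 42))
  both <- peak_significance(pmx, rule = "both")
  either <- peak_significance(pmx, rule = "either")
  expect_true(all(either$significant >= both$significant))
})

test_that("shuffling preserves per-peak multisets and the plus-one formula", {
  pmx <- simulate_peak_matrix(peak_sim_config(
    n_peaks = 50, n_cells = c(A = 10, B = 12),
    fraction_differential = 0.3, effect_size = 8, seed = 43))
  pn <- permutation_null(pmx, n_shuffles = 200, seed = 44)
  expect_length(pn$null_counts, 200)
  expect_equal(pn$p_empirical,
               (1 + sum(pn$null_counts >= pn$observed)) / 201)
  expect_gte(pn$p_empirical, 1 / 201)
  expect_lte(pn$p_empirical, 1)
  # strong planted effect: observed exceeds every null count
  expect_equal(pn$p_empirical, 1 / 201)
  expect_error(permutation_null(pmx, n_shuffles = 0), "n_shuffles")
})

test_that("an all-null matrix has empirical p 1 when observed is 0", {
  pmx <- simulate_peak_matrix(peak_sim_config(
    n_peaks = 40, n_cells = c(A = 5, B = 5), fraction_differential = 0,
    seed = 45))
  pn <- permutation_null(pmx, n_shuffles = 100, seed = 46)
  expect_equal(pn$observed, 0)
  expect_equal(pn$p_empirical, 1)
})

test_that("permutation null is reproducible from its seed", {
  pmx <- simulate_peak_matrix(peak_sim_config(n_peaks = 30, seed = 47))
  a <- permutation_null(pmx, n_shuffles = 50, seed = 48)
  b <- permutation_null(pmx, n_shuffles = 50, seed = 48)
  expect_identical(a$null_counts, b$null_counts)
})

test_that("region classification applies the published rule exactly", {
  stats <- tibble::tibble(
    region = sprintf("r%d", 1:7),
    ratio = c(1.5, 0.5, 1.000, 1.2, 1.004, 0.996, 1.02),
    fdr = c(0.005, 0.005, 0.97, 0.50, 0.96, 0.951, 0.99)
  )
  cls <- classify_regions(stats)
  expect_equal(as.character(cls$class),
               c("up", "down", "unaffected", "none", "unaffected",
                 "unaffected", "none"))
  # classes partition the rows
  expect_equal(sum(table(cls$class)), nrow(cls))
  expect_warning(
    out <- classify_regions(tibble::tibble(region = c("bad", "ok"),
                                           ratio = c(-1, 1.5),
                                           fdr = c(0.001, 0.001))),
    "bad")
  expect_equal(out$region, "ok")
})

test_that("region classification is bit-reproducible and boundary-strict", {
  stats <- tibble::tibble(region = c("a", "b", "c"),
                          ratio = c(1, 0.995, 1.005),
                          fdr = c(0.951, 0.96, 0.96))
  c1 <- classify_regions(stats)
  c2 <- classify_regions(stats)
  expect_identical(c1, c2)
  # open interval: ratio exactly at the window edge is not unaffected
  expect_equal(as.character(c1$class), c("unaffected", "none", "none"))
})

test_that("peak matrix CSV round-trips through dense and triplet forms", {
  pmx <- simulate_peak_matrix(peak_sim_config(
    n_peaks = 12, n_cells = c(A = 3, B = 4), seed = 49))
  tdir <- withr::local_tempdir()
  mp <- file.path(tdir, "m.csv")
  lp <- file.path(tdir, "l.csv")
  write_peak_matrix(pmx, mp, lp)
  back <- read_peak_matrix(mp, lp)
  expect_equal(back$intensity, pmx$intensity)
  expect_equal(back$condition, pmx$condition)

  trip <- tibble::tibble(
    peak = rep(rownames(pmx$intensity), ncol(pmx$intensity)),
    cell = rep(colnames(pmx$intensity), each = nrow(pmx$intensity)),
    value = as.vector(pmx$intensity)
  )
  tp <- file.path(tdir, "t.csv")
  readr::write_csv(trip, tp)
  back2 <- read_peak_matrix(tp, lp)
  expect_equal(back2$intensity[rownames(pmx$intensity),
                               colnames(pmx$intensity)],
               pmx$intensity)
})
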