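test_that("Tn5 shifts are +4 on plus reads, -5 on minus reads", {
  reads <- tibble::tibble(chrom = "chr1", start = c(100, 100),
                          end = c(150, 150), strand = c("+", "-"))
  out <- shift_reads(reads)
  expect_equal(out$start, c(104, 100))
  expect_equal(out$end, c(150, 145))
})

test_that("a shift that collapses a read is rejected with the record named", {
  expect_error(
    shift_reads(tibble::tibble(chrom = "chr1", start = 0, end = 3,
                               strand = "+")),
    "row 1")
  expect_error(
    shift_reads(tibble::tibble(chrom = "chr1", start = 10, end = 14,
                               strand = "-")),
    "collapses")
  expect_error(
    shift_reads(tibble::tibble(chrom = "chr1", start = 0, end = 10,
                               strand = ".")),
    "strand")
})

test_that("effective-fragment filtering applies both thresholds", {
  frags <- tibble::tibble(
    chrom = "chr1", start = c(0, 0, 0, 0),
    end = c(80, 80, 150, 150), mapq = c(35, 20, 35, 10)
  )
  kept <- filter_fragments(frags)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$end, 80)
  expect_equal(attr(kept, "dropped"), c(mapq = 2L, insert = 1L))
  # boundary values are kept: mapq == 30 and insert == 100
  edge <- tibble::tibble(chrom = "chr1", start = 0, end = 100, mapq = 30)
  expect_equal(nrow(filter_fragments(edge)), 1)
})

test_that("fragment filtering is idempotent and order-preserving", {
  withr::with_seed(51, {
    frags <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
      start = sample(0:1000, 50),
      mapq = sample(0:60, 50, replace = TRUE)
    )
    frags$end <- frags$start + sample(20:200, 50, replace = TRUE)
    once <- filter_fragments(frags)
    twice <- filter_fragments(once)
    strip <- function(x) { attr(x, "dropped") <- NULL; as.data.frame(x) }
    expect_equal(strip(twice), strip(once))
    expect_equal(attr(twice, "dropped"), c(mapq = 0L, insert = 0L))
  })
})

test_that("RPM coverage is count per million effective fragments", {
  frags <- tibble::tibble(chrom = "chr1",
                          start = c(0, 10, 20, 500, 600),
                          end = c(60, 70, 80, 560, 660),
                          mapq = 60)
  pos <- tibble::tibble(chrom = "chr1", start = c(50, 400), end = c(51, 401))
  out <- rpm_coverage(frags, pos)
  expect_equal(out$rpm, c(3 * 1e6 / 5, 0))
  expect_error(rpm_coverage(frags[0, ], pos), "No fragments")
})

test_that("RPM coverage equals the brute-force overlap oracle", {
  withr::with_seed(52, {
    for (i in 1:10) {
      frags <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
        start = sample(0:500, 40, replace = TRUE)
      )
      frags$end <- frags$start + sample(1:90, 40, replace = TRUE)
      pos <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 15,
                                           replace = TRUE),
                            start = sample(0:500, 15, replace = TRUE))
      pos$end <- pos$start + sample(1:50, 15, replace = TRUE)
      out <- rpm_coverage(frags, pos)
      counts <- rowSums(oracle_overlaps(pos, frags))
      expect_equal(out$rpm, counts * 1e6 / nrow(frags))
    }
  })
})

test_that("condition-specific peaks implement the high/low threshold rule", {
  a_high <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  empty <- a_high[0, ]
  # no low-threshold call in the other condition: specific
  out <- condition_specific_peaks(a_high, a_high, empty, empty)
  expect_equal(nrow(out$specific_to_a), 1)
  # overlapping low call in B: not specific
  b_low <- tibble::tibble(chrom = "chr1", start = 150, end = 250)
  out2 <- condition_specific_peaks(a_high, a_high, empty, b_low)
  expect_equal(nrow(out2$specific_to_a), 0)
  # half-open: abutting at the boundary is not overlap
  b_low3 <- tibble::tibble(chrom = "chr1", start = 200, end = 300)
  out3 <- condition_specific_peaks(a_high, a_high, empty, b_low3)
  expect_equal(nrow(out3$specific_to_a), 1)
  # different chromosome never overlaps
  b_low4 <- tibble::tibble(chrom = "chr2", start = 100, end = 200)
  out4 <- condition_specific_peaks(a_high, a_high, empty, b_low4)
  expect_equal(nrow(out4$specific_to_a), 1)
})

test_that("same condition on both sides yields no specific peaks", {
  withr::with_seed(53, {
    high <- tibble::tibble(chrom = "chr1",
                           start = seq(0, 900, by = 100) + sample(0:20, 10))
    high$end <- high$start + 50
    low <- dplyr::bind_rows(high, tibble::tibble(
      chrom = "chr1", start = 2000, end = 2100))
    out <- condition_specific_peaks(high, low, high, low)
    expect_equal(nrow(out$specific_to_a), 0)
    expect_equal(nrow(out$specific_to_b), 0)
  })
})

test_that("promoter association uses a half-open +/- flank window", {
  genes <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 1000,
                          strand = "+")
  inside <- tibble::tibble(chrom = "chr1", start = 1500, end = 1600)
  expect_equal(promoter_association(inside, genes)$gene, "g1")
  boundary <- tibble::tibble(chrom = "chr1", start = 2000, end = 2100)
  expect_equal(nrow(promoter_association(boundary, genes)), 0)
  # promoter clipped at 0 for a TSS near the chromosome start
  near0 <- tibble::tibble(gene = "g2", chrom = "chr1", tss = 200,
                          strand = "-")
  peak0 <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  expect_equal(promoter_association(peak0, near0)$gene, "g2")
})

test_that("promoter association equals the brute-force oracle", {
  withr::with_seed(54, {
    for (i in 1:10) {
      genes <- tibble::tibble(
        gene = sprintf("g%d", 1:12),
        chrom = sample(c("chr1", "chr2"), 12, replace = TRUE),
        tss = sample(0:5000, 12),
        strand = sample(c("+", "-"), 12, replace = TRUE)
      )
      peaks <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
        start = sample(0:5000, 20)
      )
      peaks$end <- peaks$start + sample(50:800, 20, replace = TRUE)
      out <- promoter_association(peaks, genes, flank = 1000)
      prom <- tibble::tibble(chrom = genes$chrom,
                             start = pmax(0, genes$tss - 1000),
                             end = genes$tss + 1000)
      expected <- sum(oracle_overlaps(prom, peaks))
      expect_equal(nrow(out), expected)
    }
  })
})

test_that("BED3 and BED6 round-trip bit-exactly", {
  withr::with_seed(55, {
    bed3 <- tibble::tibble(chrom = c("chr2", "chr1", "chr1"),
                           start = c(5L, 0L, 100L),
                           end = c(10L, 50L, 101L))
    p3 <- withr::local_tempfile(fileext = ".bed")
    write_bed(bed3, p3)
    expect_identical(as.data.frame(read_bed(p3)), as.data.frame(bed3))

    bed6 <- dplyr::mutate(bed3, name = c("x", "y", "z"),
                          score = c(0L, 30L, 60L),
                          strand = c("+", "-", "+"))
    p6 <- withr::local_tempfile(fileext = ".bed")
    write_bed(bed6, p6)
    expect_identical(as.data.frame(read_bed(p6)), as.data.frame(bed6))

    # fragment dialect: score column carries mapq
    frag <- dplyr::rename(bed6, mapq = score)
    pf <- withr::local_tempfile(fileext = ".bed")
    write_fragments(frag, pf)
    expect_identical(as.data.frame(read_fragments(pf)), as.data.frame(frag))
  })
})

test_that("invalid intervals are rejected with the row named", {
  bad <- tibble::tibble(chrom = "chr1", start = 10, end = 10)
  expect_error(write_bed(bad, tempfile()), "row 1")
  expect_error(rpm_coverage(
    tibble::tibble(chrom = "chr1", start = -1, end = 5, mapq = 60),
    tibble::tibble(chrom = "chr1", start = 0, end = 1)), "Invalid interval")
})
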