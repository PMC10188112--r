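#' Genomic interval tables
#'
#' Intervals throughout the package are plain tibbles in the BED convention:
#' 0-based half-open `[start, end)` with `start < end`; overlap means at
#' least one shared base, so intervals abutting at a boundary do not overlap.
#'
#' `read_bed()`/`write_bed()` handle BED3 (`chrom,start,end`) and BED6
#' (`... ,name,score,strand`) with bit-exact field round-trips.
#' `read_fragments()`/`write_fragments()` are the fragment-BED dialect where
#' the score column carries the mapping quality (`mapq`).
#'
#' @param path BED path (tab-separated, no header).
#' @return A tibble with columns `chrom`, `start`, `end` and, for BED6,
#'   `name`, `score` (or `mapq`), `strand`.
#' @name bed_io
NULL

#' @rdname bed_io
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    X1 = readr::col_character(), X2 = readr::col_integer(),
    X3 = readr::col_integer(), .default = readr::col_character()
  ), progress = FALSE)
  if (!ncol(bed) %in% c(3, 6)) abort("Expected BED3 or BED6.")
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand")[
    seq_len(ncol(bed))]
  if ("score" %in% names(bed)) bed$score <- as.integer(bed$score)
  validate_intervals(bed)
  bed
}

#' @rdname bed_io
#' @param x Interval tibble.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname bed_io
#' @export
read_fragments <- function(path) {
  rename(read_bed(path), mapq = "score")
}

#' @rdname bed_io
#' @export
write_fragments <- function(x, path) {
  write_bed(rename(x, score = "mapq"), path)
}

validate_intervals <- function(x) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort("Interval table needs columns chrom, start, end.")
  }
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf("Invalid interval at row %d: [%s, %s).",
                  bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Tn5 insertion-site read shift
#'
#' Tn5 transposition duplicates 9 bp of target sequence, so the accessibility
#' signal sits inside the read ends: plus-strand reads are offset by +4 bp
#' (`start := start + 4`) and minus-strand reads by -5 bp (`end := end - 5`).
#' A read that the shift would collapse (`start >= end`) is an error naming
#' the record.
#'
#' @param reads Interval tibble with a `strand` column (`"+"` or `"-"`).
#' @return The shifted tibble.
#' @export
#' @examples
#' shift_reads(data.frame(chrom = "chr1", start = 100, end = 150,
#'                        strand = "+"))
shift_reads <- function(reads) {
  validate_intervals(reads)
  if (!"strand" %in% names(reads)) abort("`reads` needs a strand column.")
  if (!all(reads$strand %in% c("+", "-"))) {
    abort("Read strand must be '+' or '-'.")
  }
  out <- as_tibble(reads)
  plus <- out$strand == "+"
  out$start[plus] <- out$start[plus] + 4
  out$end[!plus] <- out$end[!plus] - 5
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "Shift collapses read at row %d (%s:[%d, %d) %s).",
      bad[1], reads$chrom[bad[1]], reads$start[bad[1]], reads$end[bad[1]],
      reads$strand[bad[1]]
    ))
  }
  out
}

#' Filter fragments to effective fragments
#'
#' Keeps the fragments used for accessibility quantification: uniquely mapped
#' (mapping quality `>= min_mapq`) with insert size (`end - start`)
#' `<= max_insert`, the sub-nucleosomal "effective fragments". Order is
#' preserved and the operation is idempotent. Counts of fragments dropped by
#' each reason (mapq checked first) are attached as attribute `dropped`.
#'
#' @param frags Fragment tibble with columns `chrom`, `start`, `end`, `mapq`.
#' @param min_mapq Minimum mapping quality (default 30).
#' @param max_insert Maximum insert size in bp (default 100).
#' @return The retained fragments, with `attr(, "dropped")` =
#'   `c(mapq = ..., insert = ...)`.
#' @export
filter_fragments <- function(frags, min_mapq = 30, max_insert = 100) {
  validate_intervals(frags)
  if (!"mapq" %in% names(frags)) abort("`frags` needs a mapq column.")
  insert <- frags$end - frags$start
  fail_mapq <- frags$mapq < min_mapq
  fail_insert <- !fail_mapq & insert > max_insert
  out <- as_tibble(frags)[!(fail_mapq | fail_insert), , drop = FALSE]
  attr(out, "dropped") <- c(mapq = sum(fail_mapq),
                            insert = sum(fail_insert))
  out
}

#' Fragment coverage in reads per million (RPM)
#'
#' Normalized accessibility signal: for every query interval, the number of
#' effective fragments overlapping it (>= 1 bp), scaled per million effective
#' fragments in the sample. Pass single-base intervals for per-nucleotide
#' coverage tracks.
#'
#' @param frags Effective fragment tibble (at least one fragment).
#' @param positions Interval tibble of query positions.
#' @return `positions` with an added `rpm` column.
#' @export
rpm_coverage <- function(frags, positions) {
  validate_intervals(positions)
  if (nrow(frags) == 0) abort("No fragments: RPM is undefined.")
  validate_intervals(frags)
  # differing chromosome sets between queries and fragments are legitimate
  # (zero overlap), so the seqlevel mismatch warning is noise here
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(positions), as_granges(frags)))
  out <- as_tibble(positions)
  out$rpm <- hits * 1e6 / nrow(frags)
  out
}

#' Condition-specific peaks from high/low-threshold call sets
#'
#' A peak is specific to condition A when it is called at the stringent
#' (high) threshold in A and overlaps (>= 1 bp) no peak called at the lenient
#' (low) threshold in B — so the peak is confidently present in one condition
#' and not even weakly detected in the other; symmetrically for B. With the
#' same condition on both sides (low set covering the high set) both outputs
#' are empty.
#'
#' @param a_high,a_low,b_high,b_low Interval tibbles of peak calls at the
#'   high and low significance thresholds in each condition.
#' @return A list with elements `specific_to_a` and `specific_to_b`.
#' @export
condition_specific_peaks <- function(a_high, a_low, b_high, b_low) {
  specific <- function(high, other_low) {
    validate_intervals(high)
    if (nrow(other_low) == 0) return(as_tibble(high))
    validate_intervals(other_low)
    hits <- suppressWarnings(
      GenomicRanges::countOverlaps(as_granges(high), as_granges(other_low)))
    as_tibble(high)[hits == 0, , drop = FALSE]
  }
  list(specific_to_a = specific(a_high, b_low),
       specific_to_b = specific(b_high, a_low))
}

#' Associate peaks with gene promoters
#'
#' A gene is associated with every peak overlapping (>= 1 bp) its promoter,
#' defined as the strand-symmetric window
#' `[max(0, tss - flank), tss + flank)` around the transcription start site.
#' The `tss` column must already be the strand-aware start coordinate (for a
#' minus-strand gene, the 3'-most base of its annotated span, i.e.
#' `end - 1` in BED coordinates).
#'
#' @param peaks Interval tibble of peaks.
#' @param genes Data frame with columns `gene`, `chrom`, `tss`, `strand`
#'   (`"+"` or `"-"`).
#' @param flank Promoter half-width in bp (default 1000).
#' @return A tibble with one row per gene-peak association: `gene`, `chrom`,
#'   `peak_start`, `peak_end` (and `peak_name` when peaks are named).
#' @export
promoter_association <- function(peaks, genes, flank = 1000) {
  validate_intervals(peaks)
  if (!all(c("gene", "chrom", "tss", "strand") %in% names(genes))) {
    abort("`genes` needs columns gene, chrom, tss, strand.")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("Gene strand must be '+' or '-'.")
  }
  promoters <- tibble(chrom = genes$chrom,
                      start = pmax(0, genes$tss - flank),
                      end = genes$tss + flank)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(promoters), as_granges(peaks)))
  gi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  out <- tibble(
    gene = genes$gene[gi],
    chrom = genes$chrom[gi],
    peak_start = peaks$start[pi],
    peak_end = peaks$end[pi]
  )
  if ("name" %in% names(peaks)) out$peak_name <- peaks$name[pi]
  out
}

#' Read a gene annotation table
#'
#' CSV with columns `gene,chrom,tss,strand`; `tss` is the 0-based
#' transcription start coordinate (strand-aware).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_genes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_integer(), strand = readr::col_character()
  ), progress = FALSE)
}
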