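#' Two-condition peak intensity matrix
#'
#' Accessibility intensities of `peaks x cells` within one cell cluster, with
#' every cell labelled by one of exactly two conditions (e.g. wild type vs
#' mutant nuclei). This is the unit of the per-cluster differential
#' accessibility analysis.
#'
#' @param intensity Non-negative numeric matrix, peaks x cells, with peak ids
#'   as row names and cell ids as column names (generated if absent).
#' @param condition Named character vector mapping each cell (column) to its
#'   condition; exactly two distinct conditions, each with >= 2 cells.
#' @param planted Optional integer vector of planted differential peak
#'   indices (used by the simulator).
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(intensity, condition, planted = integer(0)) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric matrix (peaks x cells).")
  }
  if (any(!is.finite(intensity) | intensity < 0)) {
    abort("Intensities must be finite and non-negative.")
  }
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- sprintf("peak_%05d", seq_len(nrow(intensity)))
  }
  if (is.null(colnames(intensity))) {
    colnames(intensity) <- sprintf("cell_%04d", seq_len(ncol(intensity)))
  }
  if (!is.null(names(condition))) {
    if (!setequal(names(condition), colnames(intensity))) {
      abort("`condition` names must match the matrix columns.")
    }
    condition <- condition[colnames(intensity)]
  } else {
    if (length(condition) != ncol(intensity)) {
      abort("`condition` must label every cell.")
    }
    names(condition) <- colnames(intensity)
  }
  conds <- unique(condition)
  if (length(conds) != 2) abort("Exactly two conditions are required.")
  if (any(table(condition) < 2)) {
    abort("Each condition needs at least 2 cells.")
  }
  structure(
    list(intensity = intensity, condition = condition,
         conditions = conds, planted = as.integer(planted)),
    class = "peak_matrix"
  )
}

#' @export
print.peak_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("<peak_matrix> %d peaks x %d cells (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  if (length(x$planted) > 0) {
    cat("  planted differential peaks:", length(x$planted), "\n")
  }
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$intensity)

#' Read and write peak intensity matrices
#'
#' Dense format: a CSV whose first column (`peak`) holds peak ids and whose
#' remaining columns are cells. Triplet format: a CSV with columns
#' `peak,cell,value` (absent combinations default to 0). Labels: a CSV with
#' columns `cell,condition`. `read_peak_matrix()` auto-detects the two matrix
#' layouts.
#'
#' @param matrix_path Path to the dense or triplet CSV.
#' @param labels_path Path to the `cell,condition` CSV.
#' @return A [peak_matrix()].
#' @export
read_peak_matrix <- function(matrix_path, labels_path) {
  df <- readr::read_csv(matrix_path, col_types = readr::cols(), progress = FALSE)
  labels <- readr::read_csv(labels_path, col_types = readr::cols(
    cell = readr::col_character(), condition = readr::col_character()
  ), progress = FALSE)
  if (identical(sort(names(df)), sort(c("peak", "cell", "value")))) {
    wide <- pivot_wider(df, names_from = "cell", values_from = "value",
                        values_fill = 0)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$peak
  } else {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  peak_matrix(m, stats::setNames(labels$condition, labels$cell))
}

#' @rdname read_peak_matrix
#' @param x A `peak_matrix`.
#' @export
write_peak_matrix <- function(x, matrix_path, labels_path) {
  stopifnot(inherits(x, "peak_matrix"))
  df <- bind_cols(tibble(peak = rownames(x$intensity)),
                  as_tibble(x$intensity))
  readr::write_csv(df, matrix_path, progress = FALSE)
  readr::write_csv(
    tibble(cell = names(x$condition), condition = unname(x$condition)),
    labels_path, progress = FALSE
  )
  invisible(c(matrix_path, labels_path))
}
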