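# Piecewise-linear attribute measures: membership of a nutrient value in
# each of K ordered fertility grades. The measure is 1 at a grade's
# anchor point, 0.5 at the shared boundary between two grades, 0 at the
# neighbouring grades' anchors, and saturates to full membership in the
# edge grades beyond the outermost anchors; in between it is linear.
# Construction guarantees: each measure vector is a distribution on the
# K grades supported on at most two adjacent grades.

# Anchor sequence (descending, one per grade) and the full knot list for
# a canonical higher_is_better boundary vector b_1 > ... > b_{K-1}.
measure_knots <- function(boundaries, anchor) {
  b <- boundaries
  K <- length(b) + 1L
  if (anchor == "midpoint") {
    w_top <- if (K >= 3L) b[1] - b[2] else b[1]
    w_bot <- if (K >= 3L) b[K - 2L] - b[K - 1L] else b[1]
    t <- c(b[1] + w_top / 2,
           if (K >= 3L) (b[-(K - 1L)] + b[-1]) / 2,
           b[K - 1L] - w_bot / 2)
    # knots alternate anchor, boundary, anchor, ...; membership at an
    # anchor is the unit vector of its grade, at a boundary the 0.5/0.5
    # split of the two grades it separates
    x <- numeric(2L * K - 1L)
    M <- matrix(0, 2L * K - 1L, K)
    x[seq(1L, 2L * K - 1L, by = 2L)] <- t
    x[seq(2L, 2L * K - 2L, by = 2L)] <- b
    for (k in seq_len(K)) M[2L * k - 1L, k] <- 1
    for (k in seq_len(K - 1L)) M[2L * k, c(k, k + 1L)] <- 0.5
  } else {
    w_bot <- if (K >= 3L) b[K - 2L] - b[K - 1L] else b[1]
    x <- c(b, b[K - 1L] - w_bot)
    M <- diag(K)
  }
  if (any(diff(x) >= 0)) stop("degenerate (non-distinct) grade anchors")
  list(x = x, M = M)
}

# Evaluate memberships for a numeric vector on a knot system: linear
# interpolation of the knot membership rows, saturated at both ends.
interp_measure <- function(x, knots) {
  xs <- rev(knots$x)                       # ascending for findInterval
  Ms <- knots$M[rev(seq_len(nrow(knots$M))), , drop = FALSE]
  n <- length(x)
  K <- ncol(Ms)
  out <- matrix(0, n, K)
  lo <- x <= xs[1]
  hi <- x >= xs[length(xs)]
  out[lo, ] <- rep(Ms[1, ], each = sum(lo))
  out[hi, ] <- rep(Ms[length(xs), ], each = sum(hi))
  mid <- !(lo | hi)
  if (any(mid)) {
    i <- findInterval(x[mid], xs, rightmost.closed = TRUE)
    a <- (x[mid] - xs[i]) / (xs[i + 1L] - xs[i])
    out[mid, ] <- (1 - a) * Ms[i, , drop = FALSE] + a * Ms[i + 1L, , drop = FALSE]
  }
  out
}

#' Single-index attribute measure
#'
#' Degree of membership of a value `x` in each of the K fertility grades
#' implied by a boundary vector, as a piecewise-linear distribution over
#' grades (see Details). Grade 1 is the best grade.
#'
#' @details With `anchor = "midpoint"` (default) each interior grade's
#' anchor is the midpoint of its interval, edge anchors extend half an
#' adjacent interval width beyond the outermost boundaries, membership
#' is exactly 1 at anchors and exactly 0.5/0.5 at each shared grade
#' boundary, and values beyond the edge anchors belong fully to the edge
#' grade. With `anchor = "boundary"` the ramps run between consecutive
#' boundaries (membership 1 at each boundary for the grade above it).
#' Both modes return vectors that sum to 1 with at most two adjacent
#' positive entries.
#'
#' @param x non-negative finite numeric value(s).
#' @param boundaries numeric vector of K-1 grade boundaries, strictly
#'   decreasing for `higher_is_better`, strictly increasing for
#'   `lower_is_better`; all > 0.
#' @param orientation `"higher_is_better"` or `"lower_is_better"`.
#' @param anchor `"midpoint"` or `"boundary"`.
#' @return numeric vector of K grade measures (or an n-by-K matrix when
#'   `x` has length > 1), each row summing to 1.
#' @examples
#' single_index_measure(22, c(30, 20, 10))      # straddles grades 2 and 3
#' single_index_measure(3.5, c(4, 3, 2, 1, 0.6))
#' @export
single_index_measure <- function(x, boundaries,
                                 orientation = c("higher_is_better",
                                                 "lower_is_better"),
                                 anchor = c("midpoint", "boundary")) {
  orientation <- match.arg(orientation)
  anchor <- match.arg(anchor)
  if (any(!is.finite(x)) || any(x < 0))
    stop("x must be finite and >= 0")
  b <- as.numeric(boundaries)
  if (length(b) < 1L || any(!is.finite(b)) || any(b <= 0))
    stop("boundaries must be finite and > 0")
  dir_ok <- if (orientation == "higher_is_better") all(diff(b) < 0) else all(diff(b) > 0)
  if (!dir_ok) stop("boundaries not strictly monotone for this orientation")
  # canonical form works on a descending (larger = better) axis; a
  # lower_is_better index is its exact mirror: same boundaries read in
  # reverse, grade order reversed
  flip <- orientation == "lower_is_better"
  if (flip) b <- rev(b)
  kn <- measure_knots(b, anchor)
  out <- interp_measure(x, kn)
  if (flip) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  if (length(x) == 1L) drop(out) else out
}

#' Attribute-measure tensor for a sample table
#'
#' Applies [single_index_measure()] to every sample and every index of a
#' standard matrix, preserving sample order.
#'
#' @param st sample table: data frame with a `sample_id` column, a
#'   `group` column and one numeric column per index in `sm`.
#' @param sm a `standard_matrix`.
#' @param anchor passed to [single_index_measure()].
#' @param na_action `"error"` (default) to fail on missing index values,
#'   `"drop"` to drop affected samples.
#' @return a `measure_tensor`: numeric array samples x indexes x grades
#'   with dimnames, each (sample, index) slice summing to 1.
#' @export
measure_table <- function(st, sm, anchor = c("midpoint", "boundary"),
                          na_action = c("error", "drop")) {
  anchor <- match.arg(anchor)
  na_action <- match.arg(na_action)
  validate_standard(sm)
  st <- as_sample_table(st, sm)
  idx <- sm$indexes$index
  bad <- !stats::complete.cases(st[idx])
  if (any(bad)) {
    if (na_action == "error")
      stop("missing index values in sample(s): ",
           paste(st$sample_id[bad], collapse = ", "))
    st <- st[!bad, , drop = FALSE]
  }
  n <- nrow(st)
  K <- sm$K
  arr <- array(NA_real_, dim = c(n, length(idx), K),
               dimnames = list(st$sample_id, idx, paste0("G", seq_len(K))))
  for (j in seq_along(idx)) {
    ii <- idx[j]
    ori <- sm$indexes$orientation[sm$indexes$index == ii]
    m <- single_index_measure(st[[ii]], sm$boundaries[[ii]],
                              orientation = ori, anchor = anchor)
    arr[, j, ] <- if (n == 1L) matrix(m, 1L) else m
  }
  structure(arr, class = c("measure_tensor", "array"))
}

#' Export a measure tensor as long-format CSV
#'
#' Columns `sample_id,index,grade,measure`, one row per tensor entry.
#'
#' @param mt a `measure_tensor`.
#' @param path output file path.
#' @export
write_measures <- function(mt, path) {
  d <- dimnames(mt)
  long <- expand.grid(sample_id = d[[1]], index = d[[2]], grade = d[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$measure <- as.vector(mt)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Coerce and validate a sample table against a standard matrix: required
# columns present, index values numeric and >= 0, sample ids filled in.
as_sample_table <- function(st, sm = NULL) {
  st <- as.data.frame(st)
  if (is.null(st$sample_id)) st$sample_id <- paste0("S", seq_len(nrow(st)))
  st$sample_id <- as.character(st$sample_id)
  if (is.null(st$group)) stop("sample table needs a 'group' column")
  if (!is.null(sm)) {
    miss <- setdiff(sm$indexes$index, names(st))
    if (length(miss))
      stop("sample table is missing index column(s): ",
           paste(miss, collapse = ", "))
    for (ii in sm$indexes$index) {
      v <- st[[ii]]
      if (!is.numeric(v)) stop("index column '", ii, "' is not numeric")
      if (any(v < 0 | is.infinite(v), na.rm = TRUE))
        stop("index column '", ii, "' has negative or non-finite values")
    }
  }
  st
}
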