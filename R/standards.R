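#' Construct a grade standard matrix
#'
#' A standard matrix holds, for each nutrient index, the ordered grade
#' boundary values that separate K fertility grades. Grades are numbered
#' 1 (best fertility) to K (worst) throughout the package. For a
#' `higher_is_better` index the K-1 boundaries are strictly decreasing
#' (the first boundary separates grade 1 from grade 2); for
#' `lower_is_better` they are strictly increasing.
#'
#' @param indexes data frame with columns `index` (unique names),
#'   `units` (non-empty strings) and `orientation`
#'   (`"higher_is_better"` or `"lower_is_better"`).
#' @param boundaries named list (one entry per index, same order) of
#'   numeric vectors of length K-1, strictly monotone in the direction
#'   implied by the orientation, all values > 0.
#' @return An object of class `standard_matrix` with elements
#'   `indexes`, `boundaries` and `K`.
#' @examples
#' sm <- standard_matrix(
#'   data.frame(index = "SOM", units = "%",
#'              orientation = "higher_is_better"),
#'   list(SOM = c(4, 3, 2, 1, 0.6)))
#' sm$K
#' @export
standard_matrix <- function(indexes, boundaries) {
  sm <- structure(list(indexes = as.data.frame(indexes),
                       boundaries = boundaries,
                       K = length(boundaries[[1]]) + 1L),
                  class = "standard_matrix")
  validate_standard(sm)
  sm
}

#' Validate a standard matrix
#'
#' Checks index-name uniqueness, non-empty units, orientation values,
#' boundary lengths, strict monotonicity and positivity. Called by all
#' constructors and loaders; exported so user-edited standards can be
#' checked directly.
#'
#' @param sm a `standard_matrix`.
#' @return `sm`, invisibly, if valid; otherwise an error.
#' @export
validate_standard <- function(sm) {
  idx <- sm$indexes
  req <- c("index", "units", "orientation")
  if (!all(req %in% names(idx)))
    stop("standard matrix schema error: missing column(s) ",
         paste(setdiff(req, names(idx)), collapse = ", "))
  if (anyDuplicated(idx$index))
    stop("duplicate index names in standard matrix")
  if (any(!nzchar(idx$units)))
    stop("every index needs non-empty units")
  if (!all(idx$orientation %in% c("higher_is_better", "lower_is_better")))
    stop("orientation must be 'higher_is_better' or 'lower_is_better'")
  if (!setequal(names(sm$boundaries), idx$index))
    stop("boundaries must be named by the index names")
  len <- lengths(sm$boundaries)
  if (length(unique(len)) != 1L || len[1] < 1L)
    stop("all indexes must share the same number of grade boundaries (K-1 >= 1)")
  if (sm$K != len[1] + 1L) stop("K inconsistent with boundary length")
  for (i in seq_len(nrow(idx))) {
    b <- sm$boundaries[[idx$index[i]]]
    if (any(!is.finite(b)) || any(b <= 0))
      stop("boundaries for index '", idx$index[i], "' must be finite and > 0")
    d <- diff(b)
    ok <- if (idx$orientation[i] == "higher_is_better") all(d < 0) else all(d > 0)
    if (!ok)
      stop("boundaries for index '", idx$index[i],
           "' are not strictly monotone in the direction of its orientation")
  }
  invisible(sm)
}

#' Read a grade standard matrix from CSV or JSON
#'
#' CSV dialect: UTF-8, comma separated, header
#' `index,units,orientation,b1,...,b{K-1}`, one row per index.
#' JSON: an array of objects with the same fields (`boundaries` as an
#' array). Comment lines starting with `#` are ignored in CSV.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return a validated `standard_matrix`.
#' @export
load_standard <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("standard file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
    req <- c("index", "units", "orientation")
    if (!all(req %in% names(df)))
      stop("standard matrix schema error: missing column(s) ",
           paste(setdiff(req, names(df)), collapse = ", "))
    bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
    bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
    if (length(bcols) < 1L) stop("standard matrix schema error: no boundary columns b1..")
    bnd <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, bcols]))
    names(bnd) <- df$index
    standard_matrix(df[req], bnd)
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.data.frame(recs)) {
      bnd <- recs$boundaries
      names(bnd) <- recs$index
      standard_matrix(recs[c("index", "units", "orientation")],
                      lapply(bnd, as.numeric))
    } else stop("standard matrix schema error: expected an array of index records")
  }
}

#' Write a grade standard matrix to CSV or JSON
#'
#' Output is bit-stable for a fixed input and readable by
#' [load_standard()] (round-trip identity up to key order).
#'
#' @param sm a validated `standard_matrix`.
#' @inheritParams load_standard
#' @export
write_standard <- function(sm, path, format = c("auto", "csv", "json")) {
  validate_standard(sm)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    bmat <- do.call(rbind, sm$boundaries[sm$indexes$index])
    colnames(bmat) <- paste0("b", seq_len(sm$K - 1L))
    df <- cbind(sm$indexes, as.data.frame(bmat))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(sm$indexes)), function(i)
      list(index = sm$indexes$index[i],
           units = sm$indexes$units[i],
           orientation = sm$indexes$orientation[i],
           boundaries = sm$boundaries[[sm$indexes$index[i]]]))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Default six-grade nutrient standard
#'
#' Loads the editable fixture shipped with the package
#' (`inst/extdata/grade_standard_6.csv`): six fertility grades for SOM,
#' total and hydrolysable nitrogen, total and available phosphorus and
#' available potassium, following commonly tabulated national
#' soil-nutrient survey levels. The file is a configurable fixture, not
#' normative data; swap it for local standards without code changes.
#'
#' @return a `standard_matrix` with K = 6.
#' @export
default_standard <- function() {
  load_standard(system.file("extdata", "grade_standard_6.csv",
                            package = "soilgrade", mustWork = TRUE))
}

#' @export
print.standard_matrix <- function(x, ...) {
  cat("Grade standard matrix:", nrow(x$indexes), "indexes,",
      x$K, "grades (1 = best)\n")
  bmat <- do.call(rbind, x$boundaries[x$indexes$index])
  colnames(bmat) <- paste0("b", seq_len(x$K - 1L))
  print(cbind(x$indexes, as.data.frame(bmat)), row.names = FALSE)
  invisible(x)
}
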