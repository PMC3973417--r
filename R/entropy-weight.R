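# Shannon entropy weighting of nutrient indexes: indexes whose values
# are more dispersed across the samples of a group carry more
# information and receive more weight.
#
#   H_j = -(1/ln n) * sum_i p_ij ln p_ij   (0 * ln 0 == 0)
#   d_j = 1 - H_j
#   w_j = d_j / sum_j d_j

#' Normalize a sample-by-index matrix to column shares
#'
#' @param x non-negative numeric matrix (n samples x m indexes), n >= 2.
#' @param method `"proportional"`: p_ij = x_ij / column sum (requires
#'   every column sum > 0). `"minmax"`: min-max rescale each column then
#'   divide by the rescaled column sum; a constant column cannot be
#'   rescaled and is flagged instead (its shares are set uniform and it
#'   receives zero divergence downstream).
#' @return list with `p` (matrix of shares; non-constant columns sum to
#'   1) and `constant` (logical per column).
#' @export
normalize_columns <- function(x, method = c("proportional", "minmax")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples to normalize")
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be finite and >= 0")
  rng <- apply(x, 2L, function(v) max(v) - min(v))
  constant <- rng == 0
  if (method == "proportional") {
    cs <- colSums(x)
    if (any(cs == 0)) stop("zero column sum in proportional normalization")
    p <- sweep(x, 2L, cs, "/")
  } else {
    p <- x
    for (j in seq_len(ncol(x))) {
      if (constant[j]) { p[, j] <- 1 / nrow(x); next }
      r <- (x[, j] - min(x[, j])) / rng[j]
      p[, j] <- r / sum(r)
    }
  }
  list(p = p, constant = constant)
}

#' Entropy weights from a share matrix
#'
#' @param p matrix of shares (columns of non-constant indexes sum to 1),
#'   n >= 2 rows.
#' @param constant_flags optional logical per column: flagged columns
#'   get divergence 0 hence weight 0.
#' @return a `weight_vector`: named numeric weights summing to 1 with
#'   attributes `entropy` (H_j) and `divergence` (d_j). If every index
#'   has zero divergence (fully uniform data) the equal-weight fallback
#'   1/m is returned with a warning.
#' @examples
#' p <- matrix(c(1, 0, 0.5, 0.5), 2, 2)   # concentrated vs uniform
#' entropy_weights(p)
#' @export
entropy_weights <- function(p, constant_flags = NULL) {
  p <- as.matrix(p)
  n <- nrow(p)
  m <- ncol(p)
  if (n < 2L) stop("cannot compute entropy with fewer than 2 samples")
  if (is.null(constant_flags)) constant_flags <- rep(FALSE, m)
  plogp <- ifelse(p > 0, p * log(p), 0)
  H <- -colSums(plogp) / log(n)
  d <- pmax(1 - H, 0)
  d[constant_flags] <- 0
  if (sum(d) < 1e-12) {
    warning("all indexes have zero divergence; falling back to equal weights")
    w <- rep(1 / m, m)
  } else {
    w <- d / sum(d)
  }
  names(w) <- colnames(p)
  structure(w, entropy = H, divergence = d, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  grp <- attr(x, "group")
  cat("Entropy weights", if (!is.null(grp)) paste0("(", grp, ")"),
      "in percent:\n")
  print(round(100 * unclass(x), 2))
  invisible(x)
}

#' Per-group entropy weights for a sample table
#'
#' Computes one weight vector per group (land use or restoration age)
#' over that group's replicates.
#'
#' @param st sample table with `group` and index columns.
#' @param sm `standard_matrix`; required for `mode = "measure"`, used
#'   only to pick the index columns in `mode = "raw"` (defaults to the
#'   shipped six-index standard when omitted).
#' @param mode `"raw"`: entropy on the normalized raw values.
#'   `"measure"`: entropy on per-sample single-index grade scores
#'   q_ij = sum_k c_k mu_ijk (grade values `c_k` as in [score()]), for
#'   weighting inside the attribute-measure scale.
#' @param normalization passed to [normalize_columns()].
#' @param anchor measure anchoring for `mode = "measure"`.
#' @param grade_values grade values for `mode = "measure"`; default
#'   K+1-k.
#' @return named list of `weight_vector`, one per group (group label in
#'   attribute `group`).
#' @export
group_weights <- function(st, sm = NULL,
                          mode = c("raw", "measure"),
                          normalization = c("proportional", "minmax"),
                          anchor = "midpoint", grade_values = NULL) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  if (is.null(sm)) sm <- default_standard()
  st <- as_sample_table(st, sm)
  idx <- sm$indexes$index
  out <- list()
  for (g in unique(st$group)) {
    sub <- st[st$group == g, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("group '", g, "' has fewer than 2 samples; ",
           "entropy weights need replicates")
    x <- as.matrix(sub[idx])
    if (mode == "measure") {
      mt <- measure_table(sub, sm, anchor = anchor)
      cv <- grade_values %||% (sm$K + 1 - seq_len(sm$K))
      # per-sample per-index grade score, then treated like raw data
      x <- apply(mt, c(1L, 2L), function(mu) sum(cv * mu))
    }
    nc <- normalize_columns(x, method = normalization)
    w <- entropy_weights(nc$p, nc$constant)
    attr(w, "group") <- g
    attr(w, "mode") <- mode
    attr(w, "normalization") <- normalization
    out[[as.character(g)]] <- w
  }
  out
}

#' Tabulate group weights in percent
#'
#' One row per group, one column per index, weights as percents rounded
#' to 2 decimals (full precision is kept in the `weight_vector`s).
#'
#' @param gw result of [group_weights()].
#' @return data frame `group, <index columns>`.
#' @export
weights_table <- function(gw) {
  rows <- lapply(names(gw), function(g)
    data.frame(group = g, as.list(round(100 * unclass(gw[[g]]), 2)),
               check.names = FALSE))
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
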