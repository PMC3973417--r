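# Comprehensive attribute recognition: weight the single-index measure
# distributions into one distribution over grades per sample, classify
# it with the confidence criterion, and rank samples by expected grade
# value.

#' Synthesize single-index measures into comprehensive measures
#'
#' mu_ik = sum_j w_j mu_ijk: a convex combination of the per-index grade
#' distributions, so each sample's comprehensive measure is itself a
#' distribution over the K grades.
#'
#' @param mt a `measure_tensor` (samples x indexes x grades).
#' @param w a `weight_vector` (or named numeric summing to 1) over the
#'   tensor's indexes.
#' @return numeric matrix samples x grades, rows summing to 1.
#' @export
synthesize <- function(mt, w) {
  idx <- dimnames(mt)[[2]]
  w <- unclass(w)
  if (is.null(names(w))) {
    if (length(w) != length(idx)) stop("weight/index mismatch")
    names(w) <- idx
  }
  if (!setequal(names(w), idx))
    stop("weight names do not match tensor indexes")
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  w <- w[idx]
  n <- dim(mt)[1]; K <- dim(mt)[3]
  mu <- matrix(0, n, K, dimnames = list(dimnames(mt)[[1]], dimnames(mt)[[3]]))
  for (j in seq_along(idx))
    mu <- mu + w[j] * array(mt[, j, , drop = FALSE], dim = c(n, K))
  mu
}

#' Confidence-criterion grade classification
#'
#' Assigns the first grade (in best-to-worst order) at which the
#' cumulative comprehensive measure reaches the confidence level lambda:
#' k* = min\{k : sum_\{l<=k\} mu_il >= lambda\}. Equality counts
#' (cumulative exactly lambda assigns that grade).
#'
#' @param mu a measure vector of length K, or an n x K matrix (rows are
#'   samples); each row sums to 1.
#' @param lambda confidence level in (0.5, 1]. The criterion is
#'   ill-posed at or below 0.5.
#' @return integer grade(s) in 1..K.
#' @export
classify <- function(mu, lambda = 0.7) {
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      lambda <= 0.5 || lambda > 1)
    stop("lambda must lie in (0.5, 1]")
  mu <- if (is.matrix(mu)) mu else matrix(mu, 1L)
  K <- ncol(mu)
  apply(mu, 1L, function(m) {
    k <- which(cumsum(m) >= lambda)[1]
    if (is.na(k)) K else k            # guard: fp shortfall at lambda = 1
  })
}

#' Grade score of a comprehensive measure
#'
#' q_i = sum_k c_k mu_ik with default grade values c_k = K + 1 - k, so a
#' fully grade-1 sample scores K and larger scores mean better
#' fertility. Strictly monotone under first-order stochastic dominance.
#'
#' @param mu measure vector or n x K matrix.
#' @param grade_values numeric length-K vector c_k; default K+1-k.
#' @return numeric score(s) in [min c, max c].
#' @export
score <- function(mu, grade_values = NULL) {
  mu <- if (is.matrix(mu)) mu else matrix(mu, 1L)
  K <- ncol(mu)
  cvals <- grade_values %||% (K + 1 - seq_len(K))
  if (length(cvals) != K) stop("grade_values must have length K")
  drop(mu %*% cvals)
}

#' Assess soil fertility of a sample table
#'
#' End-to-end attribute recognition: per-group entropy weights, measure
#' synthesis, confidence-criterion classification and score ranking.
#' Deterministic: no randomness is involved.
#'
#' @param st sample table (`sample_id`, `group`, index columns).
#' @param sm `standard_matrix`; defaults to the shipped six-grade
#'   standard.
#' @param lambda confidence level in (0.5, 1]; default 0.7.
#' @param anchor measure anchoring, `"midpoint"` or `"boundary"`.
#' @param weight_mode `"raw"` or `"measure"` (see [group_weights()]).
#' @param normalization `"proportional"` or `"minmax"`.
#' @param grade_values grade values for scoring; default K+1-k.
#' @return list with `results` (data frame: `sample_id`, `group`,
#'   `mu_1..mu_K`, `grade`, `score`) and `weights` (per-group
#'   `weight_vector` list). Row order follows `st`.
#' @examples
#' st <- study_fixture(seed = 1)
#' res <- assess(st, default_standard())
#' head(res$results)
#' @export
assess <- function(st, sm = NULL, lambda = 0.7,
                   anchor = c("midpoint", "boundary"),
                   weight_mode = c("raw", "measure"),
                   normalization = c("proportional", "minmax"),
                   grade_values = NULL) {
  anchor <- match.arg(anchor)
  weight_mode <- match.arg(weight_mode)
  normalization <- match.arg(normalization)
  if (is.null(sm)) sm <- default_standard()
  st <- as_sample_table(st, sm)
  gw <- group_weights(st, sm, mode = weight_mode,
                      normalization = normalization, anchor = anchor,
                      grade_values = grade_values)
  mt <- measure_table(st, sm, anchor = anchor)
  K <- sm$K
  mu_all <- matrix(NA_real_, nrow(st), K)
  for (g in names(gw)) {
    rows <- which(st$group == g)
    mu_all[rows, ] <- synthesize(mt[rows, , , drop = FALSE], gw[[g]])
  }
  res <- data.frame(sample_id = st$sample_id, group = st$group,
                    stringsAsFactors = FALSE)
  mu_df <- as.data.frame(mu_all)
  names(mu_df) <- paste0("mu_", seq_len(K))
  res <- cbind(res, mu_df)
  res$grade <- classify(mu_all, lambda = lambda)
  res$score <- score(mu_all, grade_values = grade_values)
  list(results = res, weights = gw,
       config = list(lambda = lambda, anchor = anchor,
                     weight_mode = weight_mode,
                     normalization = normalization))
}
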