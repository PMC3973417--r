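# Group-level statistics for the study tables: per-group means, SDs and
# CVs, one-way ANOVA across groups, pairwise-LSD compact letter
# displays, and the weight-spread metric used to track convergence of
# index weights along the restoration chronosequence.

#' Per-group summary statistics
#'
#' Sample mean, sample SD (n-1 denominator) and CV = SD/mean for every
#' group and index, in long format.
#'
#' @param st sample table with `group` and index columns.
#' @param indexes character vector of index columns; defaults to all
#'   numeric columns other than `age_years`.
#' @return data frame `group, index, mean, sd, cv, n`.
#' @export
summarize_groups <- function(st, indexes = NULL) {
  st <- as_sample_table(st)
  indexes <- indexes %||% setdiff(
    names(st)[vapply(st, is.numeric, logical(1))], "age_years")
  rows <- list()
  for (g in unique(st$group)) {
    sub <- st[st$group == g, , drop = FALSE]
    if (nrow(sub) < 2L) stop("group '", g, "' has fewer than 2 samples")
    for (ii in indexes) {
      v <- sub[[ii]]
      m <- mean(v); s <- stats::sd(v)
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, index = ii, mean = m, sd = s,
                   cv = s / m, n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' One-way ANOVA for one index across groups
#'
#' Classical fixed-effects one-way F test via [stats::lm()]. When every
#' group has zero within-group variance the F statistic is undefined; in
#' that degenerate case p is reported as 0 if any group means differ and
#' 1 otherwise (F as Inf/0 respectively), with a message.
#'
#' @param st sample table.
#' @param index name of the index column to test.
#' @return data frame `index, F, df_between, df_within, p`.
#' @export
oneway_anova <- function(st, index) {
  st <- as_sample_table(st)
  g <- factor(st$group)
  if (nlevels(g) < 2L) stop("need at least 2 groups for ANOVA")
  if (any(table(g) < 2L)) stop("every group needs at least 2 samples")
  v <- st[[index]]
  if (is.null(v)) stop("no such index column: ", index)
  within_var <- tapply(v, g, stats::var)
  if (all(within_var == 0)) {
    means_differ <- length(unique(tapply(v, g, mean))) > 1L
    message("degenerate ANOVA for '", index,
            "': zero within-group variance everywhere")
    return(data.frame(index = index,
                      F = if (means_differ) Inf else 0,
                      df_between = nlevels(g) - 1L,
                      df_within = length(v) - nlevels(g),
                      p = if (means_differ) 0 else 1))
  }
  a <- stats::anova(stats::lm(v ~ g))
  data.frame(index = index, F = a$`F value`[1],
             df_between = a$Df[1], df_within = a$Df[2],
             p = a$`Pr(>F)`[1])
}

#' One-way ANOVA for all index columns
#'
#' @inheritParams summarize_groups
#' @return data frame with one [oneway_anova()] row per index.
#' @export
anova_table <- function(st, indexes = NULL) {
  st <- as_sample_table(st)
  indexes <- indexes %||% setdiff(
    names(st)[vapply(st, is.numeric, logical(1))], "age_years")
  do.call(rbind, lapply(indexes, function(ii) oneway_anova(st, ii)))
}

# Pairwise LSD significance matrix: pooled-MSE t tests between all
# group pairs. Returns logical matrix (TRUE = significantly different).
lsd_significance <- function(means, n, mse, df, alpha) {
  g <- length(means)
  sig <- matrix(FALSE, g, g, dimnames = list(names(means), names(means)))
  for (i in seq_len(g - 1L)) for (j in seq(i + 1L, g)) {
    delta <- abs(means[i] - means[j])
    if (mse == 0) {
      s <- delta > 0
    } else {
      tval <- delta / sqrt(mse * (1 / n[i] + 1 / n[j]))
      s <- 2 * stats::pt(-tval, df) < alpha
    }
    sig[i, j] <- sig[j, i] <- s
  }
  sig
}

#' Compact letter display from pairwise LSD tests
#'
#' Pairwise least-significant-difference t tests on the pooled ANOVA
#' mean square, summarized as letters: groups sharing a letter are not
#' significantly different at `alpha`. Letters are assigned greedily in
#' descending-mean order (maximal runs of mutually non-significant
#' groups), which is deterministic.
#'
#' @param st sample table.
#' @param index index column name.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return named character vector of letters, one per group.
#' @export
letter_display <- function(st, index, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  st <- as_sample_table(st)
  g <- factor(st$group)
  v <- st[[index]]
  means <- tapply(v, g, mean)
  n <- tapply(v, g, length)
  an <- oneway_anova(st, index)
  ss_within <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  mse <- ss_within / an$df_within
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; n <- n[ord]
  sig <- lsd_significance(means, n, mse, an$df_within, alpha)
  gn <- length(means)
  # maximal intervals of consecutive (sorted) groups with no significant
  # internal pair
  intervals <- list()
  for (i in seq_len(gn)) {
    j <- i
    while (j < gn && !any(sig[i:(j + 1L), i:(j + 1L)])) j <- j + 1L
    intervals[[i]] <- c(i, j)
  }
  keep <- vapply(seq_along(intervals), function(k) {
    !any(vapply(seq_along(intervals), function(l)
      l != k && intervals[[l]][1] <= intervals[[k]][1] &&
        intervals[[l]][2] >= intervals[[k]][2], logical(1)))
  }, logical(1))
  intervals <- unique(intervals[keep])
  letters_out <- stats::setNames(rep("", gn), names(means))
  for (k in seq_along(intervals)) {
    span <- intervals[[k]]
    lab <- letters[(k - 1L) %% 26L + 1L]
    rng <- seq(span[1], span[2])
    letters_out[rng] <- paste0(letters_out[rng], lab)
  }
  letters_out[levels(g)]
}

#' Spread of an index-weight vector
#'
#' Relative range of the weights within a group, in percent: how far the
#' most influential index is from the least influential one. Used to
#' quantify convergence of index weights along a restoration
#' chronosequence (the spread shrinks as the indexes become equally
#' informative).
#'
#' @param w a `weight_vector` or non-negative numeric vector.
#' @param method `"range_over_min"` (default): (max - min) / min * 100;
#'   `"range_over_mean"`: (max - min) / mean * 100.
#' @return data frame `group, spread_pct, method`.
#' @export
weight_spread <- function(w, method = c("range_over_min", "range_over_mean")) {
  method <- match.arg(method)
  grp <- attr(w, "group") %||% NA_character_
  w <- as.numeric(unclass(w))
  if (any(w < 0)) stop("weights must be non-negative")
  if (method == "range_over_min") {
    if (min(w) == 0)
      stop("zero minimum weight: use method = 'range_over_mean'")
    spread <- (max(w) - min(w)) / min(w) * 100
  } else {
    spread <- (max(w) - min(w)) / mean(w) * 100
  }
  data.frame(group = grp, spread_pct = spread, method = method,
             stringsAsFactors = FALSE)
}
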