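test_that("group summaries report sample mean, SD (n-1) and CV", {
  st <- data.frame(sample_id = paste0("s", 1:6), group = rep(c("a", "b"), each = 3),
                   X = c(2, 2, 2, 1, 2, 3))
  s <- summarize_groups(st, "X")
  expect_equal(s$mean, c(2, 2))
  expect_equal(s$sd, c(0, 1))
  expect_equal(s$cv, c(0, 0.5))
  expect_equal(s$n, c(3L, 3L))
  # CV * mean recovers SD
  expect_true(all(abs(s$cv * s$mean - s$sd) < 1e-9))
  # hand-computed three-value case: 4, 7, 10 -> mean 7, sd 3
  h <- summarize_groups(data.frame(group = "g", X = c(4, 7, 10)), "X")
  expect_equal(h$mean, 7)
  expect_equal(h$sd, 3)
  expect_equal(h$cv, 3 / 7)
})

test_that("summaries are permutation-invariant within groups", {
  set.seed(79)
  st <- rand_toy_table(n_groups = 3, n = 6)
  s1 <- summarize_groups(st, c("A", "B"))
  s2 <- summarize_groups(st[sample(nrow(st)), ], c("A", "B"))
  key <- function(s) s[order(s$group, s$index), c("mean", "sd", "cv", "n")]
  expect_equal(key(s2), key(s1), ignore_attr = TRUE)
})

test_that("generator moments are recovered at large n", {
  # farmland SOM parameters: mean 6.87, CV 0.30
  sp <- group_spec("big", means = c(SOM = 6.87), cvs = c(SOM = 0.30),
                   n = 1e4)
  st <- generate_groups(list(sp), seed = 101)
  s <- summarize_groups(st, "SOM")
  expect_lt(abs(s$mean - 6.87) / 6.87, 0.02)
  expect_lt(abs(s$cv - 0.30) / 0.30, 0.05)
})

test_that("one-way ANOVA handles identical groups and matches t^2", {
  st <- data.frame(group = rep(c("a", "b"), each = 4), X = rep(c(1, 2, 3, 4), 2))
  a <- oneway_anova(st, "X")
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 6L)
  set.seed(83)
  st2 <- data.frame(group = rep(c("a", "b"), each = 5), X = stats::rnorm(10))
  a2 <- oneway_anova(st2, "X")
  tt <- stats::t.test(X ~ group, data = st2, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA agrees with the summary-statistics oracle", {
  set.seed(89)
  for (rep in 1:500) {
    g <- sample(2:5, 1)
    ns <- sample(2:8, g, replace = TRUE)
    st <- data.frame(group = rep(paste0("g", seq_len(g)), ns),
                     X = stats::rnorm(sum(ns), mean = stats::runif(1, 0, 5)))
    a <- oneway_anova(st, "X")
    o <- anova_oracle(st$X, st$group)
    expect_equal(a$F, o$F, tolerance = 1e-10)
    expect_equal(a$p, o$p, tolerance = 1e-10)
    expect_gte(a$p, 0); expect_lte(a$p, 1)
  }
})

test_that("F is invariant to location shift and positive rescaling", {
  set.seed(97)
  st <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                   X = stats::rnorm(15, 10))
  f0 <- oneway_anova(st, "X")$F
  st$X <- 3.7 * st$X + 42
  expect_equal(oneway_anova(st, "X")$F, f0, tolerance = 1e-10)
})

test_that("fully degenerate ANOVA follows the documented rule", {
  st_eq <- data.frame(group = rep(c("a", "b"), each = 3), X = rep(5, 6))
  expect_message(a <- oneway_anova(st_eq, "X"), "degenerate")
  expect_equal(a$p, 1)
  st_df <- data.frame(group = rep(c("a", "b"), each = 3), X = rep(c(1, 2), each = 3))
  expect_message(b <- oneway_anova(st_df, "X"), "degenerate")
  expect_equal(b$p, 0)
})

test_that("compact letters reflect the pairwise LSD structure", {
  st_eq <- data.frame(group = rep(c("a", "b", "c"), each = 3), X = rep(5, 9))
  suppressMessages(
    expect_equal(unname(letter_display(st_eq, "X")), rep("a", 3)))
  set.seed(103)
  st_far <- data.frame(group = rep(c("lo", "hi"), each = 5),
                       X = c(stats::rnorm(5, 0, 0.1), stats::rnorm(5, 100, 0.1)))
  l <- letter_display(st_far, "X")
  expect_equal(sort(unname(l)), c("a", "b"))
  expect_false(l[["lo"]] == l[["hi"]])
})

test_that("groups sharing a letter are never significantly different", {
  set.seed(107)
  for (rep in 1:30) {
    g <- sample(3:6, 1)
    st <- data.frame(group = rep(paste0("g", seq_len(g)), each = 5),
                     X = stats::rnorm(5 * g, mean = sample(0:3, g, TRUE)))
    l <- letter_display(st, "X", alpha = 0.05)
    gr <- factor(st$group)
    means <- tapply(st$X, gr, mean)
    n <- tapply(st$X, gr, length)
    df2 <- length(st$X) - nlevels(gr)
    mse <- sum(tapply(st$X, gr, function(x) sum((x - mean(x))^2))) / df2
    for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) {
      gi <- levels(gr)[i]; gj <- levels(gr)[j]
      tval <- abs(means[gi] - means[gj]) /
        sqrt(mse * (1 / n[gi] + 1 / n[gj]))
      sig <- 2 * stats::pt(-tval, df2) < 0.05
      shared <- length(intersect(strsplit(l[[gi]], "")[[1]],
                                 strsplit(l[[gj]], "")[[1]])) > 0
      if (sig) expect_false(shared)
      # and every non-significant pair shares at least one letter
      if (!sig) expect_true(shared)
    }
  }
})

test_that("weight spread measures relative range of weights", {
  w <- rep(1 / 6, 6)
  expect_equal(weight_spread(w)$spread_pct, 0)
  expect_equal(weight_spread(w, "range_over_mean")$spread_pct, 0)
  w2 <- c(2, 1, 1) / 4                       # max 20 min 10 pattern
  expect_equal(weight_spread(w2)$spread_pct, 100)
  expect_equal(weight_spread(w2, "range_over_mean")$spread_pct, 75)
  expect_error(weight_spread(c(0.5, 0.5, 0)), "range_over_mean")
  expect_gt(weight_spread(c(0.5, 0.5, 0), "range_over_mean")$spread_pct, 0)
})
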