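test_that("zero CV yields exact replicates of the mean", {
  sp <- group_spec("g", means = c(A = 3, B = 50), cvs = c(A = 0, B = 0), n = 4)
  st <- generate_groups(list(sp), seed = 1)
  expect_equal(st$A, rep(3, 4))
  expect_equal(st$B, rep(50, 4))
})

test_that("generation is deterministic and substreams are per-group", {
  sp1 <- group_spec("g1", means = c(A = 3), cvs = c(A = 0.4))
  sp2 <- group_spec("g2", means = c(A = 5), cvs = c(A = 0.2))
  a <- generate_groups(list(sp1, sp2), seed = 9)
  b <- generate_groups(list(sp1, sp2), seed = 9)
  expect_identical(a, b)
  expect_false(identical(generate_groups(list(sp1, sp2), seed = 10), a))
  # adding or reordering groups leaves the others' draws untouched
  solo <- generate_groups(list(sp1), seed = 9)
  expect_equal(solo$A, a$A[a$group == "g1"])
  swapped <- generate_groups(list(sp2, sp1), seed = 9)
  expect_equal(swapped$A[swapped$group == "g1"], a$A[a$group == "g1"])
})

test_that("seeds are mandatory", {
  sp <- group_spec("g", means = c(A = 3), cvs = c(A = 0.4))
  expect_error(generate_groups(list(sp)), "seed")
  expect_error(study_fixture(), "seed")
  expect_error(generate_chronosequence(chronosequence_spec(sp)), "seed")
})

test_that("lognormal draws recover the specified moments at n = 10^4", {
  sp <- group_spec("farm", means = c(SOM = 6.87), cvs = c(SOM = 0.30),
                   n = 1e4)
  st <- generate_groups(list(sp), seed = 11)
  m <- mean(st$SOM); cv <- stats::sd(st$SOM) / m
  expect_lt(abs(m - 6.87) / 6.87, 0.02)
  expect_lt(abs(cv - 0.30) / 0.30, 0.05)
  expect_true(all(st$SOM > 0))
})

test_that("truncated-normal draws are positive with comparable moments", {
  sp <- group_spec("t", means = c(A = 10), cvs = c(A = 0.3), n = 1e4,
                   distribution = "truncnormal")
  st <- generate_groups(list(sp), seed = 13)
  expect_true(all(st$A > 0))
  # truncation at 0 is mild at CV 0.3: moments close to spec
  expect_lt(abs(mean(st$A) - 10) / 10, 0.02)
  expect_lt(abs(stats::sd(st$A) / mean(st$A) - 0.3) / 0.3, 0.05)
})

test_that("within-sample correlation knob induces correlated indexes", {
  sp <- group_spec("c", means = c(A = 5, B = 50), cvs = c(A = 0.3, B = 0.3),
                   n = 2000, rho = 0.8)
  st <- generate_groups(list(sp), seed = 17)
  expect_gt(stats::cor(log(st$A), log(st$B)), 0.7)
  sp0 <- group_spec("c", means = c(A = 5, B = 50), cvs = c(A = 0.3, B = 0.3),
                    n = 2000)
  st0 <- generate_groups(list(sp0), seed = 17)
  expect_lt(abs(stats::cor(log(st0$A), log(st0$B))), 0.1)
})

test_that("invalid group specs are rejected", {
  expect_error(group_spec("g", means = c(A = 0), cvs = c(A = 0.1)), "> 0")
  expect_error(group_spec("g", means = c(A = 1), cvs = c(A = -1)), ">= 0")
  expect_error(group_spec("g", means = c(A = 1), cvs = c(A = 0.1), n = 1),
               "n must be")
  expect_error(group_spec("g", means = c(A = 1), cvs = c(B = 0.1)),
               "same indexes")
})

test_that("a flat chronosequence shares one mean across ages", {
  base <- group_spec("base", means = c(A = 4, B = 40),
                     cvs = c(A = 0, B = 0), n = 5)
  cs <- chronosequence_spec(base)
  st <- generate_chronosequence(cs, seed = 19)
  expect_equal(nrow(st), 30L)                   # 6 ages x 5 replicates
  expect_equal(sort(unique(st$age_years)), c(0, 5, 10, 15, 20, 25))
  expect_true(all(st$A == 4) && all(st$B == 40))
})

test_that("the published trajectory ordering appears in large-n means", {
  lp <- landuse_params(); rp <- restoration_params()
  farm <- lp[lp$group == "Farmland", ]
  base <- group_spec("0years", means = stats::setNames(farm$mean, farm$index),
                     cvs = stats::setNames(farm$cv, farm$index), n = 1e4)
  ages <- c(0, 5, 10, 15, 20, 25)
  mult <- matrix(1, length(ages), 6,
                 dimnames = list(NULL, farm$index))
  for (a in ages[-1]) {
    sub <- rp[rp$age_years == a, ]
    mult[ages == a, sub$index] <- sub$mean / farm$mean
  }
  st <- generate_chronosequence(
    chronosequence_spec(base, ages = ages, multipliers = mult), seed = 23)
  som <- tapply(st$SOM, st$age_years, mean)
  get <- function(a) som[[as.character(a)]]
  # the dip-and-recover shape of the restoration series
  expect_true(get(15) < get(5))
  expect_true(get(5) < get(0))
  expect_true(get(0) < get(25))
  expect_true(get(25) < get(20))
  expect_true(get(10) < get(15))               # published minimum at 10 years
})

test_that("the 52-sample study fixture matches the documented composition", {
  st <- study_fixture(seed = 29)
  expect_equal(nrow(st), 52L)
  idx <- c("SOM", "N_total", "P_total", "N_hydro", "P_avail", "K_avail")
  expect_true(all(idx %in% names(st)))
  expect_true(all(as.matrix(st[idx]) > 0))
  counts <- table(st$group)
  expect_equal(unname(counts[["Farmland"]]), 7L)  # doubles as 0-year control
  expect_true(all(counts[names(counts) != "Farmland"] == 5L))
  expect_equal(unique(st$age_years[st$group == "Farmland"]), 0)
  expect_identical(study_fixture(seed = 29), st)
  # the full pipeline runs on it
  out <- assess(st, default_standard())
  expect_equal(nrow(out$results), 52L)
})
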