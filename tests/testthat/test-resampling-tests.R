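test_that("rank permutation test handles symmetric and separated inputs", {
  # identical multisets: no evidence, maximal p
  res <- mwu_permutation_test(c(1, 2, 3), c(1, 2, 3), seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # all values tied across both groups
  tied <- mwu_permutation_test(rep(2, 4), rep(2, 5), seed = 1)
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_true(tied$degenerate)
  expect_error(mwu_permutation_test(numeric(0), 1:3), "non-empty")
})

test_that("rank permutation p matches exhaustive enumeration", {
  # x = {1,2}, y = {3,4}: of the 6 assignments, 2 are as extreme
  p_exact <- exact_mwu_p(c(1, 2), c(3, 4))
  expect_equal(p_exact, 1 / 3)
  res <- mwu_permutation_test(c(1, 2), c(3, 4), n_resamples = 20000,
                              seed = 11)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 20001)

  # random small instances, including ties
  set.seed(301)
  for (i in 1:6) {
    nx <- sample(3:5, 1); ny <- sample(3:5, 1)
    x <- sample(1:4, nx, replace = TRUE)
    y <- sample(1:5, ny, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    p_exact <- exact_mwu_p(x, y)
    res <- mwu_permutation_test(x, y, n_resamples = 4000, seed = i)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 4001)
  }
})

test_that("rank permutation p agrees with the normal approximation", {
  set.seed(88)
  x <- rnorm(60); y <- rnorm(70, 0.4)
  res <- mwu_permutation_test(x, y, n_resamples = 20000, seed = 5)
  p_norm <- 2 * pnorm(-abs(res$statistic))
  expect_lt(abs(res$p_value - p_norm),
            3 * sqrt(p_norm * (1 - p_norm) / 20000) + 0.005)
  # sign convention: first group with larger values gives positive Z
  up <- mwu_permutation_test(y + 10, x, n_resamples = 999, seed = 1)
  expect_gt(up$statistic, 0)
})

test_that("Pearson chi-squared matches the closed form and base R", {
  expect_equal(as.numeric(pearson_chisq(matrix(c(10, 10, 10, 10), 2))),
               0)
  # 2x2 closed form n(ad-bc)^2/(r1 r2 c1 c2) on [[20,5],[5,20]] = 18
  expect_equal(as.numeric(pearson_chisq(matrix(c(20, 5, 5, 20), 2,
                                               byrow = TRUE))), 18)
  m <- matrix(c(12, 3, 7, 18), 2)
  expect_equal(as.numeric(pearson_chisq(m)),
               unname(chisq.test(m, correct = FALSE)$statistic))
  deg <- pearson_chisq(matrix(c(0, 3, 0, 7), 2, byrow = TRUE))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  expect_error(pearson_chisq(matrix(0, 2, 2)), "positive")
})

test_that("chi-squared permutation p matches exhaustive enumeration", {
  # label-independent outcomes: p near 1
  labs <- rep(c("con", "het"), each = 6)
  outs <- rep(c("signal", "chase"), 6)
  res <- chisq_permutation_test(labs, outs, n_resamples = 2000, seed = 3)
  expect_gt(res$p_value, 0.5)

  # perfectly separated 5+5: smallest attainable p for these margins
  labs2 <- rep(c("con", "het"), each = 5)
  outs2 <- c(rep("signal", 5), rep("chase", 5))
  p_exact <- exact_chisq_perm_p(labs2, outs2)
  expect_equal(p_exact, 2 / choose(10, 5), tolerance = 1e-12)
  res2 <- chisq_permutation_test(labs2, outs2, n_resamples = 20000,
                                 seed = 4)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res2$p_value - p_exact), 3 * se + 1 / 20001)

  # random <=10-row instances against the enumeration oracle
  set.seed(77)
  for (i in 1:6) {
    n <- sample(6:10, 1)
    labs3 <- sample(c("a", "b"), n, replace = TRUE)
    outs3 <- sample(c("s", "c"), n, replace = TRUE)
    if (length(unique(labs3)) < 2 || length(unique(outs3)) < 2) next
    p_exact <- exact_chisq_perm_p(labs3, outs3)
    res3 <- chisq_permutation_test(labs3, outs3, n_resamples = 4000,
                                   seed = i)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res3$p_value - p_exact), 3 * se + 1 / 4001)
  }
  expect_error(chisq_permutation_test(rep("a", 4),
                                      c("s", "c", "s", "c")),
               "two label levels")
})

test_that("signalling proportion ignores passive encounters", {
  mk <- function(outcomes, d = ifelse(outcomes == "chase", 1, NA)) {
    validate_encounters(data.frame(
      region = "r", reef = "rf", period = "before",
      focal_id = paste0("i", seq_along(outcomes)), focal_species = "a",
      partner_species = "b", proximity_cat = 1L, outcome = outcomes,
      chase_distance_m = d, stringsAsFactors = FALSE
    ))
  }
  expect_equal(as.numeric(signalling_proportion(
    mk(c(rep("signal", 3), "chase")))), 0.75)
  expect_equal(as.numeric(signalling_proportion(mk(rep("chase", 5)))), 0)
  expect_equal(as.numeric(signalling_proportion(
    mk(c(rep("signal", 2), rep("chase", 2), rep("passive", 7))))), 0.5)
  und <- signalling_proportion(mk(rep("passive", 3)))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("one-per-individual bootstrap matches exhaustive enumeration", {
  mk <- function(ids, vals) {
    validate_encounters(data.frame(
      region = "r", reef = "rf", period = "before", focal_id = ids,
      focal_species = "a", partner_species = "b", proximity_cat = 1L,
      outcome = "chase", chase_distance_m = vals,
      stringsAsFactors = FALSE
    ))
  }
  mean_test <- function(records) {
    list(statistic = mean(records$chase_distance_m), p_value = 0.5)
  }
  # every individual has exactly one encounter: zero-width intervals
  one <- mk(c("i1", "i2", "i3"), c(1, 2, 3))
  deg <- bootstrap_one_per_individual(one, mean_test, B = 25, seed = 2)
  expect_equal(deg$mean_statistic, 2)
  expect_equal(diff(deg$ci95_statistic), 0)
  # B = 1: mean equals the single replicate
  b1 <- bootstrap_one_per_individual(one, mean_test, B = 1, seed = 2)
  expect_equal(b1$mean_statistic,
               unname(b1$per_replicate[1, "statistic"]))
  expect_error(bootstrap_one_per_individual(one, mean_test, B = 0), "B")

  # two individuals x two encounters: 4 equally likely datasets, so the
  # replicate mean converges to the average over the enumeration
  two <- mk(c("i1", "i1", "i2", "i2"), c(1, 5, 2, 10))
  enum <- c(mean(c(1, 2)), mean(c(1, 10)), mean(c(5, 2)),
            mean(c(5, 10)))
  boot <- bootstrap_one_per_individual(two, mean_test, B = 4000,
                                       seed = 9)
  se <- sd(enum) / sqrt(4000)
  expect_lt(abs(boot$mean_statistic - mean(enum)), 4 * se)
  expect_setequal(unique(boot$per_replicate[, "statistic"]), enum)
})

test_that("resampling results are reproducible bit for bit", {
  set.seed(1000)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  a <- mwu_permutation_test(x, y, n_resamples = 1500, seed = 99)
  b <- mwu_permutation_test(x, y, n_resamples = 1500, seed = 99)
  expect_identical(a, b)
  labs <- sample(c("con", "het"), 40, replace = TRUE)
  outs <- sample(c("signal", "chase"), 40, replace = TRUE)
  c1 <- chisq_permutation_test(labs, outs, n_resamples = 1500, seed = 7)
  c2 <- chisq_permutation_test(labs, outs, n_resamples = 1500, seed = 7)
  expect_identical(c1, c2)
  # the caller's RNG stream is left untouched
  set.seed(5); before <- runif(1)
  set.seed(5)
  invisible(mwu_permutation_test(x, y, n_resamples = 999, seed = 1))
  expect_identical(runif(1), before)
})
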