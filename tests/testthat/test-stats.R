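test_that("Mann-Whitney U matches exhaustive enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)

  # property: exact p equals the enumeration oracle for random tie-free
  # samples with n + m <= 10
  set.seed(20)
  for (i in 1:40) {
    n <- sample(2:5, 1)
    m <- sample(2:5, 1)
    pool <- sample(seq(0.1, 99.9, by = 0.7), n + m)
    x <- pool[seq_len(n)]
    y <- pool[-seq_len(n)]
    got <- mann_whitney_u(x, y)
    ref <- mwu_enumeration_oracle(x, y)
    expect_equal(got$U, ref$U)
    expect_equal(got$p, ref$p)
  }
})

test_that("Mann-Whitney U is symmetric and handles identical samples", {
  x <- c(3, 1, 7, 5)
  y <- c(2, 9, 4)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(y, x)
  expect_equal(a$U, b$U)
  expect_equal(a$p, b$p)

  z <- c(1, 2, 3)
  r <- mann_whitney_u(z, z)
  expect_equal(r$U, length(z)^2 / 2)
  expect_false(r$exact)  # ties force the corrected normal approximation

  # large tie-free samples switch to the approximation
  big <- mann_whitney_u(1:10, 11:20)
  expect_false(big$exact)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis H agrees with the rank formula and is shift-invariant", {
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))$H, 0)

  g <- list(c(1, 2), c(3, 4))
  expect_equal(kruskal_wallis(g)$H, kw_rank_formula(g))

  set.seed(33)
  for (i in 1:20) {
    gs <- list(runif(4), runif(3), runif(5))
    expect_equal(kruskal_wallis(gs)$H, kw_rank_formula(gs))
    shifted <- lapply(gs, `+`, 17.3)
    expect_equal(kruskal_wallis(shifted)$H, kruskal_wallis(gs)$H)
  }
  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")
})

test_that("two-group Kruskal-Wallis is monotone in the Mann-Whitney U", {
  set.seed(41)
  res <- t(replicate(30, {
    pool <- sample(seq_len(200), 9)
    x <- pool[1:4]
    y <- pool[5:9]
    c(h = kruskal_wallis(list(x, y))$H,
      dev = abs(mann_whitney_u(x, y)$U - 4 * 5 / 2))
  }))
  o <- order(res[, "dev"])
  expect_true(all(diff(res[o, "h"]) >= -1e-9))
})

test_that("Bonferroni correction caps and never decreases p-values", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 3), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  p <- runif(10)
  adj <- bonferroni_adjust(p, m = 3)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bonferroni_adjust(1.4, m = 2), "0, 1")
})

test_that("daily comparisons separate shifted ensembles and spare identical ones", {
  fake_ensemble <- function(values_by_day, n) {
    # synthetic ensemble with a daily grid and one varying substance
    times <- seq(0, 480, by = 24)
    tr <- array(0, dim = c(length(times), 12, n),
                dimnames = list(NULL, species_ids(), NULL))
    for (d in seq_along(times))
      tr[d, "IL1", ] <- values_by_day[[d]]
    structure(list(trajectories = tr, times = times, failures = integer(0),
                   meta = list()), class = "synovial_ensemble")
  }
  n <- 50
  set.seed(8)
  base <- lapply(1:21, function(d) rnorm(n, mean = 100, sd = 1))
  far <- lapply(1:21, function(d) rnorm(n, mean = 110, sd = 1))
  ens <- list(male = fake_ensemble(base, n),
              female_low_e = fake_ensemble(base, n),
              female_peak_e = fake_ensemble(far, n))
  res <- daily_condition_tests(ens, substances = "IL1", days = 1:20)
  expect_equal(nrow(res), 20 * 3)
  expect_true(all(res$day >= 1))  # day 0 never tested
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))
  sig <- res[grepl("female_peak_e", res$pair), ]
  expect_true(all(sig$p_adjusted < 0.001))

  same <- list(male = fake_ensemble(base, n),
               female_low_e = fake_ensemble(base, n),
               female_peak_e = fake_ensemble(base, n))
  res2 <- daily_condition_tests(same, substances = "IL1", days = c(1, 10))
  expect_true(all(!res2$significant))
  expect_true(all(res2$kw_H < 1e-9))

  bad <- ens
  bad$male$times <- bad$male$times + 1
  expect_error(daily_condition_tests(bad, substances = "IL1", days = 1),
               "alignment error")
})
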