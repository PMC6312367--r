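test_that("production and decay coefficients follow the measurement formulas", {
  expect_equal(production_coefficient(100, 1e6, 24), 100 / (1e6 * 24))
  expect_equal(production_coefficient(0, 5e5, 48), 0)
  expect_equal(production_coefficient(50, 5e5, 48), 50 / (5e5 * 48))
  expect_error(production_coefficient(10, 0, 24), "invalid measurement")
  expect_error(production_coefficient(10, 1e6, -1), "invalid measurement")
  expect_error(production_coefficient(-1, 1e6, 24), "invalid measurement")

  expect_equal(decay_coefficient(0.693), 1.0)
  expect_equal(decay_coefficient(6.93), 0.1)
  expect_equal(decay_coefficient(1), 0.693)
  expect_error(decay_coefficient(0), "invalid measurement")

  # homogeneity: scaling the measurement scales the coefficient linearly,
  # scaling the half-life scales the rate inversely
  for (lam in c(0.5, 2, 10)) {
    expect_equal(production_coefficient(lam * 80, 2e5, 12),
                 lam * production_coefficient(80, 2e5, 12))
    expect_equal(decay_coefficient(lam * 3), decay_coefficient(3) / lam)
  }
})

test_that("feedback evaluators match their closed forms and bounds", {
  expect_equal(eval_down_feedback(0.7, 0.1, 0.3, 0), 1.0)
  expect_equal(eval_down_feedback(0.7, 0.1, 0.3, 10), 0.7 * exp(-1) + 0.3)
  expect_equal(eval_down_feedback(0.7, 0.1, 0.3, 1e9), 0.3, tolerance = 1e-9)
  expect_equal(eval_up_feedback(2, 0), 1.0)
  expect_equal(eval_up_feedback(2, 1), 2.0)
  expect_equal(eval_up_feedback(2, 1e12), 3.0, tolerance = 1e-9)
  expect_error(eval_down_feedback(0.7, 0.1, 0.3, -1), "non-negative")
  expect_error(eval_up_feedback(2, -0.5), "non-negative")

  # property: monotone in concentration, value at 0, bounds
  set.seed(4)
  for (i in 1:50) {
    a <- runif(1, 0, 3)
    b <- runif(1, 0, 5)
    cc <- runif(1, 0, 1)
    conc <- sort(runif(5, 0, 50))
    g <- eval_down_feedback(a, b, cc, conc)
    expect_true(all(diff(g) <= 1e-12))
    expect_equal(eval_down_feedback(a, b, cc, 0), a + cc)
    expect_true(all(g > cc - 1e-12 & g <= a + cc + 1e-12))
    f <- eval_up_feedback(a, conc)
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f >= 1 - 1e-12 & f <= 1 + a + 1e-12))
  }
})

test_that("regulator unit conversion is consistent both ways", {
  expect_equal(convert_regulator_concentration(1500, "pg/mL", "ng/mL"), 1.5)
  expect_equal(convert_regulator_concentration(1000, "pM", "nM"), 1)
  # 1 nM of estradiol (MW 272.38) is 272.38 pg/mL
  e2 <- convert_regulator_concentration(1, "nM", "pg/mL", regulator = "E2")
  expect_equal(e2, 272.38)
  back <- convert_regulator_concentration(e2, "pg/mL", "nM", regulator = "E2")
  expect_equal(back, 1)
  expect_error(convert_regulator_concentration(1, "nM", "pg/mL"),
               "molecular weight")
})

test_that("parameter files round-trip and validation names offending symbols", {
  p <- fix_synth_params(seed = 3)
  f <- tempfile(fileext = ".csv")
  write_parameter_tables(p, f)
  p2 <- load_parameter_set(f)
  expect_equal(p2$production$value, p$production$value)
  expect_equal(p2$decay, p$decay)
  expect_equal(p2$feedback$a, p$feedback$a)
  expect_equal(p2$feedback$b, p$feedback$b)
  expect_equal(p2$chemotaxis$k_M_in, p$chemotaxis$k_M_in)
  expect_equal(p2$sf_concentration, p$sf_concentration)

  # second round trip is bit-stable
  f2 <- tempfile(fileext = ".csv")
  write_parameter_tables(p2, f2)
  expect_identical(readLines(f), readLines(f2))

  # missing coefficient is reported by symbol name
  tab <- read.csv(f)
  writeLines(readLines(f)[!grepl("k_IL10_SF", readLines(f))], f)
  expect_error(load_parameter_set(f), "k_IL10_SF")

  # duplicated feedback rows are rejected
  write_parameter_tables(p, f)
  lines <- readLines(f)
  dup <- grep("f_E2_IL1", lines, value = TRUE)
  writeLines(c(lines, dup), f)
  expect_error(load_parameter_set(f), "duplicate")
})

test_that("the structural tables pin the network wiring", {
  pr <- production_structure()
  # MMP-9 has no fibroblast production term, MMP-1 no M2 term,
  # TGF-beta is the only platelet product
  expect_false(any(pr$substance == "MMP9" & pr$cell == "SF"))
  expect_false(any(pr$substance == "MMP1" & pr$cell == "M2"))
  expect_identical(pr$substance[pr$cell == "P"], "TGF")

  fb <- feedback_structure()
  expect_false(anyDuplicated(fb$symbol) > 0)
  # hormone edges act on M1 production only, with the documented signs
  h <- fb[fb$regulator %in% hormone_ids(), ]
  expect_true(all(h$cell == "M1"))
  expect_identical(h$direction[h$symbol == "f_E2_IL1"], "up")
  expect_identical(h$direction[h$symbol == "g_E2_IL10"], "down")
  expect_identical(h$direction[h$symbol == "f_T_IL10"], "up")
  expect_identical(h$direction[h$symbol == "g_T_TNF"], "down")
  expect_identical(unique(h$direction[h$regulator == "P4"]), "down")
})

test_that("parameter_set rejects incomplete or inconsistent inputs", {
  p <- fix_synth_params(seed = 3)
  pr <- p$production
  expect_error(
    parameter_set(pr[-1, ], p$decay, p$feedback, p$chemotaxis),
    pr$symbol[1])
  bad_decay <- p$decay
  bad_decay["TNF"] <- -1
  expect_error(parameter_set(pr, bad_decay, p$feedback, p$chemotaxis),
               "positive")
  dup_fb <- rbind(p$feedback, p$feedback[3, ])
  expect_error(parameter_set(pr, p$decay, dup_fb, p$chemotaxis),
               "duplicate")
})
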