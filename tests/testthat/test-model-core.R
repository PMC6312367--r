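test_that("derivative vector honours the equation structure", {
  p <- fix_synth_params(seed = 1)
  zero <- setNames(numeric(12), species_ids())

  # all-zero state: every term has a zero factor
  expect_equal(unname(model_rhs(zero, p)), numeric(12))

  # platelets alone: pure decay plus TGF-beta release
  s <- zero
  s["P"] <- 2e8
  d <- model_rhs(s, p)
  expect_equal(d[["P"]], -p$decay[["P"]] * 2e8)
  expect_equal(d[["TGF"]], get_coefficient(p, "k_TGF_P") * 2e8)
  expect_equal(unname(d[setdiff(species_ids(), c("P", "TGF"))]),
               numeric(10))

  # MMP-9 without macrophages: decay only, whatever the SF pool does
  s <- zero
  s["SF"] <- p$sf_concentration
  s["MMP9"] <- 123
  d <- model_rhs(s, p)
  expect_equal(d[["MMP9"]], -p$decay[["MMP9"]] * 123)
})

test_that("chemotactic influx gates on platelets and saturates", {
  p <- fix_synth_params(seed = 1)
  ch <- p$chemotaxis
  expect_identical(chemotactic_influx(50, 50, 0, p), 0)
  expect_identical(chemotactic_influx(1e6, 1e6,
                                      ch$platelet_threshold / 2, p), 0)
  expect_equal(chemotactic_influx(0, 0, 1e8, p), 0)
  expect_equal(chemotactic_influx(1e12, 1e12, 1e8, p),
               ch$k_M_in * (ch$f_TGF_M1$a + ch$f_TNF_M1$a),
               tolerance = 1e-6)
  # monotone gating: raising the threshold can never increase the influx
  set.seed(11)
  for (i in 1:20) {
    tgf <- runif(1, 0, 100)
    tnf <- runif(1, 0, 100)
    cp <- 10^runif(1, -14, 9)
    lo <- chemotactic_influx(tgf, tnf, cp, p)
    p_hi <- p
    p_hi$chemotaxis$platelet_threshold <- ch$platelet_threshold * 10^6
    expect_lte(chemotactic_influx(tgf, tnf, cp, p_hi), lo)
  }
})

test_that("hormone multipliers have the documented signs and neutral zero", {
  p <- fix_default_params()
  none <- hormone_scenario()
  for (s in c("IL1", "TNF", "IL6", "IL10"))
    expect_identical(hormone_multipliers(s, "M1", none, p), 1)

  e_grid <- c(10, 100, 1000, 2500)
  il1 <- vapply(e_grid, function(e)
    hormone_multipliers("IL1", "M1", hormone_scenario(estrogen = e), p),
    numeric(1))
  expect_true(all(il1 >= 1))
  expect_true(all(diff(il1) > 0))

  t_grid <- c(0.1, 1, 10, 40)
  tnf <- vapply(t_grid, function(tt)
    hormone_multipliers("TNF", "M1", hormone_scenario(testosterone = tt), p),
    numeric(1))
  i <- match("g_T_TNF", p$feedback$symbol)
  expect_true(all(tnf <= p$feedback$a[i] + p$feedback$c[i]))
  expect_true(all(diff(tnf) < 0))
})

test_that("platelet trajectory matches the closed-form exponential", {
  p <- fix_synth_params(seed = 1, profile = "minimal")
  p$production$value[] <- 0
  init <- setNames(numeric(12), species_ids())
  init["P"] <- 2e8
  tc <- simulate_injury(p, initial = init, t_end = 72, grid = 1)
  expected <- 2e8 * exp(-p$decay[["P"]] * tc[, "time"])
  expect_equal(tc[, "P"], expected, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(tc[, mediator_ids()] == 0))
})

test_that("the zero state is a fixed point of the integrated system", {
  p <- fix_synth_params(seed = 1)
  init <- setNames(numeric(12), species_ids())
  tc <- simulate_injury(p, initial = init, t_end = 48, grid = 8)
  expect_true(all(tc[, species_ids()] == 0))
})

test_that("the SF-only system stays on its equilibrium for 20 days", {
  p <- fix_default_params()
  hs <- fix_healthy(p, "default")
  tc <- simulate_injury(p, initial = hs, t_end = 480, grid = 48)
  for (s in mediator_ids()) {
    ref <- hs[[s]]
    if (ref == 0) expect_true(all(tc[, s] == 0))
    else expect_lt(max(abs(tc[, s] - ref)) / ref, 1e-6)
  }
})

test_that("M1 + M2 is conserved when decay and influx are off", {
  p <- fix_synth_params(seed = 1)
  p$decay["M"] <- 1e-12
  p$chemotaxis$k_M_in <- 0
  init <- injured_initial_state(healthy_steady_state(p), p)
  init["M1"] <- 5e5
  init["M2"] <- 1e5
  tc <- simulate_injury(p, initial = init, t_end = 120, grid = 24)
  total <- tc[, "M1"] + tc[, "M2"]
  expect_equal(total, rep(6e5, length(total)), tolerance = 1e-7,
               ignore_attr = TRUE)
  # conversion itself happened (M2 grew at M1's expense)
  expect_gt(tc[nrow(tc), "M2"], 1e5)
})

test_that("zero-delay formulations agree across integrators", {
  p <- fix_synth_params(seed = 1)
  p$chemotaxis$delay_tau <- 0
  init <- injured_initial_state(healthy_steady_state(p), p)
  tc_ode <- simulate_injury(p, initial = init, t_end = 240, grid = 12)
  tc_dede <- simulate_injury(p, initial = init, t_end = 240, grid = 12,
                             use_dede = TRUE)
  for (s in species_ids()) {
    scale <- max(tc_ode[, s], 1e-9)
    expect_lt(max(abs(tc_ode[, s] - tc_dede[, s])) / scale, 1e-5)
  }
})

test_that("a short delay perturbs the solution continuously", {
  p <- fix_synth_params(seed = 1)
  init <- injured_initial_state(healthy_steady_state(p), p)
  p0 <- p
  p0$chemotaxis$delay_tau <- 0
  p1 <- p
  p1$chemotaxis$delay_tau <- 0.25
  tc0 <- simulate_injury(p0, initial = init, t_end = 120, grid = 24)
  tc1 <- simulate_injury(p1, initial = init, t_end = 120, grid = 24)
  for (s in c("M1", "IL1", "TNF")) {
    scale <- max(tc0[, s], 1e-9)
    expect_lt(max(abs(tc0[, s] - tc1[, s])) / scale, 0.05)
  }
})

test_that("hormone scenarios at zero concentration leave dynamics unchanged", {
  p <- fix_default_params()
  init <- injured_initial_state(fix_healthy(p, "default"), p)
  tc_none <- simulate_injury(p, initial = init, t_end = 96, grid = 24)
  tc_zero <- simulate_injury(p, hormones = hormone_scenario(0, 0, 0),
                             initial = init, t_end = 96, grid = 24)
  expect_equal(unclass(tc_none)[, ], unclass(tc_zero)[, ],
               ignore_attr = TRUE)
})

test_that("time courses expose coercion, summary and file output", {
  p <- fix_default_params()
  init <- injured_initial_state(fix_healthy(p, "default"), p)
  tc <- simulate_injury(p, initial = init, t_end = 48, grid = 12)
  df <- as.data.frame(tc)
  expect_identical(names(df), c("time", species_ids()))
  su <- summary(tc)
  expect_identical(su$species, mediator_ids())
  expect_true(all(su$peak >= su$initial - 1e-12))
  f <- tempfile(fileext = ".csv")
  write_timecourse(tc, f)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".meta.yaml")))
  back <- read.csv(f)
  expect_equal(back$IL1, unname(tc[, "IL1"]))
})
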