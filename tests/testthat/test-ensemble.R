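test_that("hypercube rows are permuted arithmetic progressions", {
  m <- lhs_multiplier_matrix(5, 40, fraction = 0.6, seed = 7)
  expect_identical(dim(m), c(5L, 40L))
  target <- seq(0.4, 1.6, length.out = 40)
  for (i in 1:5) {
    expect_equal(sort(m[i, ]), target)
    expect_equal(mean(m[i, ]), 1.0)
    # exactly one sample per stratum
    bins <- cut(m[i, ], breaks = seq(0.4, 1.6, length.out = 41),
                include.lowest = TRUE)
    expect_true(all(table(bins) == 1))
  }
  m20 <- lhs_multiplier_matrix(3, 10, fraction = 0.2, seed = 7)
  expect_equal(sort(m20[2, ]), seq(0.8, 1.2, length.out = 10))

  # seeded determinism
  expect_identical(m, lhs_multiplier_matrix(5, 40, fraction = 0.6, seed = 7))
  expect_false(identical(m, lhs_multiplier_matrix(5, 40, fraction = 0.6,
                                                  seed = 8)))
  expect_error(lhs_multiplier_matrix(3, 1), "n_samples")
  expect_error(lhs_multiplier_matrix(3, 10, fraction = 1.2), "fraction")
})

test_that("range-based hypercube draws respect their rectangles", {
  r <- rbind(estrogen = c(143, 673), testosterone = c(0.069, 1.38))
  m <- lhs_range_matrix(r, 25, seed = 3)
  expect_equal(sort(m["estrogen", ]), seq(143, 673, length.out = 25))
  expect_true(all(m["testosterone", ] >= 0.069 &
                    m["testosterone", ] <= 1.38))
})

test_that("a zero-width ensemble collapses onto the nominal trajectory", {
  p <- fix_synth_params(seed = 1)
  init <- injured_initial_state(healthy_steady_state(p), p)
  nominal <- simulate_injury(p, initial = init, t_end = 96, grid = 24)
  ens <- run_ensemble(p, n_samples = 3, fraction = 0, seed = 5,
                      t_end = 96, grid = 24)
  for (i in 1:3)
    expect_equal(ens$trajectories[, , i], nominal[, species_ids()],
                 tolerance = 1e-12, ignore_attr = TRUE)
  su <- summarize_ensemble(ens)
  expect_equal(su$median, nominal[, species_ids()], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(su$q3 - su$q1 == 0))
})

test_that("each ensemble member starts on its own perturbed fixed point", {
  p <- fix_synth_params(seed = 1)
  n <- 4
  ens <- run_ensemble(p, n_samples = n, fraction = 0.6, seed = 9,
                      t_end = 48, grid = 24)
  gamma <- length(perturbed_coefficient_names(p))
  mult <- lhs_multiplier_matrix(gamma, n, fraction = 0.6, seed = 9)
  for (i in seq_len(n)) {
    pi_ <- perturb_parameters(p, mult[, i])
    med0 <- ens$trajectories[1, mediator_ids(), i]
    state <- setNames(c(0, 0, 0, pi_$sf_concentration, med0), species_ids())
    dmed <- model_rhs(state, pi_)[mediator_ids()]
    rel <- abs(dmed) / pmax(med0 * unname(pi_$decay[mediator_ids()]), 1e-9)
    expect_lt(max(rel), 1e-6)
  }
  # distinct multipliers produce distinct trajectories
  expect_gt(sd(ens$trajectories[3, "IL1", ]), 0)
  # same seed reproduces the ensemble exactly
  ens2 <- run_ensemble(p, n_samples = n, fraction = 0.6, seed = 9,
                       t_end = 48, grid = 24)
  expect_identical(ens$trajectories, ens2$trajectories)
})

test_that("summaries use type-7 quartiles and ignore member order", {
  p <- fix_synth_params(seed = 1)
  ens <- run_ensemble(p, n_samples = 4, fraction = 0.6, seed = 9,
                      t_end = 48, grid = 24)
  su <- summarize_ensemble(ens)
  vals <- ens$trajectories[2, "IL1", ]
  expect_equal(unname(su$q1[2, "IL1"]),
               unname(quantile(vals, 0.25, type = 7)))
  expect_equal(unname(su$median[2, "IL1"]),
               unname(quantile(vals, 0.5, type = 7)))
  # hand-computed type-7 quartiles of {1,2,3,4}
  expect_equal(unname(quantile(1:4, c(0.25, 0.5, 0.75), type = 7)),
               c(1.75, 2.5, 3.25))

  perm <- ens
  perm$trajectories <- ens$trajectories[, , c(3, 1, 4, 2)]
  su_p <- summarize_ensemble(perm)
  expect_equal(su$median, su_p$median)
  expect_equal(su$q1, su_p$q1)
  expect_true(all(su$q1 <= su$median & su$median <= su$q3))

  expect_error(summarize_ensemble(list(trajectories = NULL)), "summary error")
})
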