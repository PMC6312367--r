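# Latin hypercube uncertainty analysis.
#
# Each perturbed coefficient gets a row of multipliers: an evenly spaced
# grid spanning (1 - fraction) .. (1 + fraction) with one value per sample,
# independently permuted per row.  Column i of the stacked matrix is the
# i-th perturbed parameter set.  Marginal coverage of every row is exact
# (one sample per stratum), which is the defining property of the scheme.

# one permuted evenly spaced row; consumes the current RNG stream
.perm_grid_row <- function(lo, hi, n) {
  grid <- if (n == 1) (lo + hi) / 2 else seq(lo, hi, length.out = n)
  grid[sample.int(n)]
}

#' Latin hypercube multiplier matrix
#'
#' @param n_params number of perturbed coefficients (rows).
#' @param n_samples ensemble size (columns, >= 2).
#' @param fraction half-width of the relative perturbation band (0.60 for
#'   the hormone-free analysis, 0.20 for the hormone-condition analysis).
#' @param seed integer seed.
#' @return \code{n_params} x \code{n_samples} matrix of dimensionless
#'   multipliers; each row sorted ascending is the exact arithmetic
#'   progression from \code{1 - fraction} to \code{1 + fraction}.
#' @export
#' @examples
#' m <- lhs_multiplier_matrix(3, 8, fraction = 0.6, seed = 1)
#' t(apply(m, 1, sort))
lhs_multiplier_matrix <- function(n_params, n_samples, fraction = 0.60,
                                  seed = 1L) {
  if (n_params < 1) stop("n_params must be >= 1")
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_params), function(i)
    .perm_grid_row(1 - fraction, 1 + fraction, n_samples)))
}

#' @param ranges matrix with one row per quantity and columns (min, max).
#' @rdname lhs_multiplier_matrix
#' @export
lhs_range_matrix <- function(ranges, n_samples, seed = 1L) {
  set.seed(seed)
  m <- do.call(rbind, lapply(seq_len(nrow(ranges)), function(i)
    .perm_grid_row(ranges[i, 1], ranges[i, 2], n_samples)))
  rownames(m) <- rownames(ranges)
  m
}

#' Names of the perturbed coefficients, in row order
#'
#' The hypercube varies every production and decay coefficient (feedback
#' fits are left at their nominal values).
#'
#' @param params a \code{synovial_params} object.
#' @return Character vector of coefficient symbols.
#' @export
perturbed_coefficient_names <- function(params) {
  c(params$production$symbol, paste0("k_d_", names(params$decay)))
}

#' Apply a vector of multipliers to the perturbed coefficients
#'
#' @param params nominal \code{synovial_params}.
#' @param multipliers numeric vector aligned with
#'   \code{\link{perturbed_coefficient_names}}.
#' @return A perturbed \code{synovial_params}.
#' @export
perturb_parameters <- function(params, multipliers) {
  np <- nrow(params$production)
  nd <- length(params$decay)
  if (length(multipliers) != np + nd)
    stop("expected ", np + nd, " multipliers, got ", length(multipliers))
  out <- params
  out$production$value <- params$production$value * multipliers[seq_len(np)]
  out$decay <- params$decay * multipliers[np + seq_len(nd)]
  out
}

#' Run a Latin hypercube ensemble of post-injury simulations
#'
#' For each hypercube column the production and decay coefficients are
#' scaled by their multipliers, the pre-injury steady state and injured
#' initial condition are recomputed for the perturbed set, and the injury
#' simulation is integrated.  Individual integration failures are recorded
#' and excluded; more than \code{max_failure_fraction} failures aborts with
#' an error.
#'
#' @param params nominal \code{synovial_params}.
#' @param n_samples ensemble size (default 2000, the full-scale analysis).
#' @param fraction relative perturbation half-width (default 0.60).
#' @param seed integer seed driving the hypercube permutations.
#' @param hormones a single \code{\link{hormone_scenario}} applied to every
#'   sample, or a list of length \code{n_samples} pairing one scenario with
#'   each hypercube column.
#' @param t_end,grid simulation horizon and output spacing, hours.
#' @param recompute_initial recompute the healthy steady state per
#'   perturbed sample (default) rather than reusing the nominal one.
#' @param max_failure_fraction abort threshold for excluded samples.
#' @param ... further arguments to \code{\link{simulate_injury}}.
#' @return A \code{synovial_ensemble}: list with \code{trajectories}
#'   (time x species x sample array over successful samples), \code{times},
#'   \code{failures} (indices), and \code{meta}.
#' @export
#' @examples
#' p <- generate_nominal_parameters(seed = 1)
#' ens <- run_ensemble(p, n_samples = 4, seed = 1, t_end = 48, grid = 12)
#' summarize_ensemble(ens)
run_ensemble <- function(params, n_samples = 2000, fraction = 0.60,
                         seed = 1L, hormones = hormone_scenario(),
                         t_end = 480, grid = 1,
                         recompute_initial = TRUE,
                         max_failure_fraction = 0.01, ...) {
  gamma <- length(perturbed_coefficient_names(params))
  mult <- lhs_multiplier_matrix(gamma, n_samples, fraction, seed)
  scenario_list <- if (inherits(hormones, "hormone_scenario"))
    rep(list(hormones), n_samples)
  else hormones
  if (length(scenario_list) != n_samples)
    stop("hormones must be one scenario or a list of length n_samples")

  nominal_healthy <- if (!recompute_initial) healthy_steady_state(params)
  trajectories <- NULL
  times <- NULL
  failures <- integer(0)
  kept <- integer(0)
  for (i in seq_len(n_samples)) {
    res <- tryCatch({
      pi_ <- perturb_parameters(params, mult[, i])
      init <- if (recompute_initial)
        injured_initial_state(healthy_steady_state(pi_), pi_)
      else injured_initial_state(nominal_healthy, pi_)
      simulate_injury(pi_, hormones = scenario_list[[i]], initial = init,
                      t_end = t_end, grid = grid, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, i)
      next
    }
    if (is.null(trajectories)) {
      times <- res[, "time"]
      trajectories <- array(NA_real_,
                            dim = c(length(times), 12, n_samples),
                            dimnames = list(NULL, species_ids(), NULL))
    }
    trajectories[, , i] <- res[, species_ids()]
    kept <- c(kept, i)
  }
  if (length(failures) > max_failure_fraction * n_samples)
    stop("ensemble error: ", length(failures), " of ", n_samples,
         " integrations failed")
  if (length(failures))
    message(length(failures), " ensemble member(s) excluded after ",
            "integration failure")
  structure(list(trajectories = trajectories[, , kept, drop = FALSE],
                 times = times, failures = failures,
                 meta = list(n_samples = n_samples, fraction = fraction,
                             seed = seed, t_end = t_end, grid = grid,
                             recompute_initial = recompute_initial)),
            class = "synovial_ensemble")
}

#' @export
print.synovial_ensemble <- function(x, ...) {
  cat(sprintf("Synovial LHS ensemble: %d kept / %d requested samples, %d time points\n",
              dim(x$trajectories)[3], x$meta$n_samples, length(x$times)))
  cat(sprintf("  fraction +/-%d%%, seed %d\n",
              round(100 * x$meta$fraction), x$meta$seed))
  invisible(x)
}

#' Per-time median and quartiles of an ensemble
#'
#' Quartiles use linear interpolation between closest ranks
#' (\code{quantile} type 7).
#'
#' @param ensemble a \code{synovial_ensemble} with >= 2 kept samples.
#' @return An \code{ensemble_summary}: list of time x species matrices
#'   \code{median}, \code{q1}, \code{q3}, plus \code{times}.
#' @export
summarize_ensemble <- function(ensemble) {
  tr <- ensemble$trajectories
  if (is.null(tr) || dim(tr)[3] < 2)
    stop("summary error: need at least 2 successful trajectories")
  qs <- apply(tr, c(1, 2), stats::quantile,
              probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(times = ensemble$times,
                 q1 = qs[1, , ], median = qs[2, , ], q3 = qs[3, , ],
                 n = dim(tr)[3]),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble summary over %d samples, %d time points\n",
              x$n, length(x$times)))
  i <- length(x$times)
  cat("  final-time mediator medians (pg/mL):\n")
  print(signif(x$median[i, mediator_ids()], 4))
  invisible(x)
}

#' @export
as.data.frame.ensemble_summary <- function(x, ...) {
  sp <- colnames(x$median)
  do.call(rbind, lapply(sp, function(s)
    data.frame(species = s, time_h = x$times,
               median = x$median[, s], q1 = x$q1[, s], q3 = x$q3[, s],
               row.names = NULL)))
}

#' Plot a median/IQR band for one species
#'
#' @param x an \code{ensemble_summary}.
#' @param species species id to draw.
#' @param ... passed to \code{plot}.
#' @export
plot.ensemble_summary <- function(x, species = "IL1", ...) {
  t_d <- x$times / 24
  graphics::plot(t_d, x$median[, species], type = "n",
                 ylim = range(x$q1[, species], x$q3[, species]),
                 xlab = "time (days)", ylab = paste(species, "(pg/mL)"), ...)
  graphics::polygon(c(t_d, rev(t_d)),
                    c(x$q1[, species], rev(x$q3[, species])),
                    col = "grey85", border = NA)
  graphics::lines(t_d, x$median[, species], lwd = 2)
  invisible(x)
}

#' Run one hormone condition with combined coefficient and hormone sampling
#'
#' The condition's estrogen and testosterone ranges are treated as two
#' extra rows of the same hypercube that perturbs the model coefficients
#' (by \code{fraction}, default 20 percent), drawn from a single seeded
#' stream; the i-th hormone draw is paired with the i-th coefficient
#' column.
#'
#' @param params nominal \code{synovial_params}.
#' @param condition \code{"male"}, \code{"female_low_e"} or
#'   \code{"female_peak_e"}.
#' @param n ensemble size per condition (default 2000).
#' @param seed integer seed.
#' @param fraction coefficient perturbation half-width (default 0.20).
#' @param ... further arguments to \code{\link{run_ensemble}}.
#' @return A \code{synovial_ensemble} (with the condition recorded in
#'   \code{meta}).
#' @export
run_condition <- function(params, condition, n = 2000, seed = 1L,
                          fraction = 0.20, ...) {
  rng <- condition_ranges(condition)
  gamma <- length(perturbed_coefficient_names(params))
  # single stream: coefficient rows first, then the two hormone rows
  set.seed(seed)
  grid_rows <- do.call(rbind, lapply(seq_len(gamma + 2), function(i) {
    if (i <= gamma) .perm_grid_row(1 - fraction, 1 + fraction, n)
    else if (i == gamma + 1)
      .perm_grid_row(rng$estrogen[1], rng$estrogen[2], n)
    else .perm_grid_row(rng$testosterone[1], rng$testosterone[2], n)
  }))
  scenarios <- lapply(seq_len(n), function(i)
    hormone_scenario(estrogen = grid_rows[gamma + 1, i],
                     testosterone = grid_rows[gamma + 2, i]))
  # run_ensemble re-seeds with the same seed and therefore regenerates the
  # identical coefficient rows: documented pairing of draws
  ens <- run_ensemble(params, n_samples = n, fraction = fraction,
                      seed = seed, hormones = scenarios, ...)
  ens$meta$condition <- condition
  ens
}
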