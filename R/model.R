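# Delayed ODE right-hand side for the 12-species synovial network.
#
# Cell pools: platelets decay exponentially after injury; M1 macrophages
# enter by TGF-beta/TNF-alpha chemotaxis (evaluated at t - tau to account
# for monocyte-to-M1 transformation time), convert to M2 under IL-10 drive
# and decay; synovial fibroblasts are constant.  Each mediator follows
#   dC_x/dt = (prod_j g_j,x) k_x,M1 C_M1 + k_x,M2 C_M2
#             + (prod_n g_n,x) k_x,SF C_SF [+ k_TGF,P C_P] - k_d,x C_x
# with hormone multipliers constant over a simulation and therefore folded
# into effective production coefficients before integration.

#' Product of hormone feedback multipliers for one production term
#'
#' Evaluates every hormone feedback edge acting on production of
#' \code{substance} by \code{cell} at the scenario's constant
#' concentrations, converting each hormone concentration into the unit the
#' edge was fitted in.  Returns 1 when no hormone edge applies or when the
#' scenario is all-zero and the down-regulation fits satisfy
#' \eqn{a + c = 1}.
#'
#' @param substance,cell species identifiers of the production term.
#' @param hormones a \code{\link{hormone_scenario}}.
#' @param params a \code{synovial_params} object.
#' @return Dimensionless multiplier.
#' @export
hormone_multipliers <- function(substance, cell, hormones, params) {
  fb <- params$feedback
  rows <- which(fb$regulator %in% hormone_ids() &
                  fb$target == substance & fb$cell == cell)
  m <- 1
  for (i in rows) {
    # a hormone absent from the scenario leaves production unmodulated,
    # even when a fitted down-regulation has g(0) != 1
    if (.hormone_value(hormones, fb$regulator[i]) == 0) next
    conc <- convert_regulator_concentration(
      .hormone_value(hormones, fb$regulator[i]),
      from = .hormone_native_unit(fb$regulator[i]),
      to = fb$regulator_units[i],
      regulator = fb$regulator[i])
    m <- m * if (fb$direction[i] == "down")
      eval_down_feedback(fb$a[i], fb$b[i], fb$c[i], conc)
    else
      eval_up_feedback(fb$a[i], conc)
  }
  m
}

#' Chemotactic monocyte influx
#'
#' The M1 source term: \code{k_M_in} times the sum of the saturating
#' TGF-beta and TNF-alpha drives, gated to exactly zero whenever the
#' platelet concentration is below the gating threshold.  The gate prevents
#' non-physiological re-initiation of inflammation once the platelet
#' stimulus has cleared.
#'
#' @param c_tgf,c_tnf chemoattractant concentrations, pg/mL.
#' @param c_p platelet concentration, cells/mL.
#' @param params a \code{synovial_params} object.
#' @return Influx rate, cells/mL/h.
#' @export
chemotactic_influx <- function(c_tgf, c_tnf, c_p, params) {
  if (any(c(c_tgf, c_tnf, c_p) < 0))
    stop("concentrations must be non-negative")
  ch <- params$chemotaxis
  if (c_p < ch$platelet_threshold) return(0)
  sT <- convert_regulator_concentration(c_tgf, "pg/mL", ch$f_TGF_M1$units)
  sN <- convert_regulator_concentration(c_tnf, "pg/mL", ch$f_TNF_M1$units)
  ch$k_M_in * (ch$f_TGF_M1$a * sT / (1 + sT) + ch$f_TNF_M1$a * sN / (1 + sN))
}

# Precompute index vectors and hormone-folded coefficients for fast RHS
# evaluation.  All regulator concentrations are converted from pg/mL by a
# precomputed scale factor.
.mass_scale <- function(units) {
  switch(units, "pg/mL" = 1, "ng/mL" = 1e-3,
         stop("mediator feedback must be fitted in pg/mL or ng/mL, got ",
              units))
}

.build_plan <- function(params, hormones) {
  sp <- species_ids()
  pr <- params$production
  keff <- pr$value
  for (i in seq_len(nrow(pr)))
    keff[i] <- keff[i] * hormone_multipliers(pr$substance[i], pr$cell[i],
                                             hormones, params)
  term_cell <- match(pr$cell, sp)
  term_subst <- match(pr$substance, sp)

  fb <- params$feedback
  dyn <- fb[!fb$regulator %in% hormone_ids(), , drop = FALSE]
  fb_group <- match(paste(dyn$target, dyn$cell),
                    paste(pr$substance, pr$cell))
  if (anyNA(fb_group))
    stop("configuration error: feedback edge targets a production term ",
         "that does not exist")
  fb_scale <- vapply(dyn$regulator_units, .mass_scale, numeric(1))

  # aggregation matrix: mediator derivative rows x production terms
  agg <- matrix(0, nrow = 8, ncol = nrow(pr))
  agg[cbind(term_subst - 4L, seq_len(nrow(pr)))] <- 1

  kd_med <- unname(params$decay[mediator_ids()])
  ch <- params$chemotaxis
  list(keff = keff, term_cell = term_cell,
       fb_group = fb_group, fb_reg = match(dyn$regulator, sp),
       fb_down = dyn$direction == "down",
       fb_a = dyn$a, fb_b = dyn$b, fb_c = dyn$c,
       fb_scale = unname(fb_scale),
       agg = agg, kd_med = kd_med,
       kd_P = unname(params$decay["P"]), kd_M = unname(params$decay["M"]),
       k_M_in = ch$k_M_in, a_TGF = ch$f_TGF_M1$a,
       s_TGF = .mass_scale(ch$f_TGF_M1$units),
       a_TNF = ch$f_TNF_M1$a, s_TNF = .mass_scale(ch$f_TNF_M1$units),
       k_M1M2 = ch$k_M1M2, a_conv = ch$f_M1M2$a,
       s_conv = .mass_scale(ch$f_M1M2$units),
       tau = ch$delay_tau, threshold = ch$platelet_threshold)
}

# mediator production derivative contributions given a clipped state vector
.production_rates <- function(plan, yc) {
  mult <- rep.int(1, length(plan$keff))
  if (length(plan$fb_group)) {
    conc <- yc[plan$fb_reg] * plan$fb_scale
    m <- 1 + plan$fb_a * conc / (1 + conc)
    d <- plan$fb_down
    if (any(d))
      m[d] <- plan$fb_a[d] * exp(-plan$fb_b[d] * conc[d]) + plan$fb_c[d]
    for (i in seq_along(plan$fb_group)) {
      g <- plan$fb_group[i]
      mult[g] <- mult[g] * m[i]
    }
  }
  plan$keff * mult * yc[plan$term_cell]
}

#' Evaluate the model derivative vector
#'
#' Direct evaluation of the delayed right-hand side at one state, mainly
#' for inspection and testing; \code{\link{simulate_injury}} uses the same
#' assembly internally.  The chemotactic influx is evaluated on the
#' \code{lagged} state (the state at \eqn{t - \tau}), including its
#' platelet gate.
#'
#' @param state named numeric vector over \code{\link{species_ids}} (the
#'   current state).
#' @param params a \code{synovial_params} object.
#' @param hormones a \code{\link{hormone_scenario}}.
#' @param lagged state at \eqn{t - \tau}; defaults to \code{state} (no
#'   delay).
#' @return Named derivative vector (cells/mL/h and pg/mL/h).
#' @export
#' @examples
#' p <- generate_nominal_parameters(seed = 1)
#' s <- injured_initial_state(healthy_steady_state(p), p)
#' model_rhs(s, p)
model_rhs <- function(state, params, hormones = hormone_scenario(),
                      lagged = state) {
  if (any(state < 0)) stop("state must be non-negative")
  plan <- .build_plan(params, hormones)
  yc <- pmax(unname(state[species_ids()]), 0)
  yl <- pmax(unname(lagged[species_ids()]), 0)
  influx <- chemotactic_influx(yl[9], yl[6], yl[1], params)
  sc <- yc[8] * plan$s_conv
  conv <- plan$k_M1M2 * plan$a_conv * sc / (1 + sc)
  dmed <- as.vector(plan$agg %*% .production_rates(plan, yc)) -
    plan$kd_med * yc[5:12]
  stats::setNames(c(-plan$kd_P * yc[1],
                    influx - conv * yc[2] - plan$kd_M * yc[2],
                    conv * yc[2] - plan$kd_M * yc[3],
                    0, dmed), species_ids())
}

#' Simulate the post-injury inflammatory time course
#'
#' Integrates the delayed 12-species system from an initial state
#' (typically \code{\link{injured_initial_state}}) over \code{t_end} hours.
#' The monocyte influx at time \eqn{t} uses chemoattractant concentrations
#' and the platelet gate at \eqn{t - \tau}; history for \eqn{t' < 0} is the
#' pre-injury state (zero platelets, healthy mediator levels).  Because
#' platelets decay as a pure exponential, the time at which they cross the
#' gating threshold is located analytically and the integrator is forced to
#' step on it, avoiding chatter at the discontinuity.
#'
#' @param params a \code{synovial_params} object.
#' @param hormones a \code{\link{hormone_scenario}}; default no hormones.
#' @param initial named initial state over \code{\link{species_ids}};
#'   default \code{injured_initial_state(healthy_steady_state(params), params)}.
#' @param t_end simulation horizon, hours (default 480 = 20 days).
#' @param grid output grid spacing, hours (default 1).
#' @param history pre-injury state used for lagged queries at
#'   \eqn{t' < \tau}; defaults to \code{initial} with platelets set to 0.
#' @param rtol,atol_cells,atol_mediators solver tolerances.  Concentrations
#'   span many orders of magnitude, so absolute tolerances are per-class:
#'   cells/mL for the four cell pools, pg/mL for mediators.
#' @param use_dede force the delay-capable integrator even when
#'   \code{delay_tau} is 0 (the two formulations then agree within solver
#'   tolerance).
#' @return A \code{synovial_timecourse}: numeric matrix (rows = output
#'   times) with columns \code{time} and the 12 species, plus metadata
#'   attributes.
#' @export
#' @examples
#' p <- generate_nominal_parameters(seed = 1)
#' tc <- simulate_injury(p, t_end = 48, grid = 4)
#' head(as.data.frame(tc))
simulate_injury <- function(params, hormones = hormone_scenario(),
                            initial = NULL, t_end = 480, grid = 1,
                            history = NULL,
                            rtol = 1e-8, atol_cells = 1e-6,
                            atol_mediators = 1e-12,
                            use_dede = FALSE) {
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(initial))
    initial <- injured_initial_state(healthy_steady_state(params), params)
  y0 <- unname(initial[species_ids()])
  if (anyNA(y0)) stop("initial state must name every species")
  if (any(y0 < 0)) stop("initial state must be non-negative")
  if (is.null(history)) {
    history <- y0
    history[1] <- 0
  } else history <- unname(history[species_ids()])

  plan <- .build_plan(params, hormones)
  tau <- plan$tau
  thr <- plan$threshold
  # analytic gate-off time for the exponential platelet decay
  t_gate <- if (thr <= 0) Inf
  else if (y0[1] < thr) -Inf
  else log(y0[1] / thr) / plan$kd_P

  hist_TGF <- max(history[9], 0)
  hist_TNF <- max(history[6], 0)
  hist_P_on <- history[1] >= thr && thr > 0 || (thr <= 0)

  derivs <- function(t, y, parms) {
    yc <- y
    yc[yc < 0] <- 0
    tl <- t - tau
    if (tau > 0 && tl > 1e-10) {
      lag <- deSolve::lagvalue(tl, c(9L, 6L))
      lT <- max(lag[1], 0)
      lN <- max(lag[2], 0)
    } else if (tau > 0) {
      lT <- hist_TGF
      lN <- hist_TNF
    } else {
      lT <- yc[9]
      lN <- yc[6]
    }
    gate_on <- if (tl < 0) hist_P_on else tl <= t_gate
    influx <- if (gate_on) {
      sT <- lT * plan$s_TGF
      sN <- lN * plan$s_TNF
      plan$k_M_in * (plan$a_TGF * sT / (1 + sT) +
                       plan$a_TNF * sN / (1 + sN))
    } else 0
    sc <- yc[8] * plan$s_conv
    conv <- plan$k_M1M2 * plan$a_conv * sc / (1 + sc)
    dmed <- as.vector(plan$agg %*% .production_rates(plan, yc)) -
      plan$kd_med * yc[5:12]
    list(c(-plan$kd_P * yc[1],
           influx - conv * yc[2] - plan$kd_M * yc[2],
           conv * yc[2] - plan$kd_M * yc[3],
           0, dmed))
  }

  times <- seq(0, t_end, by = grid)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  kinks <- c(tau, tau + t_gate)
  kinks <- kinks[is.finite(kinks) & kinks > 0 & kinks < t_end]
  all_times <- sort(unique(c(times, kinks)))
  atol <- c(rep(atol_cells, 4), rep(atol_mediators, 8))
  hmax <- if (tau > 0) tau / 4 else Inf

  sol <- if (tau > 0 || use_dede) {
    deSolve::dede(y = y0, times = all_times, func = derivs, parms = NULL,
                  rtol = rtol, atol = atol, hmax = min(hmax, t_end))
  } else {
    deSolve::ode(y = y0, times = all_times, func = derivs, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol)
  }
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("integration error at t = ", max(sol[, 1]), " h")
  sol <- sol[sol[, 1] %in% times, , drop = FALSE]

  conc <- sol[, -1, drop = FALSE]
  worst_neg <- min(conc, 0)
  if (worst_neg < -1e3 * max(atol_cells, atol_mediators))
    warning("negative concentrations down to ", signif(worst_neg, 3),
            " clipped to 0 in the reported trajectory")
  conc[conc < 0] <- 0
  out <- cbind(time = sol[, 1], conc)
  colnames(out) <- c("time", species_ids())
  structure(out, class = c("synovial_timecourse", "matrix", "array"),
            hormones = hormones, tau = tau, t_gate = t_gate,
            solver = list(rtol = rtol, atol_cells = atol_cells,
                          atol_mediators = atol_mediators,
                          steps = if (length(istate) >= 3) unname(istate[3]) else NA))
}

#' @export
print.synovial_timecourse <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Synovial inflammation time course: %d time points over %g h\n",
              n, x[n, "time"]))
  peaks <- apply(x[, mediator_ids(), drop = FALSE], 2, max)
  cat("  mediator peaks (pg/mL):\n")
  print(signif(peaks, 4))
  invisible(x)
}

#' @export
as.data.frame.synovial_timecourse <- function(x, ...) {
  as.data.frame(unclass(x)[, , drop = FALSE])
}

#' @export
summary.synovial_timecourse <- function(object, ...) {
  med <- mediator_ids()
  peak <- apply(object[, med, drop = FALSE], 2, max)
  tpeak <- object[apply(object[, med, drop = FALSE], 2, which.max), "time"]
  data.frame(species = med,
             initial = object[1, med],
             peak = peak,
             t_peak_h = tpeak,
             final = object[nrow(object), med],
             row.names = NULL)
}

#' Plot a simulated time course
#'
#' @param x a \code{synovial_timecourse}.
#' @param species which species to draw (default: the eight mediators).
#' @param log_y draw concentrations on a log axis.
#' @param ... passed to \code{matplot}.
#' @export
plot.synovial_timecourse <- function(x, species = mediator_ids(),
                                     log_y = FALSE, ...) {
  y <- x[, species, drop = FALSE]
  if (log_y) y <- pmax(y, 1e-12)
  graphics::matplot(x[, "time"] / 24, y, type = "l", lty = 1,
                    col = seq_along(species), xlab = "time (days)",
                    ylab = "concentration",
                    log = if (log_y) "y" else "", ...)
  graphics::legend("topright", legend = species, col = seq_along(species),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write a time course to CSV with a JSON-like metadata sidecar
#'
#' @param tc a \code{synovial_timecourse}.
#' @param path output CSV path; a \code{<path>.meta.yaml} sidecar records
#'   the scenario and solver settings.
#' @return \code{path}, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  meta <- list(hormones = unclass(attr(tc, "hormones")),
               delay_tau_h = attr(tc, "tau"),
               solver = attr(tc, "solver"))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
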