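# Pre-injury initialisation.
#
# The healthy joint is approximated by the fibroblast-only subsystem: no
# platelets, no macrophages, SF at its constant concentration, hormones
# absent.  Mediator concentrations settle to the fixed point of
#   k_x,SF * F_x(C) * C_SF = k_d,x * C_x
# where F_x collects the SF feedback multipliers.  Mediators with no SF
# production term (MMP-9) have a structurally forced fixed point of 0.

#' Healthy (pre-injury) steady state of the SF-only subsystem
#'
#' Integrates the mediator subsystem with all cell pools except synovial
#' fibroblasts set to zero, then polishes the fixed point with a damped
#' Newton iteration on the algebraic balance equations.  Convergence is
#' certified by requiring the largest relative derivative to fall below
#' \code{tol} per hour.
#'
#' @param params a \code{synovial_params} object.
#' @param tol convergence tolerance on max |dC/dt| / max(C, floor), 1/h.
#' @param t_max horizon of the settling integration, hours.
#' @return Named state vector over \code{\link{species_ids}} (platelets and
#'   macrophages 0, SF at its constant concentration) with attributes
#'   \code{residual} (certified relative derivative) and \code{newton_iters}.
#' @export
#' @examples
#' p <- generate_nominal_parameters(seed = 1)
#' healthy_steady_state(p)
healthy_steady_state <- function(params, tol = 1e-8, t_max = 5000) {
  plan <- .build_plan(params, hormone_scenario())
  csf <- params$sf_concentration
  kd <- plan$kd_med

  # mediators with no (effective) SF production term: fixed point exactly 0
  sf_terms <- plan$term_cell == .sp_index("SF")
  sf_k_by_med <- as.vector(plan$agg %*% (plan$keff * sf_terms))
  forced_zero <- sf_k_by_med == 0

  deriv_med <- function(cmed) {
    yc <- c(0, 0, 0, csf, pmax(cmed, 0))
    as.vector(plan$agg %*% .production_rates(plan, yc)) - kd * cmed
  }

  # settle by integration from zero
  sol <- deSolve::ode(y = numeric(8),
                      times = c(0, t_max / 4, t_max / 2, t_max),
                      func = function(t, y, p) list(deriv_med(y)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  cmed <- pmax(sol[nrow(sol), -1], 0)
  cmed[forced_zero] <- 0

  # damped Newton polish on the non-forced coordinates
  free <- which(!forced_zero)
  iters <- 0L
  if (length(free)) {
    for (it in seq_len(50)) {
      f <- deriv_med(cmed)[free]
      if (max(abs(f)) == 0) break
      jac <- matrix(0, length(free), length(free))
      h <- pmax(abs(cmed[free]) * 1e-7, 1e-12)
      for (j in seq_along(free)) {
        cp <- cmed
        cp[free[j]] <- cp[free[j]] + h[j]
        jac[, j] <- (deriv_med(cp)[free] - f) / h[j]
      }
      step <- tryCatch(solve(jac, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      f0 <- sum(f^2)
      repeat {
        cand <- cmed
        cand[free] <- pmax(cand[free] + lam * step, 0)
        if (sum(deriv_med(cand)[free]^2) <= f0 || lam < 1e-4) break
        lam <- lam / 2
      }
      iters <- it
      if (max(abs(cand[free] - cmed[free]) /
                pmax(abs(cmed[free]), 1e-12)) < 1e-14) {
        cmed <- cand
        break
      }
      cmed <- cand
    }
  }

  resid_vec <- abs(deriv_med(cmed)) / pmax(abs(cmed), 1e-6)
  resid <- max(resid_vec)
  if (resid >= tol) {
    worst <- mediator_ids()[which.max(resid_vec)]
    stop("equilibrium error: SF-only system failed to converge ",
         "(worst species ", worst, ", relative derivative ",
         signif(resid, 3), "/h)")
  }
  state <- stats::setNames(c(0, 0, 0, csf, cmed), species_ids())
  attr(state, "residual") <- resid
  attr(state, "newton_iters") <- iters
  state
}

#' Initial state for the post-injury simulation
#'
#' Copies the healthy mediator concentrations and overwrites the cell
#' pools: platelets at the injury load, macrophages absent, fibroblasts
#' unchanged.  Applying the function twice equals applying it once.
#'
#' @param healthy state returned by \code{\link{healthy_steady_state}}.
#' @param params a \code{synovial_params} object.
#' @return Named state vector over \code{\link{species_ids}}.
#' @export
injured_initial_state <- function(healthy, params) {
  state <- stats::setNames(unname(healthy[species_ids()]), species_ids())
  state["P"] <- params$platelet_initial
  state["M1"] <- 0
  state["M2"] <- 0
  attr(state, "residual") <- NULL
  state
}
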