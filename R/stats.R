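# Per-day nonparametric comparison of hormone conditions:
# Kruskal-Wallis across the three groups, pairwise Mann-Whitney U post hoc
# with Bonferroni correction, at t = 24 h * day for days 1..20 (day 0 is
# excluded: initial conditions are identical across conditions).

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over \code{stats::kruskal.test}: H computed on midranks
#' with tie correction, p from the chi-squared approximation with k - 1
#' degrees of freedom.
#'
#' @param groups list of >= 2 non-empty numeric samples.
#' @return List with elements \code{H} and \code{p}.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 1))
    stop("every group needs at least 1 observation")
  pool <- unlist(groups)
  # fully tied data: mean ranks are equal, H = 0 (the tie-corrected
  # statistic is 0/0 there)
  if (length(unique(pool)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Reports \eqn{U = \min(U_x, U_y)}.  The p-value is exact (by
#' enumeration of the null rank distribution) when \eqn{n + m \le}
#' \code{exact_max_n} and the data are tie-free, otherwise the normal
#' approximation with tie and continuity correction is used; the
#' switchover is fixed so results are reproducible across sample sizes.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max_n largest combined sample size for the exact null
#'   distribution (default 12).
#' @return List with elements \code{U}, \code{p} and \code{exact}.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y, exact_max_n = 12) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x)
  m <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (n + m) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  ux <- unname(wt$statistic)          # number of (x_i > y_j) pairs
  list(U = min(ux, n * m - ux), p = wt$p.value, exact = use_exact)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of comparisons \code{m}, capped
#' at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m number of comparisons (>= 1); defaults to \code{length(p)}.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Per-day comparison of hormone-condition ensembles
#'
#' For each substance and day \eqn{d = 1, \dots, 20}, extracts every
#' sample's concentration at \eqn{t = 24 d} hours, runs Kruskal-Wallis
#' across the three conditions and the three pairwise Mann-Whitney U tests
#' with Bonferroni correction (m = 3).
#'
#' @param ensembles named list of three \code{synovial_ensemble} objects
#'   (conditions); each needs >= 2 kept samples and all must share the
#'   output time grid.
#' @param substances mediator ids to compare (default all eight).
#' @param days integer days to test (default 1:20).
#' @param alpha significance threshold applied to adjusted p-values.
#' @return Data frame with one row per (substance, day, pair):
#'   \code{substance, day, kw_H, kw_p, pair, U, p_raw, p_adjusted,
#'   significant}.
#' @export
daily_condition_tests <- function(ensembles, substances = mediator_ids(),
                                  days = 1:20, alpha = 0.05) {
  if (length(ensembles) != 3 || is.null(names(ensembles)))
    stop("ensembles must be a named list of three conditions")
  cn <- names(ensembles)
  for (e in ensembles)
    if (dim(e$trajectories)[3] < 2)
      stop("every condition needs at least 2 kept samples")
  times <- ensembles[[1]]$times
  for (e in ensembles[-1])
    if (!identical(e$times, times))
      stop("alignment error: ensembles do not share an output grid")

  pairs <- utils::combn(cn, 2)
  out <- vector("list", length(substances) * length(days))
  k <- 0L
  for (s in substances) {
    for (d in days) {
      ti <- which(times == 24 * d)
      if (!length(ti))
        stop("alignment error: no grid point at t = ", 24 * d, " h")
      vals <- lapply(ensembles, function(e) e$trajectories[ti, s, ])
      kw <- kruskal_wallis(vals)
      praw <- numeric(ncol(pairs))
      u <- numeric(ncol(pairs))
      for (j in seq_len(ncol(pairs))) {
        mw <- mann_whitney_u(vals[[pairs[1, j]]], vals[[pairs[2, j]]])
        u[j] <- mw$U
        praw[j] <- mw$p
      }
      padj <- bonferroni_adjust(praw, m = 3)
      k <- k + 1L
      out[[k]] <- data.frame(
        substance = s, day = d, kw_H = kw$H, kw_p = kw$p,
        pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
        U = u, p_raw = praw, p_adjusted = padj,
        significant = padj < alpha, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
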