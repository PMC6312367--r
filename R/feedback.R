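#' Rate coefficients from in vitro measurements
#'
#' Production coefficients express the amount of a substance secreted per
#' cell per hour, assuming production is a linear function of time over the
#' duration of the source experiment:
#' \deqn{k_{x,y} = C_x / (C_y \, t)}
#' where \eqn{C_x} is the measured substance concentration, \eqn{C_y} the
#' cell concentration and \eqn{t} the duration of production.  Decay
#' coefficients come from reported half-lives via \eqn{k_d = 0.693/t_{1/2}}
#' (the conventional two-significant-figure constant, kept as printed rather
#' than extended-precision \eqn{\ln 2}).
#'
#' @param c_substance measured substance concentration (mass/mL; any mass
#'   unit, the result carries the same mass unit).
#' @param c_cells cell concentration during the experiment, cells/mL; must
#'   be positive.
#' @param duration duration of production, hours; must be positive.
#' @return \code{production_coefficient}: rate in (mass unit of
#'   \code{c_substance})/cell/hour.
#' @export
#' @examples
#' production_coefficient(100, 1e6, 24)   # ng/cell/h if input was ng/mL
#' decay_coefficient(6.93)                # 0.1 per hour
production_coefficient <- function(c_substance, c_cells, duration) {
  if (any(c_cells <= 0) || any(duration <= 0))
    stop("invalid measurement: cell concentration and duration must be positive")
  if (any(c_substance < 0))
    stop("invalid measurement: substance concentration must be non-negative")
  c_substance / (c_cells * duration)
}

#' @param t_half substance half-life in hours; must be positive.
#' @return \code{decay_coefficient}: first-order decay rate, per hour.
#' @rdname production_coefficient
#' @export
decay_coefficient <- function(t_half) {
  if (any(t_half <= 0))
    stop("invalid measurement: half-life must be positive")
  0.693 / t_half
}

#' Feedback multiplier functions
#'
#' Production of each mediator is modulated by other mediators and by sex
#' hormones through dimensionless multipliers.  Down-regulation uses the
#' monotonically decreasing form
#' \deqn{g(C) = a e^{-bC} + c,}
#' bounded in \eqn{(c, a + c]}, and up-regulation uses the saturating form
#' \deqn{g(C) = 1 + a C/(1 + C),}
#' which equals 1 at zero regulator concentration and saturates at
#' \eqn{1 + a}.  The concentration \code{conc} must already be expressed in
#' the unit the coefficients were fitted in (see
#' \code{\link{convert_regulator_concentration}}).
#'
#' @param a,b,c non-negative fit coefficients.  \code{b} and \code{c} apply
#'   to down-regulation only.
#' @param conc regulator concentration (non-negative) in the fitted unit.
#' @return Dimensionless production multiplier.
#' @export
#' @examples
#' eval_down_feedback(0.7, 0.1, 0.3, 10)  # 0.7*exp(-1) + 0.3
#' eval_up_feedback(2, 1)                 # 2: half-saturation at conc = 1
eval_down_feedback <- function(a, b, c, conc) {
  if (any(conc < 0)) stop("regulator concentration must be non-negative")
  a * exp(-b * conc) + c
}

#' @rdname eval_down_feedback
#' @export
eval_up_feedback <- function(a, conc) {
  if (any(conc < 0)) stop("regulator concentration must be non-negative")
  1 + a * conc / (1 + conc)
}

#' Molecular weights used for hormone unit conversion, g/mol.
#' @keywords internal
.hormone_mw <- c(E2 = 272.38, P4 = 314.46, T = 288.42)

#' Convert a regulator concentration to the unit a feedback fit declares
#'
#' Mediator concentrations are carried internally in pg/mL and hormone
#' scenarios in pM (estrogen, progesterone) or nM (testosterone), but each
#' feedback fit declares the unit its coefficients were estimated in.
#' Supported units: \code{pg/mL}, \code{ng/mL} for mass concentrations and
#' \code{pM}, \code{nM}, \code{pg/mL} for hormones (molar to mass via the
#' hormone's molecular weight).
#'
#' @param value concentration value(s).
#' @param from,to unit strings.
#' @param regulator species or hormone id; required when converting between
#'   molar and mass units.
#' @return Converted concentration.
#' @export
#' @examples
#' convert_regulator_concentration(1500, "pg/mL", "ng/mL")
#' convert_regulator_concentration(1000, "pM", "nM")
convert_regulator_concentration <- function(value, from, to, regulator = NULL) {
  if (from == to) return(value)
  mass <- c("pg/mL" = 1, "ng/mL" = 1e3)    # pg per unit
  molar <- c("pM" = 1e-3, "nM" = 1)        # nM per unit
  if (from %in% names(mass) && to %in% names(mass))
    return(value * mass[[from]] / mass[[to]])
  if (from %in% names(molar) && to %in% names(molar))
    return(value * molar[[from]] / molar[[to]])
  # molar <-> mass needs a molecular weight
  if (is.null(regulator) || !regulator %in% names(.hormone_mw))
    stop("cannot convert between ", from, " and ", to,
         " without a known molecular weight")
  mw <- .hormone_mw[[regulator]]
  if (from %in% names(molar) && to %in% names(mass)) {
    nm <- value * molar[[from]]   # 1 nM of a compound of weight mw == mw pg/mL
    return(nm * mw / mass[[to]])
  }
  if (from %in% names(mass) && to %in% names(molar)) {
    pg <- value * mass[[from]]
    return(pg / mw / molar[[to]])
  }
  stop("unsupported unit conversion: ", from, " -> ", to)
}
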