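# Parameter data model.
#
# A complete parameter set resolves every rate symbol appearing in the model
# equations exactly once:
#   - production coefficients k_<substance>_<cell> (pg/cell/h),
#   - decay coefficients k_d_<substance>, k_d_P, k_d_M (1/h),
#   - feedback fits g_/f_<regulator>_<target> ((a,b,c) triples),
#   - chemotaxis/conversion scales k_M_in, k_M1M2 and their saturating
#     drive functions f_TGF_M1, f_TNF_M1, f_M1M2,
#   - scalar constants (SF concentration, initial platelet load, platelet
#     gating threshold, monocyte transformation delay).

#' Structural tables of the model's rate symbols
#'
#' \code{production_structure()} lists the (substance, cell) production
#' terms that exist in the mediator rate equations; notably MMP-9 has no
#' synovial-fibroblast term and MMP-1 no M2 term.
#' \code{feedback_structure()} lists every feedback edge with its regulator,
#' target substance, producing cell and direction.  Hormone edges follow the
#' network wiring: estrogen up-regulates M1 IL-1beta and down-regulates M1
#' IL-10 and IL-6; testosterone up-regulates M1 IL-10 and down-regulates M1
#' TNF-alpha; progesterone down-regulates M1 TNF-alpha and IL-6.
#'
#' @return A data.frame describing the required symbols.
#' @export
#' @examples
#' production_structure()
#' subset(feedback_structure(), regulator %in% hormone_ids())
production_structure <- function() {
  df <- rbind(
    data.frame(substance = "IL1",   cell = c("M1", "M2", "SF")),
    data.frame(substance = "TNF",   cell = c("M1", "M2", "SF")),
    data.frame(substance = "IL6",   cell = c("M1", "M2", "SF")),
    data.frame(substance = "IL10",  cell = c("M1", "M2", "SF")),
    data.frame(substance = "TGF",   cell = c("P", "M1", "M2", "SF")),
    data.frame(substance = "TIMP1", cell = c("M1", "M2", "SF")),
    data.frame(substance = "MMP9",  cell = c("M1", "M2")),
    data.frame(substance = "MMP1",  cell = c("M1", "SF"))
  )
  df$symbol <- paste0("k_", df$substance, "_", df$cell)
  rownames(df) <- NULL
  df[, c("symbol", "substance", "cell")]
}

#' @rdname production_structure
#' @export
feedback_structure <- function() {
  e <- function(symbol, regulator, target, cell, direction)
    data.frame(symbol = symbol, regulator = regulator, target = target,
               cell = cell, direction = direction)
  df <- rbind(
    # IL-1beta
    e("g_IL10_IL1",  "IL10", "IL1",   "M1", "down"),
    e("g_TGF_IL1",   "TGF",  "IL1",   "M1", "down"),
    e("f_E2_IL1",    "E2",   "IL1",   "M1", "up"),
    e("f_IL6_IL1",   "IL6",  "IL1",   "M1", "up"),
    e("f_TNF_IL1",   "TNF",  "IL1",   "SF", "up"),
    e("f_IL1_IL1",   "IL1",  "IL1",   "SF", "up"),
    # TNF-alpha
    e("g_IL10_TNF",  "IL10", "TNF",   "M1", "down"),
    e("g_TGF_TNF",   "TGF",  "TNF",   "M1", "down"),
    e("f_IL6_TNF",   "IL6",  "TNF",   "M1", "up"),
    e("g_T_TNF",     "T",    "TNF",   "M1", "down"),
    e("g_PR_TNF",    "P4",   "TNF",   "M1", "down"),
    e("f_IL1_TNF",   "IL1",  "TNF",   "SF", "up"),
    # IL-6
    e("g_IL10_IL6",  "IL10", "IL6",   "M1", "down"),
    e("f_TGF_IL6",   "TGF",  "IL6",   "M1", "up"),
    e("g_E_IL6",     "E2",   "IL6",   "M1", "down"),
    e("g_PR_IL6",    "P4",   "IL6",   "M1", "down"),
    e("f_IL1_IL6",   "IL1",  "IL6",   "SF", "up"),
    e("f_TNF_IL6",   "TNF",  "IL6",   "SF", "up"),
    # IL-10
    e("f_TGF_IL10",  "TGF",  "IL10",  "M1", "up"),
    e("f_T_IL10",    "T",    "IL10",  "M1", "up"),
    e("f_IL6_IL10",  "IL6",  "IL10",  "M1", "up"),
    e("g_E2_IL10",   "E2",   "IL10",  "M1", "down"),
    # TGF-beta
    e("f_TNF_TGF",   "TNF",  "TGF",   "SF", "up"),
    # TIMP-1 (cell-suffixed symbol names distinguish M1 from SF fits)
    e("g_TNF_TIMPa", "TNF",  "TIMP1", "M1", "down"),
    e("g_IL1_TIMPa", "IL1",  "TIMP1", "M1", "down"),
    e("g_IL10_TIMP", "IL10", "TIMP1", "M1", "down"),
    e("f_TNF_TIMPb", "TNF",  "TIMP1", "SF", "up"),
    e("f_IL1_TIMPb", "IL1",  "TIMP1", "SF", "up"),
    e("f_IL6_TIMP",  "IL6",  "TIMP1", "SF", "up"),
    # MMP-9
    e("f_IL1_MMP9",  "IL1",  "MMP9",  "M1", "up"),
    e("f_TNF_MMP9",  "TNF",  "MMP9",  "M1", "up"),
    e("g_IL6_MMP9",  "IL6",  "MMP9",  "M1", "down"),
    # MMP-1
    e("f_TNF_MMP1",  "TNF",  "MMP1",  "SF", "up"),
    e("f_IL1_MMP1",  "IL1",  "MMP1",  "SF", "up")
  )
  rownames(df) <- NULL
  df
}

.decay_symbols <- function() c("P", "M", mediator_ids())

#' Assemble and validate a complete parameter set
#'
#' @param production data.frame with columns \code{substance}, \code{cell},
#'   \code{value} (pg/cell/h) covering exactly the terms of
#'   \code{\link{production_structure}}.
#' @param decay named numeric vector of first-order rates (1/h) for
#'   \code{P}, \code{M} (shared by M1/M2) and every mediator; all positive.
#'   Synovial fibroblasts have no decay (their concentration is constant).
#' @param feedback data.frame with columns \code{regulator}, \code{target},
#'   \code{cell}, \code{direction}, \code{a}, \code{b}, \code{c},
#'   \code{regulator_units} covering exactly the edges of
#'   \code{\link{feedback_structure}}.
#' @param chemotaxis list with scalar rates \code{k_M_in} (cells/mL/h),
#'   \code{k_M1M2} (1/h), saturating drives \code{f_TGF_M1},
#'   \code{f_TNF_M1}, \code{f_M1M2} (each a list \code{(a, units)}),
#'   \code{platelet_threshold} (cells/mL) and \code{delay_tau} (h).
#' @param sf_concentration constant synovial fibroblast concentration,
#'   cells/mL.
#' @param platelet_initial platelet concentration used to initiate
#'   inflammation, cells/mL.
#' @return An object of class \code{synovial_params}.
#' @export
parameter_set <- function(production, decay, feedback, chemotaxis,
                          sf_concentration = 5e5,
                          platelet_initial = 2e8) {
  production <- as.data.frame(production)
  feedback <- as.data.frame(feedback)

  req <- production_structure()
  have <- paste0("k_", production$substance, "_", production$cell)
  if (anyDuplicated(have))
    stop("duplicate production entries: ",
         paste(unique(have[duplicated(have)]), collapse = ", "))
  missing <- setdiff(req$symbol, have)
  surplus <- setdiff(have, req$symbol)
  if (length(missing) || length(surplus))
    stop("incomplete production table",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(surplus)) paste0("; surplus: ", paste(surplus, collapse = ", ")))
  if (any(production$value < 0))
    stop("production coefficients must be non-negative")

  dreq <- .decay_symbols()
  if (anyDuplicated(names(decay)))
    stop("duplicate decay entries")
  dmiss <- setdiff(dreq, names(decay))
  dsur <- setdiff(names(decay), dreq)
  if (length(dmiss) || length(dsur))
    stop("incomplete decay table",
         if (length(dmiss)) paste0("; missing: ",
                                   paste(paste0("k_d_", dmiss), collapse = ", ")),
         if (length(dsur)) paste0("; surplus: ",
                                  paste(paste0("k_d_", dsur), collapse = ", ")))
  if (any(decay[dreq] <= 0))
    stop("decay coefficients must be positive")

  freq <- feedback_structure()
  fkey <- paste(feedback$regulator, feedback$target, feedback$cell)
  if (anyDuplicated(fkey))
    stop("duplicate feedback entries: ",
         paste(unique(fkey[duplicated(fkey)]), collapse = "; "))
  rkey <- paste(freq$regulator, freq$target, freq$cell)
  fmiss <- setdiff(rkey, fkey)
  fsur <- setdiff(fkey, rkey)
  if (length(fmiss) || length(fsur))
    stop("incomplete feedback table",
         if (length(fmiss)) paste0("; missing: ",
           paste(freq$symbol[match(fmiss, rkey)], collapse = ", ")),
         if (length(fsur)) paste0("; surplus: ", paste(fsur, collapse = "; ")))
  if (any(feedback$a < 0) || any(feedback$b < 0, na.rm = TRUE) ||
      any(feedback$c < 0, na.rm = TRUE))
    stop("feedback coefficients a, b, c must be non-negative")
  if (!all(feedback$direction %in% c("up", "down")))
    stop("feedback direction must be 'up' or 'down'")
  # carry the canonical symbol and order
  m <- match(rkey, fkey)
  feedback <- feedback[m, , drop = FALSE]
  feedback$symbol <- freq$symbol
  feedback$direction <- freq$direction[match(feedback$symbol, freq$symbol)]
  rownames(feedback) <- NULL

  for (nm in c("k_M_in", "k_M1M2", "platelet_threshold", "delay_tau"))
    if (is.null(chemotaxis[[nm]]) || chemotaxis[[nm]] < 0)
      stop("chemotaxis parameter ", nm, " missing or negative")
  for (nm in c("f_TGF_M1", "f_TNF_M1", "f_M1M2")) {
    fn <- chemotaxis[[nm]]
    if (is.null(fn) || is.null(fn$a) || fn$a < 0 || is.null(fn$units))
      stop("chemotactic drive ", nm, " must provide a non-negative 'a' and 'units'")
  }
  if (sf_concentration < 0 || platelet_initial < 0)
    stop("cell concentrations must be non-negative")

  production <- production[match(req$symbol, have),
                           c("substance", "cell", "value")]
  production$symbol <- req$symbol
  rownames(production) <- NULL

  structure(
    list(production = production,
         decay = decay[dreq],
         feedback = feedback[, c("symbol", "regulator", "target", "cell",
                                 "direction", "a", "b", "c",
                                 "regulator_units")],
         chemotaxis = chemotaxis,
         sf_concentration = sf_concentration,
         platelet_initial = platelet_initial),
    class = "synovial_params")
}

#' @export
print.synovial_params <- function(x, ...) {
  cat("Synovial inflammation model parameter set\n")
  cat(sprintf("  %d production terms, %d decay rates, %d feedback edges\n",
              nrow(x$production), length(x$decay), nrow(x$feedback)))
  cat(sprintf("  SF concentration: %.3g cells/mL; initial platelets: %.3g cells/mL\n",
              x$sf_concentration, x$platelet_initial))
  cat(sprintf("  monocyte delay: %g h; platelet gating threshold: %.3g cells/mL\n",
              x$chemotaxis$delay_tau, x$chemotaxis$platelet_threshold))
  invisible(x)
}

#' Look up a single coefficient by symbol
#'
#' @param params a \code{synovial_params} object.
#' @param symbol a symbol such as \code{"k_IL1_SF"}, \code{"k_d_TNF"} or
#'   \code{"k_M_in"}.
#' @return The coefficient value (for feedback symbols, the named vector
#'   \code{c(a, b, c)}).
#' @export
get_coefficient <- function(params, symbol) {
  if (symbol %in% params$production$symbol)
    return(params$production$value[params$production$symbol == symbol])
  if (grepl("^k_d_", symbol)) {
    id <- sub("^k_d_", "", symbol)
    if (id %in% names(params$decay)) return(unname(params$decay[id]))
  }
  if (symbol %in% c("k_M_in", "k_M1M2"))
    return(params$chemotaxis[[symbol]])
  i <- match(symbol, params$feedback$symbol)
  if (!is.na(i))
    return(c(a = params$feedback$a[i], b = params$feedback$b[i],
             c = params$feedback$c[i]))
  stop("unknown coefficient symbol: ", symbol)
}

#' Write and load parameter tables
#'
#' The on-disk form is a single columnar CSV (UTF-8, header row, one row
#' per symbol) with columns \code{symbol, kind, substance, cell, regulator,
#' direction, value, a, b, c, units, note}, chosen for diffability against
#' transcribed coefficient tables.  \code{load_parameter_set} validates
#' completeness and reports every missing or surplus coefficient by symbol
#' name.
#'
#' @param params a \code{synovial_params} object.
#' @param path file path of the CSV.
#' @return \code{load_parameter_set}: a validated \code{synovial_params};
#'   \code{write_parameter_tables}: \code{path}, invisibly.
#' @export
#' @examples
#' p <- generate_nominal_parameters(seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_parameter_tables(p, f)
#' p2 <- load_parameter_set(f)
#' all.equal(p$production$value, p2$production$value)
write_parameter_tables <- function(params, path) {
  row <- function(symbol, kind, substance = "", cell = "", regulator = "",
                  direction = "", value = NA, a = NA, b = NA, c = NA,
                  units = "", note = "")
    data.frame(symbol = symbol, kind = kind, substance = substance,
               cell = cell, regulator = regulator, direction = direction,
               value = value, a = a, b = b, c = c, units = units,
               note = note)
  pr <- params$production
  fb <- params$feedback
  ch <- params$chemotaxis
  out <- rbind(
    row(pr$symbol, "production", substance = pr$substance, cell = pr$cell,
        value = pr$value, units = "pg/cell/h"),
    row(paste0("k_d_", names(params$decay)), "decay",
        substance = names(params$decay), value = unname(params$decay),
        units = "1/h"),
    row(fb$symbol, "feedback", substance = fb$target, cell = fb$cell,
        regulator = fb$regulator, direction = fb$direction,
        a = fb$a, b = fb$b, c = fb$c, units = fb$regulator_units),
    row("k_M_in", "chemotaxis", value = ch$k_M_in, units = "cells/mL/h"),
    row("k_M1M2", "chemotaxis", value = ch$k_M1M2, units = "1/h"),
    row("f_TGF_M1", "chemotaxis_drive", regulator = "TGF", direction = "up",
        a = ch$f_TGF_M1$a, units = ch$f_TGF_M1$units),
    row("f_TNF_M1", "chemotaxis_drive", regulator = "TNF", direction = "up",
        a = ch$f_TNF_M1$a, units = ch$f_TNF_M1$units),
    row("f_M1M2", "chemotaxis_drive", regulator = "IL10", direction = "up",
        a = ch$f_M1M2$a, units = ch$f_M1M2$units),
    row("platelet_threshold", "constant", value = ch$platelet_threshold,
        units = "cells/mL"),
    row("delay_tau", "constant", value = ch$delay_tau, units = "h"),
    row("sf_concentration", "constant", value = params$sf_concentration,
        units = "cells/mL"),
    row("platelet_initial", "constant", value = params$platelet_initial,
        units = "cells/mL")
  )
  out <- out[order(out$symbol), ]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_parameter_tables
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("symbol", "kind", "substance", "cell", "regulator", "direction",
            "value", "a", "b", "c", "units")
  if (!all(need %in% names(tab)))
    stop("parameter file lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (anyDuplicated(tab$symbol))
    stop("duplicate entries for symbol(s): ",
         paste(unique(tab$symbol[duplicated(tab$symbol)]), collapse = ", "))

  pick <- function(kind) tab[tab$kind == kind, , drop = FALSE]
  pr <- pick("production")
  production <- data.frame(substance = pr$substance, cell = pr$cell,
                           value = pr$value)
  de <- pick("decay")
  decay <- stats::setNames(de$value, de$substance)
  fb <- pick("feedback")
  feedback <- data.frame(regulator = fb$regulator, target = fb$substance,
                         cell = fb$cell, direction = fb$direction,
                         a = fb$a, b = fb$b, c = fb$c,
                         regulator_units = fb$units)
  cd <- pick("chemotaxis_drive")
  drive <- function(sym) {
    i <- match(sym, cd$symbol)
    if (is.na(i)) stop("completeness error; missing symbol: ", sym)
    list(a = cd$a[i], units = cd$units[i])
  }
  const <- function(sym, kind = "constant") {
    i <- match(sym, tab$symbol)
    if (is.na(i)) stop("completeness error; missing symbol: ", sym)
    tab$value[i]
  }
  chemotaxis <- list(
    k_M_in = const("k_M_in"), k_M1M2 = const("k_M1M2"),
    f_TGF_M1 = drive("f_TGF_M1"), f_TNF_M1 = drive("f_TNF_M1"),
    f_M1M2 = drive("f_M1M2"),
    platelet_threshold = const("platelet_threshold"),
    delay_tau = const("delay_tau"))
  parameter_set(production, decay, feedback, chemotaxis,
                sf_concentration = const("sf_concentration"),
                platelet_initial = const("platelet_initial"))
}
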