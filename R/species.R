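#' Species identifiers of the synovial inflammation network
#'
#' The model tracks 12 state variables: four cell pools (platelets \code{P},
#' pro-inflammatory \code{M1} and anti-inflammatory \code{M2} macrophages,
#' synovial fibroblasts \code{SF}, all in cells/mL) and eight soluble
#' mediators (\code{IL1}, \code{TNF}, \code{IL6}, \code{IL10}, \code{TGF},
#' \code{TIMP1}, \code{MMP9}, \code{MMP1}, all in pg/mL).
#'
#' @return Character vector of the 12 species identifiers, in canonical
#'   state-vector order (cells first, then mediators).
#' @export
#' @examples
#' species_ids()
#' mediator_ids()
species_ids <- function() {
  c("P", "M1", "M2", "SF",
    "IL1", "TNF", "IL6", "IL10", "TGF", "TIMP1", "MMP9", "MMP1")
}

#' @rdname species_ids
#' @export
cell_ids <- function() c("P", "M1", "M2", "SF")

#' @rdname species_ids
#' @export
mediator_ids <- function() {
  c("IL1", "TNF", "IL6", "IL10", "TGF", "TIMP1", "MMP9", "MMP1")
}

#' Hormone identifiers
#'
#' \code{E2} estrogen (17-beta-estradiol), \code{P4} progesterone, \code{T}
#' testosterone.  Hormones are model inputs held constant over a simulation,
#' not state variables.
#'
#' @return Character vector of the three hormone identifiers.
#' @export
hormone_ids <- function() c("E2", "P4", "T")

# index helpers used throughout the RHS assembly
.sp_index <- function(id) match(id, species_ids())
.med_index <- function(id) match(id, mediator_ids())
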