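#' Tubulin sequestration state
#'
#' Describes a reaction in which stathmin sequesters free tubulin with a
#' fixed stoichiometry (by default two tubulin dimers removed per
#' stathmin molecule). `stathmin_added` supports assays where exogenous
#' stathmin is spiked on top of an endogenous pool; the effective
#' stathmin concentration is their sum.
#'
#' @param tubulin_total total tubulin, uM.
#' @param stathmin endogenous (or total) stathmin, uM.
#' @param stathmin_added exogenous stathmin added on top, uM (default 0).
#' @param stoichiometry tubulin dimers removed per stathmin (default 2).
#' @return An object of class `sequestration_state` with fields
#'   `tubulin_total`, `stathmin` (effective total), `stoichiometry` and
#'   the derived `tubulin_free`.
#' @examples
#' st <- sequestration_state(15, 4)      # 8 uM removed, 7 uM free
#' st$tubulin_free
#' sequestration_state(15, 1.5, stathmin_added = 2.7)$stathmin  # 4.2 uM
#' @export
sequestration_state <- function(tubulin_total, stathmin, stathmin_added = 0,
                                stoichiometry = 2) {
  .check_scalar(tubulin_total, "tubulin_total", lower = 0)
  .check_scalar(stathmin, "stathmin", lower = 0)
  .check_scalar(stathmin_added, "stathmin_added", lower = 0)
  .check_scalar(stoichiometry, "stoichiometry", lower = 0)
  total_stathmin <- stathmin + stathmin_added
  st <- structure(list(tubulin_total = tubulin_total,
                       stathmin = total_stathmin,
                       stoichiometry = stoichiometry,
                       tubulin_free = NA_real_),
                  class = "sequestration_state")
  st$tubulin_free <- free_tubulin(st)
  st
}

#' Free tubulin after stathmin sequestration
#'
#' Each stathmin molecule removes `stoichiometry` tubulin dimers from
#' the polymerization-competent pool, so
#' `tubulin_free = max(0, tubulin_total - stoichiometry * stathmin)`.
#' The floor at zero reflects that concentrations cannot be negative
#' when stathmin is in excess.
#'
#' @param state a [sequestration_state()] object.
#' @return Free tubulin concentration, uM.
#' @examples
#' free_tubulin(sequestration_state(15, 4))   # 7 uM
#' @export
free_tubulin <- function(state) {
  if (!inherits(state, "sequestration_state"))
    stop("'state' must be a sequestration_state", call. = FALSE)
  max(0, state$tubulin_total - state$stoichiometry * state$stathmin)
}

#' Fold change relative to a reference
#'
#' @param value measured value.
#' @param reference reference (control) value; must be > 0.
#' @return `value / reference` (dimensionless), vectorized over `value`.
#' @examples
#' fold_change(24.5, 1.2)   # ~20-fold
#' @export
fold_change <- function(value, reference) {
  .check_scalar(reference, "reference", lower = 0, strict = TRUE)
  if (!is.numeric(value)) stop("'value' must be numeric", call. = FALSE)
  value / reference
}

#' Activator-dimer occupancy of a nucleator pool
#'
#' Given the concentration of activator dimers co-purifying with a pool
#' of nucleation templates, returns the fraction of templates that
#' retained their dimer (capped at 1) and the fraction that lost it.
#' With 50 nM dimer over 150 nM templates, a third retained the dimer
#' and two thirds lost it.
#'
#' @param dimer_conc activator dimer concentration, nM (>= 0).
#' @param template_conc nucleator (template) concentration, nM (> 0).
#' @return List with `retained` and `lost` fractions (both in `[0, 1]`).
#' @examples
#' dimer_occupancy(50, 150)
#' @export
dimer_occupancy <- function(dimer_conc, template_conc) {
  .check_scalar(dimer_conc, "dimer_conc", lower = 0)
  .check_scalar(template_conc, "template_conc", lower = 0, strict = TRUE)
  retained <- min(1, dimer_conc / template_conc)
  list(retained = retained, lost = 1 - retained)
}
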