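#' Flow-condition labels
#'
#' The four flow states, ordered from no flow to high flow.  The ordering
#' matters: majority voting over chunks resolves ties toward the
#' lower-flow class, the conservative call for occlusion screening.
#'
#' @return Character vector `c("ZERO", "LOW", "MEDIUM", "HIGH")`.
#' @export
condition_levels <- function() c("ZERO", "LOW", "MEDIUM", "HIGH")

#' Velocity ranges defining each flow condition
#'
#' Cross-sectional mean velocity intervals (cm/s) assigned to each flow
#' state, per vessel diameter.  Zero flow (full occlusion) is the
#' degenerate interval `{0}`.
#'
#' @param diameter_mm Vessel inner diameter in mm, 3 or 6.  `NULL` (the
#'   default) returns the table for both diameters.
#' @return A data frame with columns `diameter_mm`, `condition`,
#'   `vmin`, `vmax` (cm/s).
#' @export
flow_conditions <- function(diameter_mm = NULL) {
  tab <- data.frame(
    diameter_mm = rep(c(3, 6), each = 4L),
    condition   = rep(condition_levels(), 2L),
    vmin        = c(0, 4.2, 27, 83, 0, 2.7, 21, 61),
    vmax        = c(0, 6.8, 54, 111, 0, 3.8, 39, 78),
    stringsAsFactors = FALSE
  )
  if (is.null(diameter_mm)) return(tab)
  out <- tab[tab$diameter_mm == diameter_mm, , drop = FALSE]
  if (nrow(out) == 0L)
    stopf("no flow conditions defined for diameter %g mm (use 3 or 6)",
          diameter_mm)
  rownames(out) <- NULL
  out
}

#' Midpoint velocity of a flow condition
#'
#' @param diameter_mm Vessel diameter in mm (3 or 6).
#' @param condition One of [condition_levels()].
#' @return Midpoint of the condition's velocity range, cm/s.
#' @export
condition_midpoint <- function(diameter_mm, condition) {
  tab <- flow_conditions(diameter_mm)
  row <- tab[tab$condition == condition, , drop = FALSE]
  if (nrow(row) == 0L) stopf("unknown flow condition '%s'", condition)
  (row$vmin + row$vmax) / 2
}

#' Draw a velocity from a condition's range
#'
#' Uniform draw from the condition's velocity interval (degenerate at 0
#' for `ZERO`).  Uses the current RNG state.
#'
#' @inheritParams condition_midpoint
#' @return Velocity in cm/s.
#' @export
draw_condition_velocity <- function(diameter_mm, condition) {
  tab <- flow_conditions(diameter_mm)
  row <- tab[tab$condition == condition, , drop = FALSE]
  if (nrow(row) == 0L) stopf("unknown flow condition '%s'", condition)
  if (row$vmin == row$vmax) row$vmin else stats::runif(1, row$vmin, row$vmax)
}
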