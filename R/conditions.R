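# Classed conditions so callers (and the solvers) can react to specific
# geometric failures instead of string-matching error messages.

stop_geobuild <- function(class, msg, call. = FALSE) {
  cond <- errorCondition(msg, class = c(class, "geobuild_error"))
  stop(cond)
}

#' @title Condition classes used by geobuild
#' @description
#' All errors signalled by the package carry the class `geobuild_error` plus
#' one specific class:
#' \describe{
#'   \item{`geobuild_degenerate_base`}{base points collinear/coplanar beyond tolerance}
#'   \item{`geobuild_not_realizable`}{a distance set admits no 3D embedding}
#'   \item{`geobuild_no_intersection`}{three spheres do not intersect}
#'   \item{`geobuild_ambiguous_placement`}{both mirror candidates match the reference distance}
#'   \item{`geobuild_inconsistent_distances`}{trilateration residual exceeds tolerance}
#'   \item{`geobuild_no_initial_base`}{no valid initial 4-clique in the distance graph}
#'   \item{`geobuild_parse_error`}{malformed input file}
#'   \item{`geobuild_generation_failure`}{synthetic generator exhausted its retry budget}
#'   \item{`geobuild_mismatched_atoms`}{structures being compared differ in atoms}
#' }
#' Warnings of class `geobuild_rank_deficient` flag superpositions whose
#' rotation is not unique.
#' @name geobuild-conditions
#' @keywords internal
NULL
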