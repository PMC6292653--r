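#' Two-state coupling response as a function of P_RR
#'
#' For a pure two-state (MWC-like) system with only RR and TT populated,
#' the coupling response under A-R binding is a closed function of the apo
#' RR probability and the ligand stabilisation:
#' \deqn{CR(P_{RR}) = \left[\frac{P_{RR} e^{-\Delta g/RT}}
#'   {1 - P_{RR} + P_{RR} e^{-\Delta g/RT}} - P_{RR}\right]
#'   \frac{1}{-\Delta g/RT}.}
#' It vanishes at both \eqn{P_{RR} = 0} and \eqn{P_{RR} = 1}: states that
#' are too stable or too unstable cannot be shifted.
#'
#' @param p_RR Apo probability of the RR state, in `[0, 1]` (vectorised).
#' @param dg_lig_A Ligand stabilising free energy, kcal/mol, < 0.
#' @param cond [conditions()].
#' @return CR values (dimensionless).
#' @examples
#' two_state_cr(0.081, -3)   # ~ 0.172, the maximum at dg = -3 kcal/mol
#' @export
two_state_cr <- function(p_RR, dg_lig_A, cond = conditions()) {
  if (any(p_RR < 0 | p_RR > 1)) stop("'p_RR' must lie in [0, 1]")
  if (dg_lig_A >= 0) stop("'dg_lig_A' must be < 0")
  x <- -dg_lig_A / cond$RT
  f <- exp(x)
  (p_RR * f / (1 - p_RR + p_RR * f) - p_RR) / x
}

#' Maximal coupling response
#'
#' The analytic maximum of the two-state coupling response over all state
#' stabilities,
#' \deqn{CR_{max} = \frac{(e^{-\Delta g/2RT} - 1)^2}
#'   {(-\Delta g/RT)(e^{-\Delta g/RT} - 1)},}
#' which also bounds `|CR|` for the full seven-state ensemble: no choice of
#' the six stability parameters can exceed it.  It decreases monotonically
#' with \eqn{-\Delta g_{Lig,A}/RT} and evaluates to 0.172 at
#' \eqn{\Delta g_{Lig,A} = -3} kcal/mol and 310.15 K.
#'
#' @inheritParams two_state_cr
#' @return The maximal CR (dimensionless).
#' @examples
#' cr_max(-3)          # 0.172
#' @export
cr_max <- function(dg_lig_A, cond = conditions()) {
  if (any(dg_lig_A >= 0)) stop("'dg_lig_A' must be < 0")
  x <- -dg_lig_A / cond$RT
  expm1(x / 2)^2 / (x * expm1(x))
}

#' Optimal P_RR for maximal coupling
#'
#' The apo RR probability at which the two-state coupling response attains
#' [cr_max()]:
#' \deqn{P_{RR}^{opt} = \frac{e^{-\Delta g/2RT} - 1}{e^{-\Delta g/RT} - 1}.}
#' At \eqn{\Delta g_{Lig,A} = -3} kcal/mol and 310.15 K this is 0.081 — the
#' optimally allosteric system keeps its substrate-competent state rare.
#'
#' @inheritParams two_state_cr
#' @return The optimal apo RR probability.
#' @examples
#' p_rr_opt(-3)        # 0.081
#' @export
p_rr_opt <- function(dg_lig_A, cond = conditions()) {
  if (any(dg_lig_A >= 0)) stop("'dg_lig_A' must be < 0")
  x <- -dg_lig_A / cond$RT
  expm1(x / 2) / expm1(x)
}

#' Two-state probability from a free-energy difference
#'
#' Logistic map between the RR/TT free-energy difference
#' \eqn{\Delta G_i = G_{RR} - G_{TT}} and the apo RR probability,
#' \eqn{P_{RR} = e^{-\Delta G_i/RT}/(e^{-\Delta G_i/RT} + 1)}.
#'
#' @param dG_i Free-energy difference `G_RR - G_TT`, kcal/mol (vectorised).
#' @param cond [conditions()].
#' @return Probabilities in (0, 1).
#' @seealso [p_rr_to_dG()] for the inverse.
#' @examples
#' p_rr_from_dG(0)     # 0.5
#' @export
p_rr_from_dG <- function(dG_i, cond = conditions()) {
  stats::plogis(-dG_i / cond$RT)
}

#' Free-energy difference from a two-state probability
#'
#' Inverse of [p_rr_from_dG()]: \eqn{\Delta G_i = -RT\,
#' \ln(P_{RR}/(1 - P_{RR}))}.
#'
#' @param p_RR Probability in (0, 1) (vectorised).
#' @param cond [conditions()].
#' @return Free-energy differences, kcal/mol.
#' @export
p_rr_to_dG <- function(p_RR, cond = conditions()) {
  if (any(p_RR <= 0 | p_RR >= 1)) stop("'p_RR' must lie strictly in (0, 1)")
  -cond$RT * stats::qlogis(p_RR)
}
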