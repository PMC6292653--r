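#' Free energy of a protein state
#'
#' Free energy (kcal/mol) of one of the seven apo states of the two-domain
#' ensemble, relative to the fully ordered RR reference state.  Each state
#' is named by the conformations of the allosteric and the functional
#' domain, e.g. `"TI"` = allosteric domain tense, functional domain
#' disordered.  `"RT"` and `"TR"` are forbidden: R and T interfaces are
#' incompatible, as in the concerted MWC picture.
#'
#' @param state Character vector of state labels among
#'   `"RR","RI","IR","II","TI","IT","TT"`.
#' @param params [free_energy_params()].
#' @return Numeric vector of free energies, kcal/mol.
#' @examples
#' p <- free_energy_params(dG_RT1 = 1, dG_RT2 = 3, dg_int_R = 2, dg_int_T = 5)
#' state_free_energy("TT", p)   # 1 + 3 + 2 - 5 = 1
#' @export
state_free_energy <- function(state, params) {
  params <- as_params(params)
  if (any(state %in% c("RT", "TR")))
    stop("states RT and TR are forbidden: R and T interfaces are incompatible")
  bad <- setdiff(state, STATE_NAMES)
  if (length(bad))
    stop("unknown state(s): ", paste(bad, collapse = ", "))
  G <- state_energy_matrix(matrix(unclass(params), nrow = 1L))
  unname(G[1L, state])
}

new_distribution <- function(p, params, ligand, cond, log_Q) {
  structure(list(probabilities = p, params = params, ligand = ligand,
                 conditions = cond, log_partition = log_Q),
            class = "allo_distribution")
}

#' @export
print.allo_distribution <- function(x, digits = 4, ...) {
  cat(if (is.null(x$ligand)) "Apo ensemble distribution"
      else sprintf("Liganded ensemble distribution (%s mode)",
                   sub("_", "-", x$ligand$mode)), "\n")
  print(round(x$probabilities, digits))
  invisible(x)
}

#' Apo ensemble distribution
#'
#' Boltzmann probabilities of the seven ligand-free states,
#' \eqn{P_i = e^{-\Delta G_i/RT}/Q}.  Free energies are shifted by their
#' minimum before exponentiation, so arbitrarily large parameter magnitudes
#' cannot overflow; the probabilities are invariant under the shift.
#'
#' @inheritParams state_free_energy
#' @param cond [conditions()].
#' @return An `"allo_distribution"`: named probability vector over the
#'   seven states (summing to 1), the input provenance, and the log
#'   partition function.
#' @examples
#' apo_distribution(free_energy_params())$probabilities   # each 1/7
#' @export
apo_distribution <- function(params, cond = conditions()) {
  params <- as_params(params)
  core <- ensemble_core(matrix(unclass(params), nrow = 1L), "A_R", -1, cond$RT)
  new_distribution(core$apo[1L, ], params, NULL, cond, core$log_Q_apo[1L])
}

#' Liganded ensemble distribution
#'
#' Ensemble distribution in the presence of the allosteric ligand A.  Each
#' binding-competent state (allosteric domain R in A-R mode, T in A-T mode)
#' is split into a free and a bound form; the bound form carries the extra
#' statistical weight \eqn{(e^{-\Delta g_{Lig,A}/RT} - 1)} times the apo
#' weight, so the free+bound pair together is the apo weight multiplied by
#' \eqn{e^{-\Delta g_{Lig,A}/RT} = 1 + K_{a,A}[A]}.  The result is
#' renormalised over nine states (seven apo + two bound).
#'
#' @inheritParams apo_distribution
#' @param ligand [ligand_conditions()].
#' @return An `"allo_distribution"` over nine states; bound states are
#'   labelled `"ARR","ARI"` (A-R mode) or `"ATT","ATI"` (A-T mode).
#' @examples
#' liganded_distribution(free_energy_params(),
#'                       ligand_conditions("A_R", dg_lig_A = -3))
#' @export
liganded_distribution <- function(params, ligand, cond = conditions()) {
  params <- as_params(params)
  stopifnot(inherits(ligand, "ligand_conditions"))
  core <- ensemble_core(matrix(unclass(params), nrow = 1L),
                        ligand$mode, ligand$dg_lig_A, cond$RT)
  new_distribution(core$lig[1L, ], params, ligand, cond, NA_real_)
}

#' Allosteric coupling response (CR)
#'
#' The central response measure of the model: the ligand-induced change in
#' the total probability of substrate-competent states (functional domain
#' in the R state), normalised by the dimensionless ligand stabilisation,
#' \deqn{CR = \frac{P_{X,[A]} - P_{X,[A]=0}}{-\Delta g_{Lig,A}/RT}.}
#' In A-R mode the bound ARR state is substrate-competent and counts in
#' \eqn{P_{X,[A]}}; ARI is not (its functional domain is disordered).
#'
#' @inheritParams liganded_distribution
#' @return An object of class `"allo_cr"`: list with `cr`,
#'   `p_X_with_ligand`, `p_X_without_ligand`, `mode`, and the two
#'   distributions.
#' @examples
#' cr <- coupling_response(free_energy_params(dG_R1 = -1, dG_R2 = 1.3,
#'                                            dG_RT1 = 1, dG_RT2 = 3),
#'                         ligand_conditions("A_R", dg_lig_A = -3))
#' cr$cr
#' @export
coupling_response <- function(params, ligand, cond = conditions()) {
  params <- as_params(params)
  stopifnot(inherits(ligand, "ligand_conditions"))
  if (ligand$dg_lig_A == 0)
    stop("dg_lig_A = 0 makes CR 0/0; use ka_times_conc > 0")
  core <- ensemble_core(matrix(unclass(params), nrow = 1L),
                        ligand$mode, ligand$dg_lig_A, cond$RT)
  structure(list(cr = core$cr_tot[1L],
                 p_X_with_ligand = core$px_lig[1L],
                 p_X_without_ligand = core$px_apo[1L],
                 mode = ligand$mode,
                 apo = core$apo[1L, ], liganded = core$lig[1L, ],
                 params = params, ligand = ligand, conditions = cond),
            class = "allo_cr")
}

#' @export
print.allo_cr <- function(x, digits = 5, ...) {
  cat(sprintf("Allosteric coupling response (%s mode)\n",
              sub("_", "-", x$mode)))
  cat(sprintf("  CR = %.*f   (P_X: %.*f apo -> %.*f liganded)\n",
              digits, x$cr, digits, x$p_X_without_ligand,
              digits, x$p_X_with_ligand))
  invisible(x)
}

#' Construct and evaluate one allosteric system
#'
#' Convenience constructor bundling one point in parameter space with its
#' ligand conditions and evaluating the whole model at once: state
#' distributions, total and per-subsystem coupling responses, pathway
#' weights, category label, two-state transition label, and the
#' thermodynamic efficacy alpha.
#'
#' @inheritParams liganded_distribution
#' @param epsilon Degeneracy cutoff on `|CR_tot|` below which pathway
#'   weights (and the category label) are reported as undefined.
#' @return An object of class `"allosteric_system"`.
#' @examples
#' sys <- allosteric_system(free_energy_params(dG_R1 = -1, dG_R2 = 1.3,
#'                                             dG_RT1 = 1, dG_RT2 = 3,
#'                                             dg_int_R = 2, dg_int_T = 4),
#'                          ligand_conditions("A_R", dg_lig_A = -3))
#' summary(sys)
#' @export
allosteric_system <- function(params,
                              ligand = ligand_conditions("A_R", dg_lig_A = -3),
                              cond = conditions(), epsilon = 1e-4) {
  params <- as_params(params)
  core <- ensemble_core(matrix(unclass(params), nrow = 1L),
                        ligand$mode, ligand$dg_lig_A, cond$RT)
  defined <- abs(core$cr_tot[1L]) >= epsilon
  structure(list(
    params = params, ligand = ligand, conditions = cond,
    apo = core$apo[1L, ], liganded = core$lig[1L, ],
    cr = core$cr_tot[1L],
    subsystem_cr = c(MWC = core$cr_mwc[1L], EAM = core$cr_eam[1L],
                     OTHERS = core$cr_others[1L]),
    weights = if (defined)
      c(MWC = core$w_mwc[1L], EAM = core$w_eam[1L], OTHERS = core$w_others[1L])
    else c(MWC = NA_real_, EAM = NA_real_, OTHERS = NA_real_),
    category = classify_core(core, eps = epsilon)[1L],
    two_state = two_state_core(core)[1L],
    alpha = core$alpha[1L],
    epsilon = epsilon), class = "allosteric_system")
}

#' @export
print.allosteric_system <- function(x, ...) {
  cat("Two-domain allosteric ensemble system\n")
  print(x$params)
  print(x$ligand)
  cat(sprintf("  CR_tot = %.5f\n", x$cr))
  invisible(x)
}

#' @export
summary.allosteric_system <- function(object, digits = 4, ...) {
  x <- object
  print(x$params); print(x$ligand); print(x$conditions)
  cat("\nApo probabilities:\n");      print(round(x$apo, digits))
  cat("Liganded probabilities:\n");   print(round(x$liganded, digits))
  cat(sprintf("\nCR_tot = %.5f  (ln alpha = %.5f)\n", x$cr, log(x$alpha)))
  cat("Subsystem CR:\n"); print(round(x$subsystem_cr, digits))
  cat("Pathway weights:\n"); print(round(x$weights, digits))
  cat(sprintf("Category: %s;  two-state transition: %s\n",
              ifelse(is.na(x$category), "undefined (|CR| < epsilon)",
                     x$category),
              ifelse(is.na(x$two_state), "none", x$two_state)))
  invisible(x)
}

#' @export
coef.allosteric_system <- function(object, ...) unclass(object$params)
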