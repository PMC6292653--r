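#' Thermodynamic conditions
#'
#' Bundles the absolute temperature with the gas constant and their product
#' `RT`, the thermal energy that scales every Boltzmann factor in the model.
#'
#' @param temperature Absolute temperature in kelvin.  The default is the
#'   physiological 310.15 K used throughout the package.
#'
#' @return An object of class `"allo_conditions"`: a list with elements
#'   `temperature` (K), `R` (kcal/(mol K)) and `RT` (kcal/mol).
#' @examples
#' cond <- conditions()
#' cond$RT   # ~0.616 kcal/mol at 310.15 K
#' @export
conditions <- function(temperature = 310.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be a single positive number (kelvin)")
  R <- 1.9872e-3  # kcal/(mol K)
  structure(list(temperature = temperature, R = R, RT = R * temperature),
            class = "allo_conditions")
}

#' @export
print.allo_conditions <- function(x, ...) {
  cat(sprintf("Conditions: T = %.2f K, RT = %.5f kcal/mol\n",
              x$temperature, x$RT))
  invisible(x)
}

#' Stability free-energy parameters of the seven-state ensemble
#'
#' The six free energies (kcal/mol) that define one system, i.e. one point
#' in the parameter space of the comprehensive ensemble model:
#' unfolding free energies of the R state of each domain, R-to-T transition
#' free energies of each domain, and the free energies of breaking the
#' ordered RR and TT domain-domain interfaces.  All energies are taken
#' relative to the fully ordered, interface-bonded RR state.
#'
#' @param dG_R1,dG_R2 Free energy of unfolding the R state of domain 1
#'   (allosteric, ligand-binding) and domain 2 (functional,
#'   substrate-binding).
#' @param dG_RT1,dG_RT2 Free energy of the R-to-T transition of each domain.
#' @param dg_int_R,dg_int_T Free energy of breaking the RR / TT interface.
#'
#' @return An object of class `"free_energy_params"` (a named numeric
#'   vector of length 6).
#' @examples
#' free_energy_params()                     # uniform 1/7 ensemble
#' free_energy_params(dG_R1 = -1, dG_R2 = 1.3, dG_RT1 = 1, dG_RT2 = 3)
#' @export
free_energy_params <- function(dG_R1 = 0, dG_R2 = 0, dG_RT1 = 0,
                               dG_RT2 = 0, dg_int_R = 0, dg_int_T = 0) {
  p <- c(dG_R1 = dG_R1, dG_R2 = dG_R2, dG_RT1 = dG_RT1,
         dG_RT2 = dG_RT2, dg_int_R = dg_int_R, dg_int_T = dg_int_T)
  if (!is.numeric(p) || length(p) != 6L || any(!is.finite(p)))
    stop("all six free-energy parameters must be finite numbers (kcal/mol)")
  structure(p, class = "free_energy_params")
}

#' @export
print.free_energy_params <- function(x, ...) {
  cat("Free-energy parameters (kcal/mol):\n")
  print(format(round(unclass(x), 4)), quote = FALSE)
  invisible(x)
}

PARAM_NAMES <- c("dG_R1", "dG_R2", "dG_RT1", "dG_RT2", "dg_int_R", "dg_int_T")

as_params <- function(params) {
  if (inherits(params, "free_energy_params")) return(params)
  if (is.numeric(params) && length(params) == 6L) {
    if (!is.null(names(params)) && setequal(names(params), PARAM_NAMES))
      params <- params[PARAM_NAMES]
    return(do.call(free_energy_params, as.list(unname(params))))
  }
  stop("'params' must be a free_energy_params object or a numeric vector of length 6")
}

#' Allosteric ligand conditions
#'
#' Describes how the allosteric effector A engages the first (allosteric)
#' domain: the binding mode and the stabilising free energy it confers on
#' binding-competent states.  The stabilisation can be given either directly
#' as `dg_lig_A` or through the dimensionless product of the association
#' constant and the free ligand concentration, `ka_times_conc`; the two are
#' linked by
#' \deqn{\Delta g_{Lig,A} = -RT \ln(1 + K_{a,A}[A]),}
#' and whichever is omitted is derived from the other.
#'
#' @param mode `"A_R"` if A binds only the R state of the allosteric domain
#'   (activating for the order-order pathway), `"A_T"` if it binds only the
#'   T state (inhibiting).
#' @param dg_lig_A Stabilising free energy in kcal/mol; must be <= 0.
#'   Defaults to -3 kcal/mol when neither representation is supplied.
#' @param ka_times_conc `K_a,A * [A]`, dimensionless, >= 0.
#' @param cond [conditions()] used for the interconversion.
#'
#' @return An object of class `"ligand_conditions"`: list with `mode`,
#'   `dg_lig_A` and `ka_times_conc`.
#' @examples
#' ligand_conditions("A_R", dg_lig_A = -3)
#' ligand_conditions("A_R", ka_times_conc = 129.1)  # ~ -3 kcal/mol
#' @export
ligand_conditions <- function(mode = c("A_R", "A_T"), dg_lig_A = NULL,
                              ka_times_conc = NULL, cond = conditions()) {
  mode <- match.arg(mode)
  if (!is.null(dg_lig_A) && !is.null(ka_times_conc))
    stop("give exactly one of 'dg_lig_A' and 'ka_times_conc'")
  if (is.null(dg_lig_A) && is.null(ka_times_conc)) dg_lig_A <- -3.0
  if (is.null(dg_lig_A)) {
    if (ka_times_conc < 0) stop("'ka_times_conc' must be >= 0")
    dg_lig_A <- -cond$RT * log1p(ka_times_conc)
  } else {
    if (!is.finite(dg_lig_A) || dg_lig_A > 0)
      stop("'dg_lig_A' must be <= 0 (a stabilising free energy)")
    ka_times_conc <- expm1(-dg_lig_A / cond$RT)
  }
  structure(list(mode = mode, dg_lig_A = dg_lig_A,
                 ka_times_conc = ka_times_conc),
            class = "ligand_conditions")
}

#' @export
print.ligand_conditions <- function(x, ...) {
  cat(sprintf("Ligand: mode %s, dg_lig_A = %.4f kcal/mol (Ka[A] = %.4g)\n",
              sub("_", "-", x$mode), x$dg_lig_A, x$ka_times_conc))
  invisible(x)
}
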