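#' Coupling response of one allosteric subsystem
#'
#' Coupling response CR computed as if the named subsystem existed alone:
#' the apo Boltzmann weights are restricted to the subsystem's states, the
#' ligand stabilisation factor is applied to the subsystem's
#' binding-competent states, and probabilities are renormalised within the
#' subsystem.  The subsystems are MWC = \{RR, TT\} (order-order),
#' EAM = \{RR, RI, IR, II\} (order-disorder) and OTHERS = \{RR, TI, IT\}
#' (mixed).  In A-T mode the EAM subsystem has no T state, so the ligand
#' cannot shift it and its CR is identically 0.
#'
#' @param subsystem `"MWC"`, `"EAM"` or `"OTHERS"`.
#' @inheritParams coupling_response
#' @return The subsystem CR (dimensionless scalar).
#' @examples
#' p <- free_energy_params(dg_int_R = 2, dg_int_T = 4)
#' subsystem_cr("MWC", p, ligand_conditions("A_R", dg_lig_A = -3))
#' @export
subsystem_cr <- function(subsystem = c("MWC", "EAM", "OTHERS"),
                         params, ligand, cond = conditions()) {
  subsystem <- match.arg(subsystem)
  params <- as_params(params)
  core <- ensemble_core(matrix(unclass(params), nrow = 1L),
                        ligand$mode, ligand$dg_lig_A, cond$RT)
  switch(subsystem, MWC = core$cr_mwc[1L], EAM = core$cr_eam[1L],
         OTHERS = core$cr_others[1L])
}

#' Pathway weights of the comprehensive system
#'
#' Contribution ratio of each pathway to the total allosteric response,
#' \deqn{Weight_s = \min(P_{s,[A]=0},\, P_{s,[A]}) \times CR_s / CR_{tot},}
#' where \eqn{P_s} is the occupancy of the subsystem's states in the full
#' system (bound forms counted on the liganded side) and \eqn{CR_s} the
#' subsystem CR.  The three weights need not sum to 1 and individual
#' weights can be negative.  When \eqn{|CR_{tot}|} is below `epsilon` the
#' ratios are ill-defined and the weights are reported as `NA`.
#'
#' @inheritParams coupling_response
#' @param epsilon Degeneracy cutoff on `|CR_tot|`.
#' @return An object of class `"pathway_weights"`: list with `weights`
#'   (named vector MWC/EAM/OTHERS or `NA`s), `subsystem_cr`, `cr_tot`,
#'   `occupancy_apo`, `occupancy_liganded`, and `defined`.
#' @examples
#' p <- free_energy_params(dG_R1 = 30, dG_R2 = 30, dG_RT1 = 29, dG_RT2 = 29)
#' pathway_weights(p, ligand_conditions("A_R", dg_lig_A = -3))$weights
#' @export
pathway_weights <- function(params, ligand, cond = conditions(),
                            epsilon = 1e-4) {
  params <- as_params(params)
  core <- ensemble_core(matrix(unclass(params), nrow = 1L),
                        ligand$mode, ligand$dg_lig_A, cond$RT)
  defined <- abs(core$cr_tot[1L]) >= epsilon
  w <- c(MWC = core$w_mwc[1L], EAM = core$w_eam[1L],
         OTHERS = core$w_others[1L])
  if (!defined) w[] <- NA_real_
  structure(list(
    weights = w,
    subsystem_cr = c(MWC = core$cr_mwc[1L], EAM = core$cr_eam[1L],
                     OTHERS = core$cr_others[1L]),
    cr_tot = core$cr_tot[1L],
    occupancy_apo = core$occ_apo[1L, ],
    occupancy_liganded = core$occ_lig[1L, ],
    defined = defined, epsilon = epsilon), class = "pathway_weights")
}

#' @export
print.pathway_weights <- function(x, digits = 4, ...) {
  cat(sprintf("CR_tot = %.5f\n", x$cr_tot))
  if (x$defined) {
    cat("Pathway weights:\n"); print(round(x$weights, digits))
  } else {
    cat(sprintf("|CR_tot| < %g: pathway weights undefined\n", x$epsilon))
  }
  invisible(x)
}

#' Classify a system by subsystem and pathway mixing
#'
#' Two binary axes at fixed thresholds: a system is a *single subsystem*
#' (S) if any one subsystem holds more than 0.99 of the probability both
#' before and after ligand binding, otherwise *mixing* (M); it is a
#' *single pathway* (S) if one pathway weight exceeds 0.99 while the other
#' two have absolute value below 0.01, otherwise mixing.  The axes combine
#' into `"SS"`, `"SM"`, `"MS"` or `"MM"`.
#'
#' @inheritParams pathway_weights
#' @return One of `"SS","SM","MS","MM"`, or `NA` when `|CR_tot| < epsilon`
#'   (weights, hence the pathway axis, are then undefined).
#' @examples
#' classify_category(free_energy_params(),
#'                   ligand_conditions("A_R", dg_lig_A = -3))  # NA: CR ~ 0
#' @export
classify_category <- function(params, ligand, cond = conditions(),
                              epsilon = 1e-4) {
  params <- as_params(params)
  core <- ensemble_core(matrix(unclass(params), nrow = 1L),
                        ligand$mode, ligand$dg_lig_A, cond$RT)
  classify_core(core, eps = epsilon)[1L]
}

#' Detect a dominant two-state transition
#'
#' A system implements allostery through a simple two-state mechanism when
#' one pair of states holds more than 0.99 of the probability both apo and
#' liganded (bound forms counted with their parent state).  The candidate
#' pairs are the five ligand-driven transitions capable of affecting
#' substrate binding: `II->RR`, `TT->RR`, `TI->RR`, `IT->RR` (positive
#' response) and `IR->RI` (negative response).  If several pairs qualify
#' (possible only when they share a dominant state), the pair with the
#' largest combined occupancy is reported.
#'
#' @inheritParams coupling_response
#' @return The transition label, or `NA_character_` if no pair qualifies.
#' @examples
#' p <- free_energy_params(dG_R1 = 30, dG_R2 = 30, dG_RT1 = 28.6,
#'                         dG_RT2 = 28.6)  # ~ pure RR/TT
#' detect_two_state(p, ligand_conditions("A_R", dg_lig_A = -3))
#' @export
detect_two_state <- function(params, ligand, cond = conditions()) {
  params <- as_params(params)
  core <- ensemble_core(matrix(unclass(params), nrow = 1L),
                        ligand$mode, ligand$dg_lig_A, cond$RT)
  two_state_core(core)[1L]
}

#' Pathway capacity curve
#'
#' The probability, per CR bin, that a randomly drawn system exhibits a
#' response in that bin *via* a given pathway:
#' \eqn{P_s(CR) = \overline{Weight_s}(CR) \times P(CR)}, the bin-wise mean
#' pathway weight multiplied by the empirical CR density.  Rows with
#' undefined weights (degenerate `|CR| < epsilon`) are excluded from the
#' weight average; weights are not clipped, so capacities can be negative.
#'
#' @param samples A `"allo_samples"` table from [sample_systems()].
#' @param pathway `"MWC"`, `"EAM"` or `"OTHERS"`.
#' @param bin_width CR bin width (default 0.005).
#' @param range CR range covered by the bins.
#' @return A data frame with `cr_mid`, `density`, `mean_weight`, `capacity`.
#' @seealso [weight_vs_cr()], [cr_histogram()]
#' @export
pathway_capacity <- function(samples, pathway = c("MWC", "EAM", "OTHERS"),
                             bin_width = 0.005, range = c(-0.2, 0.2)) {
  pathway <- match.arg(pathway)
  wcol <- paste0("weight_", tolower(pathway))
  breaks <- seq(range[1L], range[2L], by = bin_width)
  dens <- cr_histogram(samples, bin_width = bin_width, range = range)
  bin <- cut(samples$cr_tot, breaks, include.lowest = TRUE)
  w <- samples[[wcol]]
  mw <- tapply(w, bin, mean, na.rm = TRUE, default = 0)
  mw[!is.finite(mw)] <- 0
  out <- dens
  out$mean_weight <- as.numeric(mw[as.character(dens$bin)])
  out$mean_weight[is.na(out$mean_weight)] <- 0
  out$capacity <- out$mean_weight * out$density
  out$pathway <- pathway
  out
}
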