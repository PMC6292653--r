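# Joint apo distribution over the domain-state alphabet {R, T, I}.
# Rows: allosteric domain (x); columns: functional domain (y).
# RT and TR entries are structurally zero.
domain_joint <- function(params, cond) {
  apo <- apo_distribution(params, cond)$probabilities
  J <- matrix(0, 3L, 3L, dimnames = list(c("R", "T", "I"), c("R", "T", "I")))
  for (s in STATE_NAMES) J[DOMAIN1[[s]], DOMAIN2[[s]]] <- apo[[s]]
  J
}

#' Thermodynamic allosteric efficacy
#'
#' The efficacy \eqn{\alpha = K_{bound}/K_{unbound}}, the fold-change in
#' the substrate-binding equilibrium constant caused by the allosteric
#' ligand.  On the apo ensemble of the comprehensive model (A-R
#' convention) it reduces to
#' \deqn{\alpha = \frac{P_{RR}\,P_{**}}{P_{R*}\,P_{*R}},}
#' where `*` marginalises a domain, and it obeys the identity
#' \eqn{\ln\alpha = -\Delta\Delta F_{RR}} (in RT units).  Unlike CR, which
#' measures a probability *difference*, alpha measures fold change and so
#' does not penalise rare-but-strongly-shifted states.
#'
#' @inheritParams apo_distribution
#' @return A list with `alpha` and `ln_alpha`.
#' @examples
#' efficacy_alpha(free_energy_params())$ln_alpha   # log(7/4)
#' @export
efficacy_alpha <- function(params, cond = conditions()) {
  J <- domain_joint(params, cond)
  a <- J["R", "R"] / (sum(J["R", ]) * sum(J[, "R"]))
  list(alpha = a, ln_alpha = log(a))
}

#' Thermodynamic coupling function and normalised coupling table
#'
#' For each pair of domain states (x, y), the thermodynamic coupling
#' function in RT units,
#' \deqn{\Delta\Delta F(x,y) = -\ln\frac{p(x,y)}{p(x)\,p(y)},}
#' and its normalised form
#' \eqn{AC(x,y) = \ln(p(x)p(y))/\ln p(x,y) - 1 \in [-1, 1]}.  Negative
#' \eqn{\Delta\Delta F} means the joint state is favoured over independent
#' domains.  Structurally forbidden pairs (RT, TR) have `-Inf` coupling
#' (`ddF = +Inf`), reported as computed.
#'
#' @inheritParams apo_distribution
#' @return An object of class `"coupling_table"`: list with 3x3 matrices
#'   `ddF` and `ac` (rows: allosteric domain; columns: functional domain),
#'   marginals `p_x`, `p_y`, and the joint `p_xy`.
#' @examples
#' ct <- coupling_table(free_energy_params())
#' round(ct$ddF, 2)    # ddF_RR = ddF_TT = -0.56, ddF_II = 0.25
#' @export
coupling_table <- function(params, cond = conditions()) {
  J <- domain_joint(params, cond)
  px <- rowSums(J)
  py <- colSums(J)
  ddF <- -log(J / outer(px, py))
  ac <- log(outer(px, py)) / log(J) - 1
  structure(list(ddF = ddF, ac = ac, p_x = px, p_y = py, p_xy = J),
            class = "coupling_table")
}

#' @export
print.coupling_table <- function(x, digits = 4, ...) {
  cat("Thermodynamic coupling function ddF (RT units):\n")
  print(round(x$ddF, digits))
  cat("Normalised allosteric coupling AC:\n")
  print(round(x$ac, digits))
  invisible(x)
}

#' Normalised allosteric coupling of one state pair
#'
#' \eqn{AC(x,y) = -\Delta\Delta F(x,y)/\Delta\Delta F_{max}(x,y)
#'   = \ln(p(x)p(y))/\ln p(x,y) - 1}, the fraction of the maximal possible
#' coupling realised by the joint state; ranges between -1 and 1.
#'
#' @param p_xy Joint probability of the state pair, in (0, 1).
#' @param p_x,p_y Marginal probabilities, in (0, 1).
#' @return AC value in `[-1, 1]`.
#' @examples
#' normalized_ac(1/7, 2/7, 2/7)
#' @export
normalized_ac <- function(p_xy, p_x, p_y) {
  if (any(c(p_x, p_y) <= 0 | c(p_x, p_y) >= 1))
    stop("marginals must lie strictly in (0, 1)")
  if (any(p_xy >= 1))
    stop("p_xy = 1 makes the normalisation ln(p_xy) vanish")
  if (any(p_xy <= 0)) stop("'p_xy' must be > 0")
  log(p_x * p_y) / log(p_xy) - 1
}

# Enumerate the allosteric Ising model (AIM) state space.
# Components: ligand a in {on = +1, off = -1}; domains sigma in
# {R = +1, T or I = -1}.  Pair energies (RT units):
#   E_AR * a * sigma1  (ligand-domain interface)
#   E_RR * sigma1 * sigma2  (domain-domain interface)
# MWC-AIM: both domains locked to a common spin (R or T), ligand free:
#   4 states.  EAM-AIM: domains independently R or I, but the ligand can
#   only be "on" when domain 1 is R: 6 states.
aim_states <- function(model) {
  if (model == "MWC") {
    st <- expand.grid(a = c(1, -1), s1 = c(1, -1), KEEP.OUT.ATTRS = FALSE)
    st$s2 <- st$s1
    st
  } else {
    st <- expand.grid(a = c(1, -1), s1 = c(1, -1), s2 = c(1, -1),
                      KEEP.OUT.ATTRS = FALSE)
    st[!(st$a == 1 & st$s1 == -1), ]           # no ligand on a disordered domain
  }
}

#' Allosteric efficacy of the Ising-interaction (AIM) variants
#'
#' Replaces the ensemble model's interaction scheme by Ising pair
#' couplings in the spirit of the allosteric Ising model: the ligand is a
#' regular two-state (on/off) component coupled to the first domain with
#' energy `e_ar` per spin product, and the two domains couple with `e_rr`
#' (both in RT units).  The MWC variant has 4 states (both domains locked
#' R or T); the EAM variant has 6 (domains R/I, ligand on requires domain
#' 1 ordered).  Alpha is the odds ratio of the functional domain being
#' substrate-competent with the ligand on versus off, computed by explicit
#' enumeration of the state space.  For the MWC variant this equals the
#' closed form \eqn{\alpha_{MWC} = e^{-4E_{AR}/RT}}.
#'
#' @param model `"MWC"` or `"EAM"`.
#' @param e_ar,e_rr Ising couplings of the ligand-domain and domain-domain
#'   interfaces, RT units.
#' @return A list with `alpha` and `ln_alpha`.
#' @examples
#' aim_alpha("MWC", e_ar = -1, e_rr = 0)$alpha   # exp(4)
#' @export
aim_alpha <- function(model = c("MWC", "EAM"), e_ar, e_rr) {
  model <- match.arg(model)
  st <- aim_states(model)
  wgt <- exp(-(e_ar * st$a * st$s1 + e_rr * st$s1 * st$s2))
  odds <- function(on) {
    sel <- st$a == (if (on) 1 else -1)
    sum(wgt[sel & st$s2 == 1]) / sum(wgt[sel & st$s2 == -1])
  }
  a <- odds(TRUE) / odds(FALSE)
  list(alpha = a, ln_alpha = log(a))
}

#' Potts interface couplings
#'
#' Interface interaction energies for the comprehensive model recast as a
#' Potts model (the >2-state generalisation of the Ising model): each
#' ordered-ordered domain pair gets a coupling energy, the disordered I
#' state never interacts, and the mixed R-T interface remains forbidden.
#' Only the `(R,R)` and `(T,T)` couplings can therefore take values; they
#' play the roles of \eqn{-\Delta g_{int,R}} and \eqn{-\Delta g_{int,T}}.
#'
#' @param e_rr,e_tt Couplings (kcal/mol) of the RR and TT interfaces.
#' @param ... Must be empty; supplying couplings for pairs involving I
#'   (e.g. `e_ri`) is an error.
#' @return An object of class `"potts_interface"`.
#' @export
potts_interface <- function(e_rr = 0, e_tt = 0, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unsupported Potts couplings (", paste(names(extra), collapse = ", "),
         "): the disordered I state carries no interface interaction and ",
         "the mixed R-T interface is forbidden")
  stopifnot(is.finite(e_rr), is.finite(e_tt))
  structure(list(e_rr = e_rr, e_tt = e_tt), class = "potts_interface")
}

#' Comprehensive-model response under a Potts interface
#'
#' Evaluates the full seven-state model with the two interface free
#' energies supplied as Potts couplings
#' (\eqn{\Delta g_{int,R} \mapsto -E(R,R)},
#' \eqn{\Delta g_{int,T} \mapsto -E(T,T)}); the ligand keeps its two-state
#' on/off treatment and is unaffected by the Potts scheme.  Couplings
#' involving the non-interacting I state are rejected.
#'
#' @param params Either a [free_energy_params()] whose interface entries
#'   are ignored, or a named numeric vector with `dG_R1`, `dG_R2`,
#'   `dG_RT1`, `dG_RT2`.
#' @param potts A [potts_interface()].
#' @inheritParams coupling_response
#' @inheritParams pathway_weights
#' @return A list with the `"allo_cr"` object (`cr`) and the
#'   `"pathway_weights"` object (`weights`).
#' @examples
#' p <- free_energy_params(dG_R1 = -1, dG_R2 = 1.3, dG_RT1 = 1, dG_RT2 = 3)
#' potts_comprehensive_cr(p, potts_interface(e_rr = -2, e_tt = -4),
#'                        ligand_conditions("A_R", dg_lig_A = -3))$cr$cr
#' @export
potts_comprehensive_cr <- function(params, potts, ligand,
                                   cond = conditions(), epsilon = 1e-4) {
  stopifnot(inherits(potts, "potts_interface"))
  if (is.numeric(params) && length(params) == 4L && !is.null(names(params)))
    params <- c(params, dg_int_R = 0, dg_int_T = 0)
  p <- unclass(as_params(params))
  full <- free_energy_params(p[["dG_R1"]], p[["dG_R2"]], p[["dG_RT1"]],
                             p[["dG_RT2"]],
                             dg_int_R = -potts$e_rr, dg_int_T = -potts$e_tt)
  list(cr = coupling_response(full, ligand, cond),
       weights = pathway_weights(full, ligand, cond, epsilon = epsilon),
       params = full)
}
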