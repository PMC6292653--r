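# Internal vectorised core of the seven-state ensemble model.
#
# Every user-facing quantity (state probabilities, coupling response CR,
# subsystem CRs, pathway weights, category labels, alpha) reduces to a few
# algebraic combinations of the seven apo Boltzmann weights and the ligand
# stabilisation factor, so they are computed here in one pass on an
# n x 6 parameter matrix.  Scalar API functions call this with n = 1;
# the Monte-Carlo sampler calls it with n up to 10^6.

STATE_NAMES <- c("RR", "RI", "IR", "II", "TI", "IT", "TT")

# domain state of each of the seven apo states
DOMAIN1 <- c(RR = "R", RI = "R", IR = "I", II = "I", TI = "T", IT = "I", TT = "T")
DOMAIN2 <- c(RR = "R", RI = "I", IR = "R", II = "I", TI = "I", IT = "T", TT = "T")

SUBSYSTEM_STATES <- list(
  MWC    = c("RR", "TT"),
  EAM    = c("RR", "RI", "IR", "II"),
  OTHERS = c("RR", "TI", "IT")
)

TWO_STATE_PAIRS <- list(
  "II->RR" = c("II", "RR"),
  "TT->RR" = c("TT", "RR"),
  "TI->RR" = c("TI", "RR"),
  "IT->RR" = c("IT", "RR"),
  "IR->RI" = c("IR", "RI")
)

# free energies of the seven states relative to RR, as an n x 7 matrix.
# P is an n x 6 matrix with columns dG_R1, dG_R2, dG_RT1, dG_RT2,
# dg_int_R, dg_int_T.  The expressions follow the thermodynamic cycle
# RR -> (break RR interface) -> unfold / switch domains -> (form TT
# interface for TT); disordered I domains and unpaired ordered domains
# carry no interface term.
state_energy_matrix <- function(P) {
  G <- cbind(
    RR = rep_len(0, nrow(P)),
    RI = P[, 2L] + P[, 5L],
    IR = P[, 1L] + P[, 5L],
    II = P[, 1L] + P[, 2L] + P[, 5L],
    TI = P[, 3L] + P[, 2L] + P[, 5L],
    IT = P[, 1L] + P[, 4L] + P[, 5L],
    TT = P[, 3L] + P[, 4L] + P[, 5L] - P[, 6L]
  )
  G
}

row_min <- function(G) do.call(pmin, as.data.frame(G))

# Full per-system evaluation.
# P: n x 6 numeric matrix (columns in free_energy_params order)
# mode: "A_R" or "A_T"; dg_lig: kcal/mol (< 0); RT: kcal/mol
ensemble_core <- function(P, mode, dg_lig, RT) {
  P <- as.matrix(P)
  n <- nrow(P)
  G <- state_energy_matrix(P)
  w <- exp(-(G - row_min(G)) / RT)          # n x 7, max entry = 1 per row
  colnames(w) <- STATE_NAMES
  S_apo <- rowSums(w)
  apo <- w / S_apo                           # apo probabilities

  f <- exp(-dg_lig / RT)                     # ligand stabilisation factor >= 1
  # parents of the bound states: domain-1 R states in A_R, T states in A_T
  parents <- if (mode == "A_R") c("RR", "RI") else c("TT", "TI")
  bound_names <- paste0("A", parents)
  wb <- (f - 1) * w[, parents, drop = FALSE] # bound-state weights
  colnames(wb) <- bound_names
  S_lig <- S_apo + rowSums(wb)
  lig <- cbind(w, wb) / S_lig                # liganded probabilities (9 states)

  inv <- -RT / dg_lig                        # 1 / (-dg_lig / RT)

  # total CR: X = substrate-competent states (domain 2 == R), bound ARR
  # counted in A_R mode only (ARI has a disordered functional domain)
  px_apo <- apo[, "RR"] + apo[, "IR"]
  px_lig <- lig[, "RR"] + lig[, "IR"] +
    (if (mode == "A_R") lig[, "ARR"] else 0)
  cr_tot <- (px_lig - px_apo) * inv

  # subsystem CRs: apo weights restricted to the subsystem, ligand factor
  # applied to the subsystem's binding-competent parents, renormalised
  # within the subsystem.
  if (mode == "A_R") {
    cr_mwc <- (f * w[, "RR"] / (f * w[, "RR"] + w[, "TT"]) -
                 w[, "RR"] / (w[, "RR"] + w[, "TT"])) * inv
    Se <- w[, "RR"] + w[, "RI"] + w[, "IR"] + w[, "II"]
    cr_eam <- ((f * w[, "RR"] + w[, "IR"]) /
                 (f * w[, "RR"] + f * w[, "RI"] + w[, "IR"] + w[, "II"]) -
                 (w[, "RR"] + w[, "IR"]) / Se) * inv
    So <- w[, "RR"] + w[, "TI"] + w[, "IT"]
    cr_oth <- (f * w[, "RR"] / (f * w[, "RR"] + w[, "TI"] + w[, "IT"]) -
                 w[, "RR"] / So) * inv
  } else {
    cr_mwc <- (w[, "RR"] / (w[, "RR"] + f * w[, "TT"]) -
                 w[, "RR"] / (w[, "RR"] + w[, "TT"])) * inv
    cr_eam <- numeric(n)                     # no T state: ligand blind
    So <- w[, "RR"] + w[, "TI"] + w[, "IT"]
    cr_oth <- (w[, "RR"] / (w[, "RR"] + f * w[, "TI"] + w[, "IT"]) -
                 w[, "RR"] / So) * inv
  }

  # subsystem occupancies in the full system (bound forms included on the
  # liganded side), used by the pathway weights and the category labels
  occ_apo <- cbind(
    MWC    = apo[, "RR"] + apo[, "TT"],
    EAM    = apo[, "RR"] + apo[, "RI"] + apo[, "IR"] + apo[, "II"],
    OTHERS = apo[, "RR"] + apo[, "TI"] + apo[, "IT"]
  )
  if (mode == "A_R") {
    occ_lig <- cbind(
      MWC    = lig[, "RR"] + lig[, "ARR"] + lig[, "TT"],
      EAM    = lig[, "RR"] + lig[, "ARR"] + lig[, "RI"] + lig[, "ARI"] +
        lig[, "IR"] + lig[, "II"],
      OTHERS = lig[, "RR"] + lig[, "ARR"] + lig[, "TI"] + lig[, "IT"]
    )
  } else {
    occ_lig <- cbind(
      MWC    = lig[, "RR"] + lig[, "TT"] + lig[, "ATT"],
      EAM    = lig[, "RR"] + lig[, "RI"] + lig[, "IR"] + lig[, "II"],
      OTHERS = lig[, "RR"] + lig[, "TI"] + lig[, "ATI"] + lig[, "IT"]
    )
  }

  ratio <- function(cr_sub) cr_sub / cr_tot
  w_mwc <- pmin(occ_apo[, "MWC"],    occ_lig[, "MWC"])    * ratio(cr_mwc)
  w_eam <- pmin(occ_apo[, "EAM"],    occ_lig[, "EAM"])    * ratio(cr_eam)
  w_oth <- pmin(occ_apo[, "OTHERS"], occ_lig[, "OTHERS"]) * ratio(cr_oth)

  # thermodynamic efficacy on the apo ensemble (A-R convention)
  pRdot <- apo[, "RR"] + apo[, "RI"]
  pdotR <- apo[, "RR"] + apo[, "IR"]
  alpha <- apo[, "RR"] / (pRdot * pdotR)

  # two-state pair occupancies (bound forms counted with their parents)
  pair_apo <- matrix(0, n, length(TWO_STATE_PAIRS),
                     dimnames = list(NULL, names(TWO_STATE_PAIRS)))
  pair_lig <- pair_apo
  for (nm in names(TWO_STATE_PAIRS)) {
    st <- TWO_STATE_PAIRS[[nm]]
    pair_apo[, nm] <- apo[, st[1L]] + apo[, st[2L]]
    s <- lig[, st[1L]] + lig[, st[2L]]
    for (p in intersect(st, parents)) s <- s + lig[, paste0("A", p)]
    pair_lig[, nm] <- s
  }

  v <- function(x) as.vector(x)
  list(apo = apo, lig = lig, log_Q_apo = v(log(S_apo) - row_min(G) / RT),
       px_apo = v(px_apo), px_lig = v(px_lig),
       cr_tot = v(cr_tot), cr_mwc = v(cr_mwc), cr_eam = v(cr_eam),
       cr_others = v(cr_oth),
       w_mwc = v(w_mwc), w_eam = v(w_eam), w_others = v(w_oth),
       occ_apo = occ_apo, occ_lig = occ_lig,
       alpha = v(alpha), pair_apo = pair_apo, pair_lig = pair_lig)
}

# category labels from engine output; eps is the |CR_tot| degeneracy cutoff
classify_core <- function(core, eps = 1e-4) {
  single_sub <- (core$occ_apo[, "MWC"] > 0.99 & core$occ_lig[, "MWC"] > 0.99) |
    (core$occ_apo[, "EAM"] > 0.99 & core$occ_lig[, "EAM"] > 0.99) |
    (core$occ_apo[, "OTHERS"] > 0.99 & core$occ_lig[, "OTHERS"] > 0.99)
  # single pathway: exactly one weight > 0.99 and the other two |w| < 0.01
  W <- cbind(core$w_mwc, core$w_eam, core$w_others)
  single_path <- rowSums(W > 0.99) == 1L & rowSums(abs(W) < 0.01) == 2L
  defined <- abs(core$cr_tot) >= eps
  lab <- ifelse(single_sub,
                ifelse(single_path, "SS", "SM"),
                ifelse(single_path, "MS", "MM"))
  lab[!defined] <- NA_character_
  lab
}

# two-state transition label (or NA) from engine output
two_state_core <- function(core) {
  ok <- core$pair_apo > 0.99 & core$pair_lig > 0.99
  score <- (core$pair_apo + core$pair_lig) * ok
  hit <- max.col(score, ties.method = "first")
  any_ok <- rowSums(ok) > 0L
  out <- rep(NA_character_, nrow(score))
  out[any_ok] <- colnames(score)[hit[any_ok]]
  out
}
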