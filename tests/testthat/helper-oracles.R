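# Independent brute-force oracles, written symbol-by-symbol from the model
# definition and kept deliberately separate from the package's vectorised
# engine: plain exponentials of the literal state free energies, no
# overflow shift, no shared code.

RTconst <- function(temp = 310.15) 1.9872e-3 * temp

# literal free energies of the seven apo states relative to RR
oracle_energies <- function(p) {
  c(RR = 0,
    RI = p[["dG_R2"]] + p[["dg_int_R"]],
    IR = p[["dG_R1"]] + p[["dg_int_R"]],
    II = p[["dG_R1"]] + p[["dG_R2"]] + p[["dg_int_R"]],
    TI = p[["dG_RT1"]] + p[["dG_R2"]] + p[["dg_int_R"]],
    IT = p[["dG_R1"]] + p[["dG_RT2"]] + p[["dg_int_R"]],
    TT = p[["dG_RT1"]] + p[["dG_RT2"]] + p[["dg_int_R"]] - p[["dg_int_T"]])
}

# enumerate the nine liganded statistical weights and return CR
oracle_cr <- function(p, dg_lig, mode = "A_R", temp = 310.15) {
  RT <- RTconst(temp)
  G <- oracle_energies(p)
  w <- exp(-G / RT)
  ka <- exp(-dg_lig / RT) - 1          # Ka,A x [A]
  parents <- if (mode == "A_R") c("RR", "RI") else c("TT", "TI")
  wb <- ka * w[parents]
  names(wb) <- paste0("A", parents)
  all_w <- c(w, wb)
  p_lig <- all_w / sum(all_w)
  p_apo <- w / sum(w)
  px_apo <- p_apo[["RR"]] + p_apo[["IR"]]
  px_lig <- p_lig[["RR"]] + p_lig[["IR"]] +
    if (mode == "A_R") p_lig[["ARR"]] else 0
  (px_lig - px_apo) / (-dg_lig / RT)
}

# two-state MWC-pair CR computed directly on the renormalised {RR, TT} pair
oracle_mwc_pair_cr <- function(p, dg_lig, mode = "A_R", temp = 310.15) {
  RT <- RTconst(temp)
  G <- oracle_energies(p)
  wRR <- exp(-G[["RR"]] / RT); wTT <- exp(-G[["TT"]] / RT)
  f <- exp(-dg_lig / RT)
  p_apo <- wRR / (wRR + wTT)
  p_lig <- if (mode == "A_R") f * wRR / (f * wRR + wTT)
           else wRR / (wRR + f * wTT)
  (p_lig - p_apo) / (-dg_lig / RT)
}

random_params <- function(dG_max = 8)
  free_energy_params(stats::runif(1, -dG_max, dG_max),
                     stats::runif(1, -dG_max, dG_max),
                     stats::runif(1, -dG_max, dG_max),
                     stats::runif(1, -dG_max, dG_max),
                     stats::runif(1, -dG_max, dG_max),
                     stats::runif(1, -dG_max, dG_max))

LIG_AR <- ligand_conditions("A_R", dg_lig_A = -3)
LIG_AT <- ligand_conditions("A_T", dg_lig_A = -3)
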