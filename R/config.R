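#' Load a run configuration from a YAML or JSON file
#'
#' Reads a structured configuration with the sections `params` (the six
#' free energies), `ligand` (`mode` and `dg_lig_A` *or* `ka_times_conc`),
#' `conditions` (`temperature`) and optionally `sampling` (arguments of
#' [sampling_config()]).  Missing sections get the package defaults
#' (T = 310.15 K, A-R mode, `dg_lig_A = -3` kcal/mol); unknown keys at any
#' level are rejected with a message naming the key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `"run_config"` with elements `params`,
#'   `ligand`, `conditions` and (optionally) `sampling`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) stop("config file is empty: ", path)
  check_keys(raw, c("params", "ligand", "conditions", "sampling"), "top level")

  pk <- raw$params %||% list()
  check_keys(pk, PARAM_NAMES, "params")
  params <- do.call(free_energy_params, pk)

  ck <- raw$conditions %||% list()
  check_keys(ck, "temperature", "conditions")
  cond <- conditions(ck$temperature %||% 310.15)

  lk <- raw$ligand %||% list()
  check_keys(lk, c("mode", "dg_lig_A", "ka_times_conc"), "ligand")
  mode <- gsub("-", "_", lk$mode %||% "A_R")
  ligand <- if (!is.null(lk$ka_times_conc))
    ligand_conditions(mode, ka_times_conc = lk$ka_times_conc, cond = cond)
  else ligand_conditions(mode, dg_lig_A = lk$dg_lig_A %||% -3.0, cond = cond)

  out <- list(params = params, ligand = ligand, conditions = cond)
  if (!is.null(raw$sampling)) {
    sk <- raw$sampling
    check_keys(sk, setdiff(names(formals(sampling_config)),
                           c("mode", "dg_lig_A", "temperature")), "sampling")
    out$sampling <- do.call(sampling_config,
                            c(sk, list(mode = ligand$mode,
                                       dg_lig_A = ligand$dg_lig_A,
                                       temperature = cond$temperature)))
  }
  structure(out, class = "run_config")
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  invisible(x)
}

#' Write a run configuration
#'
#' Serialises a `"run_config"` (or the equivalent pieces) back to YAML or
#' JSON so that `load_config(write_config(x, f))` round-trips.
#'
#' @param config A `"run_config"` list.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- list(params = as.list(unclass(config$params)),
              ligand = list(mode = config$ligand$mode,
                            dg_lig_A = config$ligand$dg_lig_A),
              conditions = list(temperature = config$conditions$temperature))
  if (!is.null(config$sampling)) {
    s <- config$sampling
    raw$sampling <- list(dG_max = s$dG_max, n_samples = s$n_samples,
                         seed = s$seed, cr_bin_width = s$cr_bin_width,
                         degeneracy_epsilon = s$degeneracy_epsilon,
                         cr_window_center = s$cr_window_center,
                         cr_window_width = s$cr_window_width)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(raw, path)
  invisible(path)
}

#' Named reference systems
#'
#' Small library of fixed systems used in examples, tests and the
#' command-line interface:
#' \describe{
#'   \item{`uniform`}{all six free energies zero — every one of the seven
#'     apo states has probability 1/7.}
#'   \item{`interface_scan`}{the fixed stability parameters used for the
#'     interface-energy surface scan: `dG_R1 = -1.0`, `dG_R2 = 1.3`,
#'     `dG_RT1 = 1.0`, `dG_RT2 = 3.0` kcal/mol (interfaces zero), chosen
#'     to produce notable allostery.}
#'   \item{`pure_mwc`}{a two-state RR/TT system: all disordered states
#'     suppressed by +50 kcal/mol unfolding penalties, with the R-T split
#'     placed near the optimal apo `P_RR`.}
#'   \item{`pure_eam`}{an order-disorder system: the T states suppressed
#'     by +50 kcal/mol transition penalties.}
#' }
#'
#' @param name One of `"uniform"`, `"interface_scan"`, `"pure_mwc"`,
#'   `"pure_eam"`.
#' @return A `"run_config"` list (A-R mode, `dg_lig_A = -3` kcal/mol,
#'   310.15 K).
#' @examples
#' make_fixture("uniform")$params
#' @export
make_fixture <- function(name = c("uniform", "interface_scan",
                                  "pure_mwc", "pure_eam")) {
  name <- match.arg(name)
  cond <- conditions()
  params <- switch(name,
    uniform = free_energy_params(),
    interface_scan = free_energy_params(dG_R1 = -1.0, dG_R2 = 1.3,
                                        dG_RT1 = 1.0, dG_RT2 = 3.0),
    # suppress every I-containing state; G_TT = -1.55 puts the apo P_RR
    # near the optimum of the two-state response
    pure_mwc = free_energy_params(dG_R1 = 50, dG_R2 = 50, dg_int_T = 1.55),
    pure_eam = free_energy_params(dG_R1 = 1.0, dG_R2 = 1.0,
                                  dG_RT1 = 50, dG_RT2 = 50,
                                  dg_int_R = -1.0))
  structure(list(params = params,
                 ligand = ligand_conditions("A_R", dg_lig_A = -3,
                                            cond = cond),
                 conditions = cond),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  print(x$params); print(x$ligand); print(x$conditions)
  if (!is.null(x$sampling))
    cat(sprintf("Sampling: n = %d, dG_max = %g, seed = %d\n",
                x$sampling$n_samples, x$sampling$dG_max, x$sampling$seed))
  invisible(x)
}
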