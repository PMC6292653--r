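#' Monte-Carlo sampling configuration
#'
#' Settings for the random exploration of the six-dimensional free-energy
#' parameter space.  Parameters are drawn i.i.d. uniformly on
#' `[-dG_max, +dG_max]` kcal/mol; every per-system quantity of the model is
#' then evaluated at each draw.
#'
#' @param dG_max Half-width of the uniform range, kcal/mol (default 8).
#' @param n_samples Number of systems to draw (default 1e5).
#' @param seed Integer RNG seed; the run is bit-reproducible given the seed.
#' @param mode Ligand binding mode, `"A_R"` or `"A_T"`.
#' @param dg_lig_A Ligand stabilising free energy, kcal/mol (< 0).
#' @param temperature Kelvin.
#' @param cr_bin_width Bin width for CR histograms and binned averages.
#' @param degeneracy_epsilon `|CR_tot|` below which pathway weights are
#'   undefined and recorded as `NA`.
#' @param cr_window_center,cr_window_width Window for conditional analyses
#'   such as [conditional_prr_distribution()] (default `0.16 +/- 0.005`).
#' @return A list of class `"sampling_config"`.
#' @export
sampling_config <- function(dG_max = 8, n_samples = 1e5, seed = 1L,
                            mode = c("A_R", "A_T"), dg_lig_A = -3,
                            temperature = 310.15, cr_bin_width = 0.005,
                            degeneracy_epsilon = 1e-4,
                            cr_window_center = 0.16,
                            cr_window_width = 0.005) {
  mode <- match.arg(mode)
  stopifnot(dG_max >= 0, n_samples >= 1, cr_bin_width > 0,
            dg_lig_A < 0, temperature > 0)
  structure(list(dG_max = dG_max, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), mode = mode, dg_lig_A = dg_lig_A,
                 temperature = temperature, cr_bin_width = cr_bin_width,
                 degeneracy_epsilon = degeneracy_epsilon,
                 cr_window_center = cr_window_center,
                 cr_window_width = cr_window_width),
            class = "sampling_config")
}

#' Sample random allosteric systems
#'
#' Draws `n_samples` systems with the six stability free energies i.i.d.
#' uniform on `[-dG_max, +dG_max]` and evaluates the whole model for each
#' in one vectorised pass: total and subsystem CRs, pathway weights
#' (`NA` for degenerate `|CR| < epsilon` rows), category and two-state
#' labels, RR probability and subsystem occupancies before and after
#' ligand binding, and the efficacy alpha.
#'
#' @param config A [sampling_config()].
#' @return A data frame of class `"allo_samples"`, one row per system,
#'   with the configuration attached as attribute `"config"`.
#' @examples
#' s <- sample_systems(sampling_config(n_samples = 1000, seed = 42))
#' mean(abs(s$cr_tot) > 0.1)
#' @export
sample_systems <- function(config = sampling_config()) {
  stopifnot(inherits(config, "sampling_config"))
  set.seed(config$seed)
  n <- config$n_samples
  P <- matrix(stats::runif(6L * n, -config$dG_max, config$dG_max),
              nrow = n, ncol = 6L, byrow = TRUE)
  colnames(P) <- PARAM_NAMES
  cond <- conditions(config$temperature)
  core <- ensemble_core(P, config$mode, config$dg_lig_A, cond$RT)
  eps <- config$degeneracy_epsilon
  degenerate <- abs(core$cr_tot) < eps
  wm <- core$w_mwc; we <- core$w_eam; wo <- core$w_others
  wm[degenerate] <- NA_real_; we[degenerate] <- NA_real_
  wo[degenerate] <- NA_real_
  out <- data.frame(P,
    cr_tot = core$cr_tot,
    cr_mwc = core$cr_mwc, cr_eam = core$cr_eam, cr_others = core$cr_others,
    weight_mwc = wm, weight_eam = we, weight_others = wo,
    category = classify_core(core, eps = eps),
    two_state = two_state_core(core),
    p_rr_apo = core$apo[, "RR"],
    occ_mwc_apo = core$occ_apo[, "MWC"],
    occ_eam_apo = core$occ_apo[, "EAM"],
    occ_others_apo = core$occ_apo[, "OTHERS"],
    occ_mwc_lig = core$occ_lig[, "MWC"],
    occ_eam_lig = core$occ_lig[, "EAM"],
    occ_others_lig = core$occ_lig[, "OTHERS"],
    alpha = core$alpha, ln_alpha = log(core$alpha))
  attr(out, "config") <- config
  class(out) <- c("allo_samples", "data.frame")
  out
}

#' @export
print.allo_samples <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Monte-Carlo sample of %d systems (dG_max = %g kcal/mol, %s mode, seed %d)\n",
    nrow(x), cfg$dG_max, sub("_", "-", cfg$mode), cfg$seed))
  print(utils::head(as.data.frame(x)[, c("cr_tot", "weight_mwc",
                                         "weight_eam", "weight_others",
                                         "category", "two_state")]))
  cat("...\n")
  invisible(x)
}

#' @export
summary.allo_samples <- function(object, ...) {
  cfg <- attr(object, "config")
  cat(sprintf("n = %d systems, dG_max = %g kcal/mol, %s mode\n",
              nrow(object), cfg$dG_max, sub("_", "-", cfg$mode)))
  cat(sprintf("CR range: [%.4f, %.4f];  |CR| > 0.1: %.2f%%\n",
              min(object$cr_tot), max(object$cr_tot),
              100 * mean(abs(object$cr_tot) > 0.1)))
  cat(sprintf("degenerate (|CR| < %g): %.1f%%\n", cfg$degeneracy_epsilon,
              100 * mean(is.na(object$weight_mwc))))
  cat("Categories:\n")
  print(table(object$category, useNA = "ifany"))
  invisible(object)
}

#' @export
plot.allo_samples <- function(x, ...) {
  cfg <- attr(x, "config")
  h <- cr_histogram(x, bin_width = cfg$cr_bin_width)
  graphics::plot(h$cr_mid, h$density, type = "h",
                 xlab = "CR", ylab = "density",
                 main = "Distribution of the allosteric coupling response",
                 ...)
  invisible(x)
}

cr_breaks <- function(bin_width, range) {
  seq(range[1L], range[2L], by = bin_width)
}

#' Histogram of the coupling response
#'
#' Normalised empirical density of `CR_tot` over fixed-width bins.
#'
#' @param samples An `"allo_samples"` table.
#' @param bin_width Bin width (default the sampling config's, else 0.005).
#' @param range CR range covered.
#' @return A data frame with `bin` (label), `cr_mid`, `count`, `density`;
#'   the density integrates to 1 over the covered range.
#' @export
cr_histogram <- function(samples, bin_width = NULL, range = c(-0.2, 0.2)) {
  if (is.null(bin_width))
    bin_width <- attr(samples, "config")$cr_bin_width %||% 0.005
  breaks <- cr_breaks(bin_width, range)
  bin <- cut(samples$cr_tot, breaks, include.lowest = TRUE)
  count <- as.integer(table(bin))
  data.frame(bin = levels(bin),
             cr_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             count = count,
             density = count / (sum(count) * bin_width))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean pathway weights as a function of CR
#'
#' Bin-wise averages of the three pathway weights over `CR_tot`; rows with
#' undefined (degenerate) weights are excluded, as the contribution ratios
#' are meaningless at `CR ~ 0`.
#'
#' @inheritParams cr_histogram
#' @return A long data frame with `cr_mid`, `pathway`, `mean_weight`, `n`.
#' @export
weight_vs_cr <- function(samples, bin_width = NULL, range = c(-0.2, 0.2)) {
  if (is.null(bin_width))
    bin_width <- attr(samples, "config")$cr_bin_width %||% 0.005
  breaks <- cr_breaks(bin_width, range)
  keep <- !is.na(samples$weight_mwc)
  bin <- cut(samples$cr_tot[keep], breaks, include.lowest = TRUE)
  mids <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  one <- function(w, nm) {
    m <- tapply(w[keep], bin, mean)
    data.frame(cr_mid = mids, pathway = nm,
               mean_weight = as.numeric(m[levels(bin)]),
               n = as.integer(table(bin)))
  }
  rbind(one(samples$weight_mwc, "MWC"),
        one(samples$weight_eam, "EAM"),
        one(samples$weight_others, "OTHERS"))
}

#' Probability of strong allostery versus the parameter range
#'
#' For each half-width `dG_max` of the parameter range, draws a fresh
#' sample and reports the probability that a random system achieves
#' `CR_tot > threshold` through each pathway, i.e. the mean of
#' `weight * 1(CR > threshold)` (degenerate rows contribute 0), together
#' with the raw exceedance probability.  Below a pathway-specific critical
#' `dG_max` the probability is zero because the optimal two-state free
#' energy split cannot be reached.
#'
#' @param dG_max_grid Numeric vector of range half-widths, kcal/mol.
#' @param n_samples Systems per grid point.
#' @param seed Base seed; grid point i uses `seed + i - 1`.
#' @param threshold CR threshold (default 0.171, just below the analytic
#'   maximum at the default ligand conditions).
#' @param ... Further arguments passed to [sampling_config()].
#' @return A data frame with `dG_max`, `pathway`, `probability`, and the
#'   total `p_exceed`.
#' @export
capacity_vs_dGmax <- function(dG_max_grid, n_samples = 1e5, seed = 1L,
                              threshold = 0.171, ...) {
  res <- lapply(seq_along(dG_max_grid), function(i) {
    s <- sample_systems(sampling_config(dG_max = dG_max_grid[i],
                                        n_samples = n_samples,
                                        seed = seed + i - 1L, ...))
    hit <- s$cr_tot > threshold
    cap <- function(w) mean(ifelse(hit & !is.na(w), w, 0))
    data.frame(dG_max = dG_max_grid[i],
               pathway = c("MWC", "EAM", "OTHERS"),
               probability = c(cap(s$weight_mwc), cap(s$weight_eam),
                               cap(s$weight_others)),
               p_exceed = mean(hit))
  })
  do.call(rbind, res)
}

#' Category and two-state proportions along CR
#'
#' `category_proportions()` returns the per-CR-bin fractions of the four
#' mixing categories (computed over rows with defined weights, so the
#' fractions sum to 1 within each occupied bin); `two_state_proportion()`
#' returns the per-bin fraction of systems whose response runs through a
#' dominant two-state transition.
#'
#' @inheritParams cr_histogram
#' @return A data frame (long for categories, one row per bin for the
#'   two-state proportion).
#' @export
category_proportions <- function(samples, bin_width = NULL,
                                 range = c(-0.2, 0.2)) {
  if (is.null(bin_width))
    bin_width <- attr(samples, "config")$cr_bin_width %||% 0.005
  breaks <- cr_breaks(bin_width, range)
  keep <- !is.na(samples$category)
  bin <- cut(samples$cr_tot[keep], breaks, include.lowest = TRUE)
  tab <- table(bin, factor(samples$category[keep],
                           levels = c("SS", "SM", "MS", "MM")))
  tot <- rowSums(tab)
  prop <- sweep(tab, 1L, pmax(tot, 1L), "/")
  mids <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  out <- as.data.frame(as.table(prop))
  names(out) <- c("bin", "category", "proportion")
  out$cr_mid <- mids[as.integer(out$bin)]
  out$n <- as.integer(tot)[as.integer(out$bin)]
  out[, c("cr_mid", "category", "proportion", "n")]
}

#' @rdname category_proportions
#' @export
two_state_proportion <- function(samples, bin_width = NULL,
                                 range = c(-0.2, 0.2)) {
  if (is.null(bin_width))
    bin_width <- attr(samples, "config")$cr_bin_width %||% 0.005
  breaks <- cr_breaks(bin_width, range)
  bin <- cut(samples$cr_tot, breaks, include.lowest = TRUE)
  n <- as.integer(table(bin))
  hits <- tapply(!is.na(samples$two_state), bin, sum)
  hits <- ifelse(is.na(hits), 0L, hits)
  data.frame(cr_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             n = n, proportion = ifelse(n > 0, hits / n, NA_real_))
}

#' Conditional distribution of P_RR at fixed response strength
#'
#' Histograms of the apo RR probability and of the three subsystem
#' occupancies over the systems whose `CR_tot` falls in a narrow window
#' (default `0.16 +/- 0.005`).  In the two-state picture a response of
#' exactly the window centre is achieved at two roots of the
#' `CR(P_RR)` curve, and the empirical `P_RR` distribution peaks at those
#' roots; no mass lies outside their bracket.
#'
#' @param samples An `"allo_samples"` table.
#' @param center,width Window centre and half-width on `CR_tot` (defaults
#'   from the sampling config).
#' @param bin_width Histogram bin width on the probability axis.
#' @return A list with the number of selected rows `n`, the window, the
#'   two-state roots of the window centre (`roots`), and a long data frame
#'   `histograms` (`quantity`, `mid`, `count`, `density`).  With no rows
#'   in the window, `n = 0` and `histograms` is empty.
#' @export
conditional_prr_distribution <- function(samples, center = NULL,
                                         width = NULL, bin_width = 0.02) {
  cfg <- attr(samples, "config")
  center <- center %||% cfg$cr_window_center %||% 0.16
  width <- width %||% cfg$cr_window_width %||% 0.005
  sel <- abs(samples$cr_tot - center) <= width
  dg <- cfg$dg_lig_A %||% -3
  cond <- conditions(cfg$temperature %||% 310.15)
  roots <- two_state_cr_roots(center, dg, cond)
  cols <- c(p_rr_apo = "P_RR",
            occ_mwc_apo = "P_RR+TT", occ_eam_apo = "P_RR+RI+IR+II",
            occ_others_apo = "P_RR+TI+IT")
  breaks <- seq(0, 1, by = bin_width)
  hs <- lapply(names(cols), function(cn) {
    v <- samples[[cn]][sel]
    ct <- as.integer(table(cut(v, breaks, include.lowest = TRUE)))
    data.frame(quantity = cols[[cn]],
               mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
               count = ct,
               density = if (sum(ct) > 0) ct / (sum(ct) * bin_width) else 0)
  })
  list(n = sum(sel), center = center, width = width, roots = roots,
       histograms = do.call(rbind, hs))
}

# The two P_RR roots of two_state_cr(P_RR) = target (uniroot on each side
# of the maximum); used to locate the expected peaks of the conditional
# P_RR distribution.
two_state_cr_roots <- function(target, dg_lig_A, cond = conditions()) {
  popt <- p_rr_opt(dg_lig_A, cond)
  top <- two_state_cr(popt, dg_lig_A, cond)
  if (target > top) return(c(NA_real_, NA_real_))
  g <- function(p) two_state_cr(p, dg_lig_A, cond) - target
  lo <- stats::uniroot(g, c(1e-12, popt), tol = 1e-12)$root
  hi <- stats::uniroot(g, c(popt, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

#' Coupling-response surface over the two interface energies
#'
#' Dense grid scan of `CR_tot` over the interface free energies
#' `dg_int_R` and `dg_int_T` with the four stability parameters held
#' fixed — the classic landscape showing that an interface-energy
#' combination is required to maximise the response.
#'
#' @param params [free_energy_params()] supplying `dG_R1`, `dG_R2`,
#'   `dG_RT1`, `dG_RT2` (its interface entries are ignored).
#' @inheritParams coupling_response
#' @param range Grid range for both interface energies, kcal/mol.
#' @param step Grid step, kcal/mol (default 0.05).
#' @return A list of class `"cr_surface"`: `grid` (data frame with
#'   `dg_int_R`, `dg_int_T`, `cr`), `max_cr`, and `argmax` (row of the
#'   grid attaining the maximum).
#' @examples
#' sc <- grid_scan(free_energy_params(dG_R1 = -1, dG_R2 = 1.3,
#'                                    dG_RT1 = 1, dG_RT2 = 3),
#'                 ligand_conditions("A_R", dg_lig_A = -3),
#'                 range = c(-8, 8), step = 0.5)
#' sc$max_cr
#' @export
grid_scan <- function(params, ligand, cond = conditions(),
                      range = c(-8, 8), step = 0.05) {
  params <- unclass(as_params(params))
  g <- seq(range[1L], range[2L], by = step)
  grid <- expand.grid(dg_int_R = g, dg_int_T = g, KEEP.OUT.ATTRS = FALSE)
  P <- cbind(matrix(params[1:4], nrow(grid), 4L, byrow = TRUE),
             grid$dg_int_R, grid$dg_int_T)
  core <- ensemble_core(P, ligand$mode, ligand$dg_lig_A, cond$RT)
  grid$cr <- core$cr_tot
  i <- which.max(grid$cr)
  structure(list(grid = grid, max_cr = grid$cr[i], argmax = grid[i, ],
                 params = params, ligand = ligand),
            class = "cr_surface")
}

#' @export
print.cr_surface <- function(x, ...) {
  cat(sprintf(
    "CR surface over %d interface-energy grid points (%s mode)\n",
    nrow(x$grid), sub("_", "-", x$ligand$mode)))
  cat(sprintf("  max CR = %.5f at dg_int_R = %.2f, dg_int_T = %.2f\n",
              x$max_cr, x$argmax$dg_int_R, x$argmax$dg_int_T))
  invisible(x)
}
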