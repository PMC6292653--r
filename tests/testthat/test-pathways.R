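test_that("subsystem state sets cover the ensemble and overlap only in RR", {
  ss <- allostat:::SUBSYSTEM_STATES
  expect_setequal(unique(unlist(ss)), allostat:::STATE_NAMES)
  expect_identical(intersect(ss$MWC, ss$EAM), "RR")
  expect_identical(intersect(ss$MWC, ss$OTHERS), "RR")
  expect_identical(intersect(ss$EAM, ss$OTHERS), "RR")
  # the five allosterically productive transitions each stay within one
  # subsystem: no communication between pathways
  for (pair in allostat:::TWO_STATE_PAIRS)
    expect_true(any(vapply(ss, function(s) all(pair %in% s), logical(1))))
})

test_that("a pure MWC system reduces subsystem CR to the full-model CR", {
  p <- make_fixture("pure_mwc")$params
  for (lig in list(LIG_AR, LIG_AT)) {
    expect_equal(subsystem_cr("MWC", p, lig),
                 coupling_response(p, lig)$cr, tolerance = 1e-10)
  }
})

test_that("subsystem CRs match independent pairwise/renormalised oracles", {
  set.seed(11)
  dev <- vapply(1:200, function(i) {
    p <- random_params()
    mode <- if (i %% 2) "A_R" else "A_T"
    lig <- if (mode == "A_R") LIG_AR else LIG_AT
    abs(subsystem_cr("MWC", p, lig) - oracle_mwc_pair_cr(unclass(p), -3, mode))
  }, numeric(1))
  expect_lt(max(dev), 1e-10)
})

test_that("the EAM subsystem is ligand-blind in A-T mode", {
  set.seed(12)
  for (i in 1:50) {
    p <- random_params()
    expect_identical(subsystem_cr("EAM", p, LIG_AT), 0)
    w <- pathway_weights(p, LIG_AT)
    if (w$defined) expect_identical(unname(w$weights[["EAM"]]), 0)
  }
})

test_that("pathway weights recompose from occupancies and subsystem CRs", {
  set.seed(13)
  n_checked <- 0
  while (n_checked < 50) {
    p <- random_params()
    w <- pathway_weights(p, LIG_AR)
    if (!w$defined) next
    n_checked <- n_checked + 1
    for (s in c("MWC", "EAM", "OTHERS")) {
      recomposed <- min(w$occupancy_apo[[s]], w$occupancy_liganded[[s]]) *
        subsystem_cr(s, p, LIG_AR) / w$cr_tot
      expect_lt(abs(unname(w$weights[[s]]) - recomposed), 1e-8)
    }
  }
})

test_that("a pure RR/TT system carries all weight on the MWC pathway", {
  w <- pathway_weights(make_fixture("pure_mwc")$params, LIG_AR)
  expect_true(w$defined)
  expect_equal(unname(w$weights[["MWC"]]), 1, tolerance = 1e-12)
  expect_equal(classify_category(make_fixture("pure_mwc")$params, LIG_AR),
               "SS")
  # and a pure EAM system is a single EAM pathway
  we <- pathway_weights(make_fixture("pure_eam")$params, LIG_AR)
  expect_true(we$defined)
  expect_equal(unname(we$weights[["EAM"]]), 1, tolerance = 1e-6)
})

test_that("weights are reported undefined below the degeneracy cutoff", {
  # a TT/TI-dominated system: the A-R ligand targets states of negligible
  # weight, so CR ~ 0 and the contribution ratios are meaningless
  p <- free_energy_params(dG_R1 = 20, dG_R2 = 20, dG_RT1 = -30)
  lig <- LIG_AR
  w <- pathway_weights(p, lig)
  expect_false(w$defined)
  expect_true(all(is.na(w$weights)))
  expect_true(is.na(classify_category(p, lig)))
})

test_that("the uniform ensemble is a mixing-subsystem system", {
  # no subsystem can hold > 0.99 when each state has 1/7
  p <- free_energy_params()
  cat <- classify_category(p, LIG_AR)
  expect_true(startsWith(cat, "M"))
})

test_that("normalisation differs between subsystems sharing RR", {
  set.seed(14)
  p <- random_params(3)
  core <- allostat:::ensemble_core(matrix(unclass(p), nrow = 1),
                                   "A_R", -3, conditions()$RT)
  w <- exp(-(allostat:::state_energy_matrix(
    matrix(unclass(p), nrow = 1)))[1, ] / conditions()$RT)
  f <- exp(3 / conditions()$RT)
  p_mwc <- f * w[["RR"]] / (f * w[["RR"]] + w[["TT"]])
  p_oth <- f * w[["RR"]] / (f * w[["RR"]] + w[["TI"]] + w[["IT"]])
  expect_false(isTRUE(all.equal(p_mwc, p_oth)))
})

test_that("two-state transitions are detected for constructed systems", {
  lig <- LIG_AR
  # strongly stabilised RR/TT pair near the optimal split
  expect_identical(detect_two_state(make_fixture("pure_mwc")$params, lig),
                   "TT->RR")
  # uniform ensemble: the best pair holds only 2/7
  expect_true(is.na(detect_two_state(free_energy_params(), lig)))
  # II <-> RR system: G(II) ~ 1, single-I states pushed up by the
  # interface penalty, T states suppressed
  p <- free_energy_params(dG_R1 = -3.5, dG_R2 = -3.5, dG_RT1 = 50,
                          dG_RT2 = 50, dg_int_R = 8)
  expect_identical(detect_two_state(p, lig), "II->RR")
  # IR <-> RI negative-response system: both single-I states far below
  # RR, II raised by a strongly attractive interface term
  p <- free_energy_params(dG_R1 = 9.7, dG_R2 = 10, dG_RT1 = 50,
                          dG_RT2 = 50, dg_int_R = -15)
  expect_identical(detect_two_state(p, lig), "IR->RI")
})

test_that("pathway capacity recomposes as mean weight times density", {
  s <- sample_systems(sampling_config(n_samples = 2e4, seed = 31))
  capm <- pathway_capacity(s, "MWC")
  wm <- weight_vs_cr(s)
  dens <- cr_histogram(s)
  sub <- merge(capm, subset(wm, pathway == "MWC"), by = "cr_mid")
  occupied <- sub$count > 0 & sub$n > 0
  expect_equal(sub$capacity[occupied],
               (sub$mean_weight.y * sub$density)[occupied], tolerance = 1e-10)
  # a ligand-blind pathway has identically zero capacity
  s_at <- sample_systems(sampling_config(n_samples = 5e3, seed = 32,
                                         mode = "A_T"))
  cape <- pathway_capacity(s_at, "EAM")
  expect_true(all(cape$capacity == 0))
})
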