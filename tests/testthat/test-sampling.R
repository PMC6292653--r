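test_that("sampling is bit-reproducible given the seed", {
  cfg <- sampling_config(n_samples = 2000, seed = 99)
  s1 <- sample_systems(cfg)
  s2 <- sample_systems(cfg)
  expect_identical(s1, s2)
  s3 <- sample_systems(sampling_config(n_samples = 2000, seed = 100))
  expect_false(identical(s1$cr_tot, s3$cr_tot))
})

test_that("a zero-width parameter range degenerates to the uniform ensemble", {
  s <- sample_systems(sampling_config(dG_max = 0, n_samples = 50, seed = 1))
  expect_true(all(s$cr_tot == s$cr_tot[1]))
  expect_equal(s$p_rr_apo, rep(1 / 7, 50), tolerance = 1e-12)
})

test_that("the CR histogram is a normalised density with a mode at zero", {
  s <- sample_systems(sampling_config(n_samples = 5e4, seed = 7))
  h <- cr_histogram(s)
  expect_equal(sum(h$density) * 0.005, 1, tolerance = 1e-12)
  expect_equal(sum(h$count), nrow(s))
  # sharp central peak
  expect_equal(h$cr_mid[which.max(h$density)], 0, tolerance = 0.005)
  # A-T mode places no mass at positive CR
  s_at <- sample_systems(sampling_config(n_samples = 2e4, seed = 8,
                                         mode = "A_T"))
  h_at <- cr_histogram(s_at)
  expect_equal(sum(h_at$count[h_at$cr_mid > 0.005]), 0)
})

test_that("the exceedance fraction is stable under down-scaling", {
  f1 <- with(sample_systems(sampling_config(n_samples = 1e4, seed = 51)),
             mean(abs(cr_tot) > 0.1))
  f2 <- with(sample_systems(sampling_config(n_samples = 1e5, seed = 52)),
             mean(abs(cr_tot) > 0.1))
  # agreement within combined binomial error (3 SE of the smaller run)
  se <- sqrt(f2 * (1 - f2) / 1e4)
  expect_lt(abs(f1 - f2), 3 * se + sqrt(f2 * (1 - f2) / 1e5))
})

test_that("sampled systems never exceed the analytic CR bound", {
  s <- sample_systems(sampling_config(n_samples = 1e5, seed = 53))
  expect_lte(max(abs(s$cr_tot)), cr_max(-3))
})

test_that("mean pathway weights order as expected along CR", {
  s <- sample_systems(sampling_config(n_samples = 1e5, seed = 54))
  w <- weight_vs_cr(s)
  strong <- subset(w, cr_mid > 0.1 & n > 10)
  m <- tapply(strong$mean_weight, strong$pathway, mean)
  # positive response: order-order (MWC) far ahead of order-disorder (EAM)
  expect_gt(m[["MWC"]], m[["EAM"]])
  # negative response under A-R is carried by the EAM pathway
  neg <- subset(w, cr_mid < -0.05 & n > 10)
  mn <- tapply(neg$mean_weight, neg$pathway, mean)
  expect_gt(mn[["EAM"]], mn[["MWC"]])
})

test_that("category proportions partition each occupied bin", {
  s <- sample_systems(sampling_config(n_samples = 2e4, seed = 55))
  cp <- category_proportions(s)
  sums <- tapply(cp$proportion, cp$cr_mid, sum)
  occupied <- tapply(cp$n, cp$cr_mid, max) > 0
  expect_equal(as.numeric(sums[occupied]), rep(1, sum(occupied)),
               tolerance = 1e-12)
})

test_that("two-state proportion peaks at the response limits", {
  # wide parameter range: two-state mechanisms enriched, sharp peaks at
  # the positive and negative analytic limits
  s <- sample_systems(sampling_config(dG_max = 13, n_samples = 1e5,
                                      seed = 56))
  ts <- two_state_proportion(s)
  bound <- cr_max(-3)
  pos <- subset(ts, n > 5 & cr_mid > 0.02)
  expect_equal(pos$cr_mid[which.max(pos$proportion)], bound,
               tolerance = 0.0075)
  neg <- subset(ts, n > 5 & cr_mid < -0.02)
  expect_equal(neg$cr_mid[which.max(neg$proportion)], -bound,
               tolerance = 0.0075)
  # proportion rises with a wider range: compare against the default 8
  s8 <- sample_systems(sampling_config(dG_max = 8, n_samples = 5e4,
                                       seed = 56))
  expect_gt(mean(!is.na(s$two_state)), mean(!is.na(s8$two_state)))
})

test_that("the conditional P_RR distribution concentrates at the two roots", {
  s <- sample_systems(sampling_config(n_samples = 2e5, seed = 57))
  cd <- conditional_prr_distribution(s, center = 0.16, width = 0.005,
                                     bin_width = 0.02)
  expect_gt(cd$n, 100)
  roots <- cd$roots
  expect_true(all(is.finite(roots)))
  # the two roots of the closed-form curve bracket all the mass
  h <- subset(cd$histograms, quantity == "P_RR")
  inside <- h$mid >= roots[1] - 0.03 & h$mid <= roots[2] + 0.03
  expect_gt(sum(h$count[inside]) / sum(h$count), 0.995)
  # peaks sit at the roots within ~one bin, either side of the optimum
  popt <- p_rr_opt(-3)
  lowpeak <- h$mid[which.max(h$count * (h$mid < popt))]
  highpeak <- h$mid[which.max(h$count * (h$mid > popt))]
  expect_lt(abs(lowpeak - roots[1]), 0.03)
  expect_lt(abs(highpeak - roots[2]), 0.03)
  # an empty window is flagged, not an error
  cd0 <- conditional_prr_distribution(s, center = 0.25, width = 0.001)
  expect_identical(cd0$n, 0L)
})

test_that("strong-allostery capacity switches on above a critical range", {
  cap <- capacity_vs_dGmax(c(1, 3, 8), n_samples = 3e4, seed = 58)
  at1 <- subset(cap, dG_max == 1)
  expect_true(all(at1$probability == 0))
  expect_true(all(at1$p_exceed == 0))
  at8 <- subset(cap, dG_max == 8)
  expect_gt(at8$probability[at8$pathway == "MWC"], 0)
  expect_gt(at8$probability[at8$pathway == "MWC"],
            at8$probability[at8$pathway == "EAM"])
})

test_that("the interface-energy surface matches pointwise evaluation", {
  fx <- make_fixture("interface_scan")
  sc <- grid_scan(fx$params, fx$ligand, range = c(-4, 8), step = 1)
  i <- sample(nrow(sc$grid), 5)
  for (k in i) {
    p <- free_energy_params(-1, 1.3, 1, 3, sc$grid$dg_int_R[k],
                            sc$grid$dg_int_T[k])
    expect_equal(sc$grid$cr[k], coupling_response(p, fx$ligand)$cr,
                 tolerance = 1e-12)
  }
  expect_equal(sc$max_cr, max(sc$grid$cr))
})
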