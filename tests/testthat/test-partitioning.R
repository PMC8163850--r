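# Source attribution, control bases, interactive effects, mass balance.

test_that("partition_co2 follows the normalisation arithmetic", {
  ends <- natural_ends()
  tr <- treatment("mix", 1.5, 4.5)
  # choose the sample signature that yields f_daphnia = 0.25 exactly
  sig <- forward_mix(0.25, ends, "delta")
  out <- partition_co2(120, sig, ends, tr, mode = "delta")
  d <- out[out$source == "daphnia", ]
  expect_equal(d$co2_abs, 30)
  expect_equal(d$co2_per_mg, 20)
  # the two absolute values sum to the input concentration
  expect_equal(sum(out$co2_abs), 120)
  # sample at the leaf endmember: everything goes to leaves
  out <- partition_co2(120, ends$source_b, ends, tr, mode = "delta")
  expect_equal(out$f_source[out$source == "leaf"], 1)
  expect_equal(out$co2_abs[out$source == "daphnia"], 0)
})

test_that("single-source controls bypass the mixing model", {
  ends <- enriched_ends()
  out <- partition_co2(80, NA_real_, ends, treatment("Daphnia", 3, 0))
  expect_equal(out$f_source[out$source == "daphnia"], 1)
  expect_equal(out$co2_per_mg[out$source == "daphnia"], 80 / 3)
  expect_equal(out$mode[1], "bypass_single_source")
  expect_error(partition_co2(10, -20, ends, treatment("Blank", 0, 0)),
               "no substrate")
})

test_that("partition_poc mirrors partition_co2 and recovers pool masses", {
  study <- nf_study()
  cfg <- sim_config()
  ends <- study_endmembers(cfg)
  m <- study$measurements$poc
  for (id in c("DL1:1", "DL1:5")) {
    tru <- study$truths[[id]]
    fin <- tru$final
    rows <- m[m$treatment_id == id & m$phase == "final", ]
    out <- partition_poc(rows$poc_umol_l, rows$delta13C_permil, ends,
                         tru$treatment, mode = "atom")
    got_d <- mean(out$poc_abs[out$source == "daphnia"])
    expect_equal(got_d, fin$c_d + fin$biomass_d, tolerance = 1e-10)
    expect_equal(mean(out$poc_abs[out$source == "leaf"]),
                 fin$c_l + fin$biomass_l, tolerance = 1e-10)
  }
  # midpoint signature in delta mode gives a 50:50 split
  ends_n <- natural_ends()
  mid <- forward_mix(0.5, ends_n, "delta")
  out <- partition_poc(10, mid, ends_n, treatment("mix", 3, 3), mode = "delta")
  expect_equal(out$f_source, c(0.5, 0.5))
})

test_that("control basis: measured sum when masses match, per-mg pseudo otherwise", {
  controls <- tibble::tibble(source = c("daphnia", "leaf"),
                             co2 = c(90, 12), mass_mg_l = c(3, 3))
  eq <- control_basis(treatment("DL1:1", 3, 3), controls)
  expect_equal(eq$basis, "measured_sum")
  expect_equal(eq$co2_controls, 102)
  # per-mg rates 30 and 4 scaled to 1 + 5 mg: 30*1 + 4*5 = 50
  ps <- control_basis(treatment("DL1:5", 1, 5), controls)
  expect_equal(ps$basis, "per_mg_pseudo")
  expect_equal(ps$co2_controls, 50)
  expect_equal(ps$components$co2, c(30, 20))
  # bases coincide when treatment masses equal control masses
  expect_equal(eq$co2_controls,
               sum(ps$components$rate_per_mg * c(3, 3)))
  expect_error(control_basis(treatment("x", 1, 5), controls[1, ]), "both sources")
})

test_that("interactive effect is the percent excess over the control basis", {
  controls <- tibble::tibble(source = c("daphnia", "leaf"),
                             co2 = c(90, 12), mass_mg_l = c(3, 3))
  basis15 <- control_basis(treatment("DL1:5", 1, 5), controls)
  res <- interactive_effect(139, basis15)
  expect_equal(res$ie_mean, 178)
  basis11 <- control_basis(treatment("DL1:1", 3, 3),
                           tibble::tibble(source = c("daphnia", "leaf"),
                                          co2 = c(100, 50), mass_mg_l = c(3, 3)))
  expect_equal(interactive_effect(297, basis11)$ie_mean, 98)
  expect_equal(interactive_effect(150, basis11)$ie_mean, 0)
  # scale invariance: multiplying treatment and controls by c leaves IE fixed
  for (c_scale in c(0.1, 3, 42)) {
    scaled <- control_basis(treatment("DL1:5", 1, 5),
                            dplyr::mutate(controls, co2 = co2 * c_scale))
    expect_equal(interactive_effect(139 * c_scale, scaled)$ie_mean, 178,
                 tolerance = 1e-12)
  }
  # replicate aggregation and community-mismatch flag
  res <- interactive_effect(c(130, 148), basis15,
                            treatment_community = "bacterial")
  expect_equal(res$ie_mean, 178)
  expect_equal(res$n, 2)
  expect_true(res$control_community_mismatch)
  expect_error(interactive_effect(
    10, structure(list(treatment_id = "x", basis = "measured_sum",
                       co2_controls = 0, components = NULL),
                  class = "control_basis")), "non-positive")
})

test_that("net production recovers the true source CO2 and its signature", {
  study <- nf_study()
  net <- net_co2_production(study$measurements$co2)
  for (id in c("DL1:1", "DL1:3", "DL1:5", "b-DL1:1")) {
    fin <- study$truths[[id]]$final
    rows <- net[net$treatment_id == id, ]
    expect_equal(mean(rows$co2_net), fin$co2_src, tolerance = 1e-10)
    expect_equal(mean(rows$delta13C_net), fin$delta13_co2_source,
                 tolerance = 1e-9)
  }
})

test_that("interactive effects are additive-null and pseudo equals measured on linear runs", {
  base <- sim_config(priming_p = 0)
  pres <- scenario_presets(base, bacterial_k_l = base$k_l,
                           bacterial_priming_p = 0)
  s <- simulate_study(pres, seed = 7, noise = FALSE)
  ie <- interactive_effects_study(s$measurements$co2, s$measurements$design)
  expect_lt(max(abs(ie$ie_mean)), 1e-9)

  # linear rates: per-mg pseudocontrols from 3+3 mg controls match measured
  # sums of controls run at the treatment's own masses (1 + 5 mg)
  base <- sim_config(priming_p = 0)
  small <- list(
    d1 = list(treatment = treatment("d1", 1, 0), config = base),
    l5 = list(treatment = treatment("l5", 0, 5), config = base))
  s2 <- simulate_study(c(pres[c("Daphnia", "Leaves", "Blank")], small),
                       seed = 7, noise = FALSE)
  net <- net_co2_production(s2$measurements$co2)
  co2_of <- function(id) mean(net$co2_net[net$treatment_id == id])
  controls <- tibble::tibble(source = c("daphnia", "leaf"),
                             co2 = c(co2_of("Daphnia"), co2_of("Leaves")),
                             mass_mg_l = c(3, 3))
  pseudo <- control_basis(treatment("DL1:5", 1, 5), controls)
  measured <- co2_of("d1") + co2_of("l5")
  expect_equal(pseudo$co2_controls, measured, tolerance = 1e-6)
})

test_that("carbon budget closes on conservation and flags large residuals", {
  mb <- mass_balance(5, 5, 0, 0)
  expect_equal(mb$closure_residual, 0)
  expect_false(mb$flagged)
  # isotope-weighted molar mass is linear in the atom fraction
  expect_equal(molar_mass_c(0.5), (12 + 13.00335) / 2)
  expect_equal(molar_mass_c(), 12.011)
  mb <- mass_balance(5, 1, 100, 0.2, co2_atom_fraction = 0.05)
  expect_true(mb$flagged)
})

test_that("noisy budgets stay inside a Monte-Carlo residual envelope", {
  # with 5% concentration noise on POC and CO2 the closure residual should
  # scatter around zero within a few relative percent
  study <- nf_study()
  tru <- study$truths[["DL1:1"]]
  cfg <- sim_config()
  rel <- vapply(1:200, function(s) {
    meas <- emit_measurements(list(tru), seed = s)
    budget_from_measurements(meas, "DL1:1")$residual_rel
  }, numeric(1))
  expect_lt(abs(mean(rel)), 0.03)
  expect_lt(max(abs(rel)), 0.25)
})
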