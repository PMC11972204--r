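# long blocks so the HRF-convolved boxcar reaches its unit plateau
long_schedule <- function() {
  build_physical_schedule(motion_block_s = 60, alternations = 1,
                          flicker_s = 16, repetitions = 1, fixation_s = 20)
}

flat_model <- function(...) {
  laminar_response_model(bump_height = 0, drain_gain = 0, ...)
}

noiseless_run <- function(patch, model, schedule = long_schedule(), ...) {
  simulate_run(patch, model, schedule, run_type = "physical",
               noise_sd = 0, run_gain_sd = 0, ...)
}

test_that("noiseless flat-profile signal peaks at the injected beta", {
  p <- make_patch(n_columns = 4, voxels_per_column = 4, gain_sd = 0, seed = 1)
  m <- flat_model(beta_pref = 2)
  Y <- noiseless_run(p, m)
  psc <- (Y / 1000 - 1) * 100
  h <- p$true_cluster == "H"
  # plateau sample: >= 32 s (kernel support) into the 60-s horizontal block
  sch <- long_schedule()
  on <- sch$events$onset[sch$events$trial_type == "horizontal"][1]
  plateau <- floor((on + 40) / sch$tr_s) + 1
  expect_equal(max(psc[plateau, h]), 2, tolerance = 1e-6)
  # linearity: doubling beta doubles the noiseless plateau
  Y2 <- noiseless_run(p, flat_model(beta_pref = 4))
  expect_equal(max((Y2[plateau, ] / 1000 - 1) * 100), 4, tolerance = 1e-6)
})

test_that("drainage produces the superficial-increasing feedforward profile", {
  p <- make_patch(n_columns = 6, voxels_per_column = 9, gain_sd = 0,
                  curvature_sd = 0, seed = 2)
  m <- laminar_response_model(drain_gain = 1)
  Y <- noiseless_run(p, m)
  psc <- (Y / 1000 - 1) * 100
  peak <- apply(psc[, p$true_cluster == "H", drop = FALSE], 2, max)
  lay <- cut(p$d_ev[p$true_cluster == "H"], c(0, 1 / 3, 2 / 3, 1),
             include.lowest = TRUE)
  means <- tapply(peak, lay, mean)
  expect_true(all(diff(means) > 0))
  # drain_gain = 0 with the flat feedback profile: equal response at all depths
  Yf <- simulate_run(p, flat_model(), long_schedule(), scenario = "hypothesis2",
                     run_type = "physical", noise_sd = 0, run_gain_sd = 0)
  pscf <- (Yf / 1000 - 1) * 100
  peakf <- apply(pscf[, p$true_cluster == "H", drop = FALSE], 2, max)
  expect_lt(diff(range(peakf)), 1e-6)
})

test_that("the leakage drainage variant shares the additive model's limits", {
  p <- make_patch(n_columns = 6, voxels_per_column = 9, gain_sd = 0,
                  curvature_sd = 0, seed = 2)
  sch <- long_schedule()
  peak_means <- function(model) {
    Y <- simulate_run(p, model, sch, run_type = "physical", noise_sd = 0,
                      run_gain_sd = 0)
    psc <- (Y / 1000 - 1) * 100
    peak <- apply(psc[, p$true_cluster == "H", drop = FALSE], 2, max)
    lay <- cut(p$d_ev[p$true_cluster == "H"], c(0, 1 / 3, 2 / 3, 1),
               include.lowest = TRUE)
    tapply(peak, lay, mean)
  }
  # with drain_gain = 0 both variants reduce to the microvascular profile
  expect_equal(peak_means(laminar_response_model(drain_gain = 0)),
               peak_means(laminar_response_model(drain_gain = 0,
                                                 drain_model = "leakage")))
  # with drainage on, both produce the superficial-increasing profile
  expect_true(all(diff(peak_means(laminar_response_model(
    drain_model = "leakage"))) > 0))
})

test_that("AR(1) noise has the requested autocorrelation", {
  p <- make_patch(n_columns = 10, voxels_per_column = 10, seed = 3)
  m <- laminar_response_model(beta_pref = 0, beta_nonpref = 0, beta_flicker = 0)
  sch <- build_physical_schedule(repetitions = 3)
  Y <- simulate_run(p, m, sch, scenario = "null", run_type = "physical",
                    noise_sd = 2, ar1 = 0.3, seed = 7)
  E <- scale(Y, scale = FALSE)
  r1 <- sum(E[-1, ] * E[-nrow(E), ]) / sum(E^2)
  se <- 1 / sqrt(length(E))
  expect_lt(abs(r1 - 0.3), 3 * se)
  # determinism given seed
  Yb <- simulate_run(p, m, sch, scenario = "null", run_type = "physical",
                     noise_sd = 2, ar1 = 0.3, seed = 7)
  expect_identical(Y, Yb)
})

test_that("scenarios inject the hypothesized amplitude structure", {
  m <- laminar_response_model()
  p_v1 <- make_patch(roi = "V1", seed = 1)
  p_mt <- make_patch(roi = "hMT", seed = 2)
  # null: no evoked response in either condition
  for (ty in c("physical", "ambiguous")) {
    expect_true(all(scenario_amplitudes(p_v1, m, ty, "null")$amp == 0))
  }
  # hypothesis 2: both V1 clusters equally activated during ambiguity
  a2 <- scenario_amplitudes(p_v1, m, "ambiguous", "hypothesis2")
  lab <- p_v1$true_cluster
  expect_equal(unique(a2$amp[lab == "H", "horizontal"]),
               unique(a2$amp[lab == "V", "horizontal"]))
  expect_equal(unique(a2$amp[lab == "H", "vertical"]),
               unique(a2$amp[lab == "H", "horizontal"]))
  expect_identical(a2$profile, "fb")
  # hypothesis 1: percept-matched modulation only, scaled
  a1 <- scenario_amplitudes(p_v1, m, "ambiguous", "hypothesis1")
  expect_equal(unique(a1$amp[lab == "H", "horizontal"]),
               m$amplitude_scale_ambiguous * m$beta_pref)
  expect_equal(unique(a1$amp[lab == "H", "vertical"]),
               m$amplitude_scale_ambiguous * m$beta_nonpref)
  # hMT+ amplitudes are condition-invariant
  amt_p <- scenario_amplitudes(p_mt, m, "physical", "hypothesis2")
  amt_a <- scenario_amplitudes(p_mt, m, "ambiguous", "hypothesis2")
  expect_equal(amt_p$amp, amt_a$amp)
  expect_error(scenario_amplitudes(p_v1, m, "ambiguous", "flat-earth"))
})

test_that("cohorts carry the study structure and are reproducible", {
  co <- make_cohort(n_subjects = 2, hemispheres = 2, runs_per_condition = 1,
                    n_columns = 6, voxels_per_column = 4, repetitions = 1,
                    seed = 9)
  expect_length(co$units, 4)
  types <- vapply(co$units[[1]]$runs, `[[`, "", "type")
  expect_setequal(types, c("physical", "ambiguous"))
  for (u in co$units) {
    for (r in u$runs) {
      expect_equal(nrow(r$Y$V1), r$schedule$n_volumes)
      expect_equal(ncol(r$Y$V1), nrow(u$patches$V1))
    }
  }
  co2 <- make_cohort(n_subjects = 2, hemispheres = 2, runs_per_condition = 1,
                     n_columns = 6, voxels_per_column = 4, repetitions = 1,
                     seed = 9)
  expect_identical(co$units[[3]]$runs[[2]]$Y$hMT,
                   co2$units[[3]]$runs[[2]]$Y$hMT)
})
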