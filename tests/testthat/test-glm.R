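test_that("PSC normalization rescales to mean 100", {
  Y <- cbind(rep(500, 20), seq(90, 110, length.out = 20))
  Yn <- normalize_psc(Y)
  expect_equal(Yn[, 1], rep(100, 20))
  expect_equal(mean(Yn[, 2]), 100)
  # series with mean 100 is a fixed point
  expect_equal(normalize_psc(cbind(c(90, 110)))[, 1], c(90, 110))
  # idempotence: normalizing a normalized series changes nothing
  expect_equal(normalize_psc(Yn), Yn, ignore_attr = TRUE)
  # zero-mean voxels are excluded, not propagated
  Yz <- cbind(Y, c(rep(1, 10), rep(-1, 10)))
  Ynz <- normalize_psc(Yz)
  expect_equal(attr(Ynz, "excluded"), 3L)
  expect_equal(ncol(Ynz), 2)
})

test_that("DCT high-pass removes slow drift and nothing more", {
  n <- 200
  t <- seq_len(n)
  drift <- cos(pi * 4 * (t - 0.5) / n)           # 2 cycles per run
  filt <- highpass(cbind(drift), cycles_per_run = 5)
  expect_lt(sum(filt^2) / sum(drift^2), 1e-10)
  expect_equal(highpass(cbind(rep(0, n)), 5)[, 1], rep(0, n))
  # white noise loses exactly dim(projected subspace)/n of variance in
  # expectation (trace identity)
  set.seed(1)
  W <- matrix(rnorm(n * 400), n)
  ratio <- mean(apply(highpass(W, 5), 2, var) / apply(W, 2, var))
  k <- ncol(dct_basis(n, 5))
  expect_lt(abs(ratio - (1 - k / (n - 1))), 0.01)
  expect_error(dct_basis(20, 11), "Nyquist")
})

test_that("design matrices are HRF-convolved and flag degeneracy", {
  ev <- data.frame(onset = 20, duration = 10, trial_type = "horizontal",
                   source = "stimulus")
  X <- build_design(ev, 40, 2, hp_cycles = 2)
  expect_equal(attr(X, "conditions"), c("horizontal", "vertical", "flicker"))
  peak_s <- (which.max(X[, "horizontal"]) - 1) * 2
  expect_gte(peak_s - 20, 4)          # peak at least 4 s after onset
  expect_true(all(X[, "vertical"] == 0))
  expect_true(attr(X, "rank_deficient"))
  expect_error(
    build_design(data.frame(onset = 1, duration = 2, trial_type = "oblique",
                            source = "stimulus"), 40, 2),
    "unknown condition")
  sch <- build_physical_schedule(repetitions = 2)
  Xp <- build_design(sch$events, sch$n_volumes, 2)
  expect_length(attr(Xp, "task"), 3)  # exactly three task predictors
})

test_that("the GLM recovers injected betas exactly without noise", {
  sch <- build_physical_schedule(repetitions = 2)
  X <- build_design(sch$events, sch$n_volumes, 2)
  b_true <- c(1.5, -0.7, 0.4)
  y <- X[, 1:3] %*% b_true + 100
  fit <- fit_glm(cbind(as.numeric(y)), X)
  expect_equal(as.numeric(fit$beta[1:3, 1]), b_true, tolerance = 1e-6)
  # flat (all-zero) task column makes the design rank deficient
  ev0 <- sch$events[sch$events$trial_type != "vertical", ]
  X0 <- build_design(ev0, sch$n_volumes, 2)
  expect_error(fit_glm(cbind(as.numeric(y)), X0), "rank deficient")
})

test_that("AR(2) prewhitening calibrates the contrast t-test", {
  sch <- build_physical_schedule(repetitions = 3)
  X <- build_design(sch$events, sch$n_volumes, 2)
  set.seed(42)
  n <- sch$n_volumes
  nvox <- 2000
  E <- matrix(rnorm(n * nvox), n)
  for (t in 2:n) E[t, ] <- 0.4 * E[t - 1, ] + E[t, ]   # AR(1) = 0.4, null betas
  fit <- fit_glm(E + 100, X)
  t_hv <- contrast_t(fit)
  rate <- mean(abs(t_hv) > qt(0.975, attr(t_hv, "df")))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nvox))
  # Yule-Walker recovers the generating coefficients
  expect_lt(abs(fit$ar_coef[1] - 0.4), 0.05)
  expect_lt(abs(fit$ar_coef[2]), 0.05)
  # whitening with the true AR coefficients leaves white residuals
  # (Ljung-Box non-significant at alpha = 0.01 for >= 95% of voxels)
  W <- layerquartet:::whiten_segments(E, c(0.4, 0), list(seq_len(n)))
  lb <- apply(W[, 1:300], 2, function(e)
    stats::Box.test(e, lag = 10, type = "Ljung-Box")$p.value)
  expect_gte(mean(lb > 0.01), 0.95)
  # null contrast is centred on zero
  expect_lt(abs(mean(t_hv)), 3 / sqrt(nvox) * sd(t_hv))
})

test_that("contrast t is antisymmetric and guards zero residuals", {
  sch <- build_physical_schedule(repetitions = 2)
  X <- build_design(sch$events, sch$n_volumes, 2)
  set.seed(2)
  Y <- 100 + X[, 1:3] %*% rbind(2, 0.3, 0.5) %*% rep(1, 3) +
    matrix(rnorm(sch$n_volumes * 3), ncol = 3)
  fit <- fit_glm(Y, X)
  expect_equal(contrast_t(fit, "horizontal", "vertical"),
               -contrast_t(fit, "vertical", "horizontal"),
               ignore_attr = TRUE)
  expect_error(contrast_t(fit, "horizontal", "diagonal"), "absent")
  # noiseless: zero residual variance gives a capped finite sentinel
  y0 <- 100 + X[, 1:3] %*% c(2, 0.3, 0.5)
  fit0 <- fit_glm(cbind(as.numeric(y0)), X)
  expect_warning(t0 <- contrast_t(fit0), "capped")
  expect_true(is.finite(t0[1]) && t0[1] > 0)
})

test_that("PSC betas are invariant to the baseline intensity", {
  p <- make_patch(n_columns = 6, voxels_per_column = 4, gain_sd = 0, seed = 4)
  m <- laminar_response_model()
  sch <- build_physical_schedule(repetitions = 2)
  X <- build_design(sch$events, sch$n_volumes, 2)
  b <- lapply(c(500, 2000), function(base) {
    Y <- simulate_run(p, m, sch, run_type = "physical", noise_sd = 0,
                      run_gain_sd = 0, baseline = base)
    task_betas(fit_glm(normalize_psc(Y), X))
  })
  expect_equal(b[[1]], b[[2]], tolerance = 1e-8)
})

test_that("event balancing equalizes condition durations", {
  set.seed(3)
  ev <- sample_percept_stream(percept_process(), 160, seed = 5)
  bal <- balance_events(ev, tr_s = 2, seed = 1)
  tot <- function(e, cond) sum(e$duration[e$trial_type == cond])
  expect_lte(abs(tot(bal, "horizontal") - tot(bal, "vertical")), 2)
  # whole events are dropped, largest first, from the over-represented side
  over <- if (tot(ev, "horizontal") > tot(ev, "vertical")) "horizontal" else "vertical"
  if (abs(tot(ev, "horizontal") - tot(ev, "vertical")) > 2) {
    dropped <- setdiff(ev$onset[ev$trial_type == over],
                       bal$onset[bal$trial_type == over])
    kept_max <- max(bal$duration[bal$trial_type == over])
    expect_true(all(ev$duration[ev$onset %in% dropped] >= kept_max - 1e-9))
  }
  expect_identical(bal, balance_events(ev, tr_s = 2, seed = 1))
})
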