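mk_events <- function(onset, duration, cond = "horizontal") {
  data.frame(onset = onset, duration = duration, trial_type = cond,
             source = "percept")
}

test_that("trial extraction applies the onset-anchored PSC formula", {
  tc <- c(100, 103, 106, 100, 100, 100, 100, 100)
  tr <- extract_trials(tc, mk_events(0, 12), tr_s = 2, window_tr = 2)
  expect_equal(as.numeric(tr$psc), c(0, 3, 6))
  # onsets snap to the nearest earlier TR sample
  tr2 <- extract_trials(tc, mk_events(3.7, 12), tr_s = 2, window_tr = 2)
  expect_equal(as.numeric(tr2$psc[1, ]), (tc[2:4] - tc[2]) / tc[2] * 100)
  # zero onset value invalidates the trial
  tc0 <- c(0, 5, 5, 5)
  tr0 <- extract_trials(tc0, mk_events(0, 8), tr_s = 2, window_tr = 1)
  expect_equal(nrow(tr0$psc), 0)
  expect_equal(tr0$n_invalid, 1)
  # windows exceeding the run are dropped
  tr3 <- extract_trials(tc, mk_events(c(0, 12), c(12, 10)), 2, window_tr = 3)
  expect_equal(nrow(tr3$psc), 1)
  expect_error(extract_trials(tc, mk_events(99, 2), 2), "outside run")
})

test_that("duration selection enforces the 10-s minimum", {
  tc <- rep(c(100, 101), 20)
  tr <- extract_trials(tc, mk_events(c(0, 10, 24), c(8, 10, 14)), 2, 5)
  sel <- select_trials(tr, 10)
  expect_equal(nrow(sel$psc), 2)
  expect_equal(sel$n_excluded, 1)
  expect_error(select_trials(select_trials(tr, 10), 99), "no trials")
  # every retained trial contributes the full window (balanced average)
  expect_true(all(is.finite(sel$psc)))
  expect_equal(ncol(sel$psc), 6)
  # physical blocks are all 10 s: never excluded
  sch <- build_physical_schedule(repetitions = 2)
  ev <- sch$events[sch$events$trial_type == "horizontal", ]
  trp <- extract_trials(rep(c(100, 102), sch$n_volumes / 2), ev, 2, 5)
  expect_equal(select_trials(trp, 10)$n_excluded, 0)
})

test_that("role pooling merges preferred and crossed trials", {
  mk_tr <- function(vals, cond) list(psc = matrix(vals, 1), duration_s = 10,
                                     condition = cond, n_invalid = 0L)
  th <- list(psc = rbind(c(0, 1), c(0, 2)), duration_s = c(10, 10),
             condition = c("horizontal", "vertical"), n_invalid = 0L)
  tv <- list(psc = rbind(c(0, 3), c(0, 4)), duration_s = c(10, 10),
             condition = c("vertical", "horizontal"), n_invalid = 0L)
  pooled <- pool_roles_and_average(th, tv)
  expect_equal(pooled$curve_preferred, colMeans(rbind(c(0, 1), c(0, 3))))
  expect_equal(pooled$curve_not_preferred, colMeans(rbind(c(0, 2), c(0, 4))))
  # identical cluster responses: pooling leaves the curve unchanged
  pooled2 <- pool_roles_and_average(th, th)
  expect_equal(pooled2$curve_preferred, pooled2$curve_not_preferred)
  # pooling is permutation-invariant over trials
  th_perm <- list(psc = th$psc[2:1, ], duration_s = th$duration_s,
                  condition = th$condition[2:1], n_invalid = 0L)
  expect_equal(pool_roles_and_average(th_perm, tv)$curve_preferred,
               pooled$curve_preferred)
  expect_error(pool_roles_and_average(mk_tr(c(0, 1), "vertical"),
                                      mk_tr(c(0, 1), "horizontal")),
               "missing role")
})

test_that("curve similarity uses Spearman rho and the exact signed-rank", {
  a <- matrix(rep(c(0, 1, 2, 3, 4, 5), 8), nrow = 8, byrow = TRUE)
  s <- similarity_test(a, a)
  expect_equal(s$rho, rep(1, 8))
  expect_equal(s$p, 2 / 2^8)
  rev_a <- a[, c(1, 6:2)]
  expect_equal(similarity_test(a, rev_a)$rho, rep(-1, 8))
  # constant curve: subject dropped with a warning
  a2 <- a; a2[3, ] <- 5
  expect_warning(s2 <- similarity_test(a2, a), "constant curve")
  expect_equal(s2$n, 7)
  # calibration: independent noise curves reject at the nominal rate
  set.seed(9)
  rej <- replicate(1000, {
    x <- matrix(rnorm(48), 8); y <- matrix(rnorm(48), 8)
    similarity_test(x, y)$p <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.011)
})

test_that("hypothesis-2 ERAs show positive responses in both roles", {
  g <- demo_result()$group
  pref <- g$era_curves$V1_ambiguous_preferred
  nonpref <- g$era_curves$V1_ambiguous_not_preferred
  expect_gt(max(pref$mean_psc), 0)
  expect_gt(max(nonpref$mean_psc), 0)
  # physical preferred ERA rises through the HRF latency; with 10-s blocks
  # the block response keeps accumulating, so the peak falls at offsets 2-5
  phys <- g$era_curves$V1_physical_preferred
  expect_true(all(diff(phys$mean_psc[1:4]) > 0))
  expect_true((which.max(phys$mean_psc) - 1) %in% 2:5)
  # balanced average: equal trial count at every time point
  expect_equal(length(unique(pref$n)), 1)
})
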