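test_that("column extension propagates labels through the depth", {
  p <- make_patch(n_columns = 9, voxels_per_column = 5, uv_jitter_sd = 0.05,
                  seed = 2)
  lab <- rep("none", nrow(p))
  mid <- which(p$column == 5)[3]        # one mid-depth voxel in column 5
  lab[mid] <- "H"
  a <- structure(list(label = lab), class = "cluster_assignment")
  ext <- extend_clusters_columnwise(a, p, radius = 0.39)
  expect_true(all(ext$label[p$column == 5] == "H"))
  # columns with no assigned voxel within the radius stay unlabeled
  expect_true(all(ext$label[p$column == 1] == "none"))
  # radius 0 labels only columns that already contain assigned voxels
  ext0 <- extend_clusters_columnwise(a, p, radius = 0)
  expect_true(all(ext0$label[p$column == 5] == "H"))
  expect_equal(sum(ext0$label == "H"), 5)
  # conflicting labels within the radius: nearest assigned voxel wins
  lab2 <- lab
  far <- which(p$column == 5)[1]
  lab2[far] <- "V"
  p2 <- p
  p2$u[far] <- p2$u0[far] + 0.3         # push the V voxel off-center
  p2$v[far] <- p2$v0[far]
  p2$u[mid] <- p2$u0[mid]; p2$v[mid] <- p2$v0[mid]
  a2 <- structure(list(label = lab2), class = "cluster_assignment")
  ext2 <- extend_clusters_columnwise(a2, p2, radius = 0.39)
  expect_true(all(ext2$label[p$column == 5] == "H"))
})

test_that("differential profiles subtract layer-wise and antisymmetrically", {
  prof <- data.frame(cluster = "H", condition_type = rep(c("physical", "ambiguous"), each = 3),
                     layer = rep(c("deep", "middle", "superficial"), 2),
                     depth_center = rep(c(1, 3, 5) / 6, 2),
                     mean_psc = c(0.1, 0.2, 0.3, 0.1, 0.1, 0.1),
                     sem_psc = 0, n_voxels = 5)
  d <- differential_profile(prof)
  expect_equal(d$diff_psc, c(0, 0.1, 0.2))
  # identical profiles difference to zero
  same <- prof; same$mean_psc <- rep(c(0.4, 0.5, 0.6), 2)
  expect_equal(differential_profile(same)$diff_psc, rep(0, 3))
  # antisymmetry under swapping the condition types
  phys <- prof[prof$condition_type == "physical", ]
  amb <- prof[prof$condition_type == "ambiguous", ]
  expect_equal(differential_profile(phys, amb)$diff_psc,
               -differential_profile(amb, phys)$diff_psc)
  bad <- amb[-1, ]
  expect_error(differential_profile(phys, bad), "mismatch")
})

test_that("profile slopes are exact for affine profiles", {
  expect_equal(profile_slope(c(0.1, 0.2, 0.3)), 0.3)
  # affine input recovered exactly: y = a + b * depth
  centers <- depth_bins()$centers
  expect_equal(profile_slope(0.7 + 2.4 * centers), 2.4)
  expect_equal(profile_slope(c(0, 0, 0)), 0)
  expect_error(profile_slope(c(1, 2)), "3 layers")
  s <- slope_test(rep(0, 8))
  expect_false(s$defined)
})

test_that("layer binning is balanced for uniform depth sampling", {
  p <- make_patch(n_columns = 60, voxels_per_column = 9, curvature_sd = 0,
                  seed = 5)
  lay <- cut(p$d_ev, depth_bins()$edges, include.lowest = TRUE)
  counts <- as.numeric(table(lay))
  expect_true(all(abs(counts - nrow(p) / 3) <= 0.1 * nrow(p) / 3))
})

test_that("shared drainage with equal amplitudes gives a flat differential", {
  # noiseless matched-condition unit: the draining-vein term cancels exactly
  co <- make_cohort(n_subjects = 1, hemispheres = 1, scenario = "matched",
                    runs_per_condition = 1, n_columns = 8,
                    voxels_per_column = 6, repetitions = 3, noise_sd = 0,
                    voxel_gain_sd = 0, run_gain_sd = 0, seed = 3)
  unit <- co$units[[1]]
  patch <- unit$patches$V1
  betas <- lapply(c(physical = 1, ambiguous = 2), function(ri) {
    r <- unit$runs[[ri]]
    src <- if (r$type == "ambiguous") "percept" else "stimulus"
    X <- build_design(r$schedule$events, r$schedule$n_volumes, 2,
                      motion_source = src)
    task_betas(fit_glm(normalize_psc(r$Y$V1), X))
  })
  prof <- laminar_profile(truth_assignment(patch), patch,
                          betas$physical, betas$ambiguous)
  d <- differential_profile(prof)
  # flat up to the sub-percent scale difference introduced by normalizing
  # each run by its own temporal mean (which includes task signal)
  expect_lt(max(abs(d$diff_psc)), 0.02)
  for (cl in c("H", "V")) {
    dd <- d[d$cluster == cl, ]
    expect_lt(abs(profile_slope(dd$diff_psc[order(dd$depth_center)])), 0.01)
  }
})

test_that("hypothesis-2 cohorts show the laminar devein signature", {
  g <- demo_result()$group
  # physical V1 profile increases toward the superficial layer
  pr <- g$group_profiles
  v1p <- pr[pr$roi == "V1" & pr$condition_type == "physical" & pr$cluster == "H", ]
  v1p <- v1p[order(v1p$depth_center), ]
  expect_true(all(diff(v1p$mean_psc) > 0))
  # positive V1 differential slope, flat hMT+
  expect_gt(g$slope_tests$V1$mean_slope, 0)
  expect_lt(g$slope_tests$V1$p, 0.05)
  expect_gt(g$slope_tests$hMT$p, 0.05)
})
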