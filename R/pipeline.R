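#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis with defaults matching
#' the experimental conditions (TR 2 s, 10-s motion
#' blocks, 16-s flicker, 20-s fixation bookends, 6 super-block repetitions,
#' 6 runs per condition, 8 subjects x 2 hemispheres, 95th-percentile
#' clusters, 5-cycle high-pass, 0.39 column-extension radius, 10-s minimum
#' trial / 5-TR window). A run is fully reproducible from the configuration
#' plus its seed.
#'
#' @param seed Master seed (fans out to every stage).
#' @param scenario Feedback scenario (see [scenario_amplitudes()]).
#' @param n_subjects,hemispheres Cohort structure.
#' @param runs_per_condition Runs per condition type per unit.
#' @param n_columns,voxels_per_column Patch size per ROI.
#' @param repetitions Super-block repetitions per run.
#' @param tr_s Repetition time (s).
#' @param noise_sd,ar1 Noise level (PSC) and lag-1 autocorrelation.
#' @param voxel_gain_sd,run_gain_sd Response-gain heterogeneity across
#'   voxels and runs (log-scale SDs).
#' @param beta_pref,beta_nonpref,beta_flicker,drain_gain,amplitude_scale_ambiguous
#'   Response-model parameters (see [laminar_response_model()]).
#' @param pct Cluster percentile threshold.
#' @param hp_cycles High-pass cutoff (cycles per run).
#' @param radius Column-extension radius (u, v units).
#' @param min_trial_s,window_tr ERA trial selection.
#' @return Configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, scenario = "hypothesis2",
                            n_subjects = 8, hemispheres = 2,
                            runs_per_condition = 6,
                            n_columns = 16, voxels_per_column = 6,
                            repetitions = 6, tr_s = 2,
                            noise_sd = 2, ar1 = 0.3,
                            voxel_gain_sd = 0.3, run_gain_sd = 0.15,
                            beta_pref = 2, beta_nonpref = 0.2,
                            beta_flicker = 0.8, drain_gain = 1,
                            amplitude_scale_ambiguous = 0.5,
                            pct = 95, hp_cycles = 5, radius = 0.39,
                            min_trial_s = 10, window_tr = 5) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

era_trials_for_runs <- function(runs_norm, members, run_type, tr_s, window_tr) {
  if (!any(members)) return(NULL)
  acc <- list(psc = NULL, duration_s = numeric(0), condition = character(0),
              n_invalid = 0L)
  for (r in runs_norm) {
    if (r$type != run_type) next
    tc <- rowMeans(r$Y[, members, drop = FALSE])
    src <- if (run_type == "ambiguous") "percept" else "stimulus"
    ev <- r$events[r$events$source == src &
                     r$events$trial_type %in% c("horizontal", "vertical"), ]
    tr <- extract_trials(tc, ev, tr_s, window_tr)
    acc$psc <- rbind(acc$psc, tr$psc)
    acc$duration_s <- c(acc$duration_s, tr$duration_s)
    acc$condition <- c(acc$condition, tr$condition)
    acc$n_invalid <- acc$n_invalid + tr$n_invalid
  }
  acc
}

#' Analyze one subject-hemisphere unit
#'
#' Runs the full single-unit analysis for each ROI: normalization,
#' multi-run prewhitened GLMs per condition type, H > V contrast,
#' percentile winner-take-all clusters, cluster PSC and specificity
#' summaries, column-extended laminar and differential profiles with
#' per-cluster slopes, ground-truth recovery, and ERA curves per role and
#' condition type.
#'
#' @param unit One element of a [make_cohort()] `units` list.
#' @param cfg A [pipeline_config()].
#' @param design_cache Optional environment for reusing design matrices of
#'   identical (physical) schedules across units.
#' @return Named list (per ROI) of unit results.
#' @export
analyze_unit <- function(unit, cfg, design_cache = NULL) {
  tr_s <- cfg$tr_s
  types <- vapply(unit$runs, `[[`, "", "type")
  designs <- lapply(unit$runs, function(r) {
    key <- if (r$type == "physical") paste0("physical_", r$start) else NA
    if (!is.na(key) && !is.null(design_cache) &&
        !is.null(design_cache[[key]])) {
      return(design_cache[[key]])
    }
    X <- build_design(r$schedule$events, r$schedule$n_volumes, tr_s,
                      motion_source = if (r$type == "ambiguous") "percept" else "stimulus",
                      hp_cycles = cfg$hp_cycles, validate = FALSE)
    if (!is.na(key) && !is.null(design_cache)) design_cache[[key]] <- X
    X
  })
  X_joint <- list(ambiguous = stack_designs(designs[types == "ambiguous"]))
  if (!is.null(design_cache) && !is.null(design_cache$stack_physical)) {
    X_joint$physical <- design_cache$stack_physical
  } else {
    X_joint$physical <- stack_designs(designs[types == "physical"])
    if (!is.null(design_cache)) design_cache$stack_physical <- X_joint$physical
  }
  rois <- names(unit$patches)
  nvox <- vapply(unit$patches, nrow, 1L)
  roi_cols <- split(seq_len(sum(nvox)),
                    factor(rep(rois, nvox), levels = rois))
  # one fit per condition type across both ROIs (designs are shared)
  norm_runs <- lapply(unit$runs, function(r) {
    do.call(cbind, lapply(rois, function(roi) normalize_psc(r$Y[[roi]])))
  })
  fits <- lapply(c(physical = "physical", ambiguous = "ambiguous"), function(type) {
    fit_glm(do.call(rbind, norm_runs[types == type]), X_joint[[type]])
  })
  tmap_all <- contrast_t(fits$physical)
  betas_p_all <- task_betas(fits$physical)
  betas_a_all <- task_betas(fits$ambiguous)
  out <- list()
  for (roi in rois) {
    patch <- unit$patches[[roi]]
    cols <- roi_cols[[roi]]
    runs_norm <- lapply(seq_along(unit$runs), function(ri) {
      list(type = unit$runs[[ri]]$type,
           Y = norm_runs[[ri]][, cols, drop = FALSE],
           events = unit$runs[[ri]]$schedule$events,
           n_volumes = unit$runs[[ri]]$schedule$n_volumes)
    })
    tmap <- tmap_all[cols]
    assign <- define_clusters(tmap, cfg$pct)
    betas_p <- betas_p_all[cols, , drop = FALSE]
    betas_a <- betas_a_all[cols, , drop = FALSE]
    psc <- summarize_cluster_psc(assign, betas_p, betas_a)
    spec <- cluster_specificity(assign, betas_p, betas_a)
    ext <- extend_clusters_columnwise(assign, patch, cfg$radius)
    prof <- laminar_profile(ext, patch, betas_p, betas_a)
    dprof <- differential_profile(prof)
    slopes <- vapply(split(dprof, dprof$cluster), function(d) {
      d <- d[order(d$depth_center), ]
      profile_slope(d$diff_psc, d$depth_center)
    }, numeric(1))
    assigned <- assign$label != "none"
    recovery <- if (any(assigned)) {
      mean(assign$label[assigned] == patch$true_cluster[assigned])
    } else NA_real_
    era <- list()
    for (ct in c("physical", "ambiguous")) {
      th <- era_trials_for_runs(runs_norm, assign$label == "H", ct, tr_s, cfg$window_tr)
      tv <- era_trials_for_runs(runs_norm, assign$label == "V", ct, tr_s, cfg$window_tr)
      th <- select_trials(th, cfg$min_trial_s)
      tv <- select_trials(tv, cfg$min_trial_s)
      era[[ct]] <- pool_roles_and_average(th, tv)
    }
    out[[roi]] <- list(
      subject = unit$subject, hemisphere = unit$hemisphere, roi = roi,
      tmap = tmap, assignment = assign, extended = ext,
      betas_physical = betas_p, betas_ambiguous = betas_a,
      psc = psc, specificity = spec, profile = prof,
      differential = dprof, slope = mean(slopes), slopes_by_cluster = slopes,
      recovery = recovery,
      era = era)
  }
  out
}

subject_means <- function(df, value) {
  agg <- stats::aggregate(df[[value]], list(subject = df$subject), mean)
  agg$x[order(agg$subject)]
}

#' Group-level statistics over analyzed units
#'
#' Assembles per-unit results into the group comparisons: cluster PSC
#' physical vs ambiguous (per ROI and cluster, one pair per
#' subject-hemisphere), specificity physical vs ambiguous (per ROI, one
#' pair per subject after averaging clusters and hemispheres),
#' differential-profile slope vs zero (per ROI, one slope per subject), ERA
#' preferred vs not-preferred similarity (per ROI, ambiguous condition) and
#' the cross-area V1 vs hMT+ similarity of role-averaged ambiguous curves.
#' All tests are two-sided exact Wilcoxon signed-rank tests.
#'
#' @param results List (over units) of [analyze_unit()] outputs.
#' @return List with `psc_tests`, `specificity_tests`, `slope_tests`,
#'   `era_tests`, `era_cross_area`, `group_profiles`, `era_curves`,
#'   `recovery`, and the tidy per-unit tables used to compute them.
#' @export
group_stats <- function(results) {
  rois <- names(results[[1]])
  psc_rows <- list(); spec_rows <- list(); slope_rows <- list()
  prof_rows <- list(); rec <- numeric(0)
  era_unit <- list()
  for (res in results) {
    for (roi in rois) {
      u <- res[[roi]]
      id <- data.frame(subject = u$subject, hemisphere = u$hemisphere, roi = roi)
      psc_rows[[length(psc_rows) + 1L]] <- cbind(id, u$psc)
      spec_rows[[length(spec_rows) + 1L]] <- cbind(id, u$specificity)
      slope_rows[[length(slope_rows) + 1L]] <- cbind(id, slope = u$slope)
      prof_rows[[length(prof_rows) + 1L]] <- cbind(id, u$profile)
      rec <- c(rec, u$recovery)
      for (ct in names(u$era)) {
        era_unit[[length(era_unit) + 1L]] <- cbind(
          id, condition_type = ct,
          role = rep(c("preferred", "not_preferred"), each = length(u$era[[ct]]$curve_preferred)),
          tr_offset = rep(seq_along(u$era[[ct]]$curve_preferred) - 1L, 2),
          psc = c(u$era[[ct]]$curve_preferred, u$era[[ct]]$curve_not_preferred))
      }
    }
  }
  psc_tab <- do.call(rbind, psc_rows)
  spec_tab <- do.call(rbind, spec_rows)
  slope_tab <- do.call(rbind, slope_rows)
  prof_tab <- do.call(rbind, prof_rows)
  era_tab <- do.call(rbind, era_unit)

  # cluster PSC: paired over subject-hemisphere units, per ROI x cluster
  psc_tests <- list()
  for (roi in rois) for (cl in c("H", "V")) {
    d <- psc_tab[psc_tab$roi == roi & psc_tab$cluster == cl, ]
    wide <- merge(d[d$condition_type == "physical", c("subject", "hemisphere", "mean_psc")],
                  d[d$condition_type == "ambiguous", c("subject", "hemisphere", "mean_psc")],
                  by = c("subject", "hemisphere"), suffixes = c("_phys", "_amb"))
    psc_tests[[paste(roi, cl, sep = "_")]] <-
      compare_conditions(wide$mean_psc_phys, wide$mean_psc_amb)
  }

  # specificity: per subject (clusters and hemispheres averaged), per ROI
  specificity_tests <- list()
  for (roi in rois) {
    d <- spec_tab[spec_tab$roi == roi, ]
    p <- subject_means(d[d$condition_type == "physical", ], "mean_specificity")
    a <- subject_means(d[d$condition_type == "ambiguous", ], "mean_specificity")
    specificity_tests[[roi]] <- compare_conditions(p, a)
  }

  # differential slopes: per subject, per ROI
  slope_tests <- list()
  for (roi in rois) {
    s <- subject_means(slope_tab[slope_tab$roi == roi, ], "slope")
    slope_tests[[roi]] <- slope_test(s)
  }

  # group laminar profiles
  group_profiles <- stats::aggregate(
    mean_psc ~ roi + cluster + condition_type + layer + depth_center,
    data = prof_tab, FUN = mean)
  group_profiles$sem_psc <- stats::aggregate(
    mean_psc ~ roi + cluster + condition_type + layer + depth_center,
    data = prof_tab, FUN = sem)$mean_psc

  # ERA: per-subject curves (hemispheres averaged)
  curve_mat <- function(roi, ct, role) {
    d <- era_tab[era_tab$roi == roi & era_tab$condition_type == ct &
                   era_tab$role == role, ]
    agg <- stats::aggregate(psc ~ subject + tr_offset, data = d, FUN = mean)
    agg <- agg[order(agg$subject, agg$tr_offset), ]
    matrix(agg$psc, nrow = length(unique(agg$subject)), byrow = TRUE,
           dimnames = list(NULL, paste0("tr", sort(unique(agg$tr_offset)))))
  }
  era_tests <- list(); era_curves <- list()
  for (roi in rois) {
    for (ct in c("physical", "ambiguous")) {
      for (role in c("preferred", "not_preferred")) {
        era_curves[[paste(roi, ct, role, sep = "_")]] <-
          group_era_curve(curve_mat(roi, ct, role))
      }
    }
    era_tests[[roi]] <- similarity_test(curve_mat(roi, "ambiguous", "preferred"),
                                        curve_mat(roi, "ambiguous", "not_preferred"))
  }
  era_cross_area <- if (all(c("V1", "hMT") %in% rois)) {
    avg <- function(roi) (curve_mat(roi, "ambiguous", "preferred") +
                            curve_mat(roi, "ambiguous", "not_preferred")) / 2
    similarity_test(avg("V1"), avg("hMT"))
  } else NULL

  list(psc_tests = psc_tests, specificity_tests = specificity_tests,
       slope_tests = slope_tests, era_tests = era_tests,
       era_cross_area = era_cross_area,
       group_profiles = group_profiles, era_curves = era_curves,
       recovery = mean(rec, na.rm = TRUE),
       tables = list(psc = psc_tab, specificity = spec_tab,
                     slopes = slope_tab, profiles = prof_tab, era = era_tab))
}

#' Run the end-to-end pipeline
#'
#' Composes the full analysis: schedule design and percept simulation,
#' laminar BOLD generation, normalization and prewhitened GLMs, cluster
#' definition, specificity, laminar differential profiling with slope
#' tests, and event-related averaging, returning every group statistic and
#' the per-unit tables, plus a log of thresholds and exclusions. Fully
#' deterministic given the configuration (one master seed fans out to all
#' stages).
#'
#' @param config A [pipeline_config()].
#' @return List with `config`, `cohort` (the synthetic dataset), `units`
#'   (per-unit results), `group` (group statistics), and `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- laminar_response_model(
    beta_pref = config$beta_pref, beta_nonpref = config$beta_nonpref,
    beta_flicker = config$beta_flicker, drain_gain = config$drain_gain,
    amplitude_scale_ambiguous = config$amplitude_scale_ambiguous)
  cohort <- make_cohort(
    n_subjects = config$n_subjects, hemispheres = config$hemispheres,
    scenario = config$scenario, seed = config$seed,
    runs_per_condition = config$runs_per_condition,
    n_columns = config$n_columns, voxels_per_column = config$voxels_per_column,
    repetitions = config$repetitions, model = model,
    noise_sd = config$noise_sd, ar1 = config$ar1, tr_s = config$tr_s,
    voxel_gain_sd = config$voxel_gain_sd, run_gain_sd = config$run_gain_sd)
  cache <- new.env(parent = emptyenv())
  units <- lapply(cohort$units, function(u) {
    tryCatch(analyze_unit(u, config, design_cache = cache),
             error = function(e) stop_stage(
               sprintf("unit s%d h%d", u$subject, u$hemisphere), conditionMessage(e)))
  })
  group <- group_stats(units)
  log <- list(
    scenario = config$scenario, seed = config$seed,
    pct = config$pct,
    thresholds = do.call(rbind, lapply(units, function(res) {
      do.call(rbind, lapply(res, function(u) data.frame(
        subject = u$subject, hemisphere = u$hemisphere, roi = u$roi,
        threshold_hi = u$assignment$threshold_hi,
        threshold_lo = u$assignment$threshold_lo,
        n_H = sum(u$assignment$label == "H"),
        n_V = sum(u$assignment$label == "V"))))
    })),
    recovery = group$recovery)
  list(config = config, cohort = cohort, units = units, group = group, log = log)
}

#' Flat machine-readable summary of a pipeline result
#'
#' @param result From [run_pipeline()].
#' @return Named list of scalar statistics (means, test statistics,
#'   p-values, Ns), suitable for JSON/YAML export.
#' @export
pipeline_summary <- function(result) {
  g <- result$group
  out <- list(recovery = g$recovery)
  for (nm in names(g$psc_tests)) {
    t <- g$psc_tests[[nm]]
    out[[paste0("psc_", nm, "_physical")]] <- t$mean_physical
    out[[paste0("psc_", nm, "_ambiguous")]] <- t$mean_ambiguous
    out[[paste0("psc_", nm, "_p")]] <- t$p
    out[[paste0("psc_", nm, "_n")]] <- t$n
  }
  for (nm in names(g$specificity_tests)) {
    t <- g$specificity_tests[[nm]]
    out[[paste0("specificity_", nm, "_physical")]] <- t$mean_physical
    out[[paste0("specificity_", nm, "_ambiguous")]] <- t$mean_ambiguous
    out[[paste0("specificity_", nm, "_p")]] <- t$p
  }
  for (nm in names(g$slope_tests)) {
    t <- g$slope_tests[[nm]]
    out[[paste0("slope_", nm)]] <- t$mean_slope
    out[[paste0("slope_", nm, "_p")]] <- t$p
  }
  for (nm in names(g$era_tests)) {
    t <- g$era_tests[[nm]]
    out[[paste0("era_similarity_", nm, "_rho")]] <- t$mean_rho
    out[[paste0("era_similarity_", nm, "_p")]] <- t$p
  }
  if (!is.null(g$era_cross_area)) {
    out$era_cross_area_rho <- g$era_cross_area$mean_rho
    out$era_cross_area_p <- g$era_cross_area$p
  }
  out
}
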