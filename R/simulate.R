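#' Laminar microvascular + macrovascular response model
#'
#' Microvascular depth profiles are unit-mean weighting functions of
#' equivolume depth: the feedforward profile is a raised middle-layer bump
#' (thalamic input at mid-depth) on a unit floor, the feedback profile is
#' depth-uniform. The macrovascular draining-vein component is additive and
#' linear in depth, with weight proportional to the column-mean
#' microvascular signal (`drain_gain * d * mean_column(micro)`), so with
#' `drain_gain = 0` the measured profile equals the microvascular one, and
#' shared drainage cancels exactly in differential profiles of
#' equal-amplitude conditions.
#'
#' @param beta_pref Microvascular response amplitude (PSC) of a cluster to
#'   its preferred motion condition.
#' @param beta_nonpref Amplitude to the non-preferred condition.
#' @param beta_flicker Flicker response amplitude (all voxels).
#' @param drain_gain Macrovascular slope coefficient (>= 0, unitless).
#' @param amplitude_scale_ambiguous Multiplicative amplitude reduction of
#'   feedback (ambiguous) responses in V1, in (0, 1].
#' @param bump_height,bump_width Feedforward mid-depth bump parameters.
#' @param drain_model "additive" (default): macrovascular term
#'   `drain_gain * d * mean_column(micro)`; "leakage": a lower-triangular
#'   ascending-vein model where each voxel accumulates
#'   `drain_gain * d * mean(micro of voxels at or below its depth)` within
#'   its column. Both reduce to the pure microvascular profile at
#'   `drain_gain = 0`.
#' @return A `laminar_response_model` list with profile functions
#'   `micro_profile_ff(d)` and `micro_profile_fb(d)` (both unit mean over
#'   depth).
#' @export
laminar_response_model <- function(beta_pref = 2, beta_nonpref = 0.2,
                                   beta_flicker = 0.8, drain_gain = 1,
                                   amplitude_scale_ambiguous = 0.5,
                                   bump_height = 0.4, bump_width = 0.2,
                                   drain_model = c("additive", "leakage")) {
  drain_model <- match.arg(drain_model)
  stopifnot(drain_gain >= 0,
            amplitude_scale_ambiguous > 0, amplitude_scale_ambiguous <= 1)
  raw_ff <- function(d) 1 + bump_height * exp(-(d - 0.5)^2 / (2 * bump_width^2))
  norm <- stats::integrate(raw_ff, 0, 1)$value
  micro_profile_ff <- function(d) raw_ff(d) / norm
  micro_profile_fb <- function(d) rep(1, length(d))
  structure(list(beta_pref = beta_pref, beta_nonpref = beta_nonpref,
                 beta_flicker = beta_flicker, drain_gain = drain_gain,
                 amplitude_scale_ambiguous = amplitude_scale_ambiguous,
                 micro_profile_ff = micro_profile_ff,
                 micro_profile_fb = micro_profile_fb,
                 drain_model = drain_model),
            class = "laminar_response_model")
}

#' HRF-convolved condition regressors for a simulated run
#'
#' Horizontal/vertical regressors from stimulus events (physical runs) or
#' percept events (ambiguous runs), plus the stimulus-locked flicker
#' regressor; shared between the ROIs of a run.
#'
#' @param schedule Schedule list.
#' @param run_type "physical" or "ambiguous".
#' @return Matrix n_volumes x 3 (horizontal, vertical, flicker).
#' @export
run_regressors <- function(schedule, run_type) {
  events <- schedule$events
  n <- schedule$n_volumes
  tr <- schedule$tr_s
  kern <- hrf_kernel(tr)
  src <- if (run_type == "ambiguous") "percept" else "stimulus"
  ev_motion <- events[events$source == src, ]
  ev_stim <- events[events$source == "stimulus", ]
  reg <- cbind(
    horizontal = convolve_hrf(event_boxcar(ev_motion, "horizontal", n, tr), kern, tr),
    vertical = convolve_hrf(event_boxcar(ev_motion, "vertical", n, tr), kern, tr),
    flicker = convolve_hrf(event_boxcar(ev_stim, "flicker", n, tr), kern, tr))
  reg
}

#' Per-voxel microvascular amplitudes for one run
#'
#' Maps ground-truth cluster labels and the feedback scenario onto the
#' amplitude each voxel contributes to the horizontal, vertical, and
#' flicker regressors of a run.
#'
#' Scenarios (ambiguous runs, V1 only):
#' * `hypothesis1` — feedback targets the percept-matched cluster only:
#'   each V1 cluster keeps its preferred/non-preferred selectivity, scaled
#'   by `amplitude_scale_ambiguous`.
#' * `hypothesis2` — feedback activates both retinotopic clusters equally:
#'   every labeled V1 voxel responds with
#'   `amplitude_scale_ambiguous * beta_pref` to both percepts.
#' * `null` — no evoked response in either condition, anywhere.
#' * `matched` — the ambiguous response is identical to the physical one
#'   (same amplitudes, same feedforward profile, shared drainage); the
#'   no-difference configuration used for type-I calibration.
#'
#' hMT+ amplitudes are condition-invariant in all scenarios except `null`.
#'
#' @param patch Patch from [make_patch()].
#' @param model A [laminar_response_model()].
#' @param run_type "physical" or "ambiguous".
#' @param scenario One of "hypothesis1", "hypothesis2", "null", "matched".
#' @return List with matrix `amp` (voxels x conditions horizontal,
#'   vertical, flicker) and `profile` ("ff" or "fb") for the run.
#' @export
scenario_amplitudes <- function(patch, model, run_type, scenario) {
  scenario <- match.arg(scenario, c("hypothesis1", "hypothesis2", "null", "matched"))
  run_type <- match.arg(run_type, c("physical", "ambiguous"))
  nv <- nrow(patch)
  amp <- matrix(0, nv, 3, dimnames = list(NULL, c("horizontal", "vertical", "flicker")))
  if (scenario == "null") {
    return(list(amp = amp, profile = "ff"))
  }
  is_h <- patch$true_cluster == "H"
  is_v <- patch$true_cluster == "V"
  selective <- function(scale) {
    amp[is_h, "horizontal"] <<- scale * model$beta_pref
    amp[is_h, "vertical"] <<- scale * model$beta_nonpref
    amp[is_v, "vertical"] <<- scale * model$beta_pref
    amp[is_v, "horizontal"] <<- scale * model$beta_nonpref
  }
  amp[, "flicker"] <- model$beta_flicker
  profile <- "ff"
  if (run_type == "physical") {
    selective(1)
  } else {
    roi <- patch$roi[1]
    if (roi == "hMT" || scenario == "matched") {
      selective(1)                       # condition-invariant response
    } else if (scenario == "hypothesis1") {
      selective(model$amplitude_scale_ambiguous)
      profile <- "fb"
    } else {                             # hypothesis2
      s <- model$amplitude_scale_ambiguous * model$beta_pref
      amp[is_h | is_v, c("horizontal", "vertical")] <- s
      profile <- "fb"
    }
  }
  list(amp = amp, profile = profile)
}

#' Simulate one laminar BOLD run
#'
#' Voxel signal is
#' `baseline * (1 + sum_c PSC_c(d) * (boxcar_c %*% HRF) / 100) + noise`,
#' with `PSC_c(d) = amp_c * profile(d) + drain_gain * d * mean_column(amp_c
#' * profile(d))` per the linear draining-vein model, and AR(1) Gaussian
#' noise of marginal SD `noise_sd` (in PSC units of the baseline).
#' Horizontal/vertical regressors come from stimulus events in physical
#' runs and percept events in ambiguous runs; flicker always from stimulus
#' events.
#'
#' @param patch Patch from [make_patch()].
#' @param model A [laminar_response_model()].
#' @param schedule Schedule list from [build_physical_schedule()] or
#'   [build_ambiguous_schedule()].
#' @param scenario Feedback scenario, see [scenario_amplitudes()].
#' @param run_type "physical" or "ambiguous".
#' @param noise_sd Marginal noise SD (PSC units).
#' @param ar1 Lag-1 noise autocorrelation, |ar1| < 1.
#' @param baseline Baseline image intensity (arbitrary units).
#' @param run_gain_sd SD (log scale) of the run-level multiplicative
#'   response gain emulating run-to-run BOLD amplitude fluctuations
#'   (arousal, adaptation); unit mean, 0 disables.
#' @param seed Integer seed.
#' @param reg Optional precomputed regressor matrix from
#'   [run_regressors()] (shared across ROIs of the same run).
#' @param run_gain Optional fixed run gain (overrides `run_gain_sd`; used
#'   to share one gain across the ROIs of a run).
#' @return Matrix volumes x voxels, with attributes `tr_s` and `run_type`.
#' @export
simulate_run <- function(patch, model, schedule, scenario = "hypothesis2",
                         run_type = c("physical", "ambiguous"),
                         noise_sd = 2, ar1 = 0.3, baseline = 1000,
                         run_gain_sd = 0.15, seed = 1, reg = NULL,
                         run_gain = NULL) {
  run_type <- match.arg(run_type)
  stopifnot(abs(ar1) < 1, noise_sd >= 0, baseline > 0)
  events <- schedule$events
  n <- schedule$n_volumes
  tr <- schedule$tr_s
  if (any(events$onset + events$duration > schedule$total_s + 1e-9)) {
    stop("events exceed run length", call. = FALSE)
  }
  sa <- scenario_amplitudes(patch, model, run_type, scenario)
  prof_fun <- if (sa$profile == "ff") model$micro_profile_ff else model$micro_profile_fb
  prof <- prof_fun(patch$d_ev)

  if (is.null(reg)) reg <- run_regressors(schedule, run_type)

  if (is.null(run_gain)) {
    run_gain <- if (run_gain_sd > 0) {
      with_seed(seed + 1L, stats::rlnorm(1, -run_gain_sd^2 / 2, run_gain_sd))
    } else 1
  }
  vox_gain <- if (is.null(patch$gain)) rep(1, nrow(patch)) else patch$gain

  # per-voxel PSC amplitude per condition: microvascular + macrovascular
  drain_model <- model$drain_model %||% "additive"
  psc <- matrix(0, nrow(patch), 3)
  for (j in 1:3) {
    micro <- run_gain * vox_gain * sa$amp[, j] * prof
    if (drain_model == "additive") {
      drain <- stats::ave(micro, patch$column)
    } else {
      # ascending-vein leakage: each voxel sees the mean microvascular
      # signal of voxels at or below its own depth within the column
      drain <- numeric(nrow(patch))
      for (ix in split(seq_len(nrow(patch)), patch$column)) {
        o <- ix[order(patch$d_ev[ix])]
        drain[o] <- cumsum(micro[o]) / seq_along(o)
      }
    }
    psc[, j] <- micro + model$drain_gain * patch$d_ev * drain
  }
  signal <- baseline * (1 + (reg %*% t(psc)) / 100)
  if (noise_sd > 0) {
    noise <- with_seed(seed, {
      innov <- matrix(stats::rnorm(n * nrow(patch), 0,
                                   noise_sd * sqrt(1 - ar1^2)), n, nrow(patch))
      if (ar1 != 0) {
        for (t in 2:n) innov[t, ] <- innov[t, ] + ar1 * innov[t - 1L, ]
      }
      innov
    })
    signal <- signal + baseline * noise / 100
  }
  attr(signal, "tr_s") <- tr
  attr(signal, "run_type") <- run_type
  signal
}

#' Simulate a full cohort under a feedback scenario
#'
#' One unit per (subject, hemisphere); each unit holds a V1-like and an
#' hMT+-like patch and alternating physical and ambiguous runs sharing the
#' experimental block scheme. Ground truth (patches, amplitudes, events) is
#' stored losslessly alongside the time series. Defaults reproduce the
#' experimental conditions (8 analyzed subjects x 2 hemispheres, 6 runs per
#' condition, TR 2 s, 10-s motion blocks, 16-s flicker, 20-s fixation
#' bookends); smaller cohorts for simulation studies are obtained via the
#' size arguments.
#'
#' @param n_subjects,hemispheres Cohort structure.
#' @param scenario Feedback scenario, see [scenario_amplitudes()].
#' @param seed Master seed (fans out to every run and patch).
#' @param runs_per_condition Physical and ambiguous runs per unit.
#' @param n_columns,voxels_per_column Patch size per ROI.
#' @param repetitions Super-block repetitions per run.
#' @param model A [laminar_response_model()].
#' @param process A [percept_process()].
#' @param noise_sd,ar1,tr_s Acquisition parameters.
#' @param voxel_gain_sd,run_gain_sd Voxel-level and run-level response-gain
#'   heterogeneity (log-scale SDs; see [make_patch()] and
#'   [simulate_run()]).
#' @return A `quartet_cohort` list: `units` (list of subject-hemisphere
#'   units with `patches` and `runs`), plus the generating parameters.
#' @export
make_cohort <- function(n_subjects = 8, hemispheres = 2,
                        scenario = "hypothesis2", seed = 1,
                        runs_per_condition = 6,
                        n_columns = 16, voxels_per_column = 6,
                        repetitions = 6,
                        model = laminar_response_model(),
                        process = percept_process(),
                        noise_sd = 2, ar1 = 0.3, tr_s = 2,
                        voxel_gain_sd = 0.3, run_gain_sd = 0.15) {
  scenario <- match.arg(scenario, c("hypothesis1", "hypothesis2", "null", "matched"))
  n_units <- n_subjects * hemispheres
  unit_seeds <- fan_seeds(seed, n_units)
  # physical block order counterbalanced across runs (H-first, V-first, ...)
  phys <- list(
    horizontal = build_physical_schedule(repetitions = repetitions, tr_s = tr_s,
                                         start = "horizontal"),
    vertical = build_physical_schedule(repetitions = repetitions, tr_s = tr_s,
                                       start = "vertical"))
  phys_reg <- lapply(phys, run_regressors, run_type = "physical")
  units <- vector("list", n_units)
  k <- 0L
  for (subj in seq_len(n_subjects)) {
    for (hemi in seq_len(hemispheres)) {
      k <- k + 1L
      seeds <- fan_seeds(unit_seeds[k], 2L + 3L * runs_per_condition * 2L)
      patches <- list(
        V1 = make_patch(n_columns, voxels_per_column, roi = "V1",
                        gain_sd = voxel_gain_sd, seed = seeds[1]),
        hMT = make_patch(n_columns, voxels_per_column, roi = "hMT",
                         gain_sd = voxel_gain_sd, seed = seeds[2])
      )
      runs <- list()
      si <- 2L
      for (r in seq_len(runs_per_condition)) {
        for (type in c("physical", "ambiguous")) {
          if (type == "physical") {
            variant <- if (r %% 2L == 1L) "horizontal" else "vertical"
            sched <- phys[[variant]]
            reg <- phys_reg[[variant]]
          } else {
            sched <- build_ambiguous_schedule(process, seed = seeds[si + 1L],
                                              repetitions = repetitions,
                                              tr_s = tr_s)
            reg <- run_regressors(sched, "ambiguous")
          }
          run_gain <- if (run_gain_sd > 0) {
            with_seed(seeds[si + 2L], stats::rlnorm(1, -run_gain_sd^2 / 2, run_gain_sd))
          } else 1
          Y <- lapply(seq_along(patches), function(pi) {
            simulate_run(patches[[pi]], model = model, schedule = sched,
                         scenario = scenario, run_type = type,
                         noise_sd = noise_sd, ar1 = ar1,
                         seed = seeds[si + 2L] + 7919L * pi,
                         reg = reg, run_gain = run_gain)
          })
          names(Y) <- names(patches)
          runs[[length(runs) + 1L]] <- list(type = type, schedule = sched,
                                            start = if (type == "physical") variant else NA,
                                            Y = Y)
          si <- si + 3L
        }
      }
      units[[k]] <- list(subject = subj, hemisphere = hemi,
                         patches = patches, runs = runs)
    }
  }
  structure(list(units = units, scenario = scenario, model = model,
                 n_subjects = n_subjects, hemispheres = hemispheres,
                 tr_s = tr_s, seed = seed),
            class = "quartet_cohort")
}
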