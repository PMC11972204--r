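#' Normalize time courses to percent of temporal mean
#'
#' Each voxel's series is divided by its temporal mean and multiplied by
#' 100, so the normalized series has mean 100 and GLM betas on it are in
#' percent-signal-change units. Voxels with (near-)zero temporal mean are
#' excluded and reported via the `excluded` attribute rather than silently
#' propagating non-finite values.
#'
#' @param Y Matrix volumes x voxels.
#' @return Normalized matrix with attributes `normalized = TRUE` and
#'   `excluded` (indices of dropped zero-mean voxels).
#' @export
normalize_psc <- function(Y) {
  Y <- as.matrix(Y)
  mu <- colMeans(Y)
  bad <- which(!is.finite(mu) | abs(mu) < 1e-12)
  keep <- setdiff(seq_len(ncol(Y)), bad)
  out <- sweep(Y[, keep, drop = FALSE], 2, mu[keep], "/") * 100
  attr(out, "normalized") <- TRUE
  attr(out, "excluded") <- bad
  attr(out, "tr_s") <- attr(Y, "tr_s")
  out
}

#' Discrete-cosine high-pass basis
#'
#' DCT columns covering frequencies up to `cycles_per_run` cycles over the
#' run (the conventional cycles-based high-pass cutoff). Used as confound
#' columns in the design by default; [highpass()] projects them out
#' directly.
#'
#' @param n_volumes Number of volumes.
#' @param cycles_per_run High-pass cutoff in cycles per run (>= 1).
#' @return Matrix `n_volumes` x `2 * cycles_per_run` of unit-norm DCT
#'   regressors (constant term excluded).
#' @export
dct_basis <- function(n_volumes, cycles_per_run) {
  stopifnot(cycles_per_run >= 1)
  k_max <- 2L * as.integer(cycles_per_run)
  if (k_max >= n_volumes) stop("high-pass cutoff at or above Nyquist", call. = FALSE)
  t <- seq_len(n_volumes) - 0.5
  B <- sapply(seq_len(k_max), function(k) cos(pi * k * t / n_volumes))
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  colnames(B) <- paste0("dct", seq_len(k_max))
  B
}

#' Project low-frequency drift out of time courses
#'
#' @param Y Matrix volumes x voxels.
#' @param cycles_per_run High-pass cutoff in cycles per run.
#' @return Filtered matrix (mean preserved).
#' @export
highpass <- function(Y, cycles_per_run) {
  Y <- as.matrix(Y)
  B <- dct_basis(nrow(Y), cycles_per_run)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  sweep(Yc - B %*% crossprod(B, Yc), 2, mu, "+")
}

#' Build an HRF-convolved design matrix
#'
#' One task column per condition (horizontal, vertical, flicker by
#' default), each an events boxcar convolved with the canonical two-gamma
#' HRF, plus DCT high-pass confounds and an intercept. In physical runs the
#' motion columns are time-locked to stimulus events; in ambiguous runs
#' they are time-locked to percept-report events while flicker stays
#' stimulus-locked.
#'
#' @param events Events table.
#' @param n_volumes,tr_s Run geometry.
#' @param conditions Task condition labels.
#' @param motion_source Event source for the motion columns ("stimulus" or
#'   "percept").
#' @param hp_cycles High-pass cutoff in cycles per run (0 disables).
#' @param hrf HRF kernel (defaults to [hrf_kernel()] at `tr_s`).
#' @param validate Validate the events table first (skipped internally for
#'   generator-produced tables).
#' @return Design matrix with attributes `task` (task column indices),
#'   `conditions`, and `rank_deficient` (TRUE when a task column is all
#'   zero).
#' @export
build_design <- function(events, n_volumes, tr_s,
                         conditions = c("horizontal", "vertical", "flicker"),
                         motion_source = "stimulus", hp_cycles = 5,
                         hrf = NULL, validate = TRUE) {
  if (validate) validate_events(events)
  if (is.null(hrf)) hrf <- hrf_kernel(tr_s)
  run_len <- n_volumes * tr_s
  if (any(events$onset >= run_len)) stop("event onset outside run", call. = FALSE)
  cols <- sapply(conditions, function(cond) {
    src <- if (cond %in% c("horizontal", "vertical", "ambiguous")) motion_source else "stimulus"
    convolve_hrf(event_boxcar(events[events$source == src, ], cond, n_volumes, tr_s),
                 hrf, tr_s)
  })
  colnames(cols) <- conditions
  zero_col <- apply(cols, 2, function(x) all(x == 0))
  conf <- if (hp_cycles >= 1) dct_basis(n_volumes, hp_cycles) else NULL
  X <- cbind(cols, intercept = 1, conf)
  attr(X, "task") <- seq_along(conditions)
  attr(X, "conditions") <- conditions
  attr(X, "rank_deficient") <- any(zero_col)
  X
}

#' Stack per-run designs into a joint multi-run design
#'
#' Task columns are shared across runs; intercepts and confounds are
#' run-specific (block diagonal), so run-wise baselines and drifts are
#' modeled separately.
#'
#' @param designs List of per-run design matrices from [build_design()].
#' @return Joint design matrix with `task` and `runs` attributes (`runs`
#'   gives each run's row indices for segment-wise prewhitening).
#' @export
stack_designs <- function(designs) {
  task_idx <- attr(designs[[1]], "task")
  conds <- attr(designs[[1]], "conditions")
  tasks <- do.call(rbind, lapply(designs, function(X) X[, task_idx, drop = FALSE]))
  confs <- lapply(designs, function(X) X[, -task_idx, drop = FALSE])
  nconf <- vapply(confs, ncol, 1L)
  total <- sum(vapply(confs, nrow, 1L))
  conf_block <- matrix(0, total, sum(nconf))
  conf_names <- character(sum(nconf))
  row0 <- 0L; col0 <- 0L
  runs <- vector("list", length(designs))
  for (i in seq_along(confs)) {
    nr <- nrow(confs[[i]])
    conf_block[row0 + seq_len(nr), col0 + seq_len(nconf[i])] <- confs[[i]]
    conf_names[col0 + seq_len(nconf[i])] <-
      paste0("run", i, "_", colnames(confs[[i]]))
    runs[[i]] <- row0 + seq_len(nr)
    row0 <- row0 + nr; col0 <- col0 + nconf[i]
  }
  colnames(conf_block) <- conf_names
  X <- cbind(tasks, conf_block)
  attr(X, "task") <- seq_along(task_idx)
  attr(X, "conditions") <- conds
  attr(X, "runs") <- runs
  X
}

yule_walker_ar <- function(E, order, segments) {
  # pooled autocovariances across voxels, within run segments
  acov <- numeric(order + 1L)
  for (seg in segments) {
    Es <- E[seg, , drop = FALSE]
    for (k in 0:order) {
      n <- nrow(Es)
      acov[k + 1L] <- acov[k + 1L] +
        sum(Es[seq_len(n - k), , drop = FALSE] * Es[(k + 1L):n, , drop = FALSE])
    }
  }
  if (acov[1L] < 1e-12) return(rep(0, order))
  r <- acov[-1L] / acov[1L]
  R <- stats::toeplitz(c(1, r[seq_len(order - 1L)])[seq_len(order)])
  phi <- tryCatch(solve(R, r), error = function(e) rep(0, order))
  # guard against non-stationary estimates
  if (sum(abs(phi)) >= 0.99) phi <- phi * 0.98 / sum(abs(phi))
  phi
}

whiten_segments <- function(M, phi, segments) {
  p <- length(phi)
  out <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    Ms <- M[segments[[i]], , drop = FALSE]
    n <- nrow(Ms)
    W <- Ms[(p + 1L):n, , drop = FALSE]
    for (k in seq_len(p)) {
      W <- W - phi[k] * Ms[(p + 1L - k):(n - k), , drop = FALSE]
    }
    out[[i]] <- W
  }
  do.call(rbind, out)
}

#' Fit a prewhitened multi-voxel GLM
#'
#' OLS fit followed by AR(`ar_order`) correction: residual autocovariances
#' (pooled across voxels by default) give Yule-Walker AR coefficients, data
#' and design are prewhitened segment-wise within each run, and the model
#' is refit; the estimate-whiten-refit cycle runs `iterations` times
#' (two-iteration Cochrane-Orcutt). Betas on mean-100 normalized data are
#' in percent-signal-change units relative to the unmodeled baseline. When
#' residuals are numerically zero (noiseless data) whitening is skipped and
#' betas are the exact OLS solution.
#'
#' @param Y Normalized matrix volumes x voxels.
#' @param X Design from [build_design()] or [stack_designs()].
#' @param ar_order AR model order for the noise (default 2).
#' @param iterations Cochrane-Orcutt iterations.
#' @return A `glm_fit` list: `beta` (coefficients x voxels), `sigma2`
#'   (residual variance per voxel, whitened scale), `xtx_inv`, `df`,
#'   `ar_coef`, `conditions`, `task`.
#' @export
fit_glm <- function(Y, X, ar_order = 2, iterations = 2) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("Y and X row mismatch", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("more regressors than volumes", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop(sprintf("design is rank deficient (rank %d < %d columns)",
                 qrx$rank, ncol(X)), call. = FALSE)
  }
  segments <- attr(X, "runs") %||% list(seq_len(nrow(X)))
  beta <- qr.coef(qrx, Y)
  resid <- Y - X %*% beta
  # AR coefficients come from residuals of the task + intercept model: the
  # many DCT confounds absorb low-frequency noise power and would deflate
  # the Yule-Walker estimate, leaving the contrast t anti-conservative
  ar_cols <- grep("dct", colnames(X) %||% rep("", ncol(X)), invert = TRUE)
  X_ar <- X[, ar_cols, drop = FALSE]
  qr_ar <- qr(X_ar)
  resid_ar <- Y - X_ar %*% qr.coef(qr_ar, Y)
  phi <- rep(0, ar_order)
  Xw <- X; Yw <- Y; qrw <- qrx
  noiseless <- mean(resid^2) < 1e-18
  if (!noiseless && ar_order > 0) {
    for (it in seq_len(iterations)) {
      phi <- yule_walker_ar(resid_ar, ar_order, segments)
      Xw <- whiten_segments(X, phi, segments)
      Yw <- whiten_segments(Y, phi, segments)
      qrw <- qr(Xw)
      if (qrw$rank < ncol(Xw)) {
        stop(sprintf("whitened design near-singular (condition number %.3g)",
                     kappa(Xw)), call. = FALSE)
      }
      beta <- qr.coef(qrw, Yw)
      resid <- Y - X %*% beta
      resid_ar <- resid + (X[, -ar_cols, drop = FALSE] %*%
                             beta[-ar_cols, , drop = FALSE])
    }
  }
  residw <- Yw - Xw %*% beta
  df <- nrow(Xw) - ncol(Xw)
  sigma2 <- colSums(residw^2) / df
  xtx_inv <- chol2inv(qr.R(qrw))
  structure(list(beta = beta, sigma2 = sigma2, xtx_inv = xtx_inv, df = df,
                 ar_coef = phi, conditions = attr(X, "conditions"),
                 task = attr(X, "task"), residw = residw),
            class = "glm_fit")
}

#' Task betas in PSC units
#'
#' @param fit A [fit_glm()] result on normalized data.
#' @return Matrix voxels x task conditions.
#' @export
task_betas <- function(fit) {
  b <- t(fit$beta[fit$task, , drop = FALSE])
  colnames(b) <- fit$conditions
  b
}

#' Contrast t-map between two task conditions
#'
#' @param fit A [fit_glm()] result.
#' @param a,b Condition labels; the contrast is `a - b` (swapping labels
#'   negates the map exactly).
#' @param t_cap Finite sentinel for zero-residual (noiseless) voxels; a
#'   warning is raised when capping occurs.
#' @return Numeric t per voxel, with attribute `df`.
#' @export
contrast_t <- function(fit, a = "horizontal", b = "vertical", t_cap = 1e6) {
  if (!all(c(a, b) %in% fit$conditions)) {
    stop("contrast conditions absent from fit", call. = FALSE)
  }
  cvec <- rep(0, nrow(fit$beta))
  cvec[fit$task[match(a, fit$conditions)]] <- 1
  cvec[fit$task[match(b, fit$conditions)]] <- -1
  eff <- as.numeric(crossprod(cvec, fit$beta))
  cvar <- as.numeric(crossprod(cvec, fit$xtx_inv %*% cvec))
  se <- sqrt(fit$sigma2 * cvar)
  t <- eff / se
  bad <- !is.finite(t) | abs(t) > t_cap
  if (any(bad)) {
    warning("zero-residual voxels: t capped at finite sentinel", call. = FALSE)
    t[bad] <- sign(eff[bad]) * t_cap
    t[bad & eff == 0] <- 0
  }
  attr(t, "df") <- fit$df
  t
}

#' Balance event totals between two conditions
#'
#' For contrasts between conditions with unequal total durations (percept
#' events in ambiguous runs), whole events are dropped from the
#' over-represented condition, largest first, until the total durations
#' match to within one TR. Ties in duration are broken reproducibly from
#' the seed.
#'
#' @param events Events table.
#' @param a,b Condition labels to balance.
#' @param tr_s Matching tolerance (one TR).
#' @param source Event source to balance within.
#' @param seed Tie-break seed.
#' @return Events table with the dropped events removed.
#' @export
balance_events <- function(events, a = "horizontal", b = "vertical",
                           tr_s = 2, source = "percept", seed = 1) {
  sel <- events$source == source & events$trial_type %in% c(a, b)
  ev <- events[sel, , drop = FALSE]
  tot <- function(cond) sum(ev$duration[ev$trial_type == cond])
  n_dropped <- 0L
  repeat {
    d <- tot(a) - tot(b)
    if (abs(d) <= tr_s) break
    over <- if (d > 0) a else b
    cand <- which(ev$trial_type == over)
    if (!length(cand)) break
    mx <- cand[ev$duration[cand] == max(ev$duration[cand])]
    pick <- if (length(mx) > 1L) with_seed(seed + n_dropped, sample(mx, 1L)) else mx
    ev <- ev[-pick, , drop = FALSE]
    n_dropped <- n_dropped + 1L
  }
  out <- rbind(events[!sel, , drop = FALSE], ev)
  out <- out[order(out$source, out$onset), ]
  rownames(out) <- NULL
  out
}
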