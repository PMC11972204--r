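#' Wilcoxon signed-rank test with an exact small-sample distribution
#'
#' Paired two-sided signed-rank test used for all group comparisons. For
#' small samples (default N <= 25 after dropping zero differences) the
#' p-value is computed from the exact permutation distribution of the
#' positive-rank sum over all 2^N sign assignments, evaluated by a
#' shift-convolution over the (tie-averaged) ranks, so ties are handled
#' exactly rather than by falling back to a normal approximation. Above the
#' cutoff, or when `mode = "normal"`, a normal approximation with tie
#' correction is used.
#'
#' @param x Numeric vector (or paired differences when `y` is NULL).
#' @param y Optional second paired sample; the test is on `x - y`.
#' @param mode "auto" (exact for N <= `exact_max`), "exact", or "normal".
#' @param exact_max Largest N for which "auto" uses the exact distribution.
#' @return List with `statistic` (positive-rank sum V), `p` (two-sided),
#'   `n` (pairs entering the test after dropping zero differences),
#'   `n_zero` (dropped zero differences), `method`, and `defined` (FALSE
#'   when all differences are zero, in which case `p` is NA).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 mode = c("auto", "exact", "normal"),
                                 exact_max = 25L) {
  mode <- match.arg(mode)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p = NA_real_, n = 0L, n_zero = n_zero,
                method = "undefined (all differences zero)", defined = FALSE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  use_exact <- (mode == "exact") || (mode == "auto" && n <= exact_max)
  if (use_exact) {
    # exact distribution of the positive-rank sum over all sign flips:
    # double the (possibly half-integer) average ranks so support is integer
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[s+1] = #assignments with doubled sum s
    f[1L] <- 1
    for (rk in r2) {
      g <- f
      g[(rk + 1L):(total + 1L)] <- g[(rk + 1L):(total + 1L)] + f[1L:(total + 1L - rk)]
      f <- g
    }
    f <- f / sum(f)
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[1L:(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact signed-rank (shift-convolution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = v, p = p, n = n, n_zero = n_zero, method = method,
       defined = TRUE)
}

#' Spearman rank correlation of two curves
#'
#' Thin wrapper around [stats::cor()] with average-rank tie handling;
#' returns NA (rather than erroring) when either input is constant.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Spearman rho, or NA if undefined.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("curves must have equal length", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}
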