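# Pleiotropy-robust univariable estimators: MR-Egger, weighted median,
# weighted mode.

#' MR-Egger regression
#'
#' Weighted regression of the outcome effects on the exposure effects with an
#' intercept, weights \eqn{1/\sigma_{Yj}^2}, after orienting every record so
#' that \eqn{\beta_{Xj} \ge 0} (both effects are negated together, which
#' leaves the causal slope unchanged and makes the intercept well defined).
#' The slope estimates the causal effect under the INSIDE assumption; the
#' intercept estimates average directional pleiotropy. Standard errors use
#' the same capped multiplicative convention as [ivw()] (residual scale
#' bounded below by 1).
#'
#' @param set A [harmonised_set()] with at least 3 records.
#' @return List of class `egger_result` with elements `slope` (an
#'   [mr_result()], method `"mr_egger"`) and `intercept` (list with
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pvalue`).
#' @export
mr_egger <- function(set) {
  rec <- set$records
  K <- nrow(rec)
  if (K < 3L) stop("MR-Egger needs at least 3 instruments")
  sgn <- ifelse(rec$beta_x < 0, -1, 1)
  bx <- sgn * rec$beta_x
  by <- sgn * rec$beta_y
  w <- 1 / rec$se_y^2
  if (stats::var(bx) == 0) stop("collinear: no variance in exposure effects")

  # weighted least squares with intercept via the normal equations
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  intercept <- (swxx * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  resid <- by - intercept - slope * bx
  sigma2 <- sum(w * resid^2) / (K - 2L)
  scale2 <- max(1, sigma2)
  se_slope <- sqrt(sw / det * scale2)
  se_intercept <- sqrt(swxx / det * scale2)

  slope_res <- mr_result(set$exposure_id, set$outcome_id, "mr_egger",
                         estimate = slope, se = se_slope, n_snps = K,
                         diagnostics = list(sigma2 = sigma2))
  int_p <- 2 * stats::pnorm(-abs(intercept / se_intercept))
  structure(list(
    slope = slope_res,
    intercept = list(estimate = intercept, se = se_intercept,
                     ci_low = intercept - Z975 * se_intercept,
                     ci_high = intercept + Z975 * se_intercept,
                     pvalue = max(int_p, .Machine$double.xmin))),
    class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4f (se %.4f), p = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}

# Per-SNP ratio estimates and first-order inverse-variance weights shared by
# the median and mode estimators.
ratio_weights <- function(rec) {
  list(theta = rec$beta_y / rec$beta_x,
       w = rec$beta_x^2 / rec$se_y^2)
}

# Weighted-median point estimate: sort ratios, take cumulative standardised
# weight p_j = cumsum(w)_j - w_j/2, interpolate theta linearly at p = 0.5.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(theta[1L])
  n <- length(theta)
  if (0.5 >= p[n]) return(theta[n])
  j <- max(which(p <= 0.5))
  if (p[j] == 0.5) return(theta[j])
  theta[j] + (theta[j + 1L] - theta[j]) * (0.5 - p[j]) / (p[j + 1L] - p[j])
}

# Parametric bootstrap SE: resample beta_x, beta_y from normals centred on
# the observed values with their SEs, recompute the point estimate.
bootstrap_se <- function(rec, point_fun, boot_reps, seed) {
  K <- nrow(rec)
  est <- withr_seed(seed, {
    bx <- matrix(stats::rnorm(K * boot_reps, rec$beta_x, rec$se_x), nrow = K)
    by <- matrix(stats::rnorm(K * boot_reps, rec$beta_y, rec$se_y), nrow = K)
    vapply(seq_len(boot_reps), function(b) {
      theta <- by[, b] / bx[, b]
      w <- bx[, b]^2 / rec$se_y^2
      point_fun(theta, w)
    }, numeric(1))
  })
  stats::sd(est)
}

# Evaluate a block with a temporary RNG state derived from `seed`, restoring
# the caller's state afterwards.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Weighted-median MR estimate
#'
#' Per-SNP ratio estimates \eqn{\theta_j = \beta_{Yj}/\beta_{Xj}} with
#' first-order inverse-variance weights
#' \eqn{w_j = \beta_{Xj}^2/\sigma_{Yj}^2}; the estimate is the weighted
#' median obtained by linear interpolation of the cumulative standardised
#' weight function at 0.5. Consistent when at least half the weight comes
#' from valid instruments. The standard error is a seeded parametric
#' bootstrap (effects resampled from normals centred on the observed values).
#'
#' @param set A [harmonised_set()] with at least 3 records.
#' @param boot_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An [mr_result()] with method `"weighted_median"`.
#' @export
weighted_median <- function(set, boot_reps = 1000L, seed = 1L) {
  rec <- set$records
  if (nrow(rec) < 3L) stop("weighted median needs at least 3 instruments")
  rw <- ratio_weights(rec)
  est <- weighted_median_point(rw$theta, rw$w)
  se <- bootstrap_se(rec, weighted_median_point, boot_reps, seed)
  mr_result(set$exposure_id, set$outcome_id, "weighted_median",
            estimate = est, se = se, n_snps = nrow(rec),
            diagnostics = list(ratios = rw$theta, weights = rw$w,
                               boot_reps = boot_reps, seed = seed))
}

# Weighted Gaussian kernel density of the ratio estimates, maximised on a
# 512-point grid spanning [min - 3h, max + 3h] then refined by golden
# section within the bracketing grid cells.
weighted_mode_point <- function(theta, w, bandwidth_factor = 1.0) {
  w <- w / sum(w)
  s <- stats::sd(theta)
  m <- stats::mad(theta)  # includes the 1.4826 consistency constant
  h <- bandwidth_factor * 0.9 * min(s, m) * length(theta)^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # degenerate spread: all ratios (essentially) identical
    return(theta[which.max(w)])
  }
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - theta) / h)) / h,
           numeric(1))
  }
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512L)
  fx <- dens(grid)
  i <- which.max(fx)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(512L, i + 1L)]
  golden_section_max(dens, lo, hi, tol = 1e-10)
}

# Deterministic golden-section maximisation on [lo, hi].
golden_section_max <- function(f, lo, hi, tol = 1e-10, max_iter = 200L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  for (it in seq_len(max_iter)) {
    if (abs(b - a) < tol) break
    if (fc >= fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

#' Weighted-mode MR estimate
#'
#' Per-SNP ratios and weights as in [weighted_median()]; the estimate is the
#' maximiser of the weighted Gaussian kernel density of the ratios, with
#' bandwidth \eqn{h = \phi \cdot 0.9 \cdot \min(SD, MAD) \cdot K^{-1/5}}
#' (MAD with the 1.4826 normal-consistency constant). Consistent when the
#' largest subset of instruments sharing one causal estimate is valid. The
#' density is maximised on a 512-point grid followed by golden-section
#' refinement; when all ratios are identical (zero bandwidth) the common
#' ratio is returned. SE by seeded parametric bootstrap.
#'
#' @param set A [harmonised_set()] with at least 3 records.
#' @param bandwidth_factor Bandwidth multiplier \eqn{\phi} (default 1).
#' @param boot_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An [mr_result()] with method `"weighted_mode"`.
#' @export
weighted_mode <- function(set, bandwidth_factor = 1.0, boot_reps = 1000L,
                          seed = 1L) {
  rec <- set$records
  if (nrow(rec) < 3L) stop("weighted mode needs at least 3 instruments")
  rw <- ratio_weights(rec)
  est <- weighted_mode_point(rw$theta, rw$w, bandwidth_factor)
  se <- bootstrap_se(rec,
                     function(theta, w)
                       weighted_mode_point(theta, w, bandwidth_factor),
                     boot_reps, seed)
  mr_result(set$exposure_id, set$outcome_id, "weighted_mode",
            estimate = est, se = se, n_snps = nrow(rec),
            diagnostics = list(ratios = rw$theta, weights = rw$w,
                               bandwidth_factor = bandwidth_factor,
                               boot_reps = boot_reps, seed = seed))
}

#' Run the pleiotropy-robust estimator suite on one instrument set
#'
#' Applies MR-Egger, weighted median, and weighted mode (each needs K >= 3).
#'
#' @param set A [harmonised_set()].
#' @param boot_reps,seed Bootstrap controls for median/mode.
#' @param bandwidth_factor Mode bandwidth multiplier.
#' @return Named list with `mr_egger` (an `egger_result`), `weighted_median`
#'   and `weighted_mode` ([mr_result()]s), or `NULL` when K < 3.
#' @export
run_sensitivity <- function(set, boot_reps = 1000L, seed = 1L,
                            bandwidth_factor = 1.0) {
  if (nrow(set$records) < 3L) return(NULL)
  list(mr_egger = mr_egger(set),
       weighted_median = weighted_median(set, boot_reps, seed),
       weighted_mode = weighted_mode(set, bandwidth_factor, boot_reps, seed))
}
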