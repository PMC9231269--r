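# Univariable two-sample MR estimators and diagnostics.

Z975 <- stats::qnorm(0.975)

#' Construct a univariable MR result
#'
#' @param exposure_id,outcome_id Trait identifiers.
#' @param method Estimator label (`"wald_ratio"`, `"ivw"`, `"mr_egger"`,
#'   `"weighted_median"`, `"weighted_mode"`, or `"none"`).
#' @param estimate,se Point estimate (SD outcome per SD exposure) and its
#'   standard error.
#' @param n_snps Number of instruments used.
#' @param diagnostics Optional named list (Q, Q_df, Q_p, mean_F, per-SNP
#'   ratios, ...).
#' @param reason For `method = "none"`: why no estimate is available.
#' @return An `mr_result` object. The 95% CI uses normal quantiles
#'   throughout.
#' @export
mr_result <- function(exposure_id, outcome_id, method, estimate = NA_real_,
                      se = NA_real_, n_snps = 0L, diagnostics = list(),
                      reason = NULL) {
  if (!is.na(estimate)) {
    stopifnot(se > 0 || n_snps == 0L)
    ci_low <- estimate - Z975 * se
    ci_high <- estimate + Z975 * se
    pvalue <- 2 * stats::pnorm(-abs(estimate / se))
    pvalue <- max(pvalue, .Machine$double.xmin)  # keep within (0, 1]
  } else {
    ci_low <- ci_high <- pvalue <- NA_real_
  }
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 method = method, estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
                 n_snps = n_snps, diagnostics = diagnostics,
                 reason = reason),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  if (is.na(x$estimate)) {
    cat(sprintf("MR result: %s -> %s, no estimate (%s)\n",
                x$exposure_id, x$outcome_id, x$reason))
  } else {
    cat(sprintf(
      "MR result [%s]: %s -> %s\n  estimate %.4f (95%% CI %.4f, %.4f), p = %.3g, K = %d\n",
      x$method, x$exposure_id, x$outcome_id, x$estimate, x$ci_low, x$ci_high,
      x$pvalue, x$n_snps))
  }
  invisible(x)
}

#' Convert MR results to a tidy data frame
#'
#' @param results An `mr_result` or list of them.
#' @return Data frame with one row per result: exposure, outcome, method,
#'   estimate, se, ci_low, ci_high, pvalue, n_snps, and the scalar
#'   diagnostics Q, Q_df, Q_p, mean_F where available.
#' @export
mr_results_table <- function(results) {
  if (inherits(results, "mr_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    d <- r$diagnostics
    data.frame(exposure = r$exposure_id, outcome = r$outcome_id,
               method = r$method, estimate = r$estimate, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, pvalue = r$pvalue,
               n_snps = r$n_snps,
               Q = if (is.null(d$Q)) NA_real_ else d$Q,
               Q_df = if (is.null(d$Q_df)) NA_real_ else d$Q_df,
               Q_p = if (is.null(d$Q_p)) NA_real_ else d$Q_p,
               mean_F = if (is.null(d$mean_F)) NA_real_ else d$mean_F,
               reason = if (is.null(r$reason)) "" else r$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wald ratio estimate from a single instrument
#'
#' Causal effect \eqn{\theta = \beta_Y / \beta_X} with first-order
#' delta-method standard error \eqn{se = \sigma_Y / |\beta_X|}.
#'
#' @param set A [harmonised_set()] with exactly one record, or a one-row
#'   record data frame.
#' @return An [mr_result()] with method `"wald_ratio"`.
#' @export
wald_ratio <- function(set) {
  if (inherits(set, "harmonised_set")) {
    stopifnot(nrow(set$records) == 1L)
    r <- set$records[1L, ]
    exposure_id <- set$exposure_id; outcome_id <- set$outcome_id
  } else {
    r <- set[1L, ]
    exposure_id <- "exposure"; outcome_id <- "outcome"
  }
  if (r$beta_x == 0) stop("Wald ratio undefined: beta_x = 0")
  mr_result(exposure_id, outcome_id, "wald_ratio",
            estimate = r$beta_y / r$beta_x,
            se = r$se_y / abs(r$beta_x),
            n_snps = 1L)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Weighted regression of the outcome effects on the exposure effects through
#' the origin with weights \eqn{1/\sigma_{Yj}^2}:
#' \deqn{\hat\theta = \frac{\sum_j \beta_{Xj}\beta_{Yj}\sigma_{Yj}^{-2}}
#'                         {\sum_j \beta_{Xj}^2 \sigma_{Yj}^{-2}}.}
#' Under the default `capped_multiplicative` convention the standard error is
#' the fixed-effect SE inflated by the residual standard deviation when the
#' instruments are overdispersed (residual scale bounded below by 1), never
#' deflated; `fixed` gives the pure fixed-effect SE. Cochran's Q with
#' `K - 1` degrees of freedom is attached as a heterogeneity diagnostic.
#'
#' @param set A [harmonised_set()] with at least two records.
#' @param re_mode `"capped_multiplicative"` (default) or `"fixed"`.
#' @return An [mr_result()] with method `"ivw"` and diagnostics `Q`, `Q_df`,
#'   `Q_p`, `ratios`.
#' @export
ivw <- function(set, re_mode = c("capped_multiplicative", "fixed")) {
  re_mode <- match.arg(re_mode)
  rec <- set$records
  K <- nrow(rec)
  if (K < 2L) stop("IVW needs at least 2 instruments; use wald_ratio for K = 1")
  w <- 1 / rec$se_y^2
  sxx <- sum(w * rec$beta_x^2)
  theta <- sum(w * rec$beta_x * rec$beta_y) / sxx
  se_fixed <- sqrt(1 / sxx)
  Q <- sum(w * (rec$beta_y - theta * rec$beta_x)^2)
  Q_df <- K - 1L
  Q_p <- stats::pchisq(Q, df = Q_df, lower.tail = FALSE)
  scale2 <- if (re_mode == "capped_multiplicative") max(1, Q / Q_df) else 1
  mr_result(set$exposure_id, set$outcome_id, "ivw",
            estimate = theta, se = se_fixed * sqrt(scale2), n_snps = K,
            diagnostics = list(Q = Q, Q_df = Q_df, Q_p = Q_p,
                               ratios = rec$beta_y / rec$beta_x,
                               re_mode = re_mode))
}

#' Mean F-statistic of an instrument set
#'
#' Mean over instruments of \eqn{(\beta_{Xj}/\sigma_{Xj})^2}; the standard
#' single-exposure instrument-strength measure (> 10 is the usual adequacy
#' convention).
#'
#' @param set A [harmonised_set()].
#' @return Scalar mean F.
#' @export
mean_f <- function(set) {
  rec <- set$records
  if (nrow(rec) == 0L) return(NA_real_)
  mean((rec$beta_x / rec$se_x)^2)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect omitting each instrument in turn; flags
#' results driven by a single SNP.
#'
#' @param set A [harmonised_set()] with at least 3 records.
#' @param re_mode Passed to [ivw()].
#' @return Data frame with one row per omitted SNP: `omitted`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
leave_one_out <- function(set, re_mode = "capped_multiplicative") {
  rec <- set$records
  K <- nrow(rec)
  if (K < 3L) stop("leave-one-out needs at least 3 instruments")
  rows <- lapply(seq_len(K), function(j) {
    sub <- harmonised_set(set$exposure_id, set$outcome_id,
                          rec[-j, , drop = FALSE])
    fit <- ivw(sub, re_mode = re_mode)
    data.frame(omitted = rec$snp[j], estimate = fit$estimate, se = fit$se,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               pvalue = fit$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Univariable MR with automatic method dispatch
#'
#' Chooses the estimator by instrument count: no instruments yields a typed
#' missing result, one instrument the Wald ratio, two or more the IVW
#' estimate with Cochran's Q and the mean F-statistic attached.
#'
#' @param set A [harmonised_set()].
#' @param re_mode Passed to [ivw()].
#' @return An [mr_result()].
#' @export
run_uvmr <- function(set, re_mode = "capped_multiplicative") {
  K <- nrow(set$records)
  if (K == 0L) {
    return(mr_result(set$exposure_id, set$outcome_id, "none",
                     reason = "no instruments after selection/harmonisation"))
  }
  if (K == 1L) {
    res <- wald_ratio(set)
    res$exposure_id <- set$exposure_id
    res$outcome_id <- set$outcome_id
    res$diagnostics$mean_F <- mean_f(set)
    return(res)
  }
  res <- ivw(set, re_mode = re_mode)
  res$diagnostics$mean_F <- mean_f(set)
  res
}
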