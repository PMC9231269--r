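# Multivariable MR: joint direct-effect estimation, cross-trait instrument
# assembly, conditional instrument strength, heterogeneity.

#' Construct a multivariable MR dataset
#'
#' @param exposure_ids Character vector of K exposure ids.
#' @param snp_ids Character vector of L instrument ids (L > K).
#' @param Bx L x K matrix of SNP-exposure effects.
#' @param Sx L x K matrix of their standard errors (> 0).
#' @param by,sy Length-L SNP-outcome effects and standard errors (> 0).
#' @param rho K x K phenotypic correlation matrix of the exposures
#'   (symmetric, unit diagonal); used to approximate the covariance between
#'   a SNP's effect estimates on different exposures when computing
#'   conditional F-statistics. Defaults to the identity with a warning.
#' @return An `mvmr_dataset` object.
#' @export
mvmr_dataset <- function(exposure_ids, snp_ids, Bx, Sx, by, sy, rho = NULL) {
  Bx <- as.matrix(Bx); Sx <- as.matrix(Sx)
  K <- length(exposure_ids); L <- length(snp_ids)
  stopifnot(nrow(Bx) == L, ncol(Bx) == K,
            identical(dim(Bx), dim(Sx)),
            length(by) == L, length(sy) == L)
  if (L <= K) stop("underidentified: need more instruments than exposures")
  stopifnot(all(Sx > 0), all(sy > 0))
  if (is.null(rho)) {
    warning("no phenotypic correlation matrix supplied; using the identity. ",
            "Conditional F-statistics will ignore covariance between ",
            "exposure effect estimates.")
    rho <- diag(1, K)
  }
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == K, ncol(rho) == K)
  if (max(abs(rho - t(rho))) > 1e-8) stop("rho must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-8) stop("rho diagonal must be 1")
  if (max(abs(rho)) > 1 + 1e-8) stop("rho entries must lie in [-1, 1]")
  dimnames(Bx) <- dimnames(Sx) <- list(snp_ids, exposure_ids)
  dimnames(rho) <- list(exposure_ids, exposure_ids)
  structure(list(exposure_ids = exposure_ids, snp_ids = snp_ids,
                 Bx = Bx, Sx = Sx, by = as.numeric(by), sy = as.numeric(sy),
                 rho = rho),
            class = "mvmr_dataset")
}

#' @export
print.mvmr_dataset <- function(x, ...) {
  cat(sprintf("MVMR dataset: %d exposures, %d instruments\n",
              length(x$exposure_ids), length(x$snp_ids)))
  invisible(x)
}

#' Assemble a multivariable MR dataset from per-trait instrument sets
#'
#' Pools the instruments of all candidate exposures, ranks the pooled SNPs by
#' their minimum p-value across the candidate exposure tables, and greedily
#' clumps at `r2_threshold` so that no retained instrument for one trait is
#' in LD with a retained instrument for any other (ties broken by snp id).
#' Each retained SNP's effect and standard error are then looked up in every
#' candidate exposure table (an absent SNP is an error naming SNP and trait),
#' aligned across exposures to the first exposure's effect allele, and the
#' outcome is harmonised to the same allele.
#'
#' @param candidates List of [harmonised_set()] objects (>= 2), one per
#'   candidate exposure, defining the pooled instruments.
#' @param exposure_tables Named list of [gwas_table()] objects covering every
#'   candidate exposure.
#' @param outcome [gwas_table()] for the outcome.
#' @param ld [ld_matrix()] covering the pooled instruments.
#' @param rho Optional K x K phenotypic correlation matrix (exposure order).
#' @param r2_threshold Cross-trait clumping threshold (default 0.01).
#' @param maf_palindrome_limit Passed to the outcome harmonisation.
#' @return An [mvmr_dataset()].
#' @export
assemble_mvmr <- function(candidates, exposure_tables, outcome, ld,
                          rho = NULL, r2_threshold = 0.01,
                          maf_palindrome_limit = 0.42) {
  if (length(candidates) < 2L) stop("need at least 2 candidate exposures")
  exposure_ids <- vapply(candidates, function(s) s$exposure_id, character(1))
  tab_ids <- vapply(exposure_tables, trait_id, character(1))
  names(exposure_tables) <- tab_ids
  missing_tab <- setdiff(exposure_ids, tab_ids)
  if (length(missing_tab) > 0L) {
    stop("no exposure table for: ", paste(missing_tab, collapse = ", "))
  }

  pooled <- unique(unlist(lapply(candidates, function(s) s$records$snp)))
  if (length(pooled) == 0L) stop("no pooled instruments")

  # minimum p across candidate exposures
  min_p <- vapply(pooled, function(snp) {
    ps <- vapply(exposure_ids, function(id) {
      tab <- exposure_tables[[id]]
      i <- match(snp, tab$snp)
      if (is.na(i)) NA_real_ else tab$p[i]
    }, numeric(1))
    min(ps, na.rm = TRUE)
  }, numeric(1))

  missing_ld <- setdiff(pooled, rownames(ld))
  if (length(missing_ld) > 0L) {
    warning("dropping ", length(missing_ld),
            " pooled SNP(s) absent from the LD matrix")
    keep <- !pooled %in% missing_ld
    pooled <- pooled[keep]; min_p <- min_p[keep]
  }

  ord <- order(min_p, pooled)
  pooled <- pooled[ord]
  accepted <- character()
  remaining <- pooled
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    accepted <- c(accepted, best)
    r2 <- ld[remaining, best]^2
    remaining <- remaining[r2 < r2_threshold]
  }

  K <- length(exposure_ids)
  ref_tab <- exposure_tables[[exposure_ids[1L]]]

  Bx <- Sx <- matrix(NA_real_, nrow = length(accepted), ncol = K,
                     dimnames = list(accepted, exposure_ids))
  keep_snp <- rep(TRUE, length(accepted))
  by <- sy <- rep(NA_real_, length(accepted))

  for (i in seq_along(accepted)) {
    snp <- accepted[i]
    ri <- match(snp, ref_tab$snp)
    if (is.na(ri)) {
      stop("SNP ", snp, " missing from exposure table '", exposure_ids[1L], "'")
    }
    ref <- as.data.frame(ref_tab)[ri, ]
    for (k in seq_len(K)) {
      tab <- exposure_tables[[exposure_ids[k]]]
      j <- match(snp, tab$snp)
      if (is.na(j)) {
        stop("SNP ", snp, " missing from exposure table '",
             exposure_ids[k], "'")
      }
      rec <- as.data.frame(tab)[j, ]
      al <- align_to_reference(ref, rec, maf_palindrome_limit)
      if (is.na(al)) { keep_snp[i] <- FALSE; break }
      Bx[i, k] <- al * rec$beta
      Sx[i, k] <- rec$se
    }
    if (!keep_snp[i]) next
    oj <- match(snp, outcome$snp)
    if (is.na(oj)) { keep_snp[i] <- FALSE; next }
    orec <- as.data.frame(outcome)[oj, ]
    al <- align_to_reference(ref, orec, maf_palindrome_limit)
    if (is.na(al)) { keep_snp[i] <- FALSE; next }
    by[i] <- al * orec$beta
    sy[i] <- orec$se
  }

  accepted <- accepted[keep_snp]
  if (length(accepted) <= K) stop("underidentified: L <= K after clumping")
  mvmr_dataset(exposure_ids, accepted,
               Bx[keep_snp, , drop = FALSE], Sx[keep_snp, , drop = FALSE],
               by[keep_snp], sy[keep_snp], rho = rho)
}

# Sign (+1/-1) aligning `rec`'s effect to the reference record's effect
# allele, or NA when the SNP must be dropped (ambiguous palindrome,
# incompatible alleles, missing eaf on a palindrome).
align_to_reference <- function(ref, rec, maf_palindrome_limit = 0.42) {
  if (is_palindromic(ref$ea, ref$oa)) {
    if (!((rec$ea == ref$ea && rec$oa == ref$oa) ||
          (rec$ea == ref$oa && rec$oa == ref$ea))) return(NA_real_)
    if (is.na(ref$eaf) || is.na(rec$eaf)) return(NA_real_)
    sgn <- 1; eaf <- rec$eaf
    if (rec$ea == ref$oa) { sgn <- -1; eaf <- 1 - eaf }
    if (min(ref$eaf, 1 - ref$eaf) > maf_palindrome_limit ||
        min(eaf, 1 - eaf) > maf_palindrome_limit) return(NA_real_)
    if (sign(ref$eaf - 0.5) != sign(eaf - 0.5)) sgn <- -sgn
    return(sgn)
  }
  ea <- rec$ea; oa <- rec$oa
  if (ea == ref$ea && oa == ref$oa) return(1)
  if (ea == ref$oa && oa == ref$ea) return(-1)
  ea <- complement_allele(ea); oa <- complement_allele(oa)
  if (ea == ref$ea && oa == ref$oa) return(1)
  if (ea == ref$oa && oa == ref$ea) return(-1)
  NA_real_
}

#' Multivariable IVW estimate of direct effects
#'
#' Weighted multiple regression of the SNP-outcome effects on the SNP-exposure
#' effect matrix without intercept, weights \eqn{1/\sigma_{Yj}^2}:
#' \deqn{\hat\theta = (B_X^T W B_X)^{-1} B_X^T W b_y.}
#' Standard errors from the weighted-regression covariance with residual
#' scale bounded below by 1 (same convention as [ivw()]). The heterogeneity
#' Q-statistic with `L - K - 1` degrees of freedom is attached.
#'
#' @param data An [mvmr_dataset()].
#' @param re_mode `"capped_multiplicative"` (default) or `"fixed"`.
#' @return An `mvmr_result`: data frame `estimates` (exposure, estimate, se,
#'   ci_low, ci_high, pvalue, conditional_f placeholder), plus `q_stat`,
#'   `q_df`, `q_p`.
#' @export
mvmr_ivw <- function(data, re_mode = c("capped_multiplicative", "fixed")) {
  re_mode <- match.arg(re_mode)
  Bx <- data$Bx; by <- data$by; w <- 1 / data$sy^2
  L <- nrow(Bx); K <- ncol(Bx)

  Xw <- Bx * sqrt(w)
  XtWX <- crossprod(Xw)
  if (kappa(XtWX, exact = TRUE) > 1e12) {
    stop("collinear exposures: SNP-exposure effect columns are not ",
         "separable; prune genetically correlated traits before MVMR")
  }
  XtWy <- crossprod(Bx, w * by)
  theta <- solve(XtWX, XtWy)[, 1L]
  resid <- by - Bx %*% theta
  rss <- sum(w * resid^2)
  sigma2 <- rss / (L - K)
  scale2 <- if (re_mode == "capped_multiplicative") max(1, sigma2) else 1
  cov_theta <- solve(XtWX) * scale2
  se <- sqrt(diag(cov_theta))

  q <- mvmr_q(data, theta)

  est <- data.frame(exposure = data$exposure_ids, estimate = theta, se = se,
                    ci_low = theta - Z975 * se, ci_high = theta + Z975 * se,
                    pvalue = pmax(2 * stats::pnorm(-abs(theta / se)),
                                  .Machine$double.xmin),
                    conditional_f = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(estimates = est, q_stat = q$q, q_df = q$df, q_p = q$p,
                 n_snps = L, re_mode = re_mode),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("MVMR-IVW: %d exposures, L = %d instruments\n",
              nrow(x$estimates), x$n_snps))
  print(x$estimates, digits = 4)
  cat(sprintf("  Q = %.3f, df = %d, p = %.3g\n", x$q_stat, x$q_df, x$q_p))
  invisible(x)
}

#' Conditional F-statistic for one exposure in MVMR
#'
#' Instrument strength of exposure `k` conditional on the other exposures,
#' computed by minimising
#' \deqn{Q_{x,k}(\delta) = \sum_j \frac{(B_{jk} - \delta^T B_{j,-k})^2}
#'                                     {v_j(\delta)},}
#' where \eqn{v_j(\delta)} combines the standard errors of the SNP-exposure
#' effect estimates with their pairwise covariances approximated as
#' \eqn{\rho_{lm} \sigma_{jl} \sigma_{jm}} from the phenotypic correlation
#' matrix. The minimisation iterates weighted least squares with the weights
#' held fixed until the coefficient change is below `tol`. The conditional F
#' is \eqn{Q_{x,k}(\hat\delta)/(L - K + 1)}; with a single exposure it
#' reduces exactly to the mean F-statistic. Values above 10 conventionally
#' indicate adequate conditional instrument strength.
#'
#' @param data An [mvmr_dataset()].
#' @param k Exposure index or id.
#' @param tol Fixed-point tolerance on delta (default 1e-8).
#' @param max_iter Maximum IWLS iterations (default 100).
#' @return Scalar conditional F-statistic.
#' @export
conditional_f <- function(data, k, tol = 1e-8, max_iter = 100L) {
  if (is.character(k)) k <- match(k, data$exposure_ids)
  stopifnot(!is.na(k), k >= 1L, k <= length(data$exposure_ids))
  Bx <- data$Bx; Sx <- data$Sx; rho <- data$rho
  L <- nrow(Bx); K <- ncol(Bx)

  target <- Bx[, k]
  s_k <- Sx[, k]
  if (K == 1L) {
    return(sum((target / s_k)^2) / (L - K + 1L))
  }
  others <- setdiff(seq_len(K), k)
  Bo <- Bx[, others, drop = FALSE]
  So <- Sx[, others, drop = FALSE]
  rho_oo <- rho[others, others, drop = FALSE]
  rho_ko <- rho[k, others]

  v_fun <- function(delta) {
    # term2_j = sum_{l,m} delta_l delta_m rho_lm So_jl So_jm
    A <- So * matrix(delta, nrow = L, ncol = K - 1L, byrow = TRUE)
    term2 <- rowSums((A %*% rho_oo) * A)
    # term3_j = 2 * s_k * sum_l delta_l rho_kl So_jl
    term3 <- 2 * s_k * (A %*% rho_ko)[, 1L]
    s_k^2 + term2 - term3
  }

  delta <- rep(0, K - 1L)
  v <- v_fun(delta)
  for (it in seq_len(max_iter)) {
    if (any(v <= 0)) stop("invalid covariance approximation: v_j <= 0")
    wv <- 1 / v
    Xw <- Bo * sqrt(wv)
    delta_new <- solve(crossprod(Xw), crossprod(Bo, wv * target))[, 1L]
    if (max(abs(delta_new - delta)) < tol) {
      delta <- delta_new
      break
    }
    delta <- delta_new
    v <- v_fun(delta)
    if (it == max_iter) {
      stop("conditional F IWLS did not converge in ", max_iter,
           " iterations; last delta = ",
           paste(signif(delta, 6), collapse = ", "))
    }
  }
  v <- v_fun(delta)
  if (any(v <= 0)) stop("invalid covariance approximation: v_j <= 0")
  qx <- sum((target - Bo %*% delta)^2 / v)
  qx / (L - K + 1L)
}

#' Heterogeneity Q-statistic for an MVMR model
#'
#' \deqn{Q = \sum_j (b_{yj} - \theta^T B_{xj})^2 / \sigma_{yj}^2} with
#' `L - K - 1` degrees of freedom (instruments minus exposures minus one) and
#' an upper chi-square tail p-value. Large Q flags outlying or pleiotropic
#' instruments.
#'
#' @param data An [mvmr_dataset()].
#' @param theta Length-K vector of direct-effect estimates.
#' @return List with `q`, `df`, `p`.
#' @export
mvmr_q <- function(data, theta) {
  L <- nrow(data$Bx); K <- ncol(data$Bx)
  df <- L - K - 1L
  if (df <= 0L) stop("Q degrees of freedom must be positive (L - K - 1 > 0)")
  resid <- data$by - data$Bx %*% as.numeric(theta)
  q <- sum(resid^2 / data$sy^2)
  list(q = q, df = df, p = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' Run the full MVMR analysis on an assembled dataset
#'
#' [mvmr_ivw()] plus per-exposure [conditional_f()].
#'
#' @param data An [mvmr_dataset()].
#' @param re_mode Passed to [mvmr_ivw()].
#' @return An `mvmr_result` with the `conditional_f` column filled in.
#' @export
run_mvmr <- function(data, re_mode = "capped_multiplicative") {
  res <- mvmr_ivw(data, re_mode = re_mode)
  res$estimates$conditional_f <- vapply(
    seq_along(data$exposure_ids), function(k) conditional_f(data, k),
    numeric(1))
  res
}
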