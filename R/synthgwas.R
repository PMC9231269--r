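# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# Summary statistics are generated directly (no individual-level genotypes):
# for unit-variance traits the sampling variance of a per-allele effect
# estimate at a SNP with minor-allele frequency f in a sample of n is
# approximately 1 / (n * 2 f (1 - f)), which gives exact control over
# instrument strength (noncentrality) and sample-overlap correlation.

#' Define a simulation scenario
#'
#' Describes the generative model for two-sample summary statistics on K
#' standardized correlated exposures and one outcome:
#' \deqn{\gamma_j = \Gamma_j^T \theta + \alpha_j}
#' with observed effects drawn around the true values with GWAS-scale
#' standard errors. Within-SNP sampling errors across exposures are
#' correlated via `rho`, and the exposure-outcome error correlation is
#' `overlap_fraction` times the implied phenotypic exposure-outcome
#' correlation (a first-order model of shared samples).
#'
#' @param K Number of exposures.
#' @param L Number of SNPs.
#' @param Gamma L x K matrix of true SNP-exposure effects. Default: the first
#'   `ceiling(L/K)` SNPs load on exposure 1, the next block on exposure 2,
#'   etc., with effect size `gamma_scale`.
#' @param theta Length-K true causal effects of the exposures on the outcome.
#' @param alpha Length-L direct (pleiotropic) SNP-outcome effects; default 0.
#' @param rho K x K phenotypic correlation matrix of exposures (default
#'   identity); must be positive semi-definite.
#' @param n_x,n_y Exposure and outcome GWAS sample sizes.
#' @param overlap_fraction Proportion of shared samples between the two GWAS,
#'   in \[0, 1\] (default 0).
#' @param maf Length-L minor-allele frequencies, or `NULL` to draw uniformly
#'   from \[0.05, 0.5\] at simulation time.
#' @param ld_blocks Optional data frame with columns `size` and `r`: SNPs are
#'   grouped into consecutive blocks of the given sizes and each block
#'   receives constant pairwise LD `r` (marginal effects become R times the
#'   joint effects; sampling errors are correlated accordingly). SNPs not
#'   covered by blocks are independent.
#' @param gamma_scale Default per-SNP effect size used when `Gamma` is `NULL`
#'   (default 0.05 SD per allele).
#' @param seed Integer seed; every random draw in
#'   [simulate_summary_stats()] derives from it.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(K = 3L, L = 60L, Gamma = NULL, theta = rep(0, K),
                         alpha = rep(0, L), rho = diag(1, K),
                         n_x = 115078, n_y = 210267,
                         overlap_fraction = 0, maf = NULL, ld_blocks = NULL,
                         gamma_scale = 0.05, seed = 1L) {
  if (is.null(Gamma)) {
    Gamma <- matrix(0, L, K)
    block <- ceiling(L / K)
    for (k in seq_len(K)) {
      idx <- ((k - 1L) * block + 1L):min(k * block, L)
      Gamma[idx, k] <- gamma_scale
    }
  }
  Gamma <- as.matrix(Gamma)
  stopifnot(nrow(Gamma) == L, ncol(Gamma) == K,
            length(theta) == K, length(alpha) == L,
            overlap_fraction >= 0, overlap_fraction <= 1)
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == K, ncol(rho) == K)
  if (max(abs(rho - t(rho))) > 1e-8) stop("rho must be symmetric")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("rho is not positive semi-definite")
  if (!is.null(maf)) {
    stopifnot(length(maf) == L, all(maf > 0), all(maf <= 0.5))
  }
  structure(list(K = K, L = L, Gamma = Gamma, theta = as.numeric(theta),
                 alpha = as.numeric(alpha), rho = rho, n_x = n_x, n_y = n_y,
                 overlap_fraction = overlap_fraction, maf = maf,
                 ld_blocks = ld_blocks, seed = seed),
            class = "sim_scenario")
}

# Build the block-diagonal LD matrix implied by a scenario.
scenario_ld <- function(scenario, snp_ids) {
  L <- scenario$L
  R <- diag(1, L)
  blocks <- scenario$ld_blocks
  if (!is.null(blocks)) {
    pos <- 1L
    for (b in seq_len(nrow(blocks))) {
      size <- blocks$size[b]; r <- blocks$r[b]
      if (pos + size - 1L > L) stop("ld_blocks exceed L")
      idx <- pos:(pos + size - 1L)
      R[idx, idx] <- r
      diag(R)[idx] <- 1
      pos <- pos + size
    }
  }
  dimnames(R) <- list(snp_ids, snp_ids)
  R
}

# Non-palindromic allele pairs used by default.
NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate two-sample GWAS summary statistics
#'
#' Draws per-SNP allele frequencies, forms true SNP-outcome effects
#' \eqn{\gamma = \Gamma\theta + \alpha}, and emits observed effect estimates
#' with standard errors \eqn{\sigma = 1/\sqrt{n \cdot 2f(1-f)}} (unit-variance
#' traits). Sampling errors are drawn jointly: across exposures with
#' correlation `rho`, between exposures and outcome with correlation
#' `overlap_fraction` times the implied phenotypic exposure-outcome
#' correlation, and across SNPs within an LD block with correlation equal to
#' the block r (true marginal effects are likewise R times the joint
#' effects). All randomness derives from the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @return A `synthetic_truth` list: `scenario`, realized `Gamma_marginal`,
#'   `alpha`, `maf`, `exposures` (named list of [gwas_table()]), `outcome`
#'   ([gwas_table()]), `ld` ([ld_matrix()]), `rho`.
#' @export
simulate_summary_stats <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr_seed(scenario$seed, {
    K <- scenario$K; L <- scenario$L
    snp_ids <- sprintf("rs%05d", seq_len(L))
    exposure_ids <- if (is.null(colnames(scenario$Gamma))) {
      sprintf("trait_%02d", seq_len(K))
    } else colnames(scenario$Gamma)

    maf <- if (is.null(scenario$maf)) stats::runif(L, 0.05, 0.5) else
      scenario$maf
    se_x <- 1 / sqrt(scenario$n_x * 2 * maf * (1 - maf))  # per exposure, shared
    se_y <- 1 / sqrt(scenario$n_y * 2 * maf * (1 - maf))

    # implied exposure-outcome phenotypic correlation (unit-variance outcome
    # approximation), scaled by the shared-sample fraction
    c_xy <- as.numeric(scenario$rho %*% scenario$theta)
    var_y <- as.numeric(t(scenario$theta) %*% scenario$rho %*% scenario$theta)
    if (var_y > 1) c_xy <- c_xy / sqrt(var_y)
    c_err <- scenario$overlap_fraction * c_xy

    sigma_err <- rbind(cbind(scenario$rho, c_err), c(c_err, 1))
    ev <- eigen(sigma_err, symmetric = TRUE)
    if (min(ev$values) < -1e-8) {
      stop("implied error-correlation matrix is not positive semi-definite")
    }
    A_err <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)

    R <- scenario_ld(scenario, snp_ids)
    chol_R <- chol(R)

    gamma_y <- as.numeric(scenario$Gamma %*% scenario$theta + scenario$alpha)
    Gamma_marg <- R %*% scenario$Gamma
    gamma_y_marg <- as.numeric(R %*% gamma_y)

    # separable noise: Cov = R (across SNPs) x sigma_err (across traits)
    Z <- matrix(stats::rnorm(L * (K + 1L)), nrow = L)
    E <- t(chol_R) %*% Z %*% t(A_err)

    beta_x <- Gamma_marg + E[, seq_len(K), drop = FALSE] * se_x
    beta_y <- gamma_y_marg + E[, K + 1L] * se_y

    alleles <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), L, replace = TRUE), ,
                            drop = FALSE]
    eaf <- maf

    exposures <- lapply(seq_len(K), function(k) {
      gwas_table(data.frame(
        snp = snp_ids, ea = alleles[, 1L], oa = alleles[, 2L], eaf = eaf,
        beta = beta_x[, k], se = se_x,
        p = pmax(2 * stats::pnorm(-abs(beta_x[, k] / se_x)),
                 .Machine$double.xmin),
        n = scenario$n_x, stringsAsFactors = FALSE),
        trait_id = exposure_ids[k])
    })
    names(exposures) <- exposure_ids
    outcome <- gwas_table(data.frame(
      snp = snp_ids, ea = alleles[, 1L], oa = alleles[, 2L], eaf = eaf,
      beta = beta_y, se = se_y,
      p = pmax(2 * stats::pnorm(-abs(beta_y / se_y)), .Machine$double.xmin),
      n = scenario$n_y, stringsAsFactors = FALSE),
      trait_id = "outcome")

    rho_out <- scenario$rho
    dimnames(rho_out) <- list(exposure_ids, exposure_ids)
    structure(list(scenario = scenario, Gamma_marginal = Gamma_marg,
                   alpha = scenario$alpha, maf = maf,
                   exposures = exposures, outcome = outcome,
                   ld = ld_matrix(R), rho = rho_out),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic two-sample GWAS panel: %d exposures, %d SNPs, n_x = %d, n_y = %d\n",
    x$scenario$K, x$scenario$L, x$scenario$n_x, x$scenario$n_y))
  invisible(x)
}

#' Generate a panel mirroring the structure of a metabolomics MR study
#'
#' A 12-trait analysable panel: three causal exposures (a glycolysis trait
#' with effect 0.3, two amino acids with effects 0.09 and 0.14 SD outcome per
#' SD exposure), nine null traits including a near-duplicate pair (genetic
#' correlation squared above 0.985, to exercise correlation pruning) and one
#' trait with no genome-wide-significant SNPs (to exercise the
#' zero-instrument path). A fraction of SNPs are palindromic with minor
#' allele frequencies straddling the 0.42 ambiguity limit. Trait metadata
#' additionally carries one ratio-flagged trait and one within-subclass
#' lipoprotein component so the metadata filter stages operate end-to-end.
#'
#' @param seed Integer seed.
#' @param n_x,n_y GWAS sample sizes (defaults 115078 / 210267).
#' @return List: `truth` (a `synthetic_truth`), `metadata` ([trait_info()]),
#'   `causal` (named true effects of the analysable traits).
#' @export
make_metabolomics_panel <- function(seed = 1L, n_x = 115078, n_y = 210267) {
  K <- 12L
  per <- 12L             # candidate instruments per instrumented trait
  L <- per * K + 20L     # + 20 shared/pleiotropy-prone filler SNPs
  ids <- c("glucose_like", "glutamine_like", "alanine_like",
           "lactate_like", "citrate_like", "tyrosine_like",
           "acetate_like", "albumin_like", "hdl_total_like",
           "ldl_total_like", "ldl_total_dup", "weak_trait")
  theta <- c(0.30, 0.09, 0.14, rep(0, 9L))
  names(theta) <- ids

  # per-SNP effect 0.05 SD/allele: at n_x = 115078 each instrument passes
  # genome-wide significance with near certainty, and 12 instruments give the
  # weakest causal effect (0.09) a univariable z of ~4.5, i.e. > 99% power at
  # the 0.05 screen -- the panel is built so the causal traits are
  # recoverable by design
  Gamma <- matrix(0, L, K, dimnames = list(NULL, ids))
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * per + 1L):(k * per)
    Gamma[idx, k] <- 0.05
  }
  # near-duplicate pair: ldl_total_dup shares ldl_total_like's architecture
  dup_src <- match("ldl_total_like", ids)
  dup <- match("ldl_total_dup", ids)
  Gamma[, dup] <- Gamma[, dup_src]
  Gamma[((dup - 1L) * per + 1L):(dup * per), dup] <- 0  # drop its own block
  # weak trait: effects far below genome-wide significance at n_x
  weak <- match("weak_trait", ids)
  Gamma[((weak - 1L) * per + 1L):(weak * per), weak] <- 0.004

  rho <- diag(1, K)
  rho[dup_src, dup] <- rho[dup, dup_src] <- 0.99

  scn <- sim_scenario(K = K, L = L, Gamma = Gamma, theta = theta,
                      alpha = rep(0, L), rho = rho, n_x = n_x, n_y = n_y,
                      overlap_fraction = 0.3, seed = seed)
  truth <- simulate_summary_stats(scn)

  # perturb the duplicate's observed effects by 1% relative noise so the
  # estimated genetic correlation is high but not exactly 1
  truth$exposures[[dup]] <- withr_seed(seed + 1L, {
    tab <- as.data.frame(truth$exposures[[dup_src]])
    tab$beta <- tab$beta * (1 + stats::rnorm(nrow(tab), 0, 0.01))
    tab$p <- pmax(2 * stats::pnorm(-abs(tab$beta / tab$se)),
                  .Machine$double.xmin)
    gwas_table(tab, trait_id = "ldl_total_dup")
  })

  # palindromic SNPs at varied MAF: two instruments of the first causal trait
  # (one resolvable at MAF 0.35, one ambiguous at 0.45) plus filler SNPs
  truth <- withr_seed(seed + 2L, {
    filler <- (per * K + 1L):L
    pal_idx <- c(1L, 2L, filler[seq_len(min(8L, length(filler)))])
    pal_pair <- rbind(c("A", "T"), c("C", "G"))
    pick <- pal_pair[sample.int(2L, length(pal_idx), replace = TRUE), ,
                     drop = FALSE]
    pal_maf <- c(0.35, 0.45,
                 seq(0.30, 0.49, length.out = length(pal_idx) - 2L))
    for (i in seq_along(pal_idx)) {
      j <- pal_idx[i]
      for (nm in names(truth$exposures)) {
        truth$exposures[[nm]]$ea[j] <- pick[i, 1L]
        truth$exposures[[nm]]$oa[j] <- pick[i, 2L]
        truth$exposures[[nm]]$eaf[j] <- pal_maf[i]
      }
      truth$outcome$ea[j] <- pick[i, 1L]
      truth$outcome$oa[j] <- pick[i, 2L]
      truth$outcome$eaf[j] <- pal_maf[i]
    }
    truth
  })

  metadata <- trait_info(data.frame(
    trait_id = c(ids, "glucose_lactate_ratio", "ldl_cholesterol_component"),
    trait_class = c("glycolysis", "amino acids", "amino acids", "glycolysis",
                    "glycolysis", "amino acids", "ketone bodies",
                    "fluid balance", "lipoprotein subclasses",
                    "lipoprotein subclasses", "lipoprotein subclasses",
                    "other", "glycolysis", "lipoprotein subclasses"),
    is_ratio = c(rep(FALSE, K), TRUE, FALSE),
    is_composite = FALSE,
    lipoprotein_role = c(rep("none", 8L), "total-lipids-in-subclass",
                         "total-lipids-in-subclass",
                         "total-lipids-in-subclass", "none", "none",
                         "within-subclass-component"),
    stringsAsFactors = FALSE))

  list(truth = truth, metadata = metadata, causal = theta)
}
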