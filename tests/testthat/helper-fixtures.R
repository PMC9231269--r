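# Shared fixture builders for the test suite. All fixtures are generated in
# code; no files are stored.

# Quick gwas_table from parallel vectors.
make_table <- function(snp, beta, se, ea = "A", oa = "G", eaf = 0.3,
                       p = NULL, n = 10000, trait = "trait") {
  L <- length(snp)
  if (is.null(p)) p <- pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
  gwas_table(data.frame(
    snp = snp,
    ea = rep_len(ea, L), oa = rep_len(oa, L),
    eaf = rep_len(eaf, L), beta = beta, se = rep_len(se, L),
    p = rep_len(p, L), n = rep_len(n, L), stringsAsFactors = FALSE),
    trait_id = trait)
}

# Harmonised set straight from effect vectors.
make_hset <- function(beta_x, se_x, beta_y, se_y,
                      exposure = "X", outcome = "Y") {
  K <- length(beta_x)
  harmonised_set(exposure, outcome, data.frame(
    snp = sprintf("rs%03d", seq_len(K)),
    beta_x = beta_x, se_x = rep_len(se_x, K),
    beta_y = beta_y, se_y = rep_len(se_y, K),
    eaf = 0.3, palindromic = FALSE, flipped = FALSE,
    stringsAsFactors = FALSE))
}

# Random harmonised set for oracle comparisons.
random_hset <- function(K, seed) {
  set.seed(seed)
  make_hset(beta_x = rnorm(K, 0.05, 0.03),
            se_x = runif(K, 0.003, 0.01),
            beta_y = rnorm(K, 0.01, 0.02),
            se_y = runif(K, 0.002, 0.02))
}

# Independent weighted-least-squares oracle via lm(); returns estimate and
# the fixed-effect (unit residual scale) SE.
lm_wls_oracle <- function(y, X, w) {
  fit <- lm(y ~ 0 + X, weights = w)
  sigma2 <- sum(w * residuals(fit)^2) / df.residual(fit)
  list(coef = unname(coef(fit)),
       se_fixed = unname(sqrt(diag(vcov(fit)) / sigma2)),
       sigma2 = sigma2)
}

# Brute-force greedy clumping oracle working directly on p-values and the
# r-squared matrix (independent of the package's implementation details).
clump_oracle <- function(snp, p, ld, p_threshold = 5e-8,
                         r2_threshold = 0.01) {
  keep <- snp[p < p_threshold]
  keep <- keep[order(p[match(keep, snp)], keep)]
  accepted <- character()
  for (s in keep) {
    if (all(ld[s, accepted]^2 < r2_threshold)) accepted <- c(accepted, s)
  }
  accepted
}

# Temp file cleaned up at session end.
tmp_tsv <- function() tempfile(fileext = ".tsv")

# Vectorised palindrome check (A/T or C/G pair), independent of the package
# internals.
is_palindromic_vec <- function(ea, oa) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ea %in% names(comp) & unname(comp[ea]) == oa
}
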