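# Helper: random MVMR dataset with known truth.
random_mvmr <- function(L, K, theta, seed, rho = diag(1, K), noise = TRUE) {
  set.seed(seed)
  Bx <- matrix(rnorm(L * K, 0.05, 0.02), L, K)
  Sx <- matrix(runif(L * K, 0.003, 0.008), L, K)
  sy <- runif(L, 0.003, 0.008)
  by <- as.numeric(Bx %*% theta) + if (noise) rnorm(L, 0, sy) else 0
  mvmr_dataset(sprintf("exp%d", seq_len(K)), sprintf("rs%03d", seq_len(L)),
               Bx, Sx, by, sy, rho = rho)
}

test_that("dataset construction enforces dimensions, SEs and rho validity", {
  expect_error(random_mvmr(3, 3, rep(0, 3), 1), "underidentified")
  d <- random_mvmr(20, 2, c(0.1, 0), 1)
  expect_s3_class(d, "mvmr_dataset")
  bad_rho <- matrix(c(1, 0.5, 0.4, 1), 2)
  expect_error(mvmr_dataset(d$exposure_ids, d$snp_ids, d$Bx, d$Sx, d$by,
                            d$sy, rho = bad_rho), "symmetric")
  expect_warning(mvmr_dataset(d$exposure_ids, d$snp_ids, d$Bx, d$Sx, d$by,
                              d$sy), "identity")
})

test_that("single-exposure MVMR equals univariable IVW exactly", {
  d <- random_mvmr(25, 1, 0.2, 2)
  h <- harmonised_set("exp1", "outcome", data.frame(
    snp = d$snp_ids, beta_x = d$Bx[, 1], se_x = d$Sx[, 1],
    beta_y = d$by, se_y = d$sy, eaf = 0.3,
    palindromic = FALSE, flipped = FALSE))
  for (mode in c("fixed", "capped_multiplicative")) {
    mv <- mvmr_ivw(d, re_mode = mode)
    uv <- ivw(h, re_mode = mode)
    expect_equal(mv$estimates$estimate, uv$estimate, tolerance = 1e-13)
    expect_equal(mv$estimates$se, uv$se, tolerance = 1e-13)
  }
})

test_that("noise-free linear outcome effects are recovered to machine precision", {
  d <- random_mvmr(30, 2, c(0.3, 0.1), 3, noise = FALSE)
  mv <- mvmr_ivw(d)
  expect_equal(mv$estimates$estimate, c(0.3, 0.1), tolerance = 1e-12)
  q <- mvmr_q(d, c(0.3, 0.1))
  expect_equal(q$q, 0, tolerance = 1e-18)
  expect_equal(q$p, 1)
})

test_that("MVMR-IVW equals an independent GLS oracle on noisy data", {
  for (seed in 1:5) {
    d <- random_mvmr(60, 3, c(0.29, 0.07, 0.08), seed + 20)
    mv <- mvmr_ivw(d, re_mode = "fixed")
    oracle <- lm_wls_oracle(d$by, d$Bx, 1 / d$sy^2)
    expect_equal(mv$estimates$estimate, oracle$coef, tolerance = 1e-12)
    expect_equal(mv$estimates$se, oracle$se_fixed, tolerance = 1e-12)
  }
})

test_that("collinear exposures are rejected with pruning advice", {
  d <- random_mvmr(20, 2, c(0.1, 0), 4)
  Bx <- d$Bx; Bx[, 2] <- Bx[, 1]
  d2 <- mvmr_dataset(d$exposure_ids, d$snp_ids, Bx, d$Sx, d$by, d$sy,
                     rho = diag(1, 2))
  expect_error(mvmr_ivw(d2), "prune genetically correlated")
})

test_that("permuting exposure order permutes estimates and conditional Fs", {
  d <- random_mvmr(40, 3, c(0.2, 0.1, 0), 5)
  perm <- c(3, 1, 2)
  dp <- mvmr_dataset(d$exposure_ids[perm], d$snp_ids, d$Bx[, perm],
                     d$Sx[, perm], d$by, d$sy, rho = d$rho[perm, perm])
  r1 <- run_mvmr(d)
  r2 <- run_mvmr(dp)
  expect_equal(r2$estimates$estimate, r1$estimates$estimate[perm],
               tolerance = 1e-10)
  expect_equal(r2$estimates$conditional_f, r1$estimates$conditional_f[perm],
               tolerance = 1e-8)
  expect_equal(r2$q_stat, r1$q_stat)
})

test_that("conditional F reduces to the mean F-statistic for one exposure", {
  d <- random_mvmr(25, 1, 0.2, 6)
  h <- make_hset(beta_x = d$Bx[, 1], se_x = d$Sx[, 1],
                 beta_y = d$by, se_y = d$sy)
  h$records$se_x <- d$Sx[, 1]
  expect_equal(conditional_f(d, 1), mean_f(h), tolerance = 1e-12)
})

test_that("a duplicated exposure has conditional F near zero", {
  set.seed(7)
  L <- 30
  Bx1 <- rnorm(L, 0.05, 0.02)
  Bx <- cbind(Bx1, Bx1)
  Sx <- matrix(0.005, L, 2)
  sy <- rep(0.005, L)
  by <- Bx1 * 0.3 + rnorm(L, 0, sy)
  d <- mvmr_dataset(c("a", "b"), sprintf("rs%d", 1:L), Bx, Sx, by, sy,
                    rho = diag(1, 2))
  expect_lt(conditional_f(d, 1), 1)
  expect_lt(conditional_f(d, 2), 1)
})

test_that("conditional F matches a brute-force grid minimiser of Q_x", {
  # two weakly-overlapping exposures (block-specific instruments, slight
  # cross-loading), the companion exposure strongly instrumented: here the
  # Q_x profile has an interior minimum and the iterated-WLS fixed point
  # coincides with it
  set.seed(8)
  L <- 40
  Bx <- cbind(c(rnorm(20, 0.035, 0.005), rnorm(20, 0.004, 0.002)),
              c(rnorm(20, 0.004, 0.002), rnorm(20, 0.08, 0.01)))
  Sx <- matrix(runif(L * 2, 0.004, 0.006), L, 2)
  sy <- rep(0.005, L)
  by <- as.numeric(Bx %*% c(0.2, 0)) + rnorm(L, 0, sy)
  d <- mvmr_dataset(c("a", "b"), sprintf("rs%d", 1:L), Bx, Sx, by, sy,
                    rho = diag(1, 2))
  cf <- conditional_f(d, 1)

  # independent dense-grid minimisation of Q_x over delta
  qx <- function(delta) {
    sum((Bx[, 1] - delta * Bx[, 2])^2 / (Sx[, 1]^2 + delta^2 * Sx[, 2]^2))
  }
  grid <- seq(-0.5, 0.7, length.out = 20001)
  qmin <- min(vapply(grid, qx, numeric(1)))
  expect_lt(abs(cf - qmin / (L - 2 + 1)) / (qmin / (L - 1)), 0.01)
})

test_that("the covariance approximation degenerates loudly for identical exposures", {
  # exposure 2 a copy of exposure 1 with phenotypic correlation 1 and equal
  # SEs: the approximated conditional variance v_j collapses to zero and the
  # cross-term of v is what drives it there
  set.seed(18)
  L <- 30
  b <- rnorm(L, 0.05, 0.02)
  s <- matrix(0.005, L, 2)
  sy <- rep(0.005, L)
  by <- b * 0.3 + rnorm(L, 0, sy)
  d <- mvmr_dataset(c("a", "b"), sprintf("rs%d", 1:L), cbind(b, b), s,
                    by, sy, rho = matrix(1, 2, 2))
  expect_error(conditional_f(d, 1), "invalid covariance approximation")
})

test_that("conditional F decreases as two exposures' effect vectors correlate", {
  set.seed(9)
  L <- 50
  base <- rnorm(L, 0.05, 0.02)
  indep <- rnorm(L, 0.05, 0.02)
  Sx <- matrix(0.005, L, 2)
  sy <- rep(0.005, L)
  fs <- vapply(c(0, 0.5, 0.9, 0.99), function(mix) {
    Bx <- cbind(base, mix * base + (1 - mix) * indep)
    by <- as.numeric(Bx %*% c(0.2, 0.1))
    d <- mvmr_dataset(c("a", "b"), sprintf("rs%d", 1:L), Bx, Sx, by, sy,
                      rho = diag(1, 2))
    conditional_f(d, 2)
  }, numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("the Q degrees-of-freedom rule is instruments minus exposures minus one", {
  d <- random_mvmr(84, 6, rep(0.05, 6), 10)
  expect_equal(mvmr_q(d, rep(0.05, 6))$df, 77L)
  d2 <- random_mvmr(12, 6, rep(0.05, 6), 11)
  expect_equal(mvmr_q(d2, rep(0.05, 6))$df, 5L)
  d3 <- random_mvmr(7, 6, rep(0.05, 6), 12)
  expect_error(mvmr_q(d3, rep(0.05, 6)), "positive")
})

test_that("assemble_mvmr pools, clumps across traits and harmonises to the outcome", {
  # two traits with disjoint LD-free instruments: L = sum of counts
  snps <- sprintf("rs%d", 1:8)
  r <- diag(8); dimnames(r) <- list(snps, snps)
  ld <- ld_matrix(r)
  t1 <- make_table(snps, beta = c(rep(0.08, 4), rep(0.001, 4)), se = 0.008,
                   trait = "t1")
  t2 <- make_table(snps, beta = c(rep(0.001, 4), rep(0.08, 4)), se = 0.008,
                   trait = "t2")
  outc <- make_table(snps, beta = 0.01, se = 0.004, trait = "bw")
  h1 <- select_instruments(t1, outc, ld)
  h2 <- select_instruments(t2, outc, ld)
  expect_equal(n_instruments(h1) + n_instruments(h2), 8L)
  d <- assemble_mvmr(list(h1, h2), list(t1, t2), outc, ld, rho = diag(1, 2))
  expect_equal(length(d$snp_ids), 8L)

  # identical instruments across traits: deduplicated
  d2 <- assemble_mvmr(list(h1, h1_copy <- {
    h <- h1; h$exposure_id <- "t2"; h
  }), list(t1, t2), outc, ld, rho = diag(1, 2))
  expect_equal(length(d2$snp_ids), n_instruments(h1))
})

test_that("cross-trait clumping matches the brute-force oracle on block LD", {
  set.seed(13)
  L <- 24
  snps <- sprintf("rs%02d", 1:L)
  r <- matrix(0, L, L, dimnames = list(snps, snps))
  for (b in 0:5) { idx <- b * 4 + 1:4; r[idx, idx] <- 0.6 }
  diag(r) <- 1
  ld <- ld_matrix(r)
  b1 <- ifelse(seq_len(L) %% 2 == 0, 0.08, 0.02) + rnorm(L, 0, 0.005)
  b2 <- ifelse(seq_len(L) %% 2 == 1, 0.08, 0.02) + rnorm(L, 0, 0.005)
  t1 <- make_table(snps, beta = b1, se = 0.008, trait = "t1")
  t2 <- make_table(snps, beta = b2, se = 0.008, trait = "t2")
  outc <- make_table(snps, beta = 0.01, se = 0.004, trait = "bw")
  h1 <- select_instruments(t1, outc, ld)
  h2 <- select_instruments(t2, outc, ld)
  d <- assemble_mvmr(list(h1, h2), list(t1, t2), outc, ld, rho = diag(1, 2))

  pooled <- union(h1$records$snp, h2$records$snp)
  minp <- pmin(t1$p[match(pooled, t1$snp)], t2$p[match(pooled, t2$snp)])
  oracle <- clump_oracle(pooled, minp, r, p_threshold = Inf)
  expect_setequal(d$snp_ids, oracle)
  # retained pairwise r2 below threshold; every rejected pooled SNP conflicts
  # with a retained SNP of smaller min-p
  rr <- r[d$snp_ids, d$snp_ids]
  expect_true(all(rr[upper.tri(rr)]^2 < 0.01))
  for (s in setdiff(pooled, d$snp_ids)) {
    conf <- d$snp_ids[r[s, d$snp_ids]^2 >= 0.01]
    expect_gt(length(conf), 0)
  }
})

test_that("a retained SNP absent from an exposure table is a named error", {
  snps <- sprintf("rs%d", 1:6)
  r <- diag(6); dimnames(r) <- list(snps, snps)
  ld <- ld_matrix(r)
  t1 <- make_table(snps, beta = 0.08, se = 0.008, trait = "t1")
  t2 <- make_table(snps[1:3], beta = 0.08, se = 0.008, trait = "t2")
  outc <- make_table(snps, beta = 0.01, se = 0.004, trait = "bw")
  h1 <- select_instruments(t1, outc, ld)
  h2 <- select_instruments(t2, outc, ld)
  expect_error(assemble_mvmr(list(h1, h2), list(t1, t2), outc, ld,
                             rho = diag(1, 2)),
               "rs[4-6] missing from exposure table 't2'")
})

test_that("parameter recovery at the published effect scale", {
  # three exposures with direct effects (0.29, 0.07, 0.08), 60 strong
  # instruments: each recovered within 2 SE
  theta <- c(0.29, 0.07, 0.08)
  d <- random_mvmr(60, 3, theta, 14)
  mv <- run_mvmr(d)
  expect_true(all(abs(mv$estimates$estimate - theta) <
                    2 * mv$estimates$se))
  expect_true(all(mv$estimates$conditional_f > 10))
})
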