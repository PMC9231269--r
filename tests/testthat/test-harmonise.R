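test_that("swapped alleles negate the outcome effect and flag the flip", {
  exposure <- make_table("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G")
  outcome <- make_table("rs1", beta = 0.2, se = 0.02, ea = "G", oa = "A",
                        trait = "bw")
  h <- harmonise_pair(exposure, outcome)
  expect_equal(nrow(h$records), 1L)
  expect_equal(h$records$beta_y, -0.2)
  expect_true(h$records$flipped)
  expect_equal(h$records$beta_x, 0.1)  # exposure side untouched
})

test_that("alleles reported on the opposite strand are matched after complement", {
  exposure <- make_table("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G")
  # T/C is the strand complement of A/G: keep, no sign change
  outcome1 <- make_table("rs1", beta = 0.2, se = 0.02, ea = "T", oa = "C",
                         trait = "bw")
  h1 <- harmonise_pair(exposure, outcome1)
  expect_equal(h1$records$beta_y, 0.2)
  # C/T complements to G/A = swapped: negate
  outcome2 <- make_table("rs1", beta = 0.2, se = 0.02, ea = "C", oa = "T",
                         trait = "bw")
  h2 <- harmonise_pair(exposure, outcome2)
  expect_equal(h2$records$beta_y, -0.2)
})

test_that("irreconcilable alleles are removed with a reason", {
  exposure <- make_table("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G")
  outcome <- make_table("rs1", beta = 0.2, se = 0.02, ea = "A", oa = "C",
                        trait = "bw")
  h <- harmonise_pair(exposure, outcome)
  expect_equal(nrow(h$records), 0L)
  expect_equal(h$removed$reason, "incompatible_alleles")
})

test_that("palindromic SNPs above the MAF ambiguity limit are removed", {
  for (eaf in c(0.45, 0.55)) {  # min(eaf, 1-eaf) = 0.45 > 0.42 either way
    exposure <- make_table("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T",
                           eaf = eaf)
    outcome <- make_table("rs1", beta = 0.2, se = 0.02, ea = "A", oa = "T",
                          eaf = eaf, trait = "bw")
    h <- harmonise_pair(exposure, outcome)
    expect_equal(h$removed$reason, "ambiguous_palindrome")
  }
  # at exactly the limit the SNP is retained (strictly greater removes)
  exposure <- make_table("rs1", beta = 0.1, se = 0.01, ea = "C", oa = "G",
                         eaf = 0.42)
  outcome <- make_table("rs1", beta = 0.2, se = 0.02, ea = "C", oa = "G",
                        eaf = 0.42, trait = "bw")
  expect_equal(nrow(harmonise_pair(exposure, outcome)$records), 1L)
})

test_that("palindromic strand is inferred from allele-frequency side agreement", {
  exposure <- make_table("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T",
                         eaf = 0.3)
  # same side of 0.5: no flip
  out_same <- make_table("rs1", beta = 0.2, se = 0.02, ea = "A", oa = "T",
                         eaf = 0.35, trait = "bw")
  h <- harmonise_pair(exposure, out_same)
  expect_equal(h$records$beta_y, 0.2)
  expect_false(h$records$flipped)
  # opposite side: outcome effect flipped rather than dropped
  out_opp <- make_table("rs1", beta = 0.2, se = 0.02, ea = "A", oa = "T",
                        eaf = 0.65, trait = "bw")
  h2 <- harmonise_pair(exposure, out_opp)
  expect_equal(h2$records$beta_y, -0.2)
  expect_true(h2$records$flipped)
  # missing frequency on a palindrome cannot be resolved
  out_na <- make_table("rs1", beta = 0.2, se = 0.02, ea = "A", oa = "T",
                       eaf = NA, trait = "bw")
  out_na$eaf <- NA_real_
  h3 <- harmonise_pair(exposure, out_na)
  expect_equal(h3$removed$reason, "missing_eaf")
})

test_that("harmonising identical tables keeps everything and is idempotent", {
  set.seed(3)
  tab <- make_table(sprintf("rs%d", 1:8), beta = rnorm(8, 0, 0.05),
                    se = 0.01, eaf = runif(8, 0.1, 0.4))
  out <- make_table(sprintf("rs%d", 1:8), beta = rnorm(8, 0, 0.02),
                    se = 0.005, eaf = tab$eaf, trait = "bw")
  h1 <- harmonise_pair(tab, out)
  expect_equal(nrow(h1$records), 8L)
  expect_false(any(h1$records$flipped))
  # rebuild an outcome table from the harmonised records: no further change
  out2 <- make_table(h1$records$snp, beta = h1$records$beta_y,
                     se = h1$records$se_y, eaf = h1$records$eaf, trait = "bw")
  h2 <- harmonise_pair(tab, out2)
  expect_equal(h2$records$beta_y, h1$records$beta_y)
  expect_false(any(h2$records$flipped))
})

test_that("negating every outcome beta negates every harmonised beta_y", {
  set.seed(4)
  tab <- make_table(sprintf("rs%d", 1:10), beta = rnorm(10, 0.05, 0.02),
                    se = 0.01)
  out <- make_table(sprintf("rs%d", 1:10), beta = rnorm(10, 0, 0.02),
                    se = 0.005, trait = "bw")
  h_pos <- harmonise_pair(tab, out)
  out_neg <- make_table(out$snp, beta = -out$beta, se = out$se, trait = "bw")
  h_neg <- harmonise_pair(tab, out_neg)
  expect_equal(h_neg$records$beta_y, -h_pos$records$beta_y)
  # and the IVW estimate flips sign with it
  expect_equal(ivw(h_neg)$estimate, -ivw(h_pos)$estimate)
})

test_that("empty snp intersection is an error", {
  a <- make_table("rs1", beta = 0.1, se = 0.01)
  b <- make_table("rs2", beta = 0.1, se = 0.01, trait = "bw")
  expect_error(harmonise_pair(a, b), "no shared SNPs")
})

test_that("clumping keeps the stronger of two correlated SNPs", {
  tab <- make_table(c("rs1", "rs2"), beta = c(0.1, 0.09), se = 0.01,
                    p = c(1e-10, 1e-9))
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2,
              dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  kept <- clump(tab, ld_matrix(r))
  expect_equal(kept$snp, "rs1")
})

test_that("mutually independent significant SNPs all survive clumping", {
  snps <- sprintf("rs%d", 1:6)
  tab <- make_table(snps, beta = 0.1, se = 0.01,
                    p = c(1e-10, 1e-9, 1e-8, 1e-7, 4e-8, 0.5))
  r <- diag(6); dimnames(r) <- list(snps, snps)
  kept <- clump(tab, ld_matrix(r))
  expect_setequal(kept$snp, c("rs1", "rs2", "rs3", "rs5"))  # p < 5e-8 only
})

test_that("clumping matches the brute-force oracle on block-LD fixtures", {
  set.seed(11)
  for (rep in 1:10) {
    L <- 20
    snps <- sprintf("rs%02d", 1:L)
    # 4 blocks of 5 with high within-block LD
    r <- matrix(0, L, L, dimnames = list(snps, snps))
    for (b in 0:3) {
      idx <- b * 5 + 1:5
      r[idx, idx] <- runif(1, 0.3, 0.9)
    }
    diag(r) <- 1
    p <- 10^runif(L, -12, -5)
    tab <- make_table(snps, beta = 0.1, se = 0.01, p = p)
    tab$p <- p
    kept <- clump(tab, ld_matrix(r))$snp
    expect_identical(kept, clump_oracle(snps, p, r))
    # p-minimality properties
    acc <- kept
    rej <- setdiff(snps[p < 5e-8], acc)
    if (length(acc) > 1) {
      expect_true(all(r[acc, acc][upper.tri(diag(length(acc)))]^2 < 0.01))
    }
    for (s in rej) {
      conflicts <- acc[r[s, acc]^2 >= 0.01]
      expect_true(length(conflicts) > 0)
      expect_true(min(p[match(conflicts, snps)]) <= p[match(s, snps)])
    }
  }
})

test_that("SNPs absent from the LD matrix are dropped with a warning", {
  tab <- make_table(c("rs1", "rs2"), beta = 0.1, se = 0.01, p = 1e-10)
  r <- matrix(1, 1, 1, dimnames = list("rs1", "rs1"))
  expect_warning(kept <- clump(tab, ld_matrix(r)), "absent from the LD")
  expect_equal(kept$snp, "rs1")
})

test_that("select_instruments composes clumping and harmonisation", {
  snps <- sprintf("rs%d", 1:5)
  exposure <- make_table(snps, beta = 0.1, se = 0.01,
                         p = c(1e-10, 1e-9, 1e-9, 0.5, 0.9))
  outcome <- make_table(snps, beta = 0.01, se = 0.005, trait = "bw")
  r <- diag(5); dimnames(r) <- list(snps, snps)
  h <- select_instruments(exposure, outcome, ld_matrix(r))
  expect_equal(n_instruments(h), 3L)
})

test_that("a lone significant ambiguous palindrome yields a typed empty set", {
  exposure <- make_table(c("rs1", "rs2"), beta = c(0.1, 0.001),
                         se = 0.01, ea = "A", oa = "T", eaf = 0.45,
                         p = c(1e-10, 0.8))
  outcome <- make_table(c("rs1", "rs2"), beta = 0.01, se = 0.005,
                        ea = "A", oa = "T", eaf = 0.45, trait = "bw")
  r <- diag(2); dimnames(r) <- list(c("rs1", "rs2"), c("rs1", "rs2"))
  h <- select_instruments(exposure, outcome, ld_matrix(r))
  expect_equal(n_instruments(h), 0L)
  expect_equal(nrow(h$removed), 1L)
  expect_equal(h$removed$reason, "ambiguous_palindrome")
})

test_that("instrument counts match direct enumeration under no LD", {
  truth <- simulate_summary_stats(sim_scenario(
    K = 1L, L = 40L, Gamma = matrix(0.04, 40, 1), theta = 0.2,
    n_x = 50000, n_y = 100000, seed = 99L))
  exposure <- truth$exposures[[1]]
  h <- select_instruments(exposure, truth$outcome, truth$ld)
  expected <- sum(exposure$p < 5e-8)
  expect_equal(n_instruments(h), expected)
})

test_that("LD matrix validation and TSV round trip", {
  snps <- c("rs1", "rs2")
  bad <- matrix(c(1, 0.5, 0.4, 1), 2, dimnames = list(snps, snps))
  expect_error(ld_matrix(bad), "symmetric")
  good <- ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(snps, snps)))
  path <- tmp_tsv()
  write_ld_matrix(good, path)
  expect_equal(unclass(read_ld_matrix(path)), unclass(good),
               ignore_attr = TRUE)
})
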