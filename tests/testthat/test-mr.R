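test_that("Wald ratios follow the delta-method arithmetic", {
  h <- make_harmonized(c("rs1", "rs2"),
                       beta_exp = c(0.2, 0.2), se_exp = c(0.02, 0.02),
                       beta_out = c(0.02, 0), se_out = c(0.01, 0.01))
  w <- wald_ratio(h)
  expect_equal(w$theta, c(0.1, 0))
  expect_equal(w$se_theta, c(0.05, 0.05))

  # negative exposure beta: ratio flips, se stays positive
  hn <- make_harmonized("rs1", beta_exp = -0.2, se_exp = 0.02,
                        beta_out = 0.02, se_out = 0.01)
  wn <- wald_ratio(hn)
  expect_equal(wn$theta, -0.1)
  expect_equal(wn$se_theta, 0.05)

  hz <- make_harmonized("rs1", beta_exp = 0, se_exp = 0.02,
                        beta_out = 0.02, se_out = 0.01)
  expect_error(wald_ratio(hz), "zero exposure beta")
})

test_that("correlated IVW reduces to the Wald ratio for one variant", {
  h <- make_harmonized("rs1", beta_exp = 0.2, se_exp = 0.02,
                       beta_out = 0.02, se_out = 0.01)
  ld <- ld_matrix(diag(1), "rs1")
  est <- correlated_ivw(h, ld)
  w <- wald_ratio(h)
  expect_equal(est$beta, w$theta)
  expect_equal(est$se, w$se_theta)
  expect_equal(est$phi, 1)
})

test_that("correlated IVW solves the worked two-variant GLS case", {
  h <- make_harmonized(c("rs1", "rs2"),
                       beta_exp = c(0.2, 0.1), se_exp = c(0.02, 0.02),
                       beta_out = c(0.02, 0.01), se_out = c(0.01, 0.01))
  r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  est <- correlated_ivw(h, ld_matrix(r, c("rs1", "rs2")))
  expect_equal(est$beta, 0.1, tolerance = 1e-12)
  expect_equal(est$q, 0, tolerance = 1e-12)
  expect_equal(est$phi, 1)
  expect_equal(est$se, 0.05, tolerance = 1e-12)
  expect_equal(est$ci_low, 0.1 - qnorm(0.975) * 0.05, tolerance = 1e-12)
})

test_that("with identity LD the estimator equals independent IVW", {
  set.seed(303)
  for (i in 1:50) {
    j <- sample(1:8, 1)
    g <- rnorm(j, 0.15, 0.05)
    g[abs(g) < 0.02] <- 0.05
    G <- 0.1 * g + rnorm(j, 0, 0.01)
    se_out <- runif(j, 0.005, 0.05)
    h <- make_harmonized(paste0("rs", 1:j), g, 0.02, G, se_out)
    est <- correlated_ivw(h, ld_matrix(diag(j), h$rsid))
    want <- oracle_ivw_independent(g, G, se_out)
    expect_equal(est$beta, want$beta, tolerance = 1e-10)
    # base (phi-free) se matches the oracle
    expect_equal(est$se / sqrt(est$phi), want$se, tolerance = 1e-10)
  }
})

test_that("scale equivariance and allele-relabeling invariance hold", {
  set.seed(44)
  j <- 5
  g <- runif(j, 0.05, 0.2)
  G <- 0.1 * g + rnorm(j, 0, 0.005)
  r <- random_corr(j)
  rsid <- paste0("rs", 1:j)
  ld <- ld_matrix(r, rsid)
  h <- make_harmonized(rsid, g, 0.02, G, 0.01)
  est <- correlated_ivw(h, ld)

  # multiplying exposure betas by c divides the slope by c
  h2 <- h; h2$beta_exp <- h$beta_exp * 4; h2$se_exp <- h$se_exp * 4
  est2 <- correlated_ivw(h2, ld)
  expect_equal(est2$beta, est$beta / 4, tolerance = 1e-12)
  expect_equal(est2$se, est$se / 4, tolerance = 1e-12)

  # flipping a variant's alleles (both betas) with its LD row/column sign
  flip <- c(2, 4)
  h3 <- h
  h3$beta_exp[flip] <- -h3$beta_exp[flip]
  h3$beta_out[flip] <- -h3$beta_out[flip]
  est3 <- correlated_ivw(h3, align_ld_signs(ld, rsid[flip]))
  expect_equal(est3$beta, est$beta, tolerance = 1e-12)
  expect_equal(est3$se, est$se, tolerance = 1e-12)
})

test_that("phi floors at 1 under homogeneity and inflates under dispersion", {
  # exactly proportional: q = 0, phi = 1
  g <- c(0.2, 0.15, 0.1)
  h <- make_harmonized(paste0("rs", 1:3), g, 0.02, 0.1 * g, 0.01)
  est <- correlated_ivw(h, ld_matrix(diag(3), h$rsid))
  expect_equal(est$q, 0, tolerance = 1e-20)
  expect_equal(est$phi, 1)

  # a gross outlier inflates phi and widens the interval
  ho <- h; ho$beta_out[3] <- 0.1
  esto <- correlated_ivw(ho, ld_matrix(diag(3), h$rsid))
  expect_gt(esto$phi, 1)
  expect_gt(esto$se, est$se)
  expect_equal(esto$phi, max(1, esto$q / 2))
})

test_that("leave-one-out isolates a planted outlier", {
  g <- c(0.2, 0.18, 0.15, 0.12)
  G <- 0.1 * g
  G[2] <- 0.1 * g[2] + 0.03            # planted direct effect
  h <- make_harmonized(paste0("rs", 1:4), g, 0.02, G, 0.01)
  ld <- ld_matrix(diag(4), h$rsid)
  full <- correlated_ivw(h, ld)
  loo <- leave_one_out(h, ld)
  expect_length(loo, 4)
  # omitting the outlier lands exactly on the common ratio of the rest
  expect_equal(loo[["rs2"]]$beta, 0.1, tolerance = 1e-10)
  expect_lt(abs(loo[["rs2"]]$beta - 0.1), abs(full$beta - 0.1))
  # omitting a clean variant keeps the estimate pulled by the outlier
  expect_gt(abs(loo[["rs1"]]$beta - 0.1), abs(loo[["rs2"]]$beta - 0.1))

  # two variants: each result equals the retained variant's Wald ratio
  h2 <- h[1:2, ]
  loo2 <- leave_one_out(h2, ld)
  expect_equal(loo2[["rs1"]]$beta, wald_ratio(h2[2, ])$theta)
  expect_equal(loo2[["rs2"]]$beta, wald_ratio(h2[1, ])$theta)
  expect_error(leave_one_out(h[1, ], ld), "at least 2")
})

test_that("per-gene estimates expose between-region heterogeneity", {
  g <- c(0.2, 0.15, 0.18, 0.12)
  region <- c("CYP1A2", "CYP1A2", "AHR", "AHR")
  # both regions share the true slope: I2 = 0
  h0 <- make_harmonized(paste0("rs", 1:4), g, 0.02, 0.1 * g, 0.01,
                        region = region)
  ld <- ld_matrix(diag(4), h0$rsid)
  pg0 <- per_gene_estimates(h0, ld)
  expect_named(pg0$estimates, c("CYP1A2", "AHR"))
  expect_equal(pg0$het$i2, 0)
  expect_equal(pg0$estimates$CYP1A2$beta, 0.1, tolerance = 1e-10)

  # one region's slope offset by a constant: Q grows
  G1 <- 0.1 * g
  G1[region == "AHR"] <- 0.25 * g[region == "AHR"]
  h1 <- make_harmonized(paste0("rs", 1:4), g, 0.02, G1, 0.01,
                        region = region)
  pg1 <- per_gene_estimates(h1, ld)
  expect_gt(pg1$het$q, 0)
  expect_gt(pg1$het$q, pg0$het$q)

  hsolo <- make_harmonized(paste0("rs", 1:2), g[1:2], 0.02, 0.1 * g[1:2],
                           0.01, region = "CYP1A2")
  expect_error(per_gene_estimates(hsolo, ld), ">= 2 regions")
})

test_that("lead-variant analysis restricts the estimator and loses precision", {
  set.seed(61)
  j <- 6
  g <- runif(j, 0.08, 0.2)
  G <- 0.1 * g + rnorm(j, 0, 0.002)
  rsid <- paste0("rs", 1:j)
  r <- 0.6^abs(outer(1:j, 1:j, "-"))
  ld <- ld_matrix(r, rsid)
  h <- make_harmonized(rsid, g, 0.02, G, 0.01)

  # leads = all variants reproduces the full estimate
  all_leads <- lead_snp_analysis(h, ld, rsid)
  full <- correlated_ivw(h, ld)
  expect_equal(all_leads$beta, full$beta, tolerance = 1e-12)

  # two uncorrelated leads equal the independent 2-variant IVW
  ld_ind <- ld_matrix(diag(j), rsid)
  two_ind <- lead_snp_analysis(h, ld_ind, c("rs1", "rs4"))
  want <- oracle_ivw_independent(g[c(1, 4)], G[c(1, 4)], rep(0.01, 2))
  expect_equal(two_ind$beta, want$beta, tolerance = 1e-10)

  # under the same LD, fewer instruments cannot beat the full base precision
  two <- lead_snp_analysis(h, ld, c("rs1", "rs4"))
  expect_gte(two$se / sqrt(two$phi), full$se / sqrt(full$phi))
  expect_error(lead_snp_analysis(h, ld, "rs99"), "absent")
})
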