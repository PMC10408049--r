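test_that("region selection applies the p threshold and inclusive flanked bounds", {
  regions <- caffeine_regions()   # CYP1A2 15:75041185-75048543, AHR 7:17338246-17385776
  s <- make_set(c("rs_in", "rs_wrongchr", "rs_edge", "rs_weak", "rs_ahr"),
                beta = c(0.1, 0.1, 0.1, 0.01, 0.1), se = 0.02,
                chrom = c("15", "1", "15", "15", "7"),
                pos = c(75000000, 75000000, 75041185 - 1e5, 75045000, 17350000),
                pval = c(1e-6, 1e-6, 1e-6, 0.2, 1e-7))
  out <- select_region_snps(s, regions)
  # inside the flanked window with strong p: kept and assigned
  expect_true("rs_in" %in% out$rsid)
  expect_equal(out$region[out$rsid == "rs_in"], "CYP1A2")
  # wrong chromosome is excluded regardless of p
  expect_false("rs_wrongchr" %in% out$rsid)
  # boundary position start - flank is inside (inclusive)
  expect_true("rs_edge" %in% out$rsid)
  # below-threshold association is excluded
  expect_false("rs_weak" %in% out$rsid)
  expect_equal(out$region[out$rsid == "rs_ahr"], "AHR")
  # the pre-threshold region count feeds FIQT's m_total
  expect_equal(attr(out, "n_region_variants"), 4L)

  expect_error(select_region_snps(s, list(gene_region("X", "22", 1, 2, 0))),
               "no variants pass")
})

test_that("selection with zero flank is a subset of selection with 100 kb flank", {
  set.seed(11)
  n <- 200
  p <- runif(n)^4
  s <- make_set(paste0("rs", 1:n),
                beta = qnorm(p / 2, lower.tail = FALSE) * 0.02, se = 0.02,
                chrom = "15", pos = round(runif(n, 74.8e6, 75.3e6)),
                pval = p)
  narrow <- try(select_region_snps(s, caffeine_regions(flank = 0)), silent = TRUE)
  wide <- select_region_snps(s, caffeine_regions(flank = 1e5))
  if (!inherits(narrow, "try-error")) {
    expect_true(all(narrow$rsid %in% wide$rsid))
  }
  expect_gt(nrow(wide), 0)
})

test_that("clumping keeps the strongest variant of each correlated group", {
  zp <- function(p) qnorm(p / 2, lower.tail = FALSE) * 0.02

  # single variant passes through
  s1 <- make_set("rs1", zp(1e-8), 0.02, pval = 1e-8)
  ld1 <- ld_matrix(diag(1), "rs1")
  expect_equal(clump(s1, ld1)$rsid, "rs1")

  # perfectly correlated pair: smaller p wins
  s2 <- make_set(c("rsA", "rsB"), zp(c(1e-8, 1e-6)), 0.02,
                 pval = c(1e-8, 1e-6))
  r2 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(clump(s2, ld_matrix(r2, c("rsA", "rsB")))$rsid, "rsA")

  # worked three-variant case: A removes B (r2 = 0.5), C survives (r2 = 0.1)
  s3 <- make_set(c("rsA", "rsB", "rsC"), zp(c(1e-8, 1e-6, 1e-5)), 0.02,
                 pval = c(1e-8, 1e-6, 1e-5))
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.5)
  r[1, 3] <- r[3, 1] <- sqrt(0.1)
  r[2, 3] <- r[3, 2] <- sqrt(0.2)
  out <- clump(s3, ld_matrix(r, c("rsA", "rsB", "rsC")))
  expect_equal(out$rsid, c("rsA", "rsC"))

  # distance window: correlated variants beyond the window both survive
  s4 <- make_set(c("rsA", "rsB"), zp(c(1e-8, 1e-6)), 0.02,
                 pos = c(1, 2e7), pval = c(1e-8, 1e-6))
  expect_equal(nrow(clump(s4, ld_matrix(r2, c("rsA", "rsB")))), 2L)

  expect_error(clump(s2, ld1), "absent from LD matrix")
})

test_that("clumping matches the exhaustive greedy oracle on random instances", {
  set.seed(202)
  for (i in 1:150) {
    n <- sample(2:8, 1)
    rsid <- paste0("rs", sample(100:999, n))
    pval <- round(runif(n)^3, sample(2:6, 1))  # rounding provokes p ties
    pos <- sort(sample(1:20000, n)) * 1000
    r <- random_corr(n)
    ld <- ld_matrix(r, rsid)
    cfg <- selection_config(clump_r2 = runif(1, 0.05, 0.9),
                            clump_window_kb = sample(c(100, 5000, 10000), 1))
    pval <- pmax(pval, 1e-12)
    z <- qnorm(pval / 2, lower.tail = FALSE) * sample(c(-1, 1), n, TRUE)
    s <- make_set(rsid, beta = z * 0.02, se = 0.02,
                  pos = pos, pval = pval)
    got <- clump(s, ld, cfg)
    want <- oracle_clump(s$rsid, s$pval, s$chrom, s$pos, unclass(ld)^2,
                         cfg$clump_r2, cfg$clump_window_kb * 1000)
    expect_equal(got$rsid, s$rsid[want])
    # no retained pair in LD above the cutoff within the window
    if (nrow(got) > 1) {
      rr <- unclass(ld)[got$rsid, got$rsid]^2
      dd <- abs(outer(got$pos, got$pos, "-")) <= cfg$clump_window_kb * 1000
      offdiag <- upper.tri(rr)
      expect_false(any(rr[offdiag] > cfg$clump_r2 & dd[offdiag]))
    }
  }
})

test_that("FIQT shrinks selected effect estimates toward zero", {
  # worked two-variant case: z = 4 and z = 2 with m = 2 tests
  z <- c(4, 2)
  s <- make_set(c("rs1", "rs2"), beta = z * 0.02, se = 0.02)
  adj <- fiqt_adjust(s, m_total = 2)
  expect_equal(adj$beta / adj$se, c(3.8328, 2.0000), tolerance = 1e-4)
  expect_equal(adj$beta_raw, z * 0.02)

  # single variant with m_total = 1: BH leaves p intact, beta unchanged
  s1 <- make_set("rs1", beta = 0.08, se = 0.02)
  expect_equal(fiqt_adjust(s1, m_total = 1)$beta, 0.08, tolerance = 1e-12)

  # zero effect stays zero
  s0 <- make_set("rs0", beta = 0, se = 0.02, pval = 1)
  expect_warning(a0 <- fiqt_adjust(s0, m_total = 1), "adjusted p >= 1")
  expect_equal(a0$beta, 0)

  # shrinkage and rank preservation on random draws
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    beta <- rnorm(n, 0, 0.1)
    s <- make_set(paste0("rs", 1:n), beta = beta, se = 0.02)
    a <- suppressWarnings(fiqt_adjust(s, m_total = n + sample(0:20, 1)))
    expect_true(all(abs(a$beta) <= abs(a$beta_raw) + 1e-12))
    # |z| order preserved weakly (BH step-up can tie neighbours)
    z_adj_sorted <- abs(a$beta / a$se)[order(abs(beta / 0.02))]
    expect_true(all(diff(z_adj_sorted) >= -1e-12))
  }

  expect_error(fiqt_adjust(s, m_total = 1), "smaller than the number")
})

test_that("FIQT counters selection-induced inflation under the null", {
  # null effects selected for significance overshoot zero; FIQT pulls back
  set.seed(99)
  raw_sel <- c(); adj_sel <- c()
  for (i in 1:100) {
    z <- rnorm(5000)
    p <- 2 * pnorm(-abs(z))
    sel <- p < 5e-5
    if (!any(sel)) next
    s <- make_set(paste0("rs", which(sel)), beta = z[sel] * 0.02, se = 0.02,
                  pval = p[sel])
    a <- suppressWarnings(fiqt_adjust(s, m_total = 5000))
    raw_sel <- c(raw_sel, abs(a$beta_raw))
    adj_sel <- c(adj_sel, abs(a$beta))
  }
  expect_gt(length(raw_sel), 10)
  expect_lt(mean(adj_sel), mean(raw_sel))
})

test_that("instrument strength decorrelates z-scores through the LD matrix", {
  # independent variants: mean F is the mean squared z
  s <- make_set(c("rs1", "rs2"), beta = c(0.04, 0.04), se = 0.02)
  expect_equal(instrument_strength(s, ld_matrix(diag(2), c("rs1", "rs2")))$mean_f, 4)

  # correlated pair, z = (3, 3), r = 0.5: quadratic form gives 6
  s2 <- make_set(c("rs1", "rs2"), beta = c(0.06, 0.06), se = 0.02)
  r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  rep2 <- instrument_strength(s2, ld_matrix(r, c("rs1", "rs2")))
  expect_equal(rep2$mean_f, 6)
  expect_equal(rep2$approx_relative_bias, 1 / 6)

  # plain method ignores LD
  expect_equal(instrument_strength(s2, method = "plain")$mean_f, 9)
})
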