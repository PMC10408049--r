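# fixture builders and independent oracles shared across the suite

make_set <- function(rsid, beta, se,
                     chrom = "1", pos = seq_along(rsid) * 1000,
                     ea = "C", oa = "T", eaf = 0.3,
                     pval = 2 * pnorm(-abs(beta / se)),
                     n = 1000, trait = "trait",
                     trait_type = "continuous", source = NULL) {
  summary_set(data.frame(rsid = rsid, chrom = chrom, pos = pos,
                         ea = ea, oa = oa, eaf = eaf,
                         beta = beta, se = se, pval = pval, n = n,
                         stringsAsFactors = FALSE),
              trait = trait, trait_type = trait_type, source = source)
}

# harmonized set built directly, bypassing allele logic, for estimator tests
make_harmonized <- function(rsid, beta_exp, se_exp, beta_out, se_out,
                            region = NA_character_) {
  structure(data.frame(rsid = rsid, chrom = "1",
                       pos = seq_along(rsid) * 1000,
                       ea = "C", oa = "T", eaf = 0.3,
                       region = region,
                       beta_exp = beta_exp, se_exp = se_exp,
                       pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
                       beta_exp_raw = beta_exp,
                       beta_out = beta_out, se_out = se_out,
                       pval_out = 2 * pnorm(-abs(beta_out / se_out)),
                       eaf_out = 0.3, n_out = NA_real_,
                       source_out = "test",
                       stringsAsFactors = FALSE),
            exclusions = data.frame(rsid = character(),
                                    reason = character()),
            class = c("harmonized_set", "data.frame"))
}

# random positive-definite correlation matrix (via random factor loading)
random_corr <- function(n) {
  a <- matrix(rnorm(n * (n + 2)), n, n + 2)
  s <- tcrossprod(a) + diag(n) * 0.1
  d <- sqrt(diag(s))
  s / outer(d, d)
}

# --- independent oracles ----------------------------------------------------

# textbook IVW of Wald ratios with first-order weights (independent variants)
oracle_ivw_independent <- function(g, G, se_out) {
  theta <- G / g
  w <- (g / se_out)^2          # 1 / se_theta^2
  beta <- sum(w * theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(beta = beta, se = se)
}

# exhaustive greedy clumping: at each step scan every remaining variant for
# the current p-minimum (rsid tie-break), then remove its LD partners
oracle_clump <- function(rsid, pval, chrom, pos, r2, clump_r2, window_bp) {
  remaining <- seq_along(rsid)
  kept <- integer()
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    for (i in remaining) {
      if (pval[i] < pval[best] ||
          (pval[i] == pval[best] && rsid[i] < rsid[best])) best <- i
    }
    kept <- c(kept, best)
    drop <- best
    for (i in setdiff(remaining, best)) {
      if (chrom[i] == chrom[best] &&
          abs(pos[i] - pos[best]) <= window_bp &&
          r2[i, best] > clump_r2) drop <- c(drop, i)
    }
    remaining <- setdiff(remaining, drop)
  }
  sort(kept)
}

# step-up BH from its definition: p_adj(i) = min_{j >= rank_i} p(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    candidates <- vapply(k:m, function(j) p[ord[j]] * m / j, numeric(1))
    adj[ord[k]] <- min(1, candidates)
  }
  adj
}

# two-pass Pearson correlation for all variant pairs of a dosage matrix
oracle_pearson_all <- function(d) {
  n <- nrow(d)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- d[i, ]; y <- d[j, ]
      xc <- x - mean(x); yc <- y - mean(y)
      out[i, j] <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
    }
  }
  out
}

# textbook DerSimonian-Laird random-effects pool
oracle_dl <- function(b, s) {
  w <- 1 / s^2
  pooled <- sum(w * b) / sum(w)
  q <- sum(w * (b - pooled)^2)
  df <- length(b) - 1
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (s^2 + tau2)
  list(beta = sum(ws * b) / sum(ws), se = 1 / sqrt(sum(ws)), tau2 = tau2)
}
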